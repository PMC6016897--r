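test_that("cusp meshes sit on the cylinder and approximate the area", {
  cusp <- paper_cusp()
  mesh <- cusp_mesh(cusp, 64, 32)
  r2 <- mesh$vertices[, 1L]^2 + mesh$vertices[, 2L]^2
  expect_equal(r2, rep(cusp$radius^2, length(r2)), tolerance = 1e-9)
  expect_equal(mesh_area(mesh), 2 * 14.20 * 20.211 / pi, tolerance = 0.01)
  # no degenerate faces after commissure cleanup
  areas <- valvegeom:::face_areas(mesh$vertices, mesh$faces)
  expect_true(all(areas > 0))
  # outward winding: all face normals have nonnegative radial component
  nrm <- valvegeom:::facet_normals(mesh)
  centroid <- (mesh$vertices[mesh$faces[, 1L], ] +
                 mesh$vertices[mesh$faces[, 2L], ] +
                 mesh$vertices[mesh$faces[, 3L], ]) / 3
  radial <- nrm[, 1L] * centroid[, 1L] + nrm[, 2L] * centroid[, 2L]
  expect_true(all(radial > -1e-12))
})

test_that("minimal resolution still yields a valid mesh", {
  cusp <- paper_cusp()
  mesh <- cusp_mesh(cusp, 2, 1)
  expect_gte(nrow(mesh$faces), 1L)
  r2 <- mesh$vertices[, 1L]^2 + mesh$vertices[, 2L]^2
  expect_equal(r2, rep(cusp$radius^2, length(r2)), tolerance = 1e-9)
  expect_error(cusp_mesh(paper_cusp(), 1, 1), "n_theta")
  expect_error(cusp_mesh(paper_cusp(), 8, 0), "n_z")
})

test_that("rotation about the valve axis is a rigid motion", {
  mesh <- cusp_mesh(paper_cusp(), 16, 8)
  expect_equal(rotate_mesh(mesh, 0)$vertices, mesh$vertices)
  expect_equal(rotate_mesh(mesh, 2 * pi)$vertices, mesh$vertices,
               tolerance = 1e-12)
  thrice <- rotate_mesh(rotate_mesh(rotate_mesh(mesh, 2 * pi / 3),
                                    2 * pi / 3), 2 * pi / 3)
  expect_equal(thrice$vertices, mesh$vertices, tolerance = 1e-12)
  rot <- rotate_mesh(mesh, 1.234)
  expect_equal(rot$vertices[, 3L], mesh$vertices[, 3L])
  # pairwise distances preserved (spot check on a subset)
  idx <- seq(1L, nrow(mesh$vertices), by = 37L)
  expect_equal(as.vector(dist(mesh$vertices[idx, ])),
               as.vector(dist(rot$vertices[idx, ])), tolerance = 1e-12)
  expect_equal(mesh_area(rot), mesh_area(mesh), tolerance = 1e-12)
})

test_that("the assembled valve is three rotated copies of one cusp", {
  cusp <- paper_cusp()
  single <- cusp_mesh(cusp, 32, 16)
  valve <- assemble_valve(cusp, 32, 16)
  expect_equal(mesh_area(valve), 3 * mesh_area(single), tolerance = 1e-9)
  # commissure seams deduplicated: no coincident vertex pairs remain
  key <- apply(round(valve$vertices, 9L), 1L, paste, collapse = ",")
  expect_false(any(duplicated(key)))
  expect_lt(nrow(valve$vertices), 3L * nrow(single$vertices))
  # three-fold symmetry as a point set
  rot <- rotate_mesh(valve, 2 * pi / 3)
  expect_lt(max_pointset_dist(valve$vertices, rot$vertices), 1e-9)
})

test_that("meshes round-trip through every supported format", {
  meshes <- list(random = random_mesh(12L),
                 cusp = cusp_mesh(paper_cusp(), 8, 4))
  for (mesh in meshes) {
    dir <- withr::local_tempdir()
    # indexed ASCII formats: exact topology, near-exact coordinates
    for (fmt in c("obj", "ply", "vtk-legacy")) {
      path <- file.path(dir, paste0("m.", sub("-.*", "", fmt)))
      write_mesh(mesh, path, fmt)
      back <- read_mesh(path, fmt)
      expect_identical(back$faces, mesh$faces)
      expect_equal(back$vertices, mesh$vertices, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
    # STL: triangle soup, binary exact to float32, ascii to %.9e
    for (fmt in c("stl-binary", "stl-ascii")) {
      path <- file.path(dir, paste0(gsub("-", "_", fmt), ".stl"))
      write_mesh(mesh, path, fmt)
      back <- read_mesh(path)
      expect_equal(nrow(back$faces), nrow(mesh$faces))
      soup <- mesh$vertices[t(mesh$faces), ]
      expect_equal(back$vertices, soup, tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("format details follow each specification", {
  mesh <- valve_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  dir <- withr::local_tempdir()
  obj <- file.path(dir, "two.obj")
  write_mesh(mesh, obj, "obj")
  lines <- readLines(obj)
  expect_length(grep("^v ", lines), 4L)
  expect_length(grep("^f ", lines), 2L)
  expect_true("f 1 2 3" %in% lines)   # 1-based on disk

  vtk <- file.path(dir, "two.vtk")
  write_mesh(mesh, vtk, "vtk-legacy")
  expect_match(readLines(vtk, n = 1L), "^# vtk DataFile Version")

  ply <- file.path(dir, "two.ply")
  write_mesh(mesh, ply, "ply")
  expect_identical(readLines(ply, n = 1L), "ply")
  expect_true("3 0 1 2" %in% readLines(ply))  # 0-based on disk

  expect_error(write_mesh(mesh, file.path(dir, "two.xyz")), "extension")
  expect_error(valve_mesh(mesh$vertices, rbind(c(1L, 2L, 9L))),
               "out of range")
})
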