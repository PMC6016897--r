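test_that("radius derives from width by the arc-length relation", {
  expect_equal(radius_from_width(20.211, 3), 9.65, tolerance = 5e-4)
  expect_equal(radius_from_width(2 * pi, 2), 2, tolerance = 1e-12)
  expect_equal(radius_from_width(15, 3), 15 * 3 / (2 * pi),
               tolerance = 1e-12)
  # round trip: one cusp arc at the derived radius has length = width
  r <- radius_from_width(17.3, 4)
  expect_equal(r * 2 * pi / 4, 17.3, tolerance = 1e-12)
  expect_error(radius_from_width(-1, 3), "positive")
  expect_error(radius_from_width(10, 1), "n_cusps")
})

test_that("cusp construction yields the published parameterization", {
  cusp <- paper_cusp()
  expect_equal(cusp$radius, 9.65, tolerance = 5e-4)
  expect_equal(cusp$max_height, 14.20)
  expect_equal(cusp$angular_extent, 2 * pi / 3)
  expect_equal(cusp$wavenumber, 1.5)
  # the published wavenumber factor is n/2 rounded through the printed width
  expect_equal(cusp$wavenumber, 9650 * pi / 20211, tolerance = 5e-5)

  other <- pv_cusp(10, 5, 4)
  expect_equal(other$radius, 10 * 4 / (2 * pi), tolerance = 1e-12)
  expect_equal(other$angular_extent, pi / 2)
  expect_equal(other$wavenumber, 2)
  expect_error(pv_cusp(10, -2, 3), "max_height")
})

test_that("the free edge pins at the commissures for any construction", {
  for (cusp in random_cusps(20)) {
    expect_equal(cusp$wavenumber * cusp$angular_extent, pi,
                 tolerance = 1e-12)
    expect_equal(boundary_height(cusp, 0), 0)
    expect_equal(boundary_height(cusp, cusp$angular_extent), 0,
                 tolerance = 1e-12 * cusp$max_height)
    expect_equal(boundary_height(cusp, cusp$angular_extent / 2),
                 cusp$max_height, tolerance = 1e-12)
  }
})

test_that("boundary height matches the sine model and is symmetric", {
  cusp <- paper_cusp()
  expect_equal(boundary_height(cusp, pi / 3), 14.20)
  expect_equal(boundary_height(cusp, 0), 0)
  # published wavenumber evaluated independently: 14.2 sin(9650pi/20211 * pi/6)
  expect_equal(boundary_height(cusp, pi / 6),
               14.2 * sin(9650 * pi / 20211 * pi / 6), tolerance = 1e-4)
  theta <- seq(0, cusp$angular_extent, length.out = 41L)
  expect_equal(boundary_height(cusp, theta),
               boundary_height(cusp, cusp$angular_extent - theta),
               tolerance = 1e-12)
  expect_true(all(boundary_height(cusp, theta) >= 0))
  expect_error(boundary_height(cusp, -0.1), "domain")
  expect_error(boundary_height(cusp, cusp$angular_extent + 0.1), "domain")
})

test_that("surface points realize the cylindrical-shell equation", {
  cusp <- paper_cusp()
  expect_equal(unname(surface_point(cusp, 0, 0.7)),
               matrix(c(9.65, 0, 0), nrow = 1L), tolerance = 5e-4)
  apex <- surface_point(cusp, pi / 3, 1)
  expect_equal(unname(apex[1, ]),
               c(9.65 * cos(pi / 3), 9.65 * sin(pi / 3), 14.20),
               tolerance = 5e-4)
  for (cusp in random_cusps(10, seed = 3L)) {
    theta <- runif(25, 0, cusp$angular_extent)
    zf <- runif(25)
    p <- surface_point(cusp, theta, zf)
    expect_equal(p[, 1L]^2 + p[, 2L]^2, rep(cusp$radius^2, 25L),
                 tolerance = 1e-9)
  }
  expect_error(surface_point(cusp, 0.1, 1.5), "zfrac")
})

test_that("flattening is the isometric development x = r*theta", {
  cusp <- paper_cusp()
  far <- flatten(cusp, cusp$angular_extent, 0)
  expect_equal(far[1, "x"], c(x = 20.211), tolerance = 5e-5)
  expect_equal(unname(flatten(cusp, 0, 3.2)[1, ]), c(0, 3.2))
  expect_equal(flatten(cusp, pi / 3, 7)[1, "x"], c(x = 9.65 * pi / 3),
               tolerance = 5e-4)
  # matches the published fitted peak abscissa W/2 = 10.1055
  expect_equal(flatten(cusp, cusp$angular_extent / 2)[1, "x"],
               c(x = 10.1055), tolerance = 1e-4)
  for (cusp in random_cusps(10, seed = 11L)) {
    theta <- runif(20, 0, cusp$angular_extent)
    z <- runif(20, 0, cusp$max_height)
    flat <- flatten(cusp, theta, z)
    back <- unflatten(cusp, flat[, "x"], flat[, "z"])
    expect_equal(back[, "theta"], theta, tolerance = 1e-12)
    expect_equal(back[, "z"], z, tolerance = 1e-12)
    # the full development spans the cusp's share of the circumference
    expect_equal(unname(flatten(cusp, cusp$angular_extent)[1, "x"]) *
                   cusp$n_cusps,
                 2 * pi * cusp$radius, tolerance = 1e-12)
  }
})

test_that("cusp methods print, summarize and predict", {
  cusp <- paper_cusp()
  expect_output(print(cusp), "radius")
  expect_named(coef(cusp)["radius"], "radius")
  expect_equal(predict(cusp, pi / 3), 14.20)
  pdf(NULL)
  on.exit(dev.off())
  flat <- plot(cusp, n = 50L)
  expect_equal(nrow(flat), 50L)
})
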