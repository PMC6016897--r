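#' Write a mesh to a standard surface format
#'
#' Supported formats: `"stl-binary"` and `"stl-ascii"` (triangle soup, no
#' shared vertices, per the STL definition; binary stores float32),
#' `"obj"` (Wavefront, 1-based indices on disk), `"ply"` (ASCII PLY with
#' double-precision vertices) and `"vtk-legacy"` (legacy VTK POLYDATA).
#' Output is written to a temporary file and renamed into place, so a
#' failure never leaves a partial file.
#'
#' @param mesh A [valve_mesh()] object.
#' @param path Output file path.
#' @param format One of `"stl-binary"`, `"stl-ascii"`, `"obj"`, `"ply"`,
#'   `"vtk-legacy"`. Default guesses from the file extension
#'   (`.stl` = binary STL).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "stl-binary", "stl-ascii", "obj",
                                  "ply", "vtk-legacy")) {
  stopifnot(inherits(mesh, "valve_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     stl = "stl-binary", obj = "obj", ply = "ply",
                     vtk = "vtk-legacy",
                     stop("cannot infer mesh format from extension '.",
                          ext, "'"))
  }
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  switch(format,
         "stl-binary" = write_stl_binary(mesh, tmp),
         "stl-ascii" = write_stl_ascii(mesh, tmp),
         "obj" = write_obj(mesh, tmp),
         "ply" = write_ply(mesh, tmp),
         "vtk-legacy" = write_vtk(mesh, tmp))
  file.rename(tmp, path)
  invisible(path)
}

# unit facet normals, one per face (outward by the mesh winding convention)
facet_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  nrm <- facet_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  # per facet: normal, v1, v2, v3 as float32, then a zero uint16 attribute
  block <- cbind(nrm,
                 v[f[, 1L], , drop = FALSE],
                 v[f[, 2L], , drop = FALSE],
                 v[f[, 3L], , drop = FALSE])
  floats <- writeBin(as.numeric(t(block)), raw(), size = 4L,
                     endian = "little")
  rec <- matrix(as.raw(0L), nrow = 50L, ncol = nf)
  rec[1:48, ] <- matrix(floats, nrow = 48L)
  writeBin(as.vector(rec), con)
}

write_stl_ascii <- function(mesh, path) {
  nrm <- facet_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  out <- c("solid valvegeom",
           unlist(lapply(seq_len(nrow(f)), function(i) {
             c(sprintf("facet normal %.9e %.9e %.9e",
                       nrm[i, 1L], nrm[i, 2L], nrm[i, 3L]),
               "  outer loop",
               sprintf("    vertex %.9e %.9e %.9e",
                       v[f[i, ], 1L], v[f[i, ], 2L], v[f[i, ], 3L]),
               "  endloop",
               "endfacet")
           })),
           "endsolid valvegeom")
  writeLines(out, path)
}

write_obj <- function(mesh, path) {
  out <- c("# valvegeom surface mesh",
           sprintf("v %.12g %.12g %.12g",
                   mesh$vertices[, 1L], mesh$vertices[, 2L],
                   mesh$vertices[, 3L]),
           sprintf("f %d %d %d",
                   mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]))
  writeLines(out, path)
}

write_ply <- function(mesh, path) {
  out <- c("ply",
           "format ascii 1.0",
           "comment valvegeom surface mesh",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices",
           "end_header",
           sprintf("%.17g %.17g %.17g",
                   mesh$vertices[, 1L], mesh$vertices[, 2L],
                   mesh$vertices[, 3L]),
           sprintf("3 %d %d %d",
                   mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L))
  writeLines(out, path)
}

write_vtk <- function(mesh, path) {
  nf <- nrow(mesh$faces)
  out <- c("# vtk DataFile Version 3.0",
           "valvegeom surface mesh",
           "ASCII",
           "DATASET POLYDATA",
           sprintf("POINTS %d double", nrow(mesh$vertices)),
           sprintf("%.17g %.17g %.17g",
                   mesh$vertices[, 1L], mesh$vertices[, 2L],
                   mesh$vertices[, 3L]),
           sprintf("POLYGONS %d %d", nf, 4L * nf),
           sprintf("3 %d %d %d",
                   mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L))
  writeLines(out, path)
}

#' Read a mesh written by [write_mesh()]
#'
#' Round-trip reader for the supported formats. STL (a triangle soup)
#' returns three unshared vertices per face; indexed formats return the
#' original topology.
#'
#' @param path Mesh file path.
#' @param format As [write_mesh()]; `"auto"` infers from the extension, and
#'   for `.stl` detects ASCII vs binary from the file content.
#' @return A [valve_mesh()] object.
#' @export
read_mesh <- function(path,
                      format = c("auto", "stl-binary", "stl-ascii", "obj",
                                 "ply", "vtk-legacy")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     stl = sniff_stl(path), obj = "obj", ply = "ply",
                     vtk = "vtk-legacy",
                     stop("cannot infer mesh format from extension '.",
                          ext, "'"))
  }
  switch(format,
         "stl-binary" = read_stl_binary(path),
         "stl-ascii" = read_stl_ascii(path),
         "obj" = read_obj(path),
         "ply" = read_ply(path),
         "vtk-legacy" = read_vtk(path))
}

sniff_stl <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  txt <- rawToChar(head[head >= as.raw(0x09) & head <= as.raw(0x7e)])
  if (startsWith(txt, "solid") && grepl("facet", txt)) "stl-ascii"
  else "stl-binary"
}

soup_to_mesh <- function(tri) {
  # tri: (3*nf) x 3 matrix of facet vertices in order
  nf <- nrow(tri) %/% 3L
  valve_mesh(tri, matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  body <- readBin(con, "raw", n = 50L * nf)
  rec <- matrix(body, nrow = 50L)
  floats <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                    n = 12L * nf, size = 4L, endian = "little")
  per_face <- matrix(floats, nrow = 12L)  # normal + 3 vertices per column
  tri <- matrix(as.vector(per_face[4:12, , drop = FALSE]), ncol = 3L,
                byrow = TRUE)
  soup_to_mesh(tri)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "vertex")]
  tri <- do.call(rbind, lapply(strsplit(vl, "[ \t]+"), function(f)
    as.numeric(f[2:4])))
  soup_to_mesh(tri)
}

read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(vl, "[ \t]+"), function(f)
    as.numeric(f[2:4])))
  f <- do.call(rbind, lapply(strsplit(fl, "[ \t]+"), function(x)
    as.integer(sub("/.*$", "", x[2:4]))))
  valve_mesh(v, f)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(lines == "end_header")[1L]
  if (is.na(end)) stop("not a PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1L]))
  body <- lines[(end + 1L):length(lines)]
  v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "[ \t]+"),
                             function(f) as.numeric(f[1:3])))
  f <- do.call(rbind,
               lapply(strsplit(trimws(body[nv + seq_len(nf)]), "[ \t]+"),
                      function(x) as.integer(x[2:4]) + 1L))
  valve_mesh(v, f)
}

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS ", lines)[1L]
  nv <- as.integer(strsplit(lines[ip], "[ \t]+")[[1L]][2L])
  v <- do.call(rbind, lapply(strsplit(trimws(lines[ip + seq_len(nv)]),
                                      "[ \t]+"),
                             function(f) as.numeric(f[1:3])))
  if_ <- grep("^POLYGONS ", lines)[1L]
  nf <- as.integer(strsplit(lines[if_], "[ \t]+")[[1L]][2L])
  f <- do.call(rbind,
               lapply(strsplit(trimws(lines[if_ + seq_len(nf)]), "[ \t]+"),
                      function(x) as.integer(x[2:4]) + 1L))
  valve_mesh(v, f)
}
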