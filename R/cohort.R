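#' Published per-cusp morphometric distribution
#'
#' Mean and standard deviation of width and height (mm) for the left, right
#' and anterior cusps of the human pulmonary valve, from published cadaveric
#' morphometry, shipped as a plain-text fixture. These are the default
#' population parameters for [sample_cohort()].
#'
#' @return A data frame with columns `cusp`, `width_mean`, `width_sd`,
#'   `height_mean`, `height_sd`.
#' @export
pulmonary_morphometry <- function() {
  path <- system.file("extdata", "cusp_morphometry.csv",
                      package = "valvegeom", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

check_morphometry <- function(dist) {
  dist <- as.data.frame(dist)
  need <- c("cusp", "width_mean", "width_sd", "height_mean", "height_sd")
  if (!all(need %in% names(dist)))
    stop("morphometric distribution needs columns ",
         paste(need, collapse = ", "))
  if (any(dist$width_mean <= 0) || any(dist$height_mean <= 0))
    stop("morphometric means must be positive")
  if (any(dist$width_sd < 0) || any(dist$height_sd < 0))
    stop("morphometric SDs must be nonnegative")
  dist
}

# normal draws truncated at zero: nonpositive draws are resampled
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Sample a synthetic morphometric cohort
#'
#' Draws `n` independent (width, height) pairs per cusp from normal
#' distributions with the given per-cusp means and SDs, truncated at zero
#' (nonpositive draws are resampled). Width and height are sampled
#' independently; no covariance is modelled.
#'
#' @param dist Per-cusp distribution parameters, as
#'   [pulmonary_morphometry()] (the default).
#' @param n Number of samples per cusp (>= 1).
#' @param seed Integer RNG seed; required so every cohort is reproducible.
#' @return A data frame with columns `cusp`, `width_mm`, `height_mm`
#'   (`n` rows per cusp).
#' @examples
#' cohort <- sample_cohort(n = 5, seed = 1)
#' @export
sample_cohort <- function(dist = pulmonary_morphometry(), n, seed) {
  dist <- check_morphometry(dist)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a positive count")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(nrow(dist)), function(i) {
    data.frame(cusp = dist$cusp[i],
               width_mm = rnorm_pos(n, dist$width_mean[i], dist$width_sd[i]),
               height_mm = rnorm_pos(n, dist$height_mean[i],
                                     dist$height_sd[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Sample a noisy free-edge boundary point cloud
#'
#' Generates synthetic flattened boundary measurements for a cusp: abscissae
#' uniform on `[0, W]`, heights `h*sin(pi*x/W)` plus additive Gaussian noise.
#' The natural input for [fit_sine_boundary()].
#'
#' @param cusp A [pv_cusp()] object.
#' @param n_points Number of points (>= 3).
#' @param noise_sd Noise standard deviation in mm (>= 0).
#' @param seed Integer RNG seed.
#' @return A numeric matrix with columns `x`, `z` (mm).
#' @export
sample_boundary_points <- function(cusp, n_points, noise_sd, seed) {
  stopifnot(inherits(cusp, "pv_cusp"))
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 3)
    stop("`n_points` must be >= 3")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be >= 0")
  n_points <- as.integer(n_points)
  set.seed(as.integer(seed))
  x <- stats::runif(n_points, 0, cusp$width)
  z <- cusp$max_height * sin(pi * x / cusp$width) +
    stats::rnorm(n_points, 0, noise_sd)
  cbind(x = x, z = z)
}

#' Per-sample valve measurements for a cohort
#'
#' Applies the geometric model to every cohort record: each (width, height)
#' pair defines a cusp, and the derived metrics are computed per sample.
#'
#' @param cohort A data frame from [sample_cohort()].
#' @param n_cusps Number of cusps per sampled valve (default 3).
#' @param flap_to_valve_ratio As [valve_measurements()].
#' @return The cohort with columns `radius_mm`, `cusp_area_mm2`,
#'   `annulus_diameter_mm`, `annulus_circumference_mm`, `valve_area_mm2`,
#'   `orifice_area_mm2` appended.
#' @export
measure_cohort <- function(cohort, n_cusps = 3L,
                           flap_to_valve_ratio = 1.55) {
  stopifnot(is.data.frame(cohort),
            all(c("width_mm", "height_mm") %in% names(cohort)))
  n_cusps <- check_n_cusps(n_cusps)
  r <- cohort$width_mm * n_cusps / (2 * pi)
  a <- 2 * cohort$height_mm * cohort$width_mm / pi
  cohort$radius_mm <- r
  cohort$cusp_area_mm2 <- a
  cohort$annulus_diameter_mm <- 2 * r
  cohort$annulus_circumference_mm <- 2 * pi * r
  cohort$valve_area_mm2 <- n_cusps * a
  cohort$orifice_area_mm2 <- n_cusps * a / flap_to_valve_ratio
  cohort
}

#' Write a cohort table to delimited text
#'
#' Comma-separated with a header row; written to a temporary file and
#' renamed into place.
#'
#' @param cohort A data frame ([sample_cohort()] or [measure_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  utils::write.csv(cohort, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
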