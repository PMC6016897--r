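#' Annulus circumference and diameter
#'
#' The annulus (valve ring) of the model is the circle of radius `r` in the
#' z = 0 plane, so its circumference is \eqn{2\pi r = nW} and its diameter
#' \eqn{2r}.
#'
#' @param cusp A [pv_cusp()] object.
#' @return Length in mm.
#' @export
ring_circumference <- function(cusp) {
  stopifnot(inherits(cusp, "pv_cusp"))
  2 * pi * cusp$radius
}

#' @rdname ring_circumference
#' @export
annulus_diameter <- function(cusp) {
  stopifnot(inherits(cusp, "pv_cusp"))
  2 * cusp$radius
}

#' Cusp surface area, closed form
#'
#' The cylinder is developable, so the cusp area equals the flattened area
#' under the sine free edge:
#' \deqn{\int_0^W h \sin(\pi x / W)\, dx = 2 h W / \pi.}
#'
#' @param cusp A [pv_cusp()] object.
#' @return Area in mm^2.
#' @export
cusp_area_closed_form <- function(cusp) {
  stopifnot(inherits(cusp, "pv_cusp"))
  2 * cusp$max_height * cusp$width / pi
}

#' Cusp surface area by mesh quadrature
#'
#' Independent numerical check on [cusp_area_closed_form()]: sums the
#' triangle areas of a structured surface mesh of the cusp. Converges to the
#' closed form at second order in the angular resolution.
#'
#' @param cusp A [pv_cusp()] object.
#' @param n_theta,n_z Grid resolution (angular and height subdivisions).
#' @return Area in mm^2.
#' @export
cusp_area_quadrature <- function(cusp, n_theta = 256L, n_z = 128L) {
  mesh_area(cusp_mesh(cusp, n_theta, n_z))
}

#' Flattened cusp area by 1-D quadrature
#'
#' Integrates the boundary height along the developed arc length,
#' \eqn{\int_0^{2\pi/n} h\sin(k\theta)\, r\, d\theta}, with adaptive
#' quadrature. Because the development is an isometry this equals the 3-D
#' surface area; it serves as a second independent oracle.
#'
#' @param cusp A [pv_cusp()] object.
#' @return Area in mm^2.
#' @export
flat_area_quadrature <- function(cusp) {
  stopifnot(inherits(cusp, "pv_cusp"))
  stats::integrate(function(th) boundary_height(cusp, th) * cusp$radius,
                   0, cusp$angular_extent,
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}

#' Derived valve measurements
#'
#' Computes the scalar metrics of the open-valve model: single-cusp area
#' (closed form), annulus diameter and circumference, total valve area
#' (`n_cusps` times the cusp area), and the orifice ("valve flap") area
#' obtained by dividing the valve area by the literature flap-to-valve area
#' ratio (default 1.55).
#'
#' @param cusp A [pv_cusp()] object.
#' @param flap_to_valve_ratio Positive ratio of valve area to orifice area;
#'   default 1.55 (published cadaveric value).
#' @return An object of class `valve_measurements` with fields `cusp_area`,
#'   `annulus_diameter`, `annulus_circumference`, `valve_area`,
#'   `orifice_area`, `flap_to_valve_ratio`, `n_cusps`.
#' @examples
#' m <- valve_measurements(pv_cusp(20.211, 14.20))
#' m
#' @export
valve_measurements <- function(cusp, flap_to_valve_ratio = 1.55) {
  stopifnot(inherits(cusp, "pv_cusp"))
  if (!is.finite(flap_to_valve_ratio) || flap_to_valve_ratio <= 0)
    stop("`flap_to_valve_ratio` must be positive")
  a <- cusp_area_closed_form(cusp)
  structure(
    list(cusp_area = a,
         annulus_diameter = annulus_diameter(cusp),
         annulus_circumference = ring_circumference(cusp),
         valve_area = cusp$n_cusps * a,
         orifice_area = cusp$n_cusps * a / flap_to_valve_ratio,
         flap_to_valve_ratio = flap_to_valve_ratio,
         n_cusps = cusp$n_cusps),
    class = "valve_measurements")
}

#' @export
print.valve_measurements <- function(x, ...) {
  cat("Valve measurements (", x$n_cusps, " cusps)\n", sep = "")
  cat(sprintf("  cusp area             : %.4f mm^2\n", x$cusp_area))
  cat(sprintf("  annulus diameter      : %.4f mm\n", x$annulus_diameter))
  cat(sprintf("  annulus circumference : %.4f mm\n",
              x$annulus_circumference))
  cat(sprintf("  valve area            : %.4f mm^2\n", x$valve_area))
  cat(sprintf("  orifice area          : %.4f mm^2 (ratio 1:%.2f)\n",
              x$orifice_area, x$flap_to_valve_ratio))
  invisible(x)
}

#' Published cadaveric reference values
#'
#' Mean and standard deviation of the four derived valve metrics measured on
#' cadaveric human pulmonary valves (Yang's series), shipped as a plain-text
#' fixture. Used by [compare_to_reference()].
#'
#' @return A data frame with columns `metric`, `mean`, `sd`.
#' @export
yang_reference <- function() {
  path <- system.file("extdata", "yang_valve_reference.csv",
                      package = "valvegeom", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Compare measurements against a mean/SD reference table
#'
#' Descriptive z-scores of each model metric against a published reference
#' distribution, flagging metrics inside one standard deviation.
#'
#' @param report A [valve_measurements()] object.
#' @param reference Data frame with columns `metric`, `mean`, `sd`; metric
#'   names must match report field names. Default [yang_reference()].
#' @return Data frame with columns `metric`, `value`, `mean`, `sd`, `z`,
#'   `within_1sd`.
#' @export
compare_to_reference <- function(report, reference = yang_reference()) {
  stopifnot(inherits(report, "valve_measurements"))
  reference <- as.data.frame(reference)
  need <- c("metric", "mean", "sd")
  if (!all(need %in% names(reference)))
    stop("reference needs columns metric, mean, sd")
  if (any(!is.finite(reference$sd)) || any(reference$sd <= 0))
    stop("reference SDs must be positive")
  missing <- setdiff(reference$metric, names(report))
  if (length(missing))
    stop("unknown metric(s) in reference: ", paste(missing, collapse = ", "))
  value <- vapply(reference$metric, function(m) report[[m]], numeric(1L))
  z <- (value - reference$mean) / reference$sd
  data.frame(metric = reference$metric, value = value,
             mean = reference$mean, sd = reference$sd,
             z = z, within_1sd = abs(z) <= 1, row.names = NULL)
}

#' Write a measurement report to disk
#'
#' Writes the report as tab-delimited text (`format = "tsv"`) or JSON
#' (`format = "json"`). Output is written to a temporary file and renamed
#' into place so a failure never leaves a partial file.
#'
#' @param report A [valve_measurements()] object.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "valve_measurements"))
  format <- match.arg(format)
  vals <- report[c("cusp_area", "annulus_diameter", "annulus_circumference",
                   "valve_area", "orifice_area", "flap_to_valve_ratio",
                   "n_cusps")]
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  if (format == "json") {
    jsonlite::write_json(vals, tmp, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(metric = names(vals),
                     value = vapply(vals, as.numeric, numeric(1L)))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  file.rename(tmp, path)
  invisible(path)
}
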