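#' Cylinder radius from cusp width
#'
#' A cusp spans one n-th of the valve cylinder, so its flattened width equals
#' the arc length \eqn{W = r \theta_{max} = r \cdot 2\pi/n}. Inverting gives
#' \eqn{r = W n / (2\pi)}.
#'
#' @param width Cusp width in mm (arc distance between attachment pedicles).
#' @param n_cusps Number of cusps on the valve (>= 2; 3 for a semilunar
#'   valve).
#' @return Cylinder radius in mm.
#' @examples
#' radius_from_width(20.211, 3) # 9.65 to 3 significant figures
#' @export
radius_from_width <- function(width, n_cusps) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) ||
      width <= 0)
    stop("`width` must be a single positive finite number (mm)")
  check_n_cusps(n_cusps)
  width * n_cusps / (2 * pi)
}

check_n_cusps <- function(n_cusps) {
  if (!is.numeric(n_cusps) || length(n_cusps) != 1L ||
      !is.finite(n_cusps) || n_cusps != round(n_cusps) || n_cusps < 2)
    stop("`n_cusps` must be a single integer >= 2")
  invisible(as.integer(n_cusps))
}

#' Construct a cusp parameterization
#'
#' Builds the complete specification of one cusp surface: cylinder radius
#' \eqn{r = Wn/(2\pi)}, maximum height \eqn{h}, angular extent
#' \eqn{2\pi/n}, and free-edge wavenumber \eqn{k = \pi r / W} (exactly
#' \eqn{n/2}), so that the sine boundary \eqn{h\sin(k\theta)} returns to zero
#' precisely at the cusp's far edge.
#'
#' @param width Cusp width in mm.
#' @param max_height Maximum cusp height in mm (free edge to attachment
#'   midpoint).
#' @param n_cusps Number of cusps (default 3).
#' @return An object of class `pv_cusp` with fields `radius`, `max_height`,
#'   `width`, `angular_extent`, `wavenumber`, `n_cusps`.
#' @examples
#' cusp <- pv_cusp(20.211, 14.20)
#' cusp$radius        # 9.65...
#' cusp$wavenumber    # 1.5
#' @export
pv_cusp <- function(width, max_height, n_cusps = 3L) {
  n_cusps <- check_n_cusps(n_cusps)
  if (!is.numeric(max_height) || length(max_height) != 1L ||
      !is.finite(max_height) || max_height <= 0)
    stop("`max_height` must be a single positive finite number (mm)")
  r <- radius_from_width(width, n_cusps)
  extent <- 2 * pi / n_cusps
  k <- pi * r / width
  # k * extent == pi must hold for the free edge to pin at both commissures
  stopifnot(abs(k * extent - pi) <= 1e-6 * pi)
  structure(
    list(radius = r, max_height = max_height, width = width,
         angular_extent = extent, wavenumber = k, n_cusps = n_cusps),
    class = "pv_cusp")
}

#' @export
print.pv_cusp <- function(x, digits = 4L, ...) {
  cat("Semilunar valve cusp (1/", x$n_cusps, " cylindrical shell)\n",
      sep = "")
  cat(sprintf("  width W          : %.*f mm\n", digits, x$width))
  cat(sprintf("  max height h     : %.*f mm\n", digits, x$max_height))
  cat(sprintf("  cylinder radius r: %.*f mm\n", digits, x$radius))
  cat(sprintf("  angular extent   : %.*f rad (2pi/%d)\n", digits,
              x$angular_extent, x$n_cusps))
  cat(sprintf("  wavenumber k     : %.*f (= n/2)\n", digits, x$wavenumber))
  invisible(x)
}

#' @export
coef.pv_cusp <- function(object, ...) {
  c(radius = object$radius, max_height = object$max_height,
    width = object$width, angular_extent = object$angular_extent,
    wavenumber = object$wavenumber, n_cusps = as.numeric(object$n_cusps))
}

check_theta <- function(cusp, theta, tol = 1e-12) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("`theta` must be finite numeric")
  if (any(theta < -tol) || any(theta > cusp$angular_extent + tol))
    stop("`theta` outside the cusp domain [0, ", format(cusp$angular_extent),
         "]")
  pmin(pmax(theta, 0), cusp$angular_extent)
}

#' Free-edge height above the annulus
#'
#' The local height of the sine free edge, \eqn{h \sin(k\theta)}; zero at
#' both commissures and maximal (\eqn{h}) at the cusp midline.
#'
#' @param cusp A [pv_cusp()] object.
#' @param theta Angle(s) in `[0, angular_extent]` (radians). Vectorized.
#' @return Height(s) in mm.
#' @export
boundary_height <- function(cusp, theta) {
  stopifnot(inherits(cusp, "pv_cusp"))
  theta <- check_theta(cusp, theta)
  cusp$max_height * sin(cusp$wavenumber * theta)
}

#' @export
#' @rdname boundary_height
#' @param object,... `predict` method arguments; `theta` is passed on.
predict.pv_cusp <- function(object, theta, ...) boundary_height(object, theta)

#' Evaluate the 3-D cusp surface
#'
#' Points of the cylindrical-shell surface
#' \eqn{(r\cos\theta,\; r\sin\theta,\; z_{frac}\, h\sin(k\theta))}, where
#' `zfrac` in `[0, 1]` runs from the annulus plane (0) up to the local free
#' edge (1). The valve axis is global +z and the annulus circle lies in the
#' z = 0 plane.
#'
#' @param cusp A [pv_cusp()] object.
#' @param theta Angle(s) in `[0, angular_extent]`. Recycled against `zfrac`.
#' @param zfrac Height fraction(s) in `[0, 1]`.
#' @return A numeric matrix with columns `x`, `y`, `z` (mm), one row per
#'   point.
#' @examples
#' cusp <- pv_cusp(20.211, 14.20)
#' surface_point(cusp, pi / 3, 1) # the cusp apex (4.825, 8.357, 14.2)
#' @export
surface_point <- function(cusp, theta, zfrac) {
  stopifnot(inherits(cusp, "pv_cusp"))
  theta <- check_theta(cusp, theta)
  if (!is.numeric(zfrac) || any(!is.finite(zfrac)) ||
      any(zfrac < -1e-12) || any(zfrac > 1 + 1e-12))
    stop("`zfrac` must lie in [0, 1]")
  zfrac <- pmin(pmax(zfrac, 0), 1)
  n <- max(length(theta), length(zfrac))
  theta <- rep_len(theta, n)
  zfrac <- rep_len(zfrac, n)
  cbind(x = cusp$radius * cos(theta),
        y = cusp$radius * sin(theta),
        z = zfrac * boundary_height(cusp, theta))
}

#' Flatten the cylindrical surface (isometric development)
#'
#' The cylinder is developable: unrolling maps \eqn{(\theta, z)} to the
#' plane point \eqn{(x, z)} with \eqn{x = r\theta}, preserving all
#' in-surface distances. `unflatten()` inverts the map.
#'
#' @param cusp A [pv_cusp()] object.
#' @param theta Angle(s) in `[0, angular_extent]`.
#' @param z Height(s) in mm (passed through unchanged).
#' @return `flatten()`: matrix with columns `x` (arc length, mm) and `z`;
#'   `unflatten()`: matrix with columns `theta` and `z`.
#' @export
flatten <- function(cusp, theta, z = 0) {
  stopifnot(inherits(cusp, "pv_cusp"))
  theta <- check_theta(cusp, theta)
  n <- max(length(theta), length(z))
  cbind(x = cusp$radius * rep_len(theta, n), z = rep_len(z, n))
}

#' @rdname flatten
#' @param x Flattened arc-length coordinate(s) in `[0, W]` (mm).
#' @export
unflatten <- function(cusp, x, z = 0) {
  stopifnot(inherits(cusp, "pv_cusp"))
  if (any(!is.finite(x)) || any(x < -1e-9) || any(x > cusp$width + 1e-9))
    stop("`x` outside [0, width]")
  n <- max(length(x), length(z))
  cbind(theta = rep_len(x, n) / cusp$radius, z = rep_len(z, n))
}

#' Plot a cusp in its flattened development
#'
#' Draws the region under the sine free edge in the developed (arc length,
#' height) plane.
#'
#' @param x A [pv_cusp()] object.
#' @param n Number of boundary samples.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pv_cusp <- function(x, n = 200L, ...) {
  theta <- seq(0, x$angular_extent, length.out = n)
  flat <- flatten(x, theta, boundary_height(x, theta))
  graphics::plot(flat[, "x"], flat[, "z"], type = "l",
                 xlab = "arc length x (mm)", ylab = "height z (mm)",
                 main = "Flattened cusp free edge", ...)
  graphics::abline(h = 0, col = "grey60")
  invisible(flat)
}
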