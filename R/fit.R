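#' Fit a sine free-edge curve to boundary points
#'
#' Least-squares fit of the flattened free-edge model
#' \eqn{z(x) = A \sin(\pi x / W)} to measured boundary points. With `width`
#' supplied the problem is linear in the amplitude \eqn{A} and solved in
#' closed form; with `width` free the amplitude is profiled out (it is
#' linear given \eqn{W}) and \eqn{W} is located by a coarse scan plus Brent
#' search on the profiled residual sum of squares, then both parameters are
#' polished by damped Gauss-Newton to machine precision.
#'
#' @param points A two-column matrix or data frame of boundary samples:
#'   column 1 the arc-length coordinate `x` (mm), column 2 the height `z`
#'   (mm). Alternatively a numeric vector `x` with `z` given separately.
#' @param z Heights (mm) when `points` is a plain `x` vector.
#' @param width Optional fixed width `W` (mm). When `NULL` (default) `W` is
#'   estimated.
#' @return An object of class `sine_fit`: list with `amplitude`, `width`,
#'   `width_fixed` (logical), `fitted`, `residuals`, `rss`, `rms`
#'   (root-mean-square residual), `se` (standard errors, `NA` when not
#'   estimable), `n`, and the input data.
#' @examples
#' # the three-point construction: peak (10.1055, 1), feet (0,0), (20.211,0)
#' fit <- fit_sine_boundary(cbind(c(0, 10.1055, 20.211), c(0, 1, 0)))
#' coef(fit) # amplitude 1, width 20.211, zero residual
#' @export
fit_sine_boundary <- function(points, z = NULL, width = NULL) {
  if (is.null(z)) {
    points <- as.matrix(points)
    if (ncol(points) < 2L) stop("`points` needs two columns (x, z)")
    x <- as.numeric(points[, 1L]); zz <- as.numeric(points[, 2L])
  } else {
    x <- as.numeric(points); zz <- as.numeric(z)
  }
  if (length(x) != length(zz)) stop("x and z lengths differ")
  keep <- is.finite(x) & is.finite(zz)
  x <- x[keep]; zz <- zz[keep]
  n <- length(x)
  if (n < 3L) stop("at least 3 boundary points are required")

  if (!is.null(width)) {
    if (!is.finite(width) || width <= 0) stop("`width` must be positive")
    if (any(x < -1e-9) || any(x > width + 1e-9))
      stop("x values must lie within [0, width]")
    s <- sin(pi * x / width)
    ss <- sum(s * s)
    if (ss <= 0) stop("degenerate fit: all basis values zero")
    A <- sum(zz * s) / ss
    W <- width
    fixed <- TRUE
  } else {
    if (all(zz == 0))
      stop("degenerate fit: all z = 0 with width free")
    rng <- diff(range(x))
    if (rng <= 0) stop("degenerate fit: zero x-range")
    prss <- function(W) {
      s <- sin(pi * x / W)
      ss <- sum(s * s)
      if (ss <= 0) return(sum(zz^2))
      sum(zz^2) - sum(zz * s)^2 / ss
    }
    # coarse scan guards against the oscillatory local minima of the
    # profiled objective, then Brent refines within the best bracket
    grid <- seq(0.5 * rng, 3 * rng, length.out = 121L)
    vals <- vapply(grid, prss, numeric(1L))
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    W <- stats::optimize(prss, c(lo, hi), tol = 1e-10 * rng)$minimum
    s <- sin(pi * x / W)
    A <- sum(zz * s) / sum(s * s)
    gn <- gauss_newton_sine(x, zz, A, W)
    A <- gn$A; W <- gn$W
    fixed <- FALSE
  }

  s <- sin(pi * x / W)
  fitted <- A * s
  res <- zz - fitted
  rss <- sum(res^2)
  p <- if (fixed) 1L else 2L
  sigma2 <- if (n > p) rss / (n - p) else NA_real_
  se <- c(amplitude = NA_real_, width = NA_real_)
  if (is.finite(sigma2)) {
    if (fixed) {
      se["amplitude"] <- sqrt(sigma2 / sum(s * s))
    } else {
      J <- cbind(s, A * cos(pi * x / W) * (-pi * x / W^2))
      xtx <- crossprod(J)
      if (rcond_2x2(xtx) > 1e-14) {
        v <- diag(solve(xtx)) * sigma2
        se <- sqrt(pmax(v, 0))
        names(se) <- c("amplitude", "width")
      }
    }
  }
  structure(
    list(amplitude = A, width = W, width_fixed = fixed,
         x = x, z = zz, fitted = fitted, residuals = res,
         rss = rss, rms = sqrt(rss / n), se = se, n = n),
    class = "sine_fit")
}

rcond_2x2 <- function(m) {
  e <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) 0 else min(e) / max(e)
}

# damped Gauss-Newton on (A, W) for z ~ A sin(pi x / W)
gauss_newton_sine <- function(x, z, A, W) {
  rss <- function(A, W) sum((z - A * sin(pi * x / W))^2)
  cur <- rss(A, W)
  for (it in seq_len(100L)) {
    s <- sin(pi * x / W)
    r <- z - A * s
    J <- cbind(s, A * cos(pi * x / W) * (-pi * x / W^2))
    xtx <- crossprod(J)
    if (rcond_2x2(xtx) < 1e-15) break
    step <- solve(xtx, crossprod(J, r))
    lam <- 1
    repeat {
      A2 <- A + lam * step[1L]; W2 <- W + lam * step[2L]
      if (W2 > 0 && rss(A2, W2) <= cur + 1e-300) break
      lam <- lam / 2
      if (lam < 1e-8) { A2 <- A; W2 <- W; break }
    }
    moved <- abs(A2 - A) + abs(W2 - W)
    A <- A2; W <- W2
    new <- rss(A, W)
    if (moved <= 1e-15 * (abs(A) + abs(W)) || cur - new <= 1e-30 * (cur + 1e-30)) {
      cur <- new
      break
    }
    cur <- new
  }
  list(A = A, W = W)
}

#' @export
print.sine_fit <- function(x, digits = 6L, ...) {
  cat("Sine free-edge fit: z(x) = A sin(pi x / W)\n")
  cat(sprintf("  amplitude A : %.*g mm%s\n", digits, x$amplitude,
              if (is.finite(x$se["amplitude"]))
                sprintf("  (se %.3g)", x$se["amplitude"]) else ""))
  cat(sprintf("  width W     : %.*g mm%s%s\n", digits, x$width,
              if (x$width_fixed) "  [fixed]" else "",
              if (!x$width_fixed && is.finite(x$se["width"]))
                sprintf("  (se %.3g)", x$se["width"]) else ""))
  cat(sprintf("  n = %d points, residual RMS = %.3g mm\n", x$n, x$rms))
  invisible(x)
}

#' @export
summary.sine_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual range: [%.3g, %.3g] mm\n",
              min(object$residuals), max(object$residuals)))
  invisible(object)
}

#' @export
coef.sine_fit <- function(object, ...) {
  c(amplitude = object$amplitude, width = object$width)
}

#' @export
residuals.sine_fit <- function(object, ...) object$residuals

#' @export
fitted.sine_fit <- function(object, ...) object$fitted

#' @export
#' @rdname fit_sine_boundary
#' @param object A `sine_fit` object.
#' @param newdata Optional new `x` values (mm) at which to evaluate the
#'   fitted curve; defaults to the fitting abscissae.
#' @param ... Unused.
predict.sine_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$amplitude * sin(pi * x / object$width)
}

#' Convert a fitted free edge to a cusp parameterization
#'
#' Uses the fitted width as the cusp width and the fitted amplitude as the
#' maximum height.
#'
#' @param fit A [fit_sine_boundary()] result.
#' @param n_cusps Number of cusps (default 3).
#' @return A [pv_cusp()] object.
#' @export
as_pv_cusp <- function(fit, n_cusps = 3L) {
  stopifnot(inherits(fit, "sine_fit"))
  pv_cusp(fit$width, fit$amplitude, n_cusps)
}

#' Read boundary points from a delimited text file
#'
#' Reads a two-column plain-text table of boundary samples (x and z, mm).
#' Lines starting with `#` are comments; an optional single header row is
#' auto-detected (first line whose fields are not all numeric). Fields may
#' be separated by whitespace, commas, or tabs.
#'
#' @param path File path.
#' @return A numeric matrix with columns `x` and `z`.
#' @export
read_boundary_points <- function(path) {
  if (!file.exists(path)) stop("points file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no data in ", path)
  split_fields <- function(l) strsplit(l, "[,\t ]+")[[1L]]
  first <- suppressWarnings(as.numeric(split_fields(lines[1L])))
  if (any(is.na(first))) lines <- lines[-1L]
  if (length(lines) == 0L) stop("no numeric rows in ", path)
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(split_fields(l)))
    if (length(v) < 2L || any(is.na(v[1:2])))
      stop("unparseable row in ", path, ": ", l)
    v[1:2]
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("x", "z")
  m
}
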