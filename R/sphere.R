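#' Least-squares sphere fit
#'
#' Estimates the centre and radius of a sphere from surface points, used to
#' locate the hip centre of rotation from femoral-head vertices. The
#' algebraic fit solves the linear least-squares system
#' `2 p.c + (r^2 - |c|^2) = |p|^2`; with `refine = TRUE` (default) the
#' algebraic solution seeds a Gauss-Newton minimization of the geometric
#' loss `sum((|p - c| - r)^2)`.
#'
#' @param points numeric n x 3 matrix of surface points (cm), n >= 4 and
#'   not coplanar.
#' @param refine refine the algebraic fit geometrically.
#' @return an object of class `sphere_fit`: list with `center`, `radius`,
#'   `rms_residual` (of the geometric residuals), `n_points`.
#' @export
fit_sphere <- function(points, refine = TRUE) {
  if (!is.matrix(points) || ncol(points) != 3L || !is.numeric(points))
    .stop_geom("points must be a numeric n x 3 matrix")
  if (any(!is.finite(points))) .stop_geom("points contain non-finite values")
  n <- nrow(points)
  if (n < 4L) .stop_geom("sphere fit needs at least 4 points, got %d", n)
  A <- cbind(2 * points, 1)
  if (qr(A)$rank < 4L)
    .stop_geom("degenerate point configuration (coplanar or coincident): sphere underdetermined")
  b <- rowSums(points^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(max(sol[4] + sum(center^2), 0))
  if (refine) {
    loss <- function(th) {
      r <- sqrt(colSums((t(points) - th[1:3])^2)) - th[4]
      sum(r^2)
    }
    opt <- stats::optim(c(center, radius), loss, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    center <- opt$par[1:3]
    radius <- opt$par[4]
  }
  if (radius <= 0) .stop_geom("degenerate sphere fit: nonpositive radius")
  res <- sqrt(colSums((t(points) - center)^2)) - radius
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 rms_residual = sqrt(mean(res^2)), n_points = n),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("Sphere fit: center (%.4f, %.4f, %.4f), radius %.4f, rms %.2e, n = %d\n",
              x$center[1], x$center[2], x$center[3], x$radius,
              x$rms_residual, x$n_points))
  invisible(x)
}
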