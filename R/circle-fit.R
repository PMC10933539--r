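#' Algebraic (Kasa) circle fit
#'
#' Linear least-squares circle through planar points: minimises
#' `sum((x^2 + y^2 - 2ax - 2by - c)^2)`, solved from the normal equations.
#' Fast and non-iterative; used to initialise the geometric fit and as an
#' independent reference in tests.
#'
#' @param x,y Planar coordinates (metres).
#' @return A list of class `circle_fit` with `cx`, `cy`, `radius`,
#'   `rms_residual` (geometric residual r.m.s., m) and `n_points`.
#' @export
fit_circle_kasa <- function(x, y) {
  n <- length(x)
  if (n < 3) stop_bad_arg("circle fit needs >= 3 points, got %d", n)
  # centre the data first: keeps the normal equations well conditioned and
  # the fit exactly translation invariant
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop_bad_arg("circle fit failed: points are collinear or degenerate",
                 class = "tlscarbon_fit_failure"))
  cx <- sol[1]; cy <- sol[2]
  r2 <- sol[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0)
    stop_bad_arg("circle fit failed: non-positive squared radius",
                 class = "tlscarbon_fit_failure")
  r <- sqrt(r2)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(list(cx = unname(cx) + mx, cy = unname(cy) + my, radius = unname(r),
                 rms_residual = sqrt(mean((d - r)^2)), n_points = n),
            class = "circle_fit")
}

#' Geometric least-squares circle fit
#'
#' The orthogonal-distance circle: minimises `sum((d_i - r)^2)` where `d_i`
#' is the distance of point i to the centre. Gauss-Newton with the analytic
#' Jacobian, initialised from the Kasa fit ([fit_circle_kasa()]), with a
#' step-halving safeguard; converged when the parameter step drops below
#' `tol` (metres) or after `max_iter` iterations. This is the standard
#' "geometric fit" used for stem diameters from TLS cross-sections.
#'
#' @inheritParams fit_circle_kasa
#' @param min_points Minimum number of points required (20 by default, the
#'   floor applied to diameter slices).
#' @param tol Convergence tolerance on the parameter step (m).
#' @param max_iter Iteration cap.
#' @return A `circle_fit` list; see [fit_circle_kasa()].
#' @export
fit_circle_geometric <- function(x, y, min_points = 3L, tol = 1e-10, max_iter = 100L) {
  n <- length(x)
  if (n < min_points)
    stop_bad_arg("insufficient points for circle fit: %d < %d", n, min_points,
                 class = "tlscarbon_insufficient_points")
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  init <- fit_circle_kasa(x, y)
  p <- c(init$cx, init$cy, init$radius)
  obj <- function(p) {
    d <- sqrt((x - p[1])^2 + (y - p[2])^2)
    sum((d - p[3])^2)
  }
  f0 <- obj(p)
  for (it in seq_len(max_iter)) {
    d <- sqrt((x - p[1])^2 + (y - p[2])^2)
    d <- pmax(d, 1e-300)
    r_res <- d - p[3]
    J <- cbind(-(x - p[1]) / d, -(y - p[2]) / d, -1)
    step <- tryCatch(qr.solve(crossprod(J), -crossprod(J, r_res)),
                     error = function(e) NULL)
    if (is.null(step))
      stop_bad_arg("circle fit failed: singular normal equations (degenerate points)",
                   class = "tlscarbon_fit_failure")
    step <- drop(step)
    lambda <- 1
    repeat {
      p_new <- p + lambda * step
      if (p_new[3] > 0 && obj(p_new) <= f0 + 1e-15) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { p_new <- p; break }
    }
    moved <- sqrt(sum((p_new - p)^2))
    p <- p_new
    f0 <- obj(p)
    if (moved < tol) break
  }
  d <- sqrt((x - p[1])^2 + (y - p[2])^2)
  structure(list(cx = p[1] + mx, cy = p[2] + my, radius = p[3],
                 rms_residual = sqrt(mean((d - p[3])^2)), n_points = n),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("circle fit: centre (%.4f, %.4f) m, radius %.4f m, rms %.2g m, n = %d\n",
              x$cx, x$cy, x$radius, x$rms_residual, x$n_points))
  invisible(x)
}
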