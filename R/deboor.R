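#' One de Boor equidistribution step
#'
#' Given a partition `0 = u_0 < ... < u_N = 1` and positive per-cell
#' densities `rho_j` (piecewise constant over the old cells), returns the new
#' partition whose points exactly equidistribute rho over the old cells:
#' `u_k` solves `R(u_k) = (k/N) R(1)` where R is the cumulative integral of
#' the piecewise-constant density.  Because R is piecewise linear and
#' strictly increasing this is inverse linear interpolation; endpoints stay
#' fixed and monotonicity is preserved.
#'
#' @param partition Numeric vector of length N + 1, strictly increasing from
#'   0 to 1.
#' @param rho Positive density value per cell (length N).
#' @return The new partition (length N + 1).
#' @examples
#' deboor_step(c(0, .25, .5, .75, 1), c(1, 1, 3, 3))
#' @export
deboor_step <- function(partition, rho) {
  n <- length(rho)
  if (length(partition) != n + 1) abort("`rho` must have one value per cell")
  if (any(rho <= 0) || !all(is.finite(rho))) {
    abort("cell densities must be positive and finite")
  }
  if (is.unsorted(partition, strictly = TRUE)) {
    abort("`partition` must be strictly increasing")
  }
  R <- c(0, cumsum(rho * diff(partition)))
  targets <- seq(0, R[n + 1], length.out = n + 1)
  out <- approx(R, partition, xout = targets, ties = "ordered")$y
  out[1] <- partition[1]
  out[n + 1] <- partition[n + 1]
  out
}

#' Generate an initially equidistributed mesh on a parametric curve
#'
#' Iterates the de Boor algorithm to place N sample points on a parametric
#' curve so that the monitor function is (approximately) equidistributed
#' along the resulting polygon.  Each iteration samples the curve on the
#' current partition, evaluates the monitor on the sampled polygon (with
#' smoothing per the spec), forms the per-cell density
#' `rho_j = M(u_{j+1/2}) |x_u|(u_{j+1/2})` at cell midpoints, and applies
#' [deboor_step()].  Iteration stops when the maximal partition update falls
#' below `tol` or after `max_iter` iterations; in the latter case the result
#' carries `converged = FALSE` (with a warning) rather than failing, since
#' the iteration converges slowly on some shapes.
#'
#' Midpoint monitor values are averaged from the two adjacent node values;
#' `|x_u|` at midpoints uses the generator's analytic derivative when
#' available and otherwise central differences on a 10x refined local sample.
#'
#' @param pc A [parametric_curve()].
#' @param n_nodes Number of mesh nodes N >= 4.
#' @param monitor A [monitor_spec()].
#' @param tol Stopping tolerance on the maximal partition update.
#' @param max_iter Maximal number of de Boor iterations.
#' @return A curve tibble with attributes `partition`, `iterations`,
#'   `converged`, `final_update`.
#' @examples
#' crv <- equidistribute_curve(curve_generator("ellipse"), 64,
#'                             monitor_spec("uniform"))
#' equidistribution_ratio(crv, spec = monitor_spec("uniform"))
#' @export
equidistribute_curve <- function(pc, n_nodes, monitor = monitor_spec(),
                                 tol = 1e-10, max_iter = 100) {
  if (!inherits(pc, "parametric_curve")) abort("`pc` must be a parametric_curve")
  n <- as.integer(n_nodes)
  if (n < 4) abort("need at least 4 nodes")
  if (tol <= 0) abort("`tol` must be positive")

  speed_mid <- function(um, du) {
    if (!is.null(pc$deriv)) {
      d <- pc$deriv(um)
      sqrt(d[, 1]^2 + d[, 2]^2)
    } else {
      delta <- du / 20           # central difference on a 10x refined scale
      hi <- pc$fun(um + delta)
      lo <- pc$fun(um - delta)
      sqrt((hi[, 1] - lo[, 1])^2 + (hi[, 2] - lo[, 2])^2) / (2 * delta)
    }
  }

  u <- seq(0, 1, length.out = n + 1)
  converged <- FALSE
  upd <- NA_real_
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    pts <- pc$fun(u[seq_len(n)])
    crv_x <- pts[, 1]
    crv_y <- pts[, 2]
    fr <- frame_impl(crv_x, crv_y)
    m <- raw_monitor_impl(fr, monitor)
    if (needs_smoothing(monitor)) {
      m <- smooth_monitor(m, monitor$smooth_p, monitor$smooth_q)
    }
    m_mid <- (m + m[idx_up(n)]) / 2
    um <- (u[-(n + 1)] + u[-1]) / 2
    rho <- m_mid * speed_mid(um, diff(u))
    u_new <- deboor_step(u, rho)
    upd <- max(abs(u_new - u))
    u <- u_new
    if (upd < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "de Boor iteration stopped after %d iterations with update %.3g >= tol %.3g",
      iter, upd, tol))
  }
  out <- as_curve(pc$fun(u[seq_len(n)]))
  attr(out, "partition") <- u
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "final_update") <- upd
  out
}
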