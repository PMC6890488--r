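#' Assemble the coupled implicit system for one Picard iterate
#'
#' Builds the 2N x 2N cyclic block-tridiagonal system (2x2 blocks over the
#' periodic three-node stencil) whose solution is the next Picard iterate.
#' Per node i there are two scalar equations in the unknown positions
#' `x_{i-1}, x_i, x_{i+1}`:
#'
#' * a normal equation, backward Euler
#'   `(-mu x_{i-1} + (1 + 2 mu) x_i - mu x_{i+1}) . n_i = x_i^n . n_i +
#'   dt beta_i` with `mu_i = 4 dt alpha_i / |x_{i+1} - x_{i-1}|^2` evaluated
#'   on the lagged iterate, or its Crank-Nicolson variant with halved
#'   implicit weights, the explicit second difference on the right-hand
#'   side, the trapezoidal forcing average, and the averaged (unnormalised)
#'   normal `(n_i^{iter} + n_i^n) / 2`;
#' * a tangential moving-mesh equation, always backward Euler,
#'   `(-nu x_{i-1} + (1 + 2 nu) x_i - nu x_{i+1}) . t_i = x_i^n . t_i +
#'   dt P_i (M_{i+1} - M_{i-1}) / (tau M_i^2 |x_{i+1} - x_{i-1}|)` with
#'   `nu_i = 4 dt M_i P_i / (tau (M_i |x_{i+1} - x_{i-1}|)^2)`.
#'
#' The monitor values `M` and balancing operator `P` are always taken from
#' the previous time level (treated explicitly); tangent/normal/chord are
#' taken from the lagged iterate.  The right-hand side of the tangential
#' equation is the discretisation of `P M_xi |x_xi| / (tau (M |x_xi|)^2)`:
#' central differences give
#' `P_i (M_{i+1} - M_{i-1}) / (2 dxi) * (|chord_i| / (2 dxi)) /
#' (tau M_i^2 (|chord_i| / (2 dxi))^2)`, in which the parameter steps and
#' one chord power cancel, leaving the expression above.
#'
#' This function exists mainly for inspection and testing; [picard_step()]
#' and [evolve_curve()] assemble internally.
#'
#' @param curve_prev Curve at the previous time level (tibble or data frame
#'   with `x`, `y`).
#' @param curve_iter Current Picard iterate (same layout).
#' @param monitor_prev Per-node monitor values at the previous level.
#' @param p_prev Per-node balancing-operator values at the previous level.
#' @param forcing A [forcing()].
#' @param scheme `"be"` or `"cnbe"`.
#' @param dt Time-step size.
#' @param tau Mesh relaxation time.
#' @param t_next Time level being solved for.
#' @return A list with N x 4 block matrices `L`, `D`, `U` (entries a11, a12,
#'   a21, a22; row 1 of each block is the normal equation, row 2 the
#'   tangential one), right-hand side `rhs` (interleaved x1, y1, ...), and
#'   the coefficient vectors `mu`, `nu`.
#' @export
assemble_system <- function(curve_prev, curve_iter, monitor_prev, p_prev,
                            forcing, scheme = c("cnbe", "be"), dt, tau,
                            t_next) {
  scheme <- match.arg(scheme)
  curve_prev <- as_curve(curve_prev)
  curve_iter <- as_curve(curve_iter)
  n <- nrow(curve_prev)
  lev <- level_quantities(curve_prev$x, curve_prev$y, monitor_prev, p_prev,
                          forcing, dt, t_next - dt, tau)
  asm <- assemble_impl(curve_iter$x, curve_iter$y, lev, forcing, scheme, dt,
                       tau, t_next)
  if (is.null(asm)) abort("degenerate chord in the Picard iterate")
  asm
}

# Quantities fixed for a whole time step: level-n frame, monitor differences,
# explicit CN right-hand side pieces.  M and P are supplied by the caller.
level_quantities <- function(xn, yn, m_prev, p_prev, forcing, dt, t_n, tau) {
  n <- length(xn)
  up <- idx_up(n)
  dn <- idx_dn(n)
  cx <- xn[up] - xn[dn]
  cy <- yn[up] - yn[dn]
  ch2 <- cx * cx + cy * cy
  ch <- sqrt(ch2)
  txn <- cx / ch
  tyn <- cy / ch
  alpha_n <- forcing$alpha(xn, yn, t_n)
  list(
    xn = xn, yn = yn, up = up, dn = dn,
    nxn = tyn, nyn = -txn,
    lapx = xn[dn] - 2 * xn + xn[up],
    lapy = yn[dn] - 2 * yn + yn[up],
    mun = 4 * dt * alpha_n / ch2,
    beta_n = forcing$beta(xn, yn, t_n),
    m = m_prev,
    dm = m_prev[up] - m_prev[dn],
    p = p_prev,
    tang_coef = dt * p_prev * (m_prev[up] - m_prev[dn]) / (tau * m_prev^2)
  )
}

# Assemble blocks and rhs at the lagged iterate (xi, yi).  Returns NULL on a
# degenerate or non-finite chord so callers can signal a singularity.
assemble_impl <- function(xi, yi, lev, forcing, scheme, dt, tau, t_next) {
  n <- length(xi)
  up <- lev$up
  dn <- lev$dn
  cx <- xi[up] - xi[dn]
  cy <- yi[up] - yi[dn]
  ch2 <- cx * cx + cy * cy
  if (!all(is.finite(ch2)) || any(ch2 == 0)) return(NULL)
  ch <- sqrt(ch2)
  tx <- cx / ch
  ty <- cy / ch
  nx <- ty
  ny <- -tx

  alpha_i <- forcing$alpha(xi, yi, t_next)
  beta_i <- forcing$beta(xi, yi, t_next)
  mu <- 4 * dt * alpha_i / ch2
  nu <- 4 * dt * lev$p / (tau * lev$m * ch2)

  if (scheme == "cnbe") {
    anx <- (nx + lev$nxn) / 2        # averaged normal, deliberately not
    any_ <- (ny + lev$nyn) / 2       # re-normalised to unit length
    off_n <- -mu / 2
    dia_n <- 1 + mu
    rhs_n <- (lev$mun / 2) * (lev$lapx * anx + lev$lapy * any_) +
      lev$xn * anx + lev$yn * any_ + (dt / 2) * (beta_i + lev$beta_n)
  } else {
    anx <- nx
    any_ <- ny
    off_n <- -mu
    dia_n <- 1 + 2 * mu
    rhs_n <- lev$xn * anx + lev$yn * any_ + dt * beta_i
  }
  rhs_t <- lev$xn * tx + lev$yn * ty + lev$tang_coef / ch

  L <- cbind(off_n * anx, off_n * any_, -nu * tx, -nu * ty)
  D <- cbind(dia_n * anx, dia_n * any_, (1 + 2 * nu) * tx, (1 + 2 * nu) * ty)
  rhs <- numeric(2 * n)
  rhs[seq(1, 2 * n, by = 2)] <- rhs_n
  rhs[seq(2, 2 * n, by = 2)] <- rhs_t
  list(L = L, D = D, U = L, rhs = rhs, mu = mu, nu = nu)
}

# One implicit step by Picard iteration on plain coordinate vectors.
# Returns list(x, y, iters, status) with status "converged", "capped",
# "singularity" (degenerate geometry or iteration budget exhausted) or
# "diverged" (non-finite coordinates).
picard_advance <- function(xn, yn, m_prev, p_prev, forcing, scheme, dt, tau,
                           t_next, picard_tol, picard_max, picard_cap) {
  lev <- level_quantities(xn, yn, m_prev, p_prev, forcing, dt, t_next - dt, tau)
  xi <- xn
  yi <- yn
  m <- 0L
  odd <- seq(1, 2 * length(xn), by = 2)
  repeat {
    asm <- assemble_impl(xi, yi, lev, forcing, scheme, dt, tau, t_next)
    if (is.null(asm)) {
      if (!all(is.finite(xi)) || !all(is.finite(yi))) {
        return(list(x = xi, y = yi, iters = m, status = "diverged"))
      }
      return(list(x = xi, y = yi, iters = m, status = "singularity"))
    }
    sol <- cyclic_block_solve(asm$L, asm$D, asm$U, asm$rhs)
    m <- m + 1L
    x_new <- sol[odd]
    y_new <- sol[odd + 1]
    upd <- max(sqrt((x_new - xi)^2 + (y_new - yi)^2))
    xi <- x_new
    yi <- y_new
    if (!is.finite(upd)) {
      return(list(x = xi, y = yi, iters = m, status = "diverged"))
    }
    if (!is.null(picard_cap)) {
      if (m >= picard_cap) {
        return(list(x = xi, y = yi, iters = m, status = "capped"))
      }
    } else {
      if (upd < picard_tol) {
        return(list(x = xi, y = yi, iters = m, status = "converged"))
      }
      if (m >= picard_max) {
        return(list(x = xi, y = yi, iters = m, status = "singularity"))
      }
    }
  }
}

#' One implicit time step via Picard iteration
#'
#' Advances the curve by a single time step of the coupled
#' normal/tangential system.  The geometric coefficients (tangents, normals,
#' chords) are lagged one Picard iterate behind; each iteration solves the
#' resulting linear cyclic block-tridiagonal system exactly and the
#' iteration stops when the maximal nodal displacement between consecutive
#' iterates falls below `picard_tol` (initial guess: the previous-level
#' curve).  With `picard_cap` set, exactly `cap` iterations are performed
#' regardless of the update — the semi-implicit mode that can step across a
#' geometric singularity (cap 1 for the BE scheme, 2 for CNBE).
#'
#' Monitor and balancing-operator values are evaluated once from the
#' previous-level curve and held fixed across the iterations.
#'
#' @param curve Curve at the previous time level.
#' @param dt Time-step size.
#' @param t_now Time of `curve` (the step solves for `t_now + dt`).
#' @param scheme `"cnbe"` (Crank-Nicolson normal + backward Euler
#'   tangential) or `"be"` (backward Euler throughout).
#' @param monitor A [monitor_spec()].
#' @param tau Mesh relaxation time (> 0); small tau relaxes the mesh towards
#'   equidistribution quickly.
#' @param p_mode Spatial balancing operator: `"balanced"` is
#'   `P = M |x_xi|^2` (discretely `M_i (|x_{i+1} - x_{i-1}| / (2 dxi))^2`),
#'   which makes the relaxation rate resolution-independent and tolerant of
#'   larger tau; `"identity"` is `P = 1` (steepest descent).
#' @param force A [forcing()].
#' @param picard_tol Stopping tolerance on the maximal nodal displacement.
#' @param picard_max Iteration budget; exhausting it without convergence is
#'   reported as a singularity.
#' @param picard_cap Optional fixed iteration count (semi-implicit mode).
#' @return A list with the advanced `curve`, the iteration count `iters`,
#'   and `status` (`"converged"`, `"capped"`, `"singularity"`,
#'   `"diverged"`).
#' @export
picard_step <- function(curve, dt, t_now = 0, scheme = c("cnbe", "be"),
                        monitor = monitor_spec(), tau = 1,
                        p_mode = c("balanced", "identity"),
                        force = forcing(), picard_tol = 1e-6,
                        picard_max = 200L, picard_cap = NULL) {
  scheme <- match.arg(scheme)
  p_mode <- match.arg(p_mode)
  curve <- as_curve(curve)
  if (dt <= 0 || tau <= 0) abort("`dt` and `tau` must be positive")
  mp <- monitor_and_p(curve$x, curve$y, monitor, p_mode)
  res <- picard_advance(curve$x, curve$y, mp$m, mp$p, force, scheme, dt, tau,
                        t_now + dt, picard_tol, picard_max, picard_cap)
  list(curve = as_curve(tibble(x = res$x, y = res$y)),
       iters = res$iters, status = res$status)
}

# monitor values (smoothed per spec) and discrete P at a time level
monitor_and_p <- function(x, y, monitor, p_mode) {
  fr <- frame_impl(x, y)
  m <- raw_monitor_impl(fr, monitor)
  if (needs_smoothing(monitor)) {
    m <- smooth_monitor(m, monitor$smooth_p, monitor$smooth_q)
  }
  if (p_mode == "balanced") {
    dxi <- 1 / length(x)
    p <- m * (fr$chord / (2 * dxi))^2
  } else {
    p <- rep(1, length(x))
  }
  list(m = m, p = p)
}

#' Evolve a closed curve under forced curve shortening flow
#'
#' Marches the curve from t = 0 to `t_final` in `n_steps` implicit steps of
#' [picard_step()], recording the enclosed area and the Picard iteration
#' count at every step and curve snapshots at a chosen stride.  If the
#' Picard solver fails to converge (the signature of an approaching
#' geometric singularity for a fully implicit scheme) the march stops with
#' status `"singularity"` and the partial series intact; non-finite
#' coordinates stop it with status `"diverged"`.
#'
#' @param curve Initial curve (tibble or data frame with `x`, `y`; see
#'   [as_curve()]).  Use [make_curve()] for an initially equidistributed
#'   mesh.
#' @param t_final Final time T; step size is `dt = t_final / n_steps`.
#' @param n_steps Number of time steps.
#' @inheritParams picard_step
#' @param snapshot_stride Record a curve snapshot every this many steps (the
#'   initial and final curves are always kept).  Default: only first/last.
#' @param record_edge_ratio Also record [edge_length_ratio()] per step.
#' @return An object of class `curve_evolution`; see [tidy.curve_evolution()]
#'   and [glance.curve_evolution()].
#' @examples
#' circ <- make_curve("circle", 64, monitor_spec("uniform"))
#' ev <- evolve_curve(circ, t_final = 0.1, n_steps = 20,
#'                    scheme = "cnbe", monitor = monitor_spec("uniform"),
#'                    tau = 0.1, p_mode = "identity")
#' glance(ev)
#' @export
evolve_curve <- function(curve, t_final, n_steps, scheme = c("cnbe", "be"),
                         monitor = monitor_spec(), tau = 1,
                         p_mode = c("balanced", "identity"),
                         force = forcing(), picard_tol = 1e-6,
                         picard_max = 200L, picard_cap = NULL,
                         snapshot_stride = NULL, record_edge_ratio = FALSE) {
  scheme <- match.arg(scheme)
  p_mode <- match.arg(p_mode)
  curve <- as_curve(curve)
  n_steps <- as.integer(n_steps)
  if (t_final <= 0 || n_steps < 1) abort("`t_final` and `n_steps` must be positive")
  if (!is.null(picard_cap) && picard_cap > picard_max) {
    abort("`picard_cap` must not exceed `picard_max`")
  }
  dt <- t_final / n_steps

  x <- curve$x
  y <- curve$y
  up <- idx_up(length(x))
  area_fn <- function(x, y) 0.5 * sum(x * y[up] - x[up] * y)
  ratio_fn <- function(x, y) {
    h <- sqrt((x[up] - x)^2 + (y[up] - y)^2)
    max(h) / min(h)
  }

  areas <- numeric(n_steps + 1)
  areas[1] <- area_fn(x, y)
  iters <- integer(n_steps)
  ratios <- if (record_edge_ratio) numeric(n_steps + 1) else NULL
  if (record_edge_ratio) ratios[1] <- ratio_fn(x, y)
  snapshots <- list(`0` = tibble(x = x, y = y))
  status <- "completed"
  t_fail <- NA_real_
  done <- 0L

  for (step in seq_len(n_steps)) {
    t_next <- step * dt
    mp <- monitor_and_p(x, y, monitor, p_mode)
    res <- picard_advance(x, y, mp$m, mp$p, force, scheme, dt, tau, t_next,
                          picard_tol, picard_max, picard_cap)
    if (res$status %in% c("singularity", "diverged")) {
      status <- res$status
      t_fail <- t_next
      break
    }
    x <- res$x
    y <- res$y
    done <- step
    areas[step + 1] <- area_fn(x, y)
    iters[step] <- res$iters
    if (record_edge_ratio) ratios[step + 1] <- ratio_fn(x, y)
    if (!is.null(snapshot_stride) && step %% snapshot_stride == 0) {
      snapshots[[as.character(step)]] <- tibble(x = x, y = y)
    }
  }
  if (is.null(snapshots[[as.character(done)]]) && done > 0L) {
    snapshots[[as.character(done)]] <- tibble(x = x, y = y)
  }

  structure(list(
    times = seq(0, by = dt, length.out = done + 1L),
    dt = dt, t_final = t_final, n_steps = n_steps, steps_done = done,
    area = areas[seq_len(done + 1L)],
    picard_iters = iters[seq_len(done)],
    edge_ratio = if (record_edge_ratio) ratios[seq_len(done + 1L)] else NULL,
    snapshots = snapshots,
    status = status, t_fail = t_fail,
    config = list(scheme = scheme, monitor = monitor, tau = tau,
                  p_mode = p_mode, picard_tol = picard_tol,
                  picard_max = picard_max, picard_cap = picard_cap,
                  n_nodes = length(x))
  ), class = "curve_evolution")
}
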