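#' Monitor-function specification
#'
#' The monitor function M > 0 is the mesh-density weight whose
#' equidistribution (constant `M ds` between neighbouring nodes) defines the
#' desired mesh.  `kind = "uniform"` (M = 1) targets a uniform arc-length
#' mesh; `kind = "curvature"` targets
#' `M = (1/2) * (M_floor + |kappa|^gamma)`, concentrating nodes in
#' high-curvature regions.  The floor is the curve average of `|kappa|^gamma`
#' and keeps the density positive on flat segments; it is recomputed from the
#' current curve every time the monitor is evaluated, so it adapts to the
#' evolving length.
#'
#' The exponent `gamma = 1/2` equidistributes the weight that minimises the
#' maximal distance between the curve and its polygonal interpolant;
#' `gamma = 1/3` and `2/3` target enclosed-area and total-length discrepancy
#' respectively and are exposed through the same parameter.
#'
#' Smoothing is a normalised geometric-decay moving average over
#' `2 * smooth_p + 1` nodes with weights `(q/(q+1))^|k|`; with the defaults
#' `p = 2`, `q = 3` the stencil weights are (9/16, 3/4, 1, 3/4, 9/16).
#'
#' @param kind `"curvature"` or `"uniform"`.
#' @param exponent Curvature exponent gamma in (0, 1]; ignored for
#'   `kind = "uniform"`.
#' @param smooth_p Nonnegative integer half-width of the smoothing stencil.
#' @param smooth_q Positive decay parameter of the smoothing weights.
#' @param smoothing Logical; apply smoothing whenever the monitor is
#'   evaluated.
#' @return A list of class `monitor_spec`.
#' @examples
#' monitor_spec("uniform")
#' monitor_spec("curvature", exponent = 1 / 3)
#' @export
monitor_spec <- function(kind = c("curvature", "uniform"), exponent = 0.5,
                         smooth_p = 2L, smooth_q = 3, smoothing = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(exponent) || exponent <= 0 || exponent > 1) {
    abort("`exponent` must lie in (0, 1]")
  }
  smooth_p <- as.integer(smooth_p)
  if (smooth_p < 0) abort("`smooth_p` must be a nonnegative integer")
  if (!is.numeric(smooth_q) || smooth_q <= 0) {
    abort("`smooth_q` must be positive")
  }
  structure(list(kind = kind, exponent = exponent, smooth_p = smooth_p,
                 smooth_q = smooth_q, smoothing = isTRUE(smoothing)),
            class = "monitor_spec")
}

#' @export
print.monitor_spec <- function(x, ...) {
  if (x$kind == "uniform") {
    cat("Monitor: uniform arc-length (M = 1)\n")
  } else {
    cat(sprintf(
      "Monitor: curvature-based, M = (floor + |kappa|^%g)/2, smoothing %s (p = %d, q = %g)\n",
      x$exponent, if (x$smoothing) "on" else "off", x$smooth_p, x$smooth_q))
  }
  invisible(x)
}

# raw (unsmoothed) node values on a frame list from frame_impl()
raw_monitor_impl <- function(frame, spec) {
  n <- length(frame$kappa)
  if (spec$kind == "uniform") return(rep(1, n))
  if (!all(is.finite(frame$kappa))) {
    abort(sprintf("non-finite curvature at node %d",
                  which(!is.finite(frame$kappa))[1]))
  }
  ak <- abs(frame$kappa)^spec$exponent
  up <- idx_up(n)
  floor_val <- sum((ak[up] + ak) / 2 * frame$edge_len) / frame$length
  0.5 * floor_val + 0.5 * ak
}

#' Evaluate the monitor function on a curve
#'
#' Returns the per-node monitor values for the given [monitor_spec()]; the
#' smoothing pass is applied when `spec$smoothing` is `TRUE`.
#' [raw_monitor()] returns the unsmoothed values.
#'
#' @param curve A curve as accepted by [as_curve()].
#' @param spec A [monitor_spec()].
#' @return Numeric vector of N positive monitor values aligned with the
#'   curve nodes.
#' @examples
#' octagon <- make_curve("circle", 8, mesh = "uniform_u")
#' monitor_values(octagon, monitor_spec("curvature"))  # constant on an N-gon
#' @export
monitor_values <- function(curve, spec = monitor_spec()) {
  curve <- as_curve(curve)
  m <- raw_monitor_impl(frame_impl(curve$x, curve$y), spec)
  if (needs_smoothing(spec)) m <- smooth_monitor(m, spec$smooth_p, spec$smooth_q)
  m
}

# smoothing is the identity on the constant uniform monitor, so skip it
# (this also keeps very small N valid, where the stencil would not fit)
needs_smoothing <- function(spec) spec$smoothing && spec$kind != "uniform"

#' @rdname monitor_values
#' @export
raw_monitor <- function(curve, spec = monitor_spec()) {
  curve <- as_curve(curve)
  raw_monitor_impl(frame_impl(curve$x, curve$y), spec)
}

#' Smooth node values by a periodic weighted moving average
#'
#' `Mtilde_i = sum_{k=i-p}^{i+p} M_k w^{|k-i|} / sum w^{|k-i|}` with
#' `w = q/(q+1)` and periodic indexing.  A convex combination: the output
#' stays within the range of the input and constants are fixed points.
#'
#' @param values Numeric vector of node values.
#' @param p Stencil half-width (nonnegative integer, `p < N/2`).
#' @param q Positive decay parameter.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_monitor <- function(values, p = 2L, q = 3) {
  n <- length(values)
  p <- as.integer(p)
  if (p >= n / 2) abort("smoothing half-width `p` must be < N/2")
  if (p == 0L) return(values)
  w <- (q / (q + 1))^(0:p)
  acc <- values
  for (k in seq_len(p)) {
    sh_up <- c(values[(k + 1):n], values[1:k])        # M_{i+k}
    sh_dn <- c(values[(n - k + 1):n], values[1:(n - k)])  # M_{i-k}
    acc <- acc + w[k + 1] * (sh_up + sh_dn)
  }
  acc / (1 + 2 * sum(w[-1]))
}

#' Discrete equidistribution ratio
#'
#' Measures how far the mesh is from equidistributing the monitor: per edge j
#' the weighted arc-length `w_j = ((M_j + M_{j+1})/2) h_j` is computed and
#' `max(w) / min(w)` returned.  Exactly 1 means the discrete `M ds` is
#' constant between neighbouring nodes.
#'
#' @param curve A curve as accepted by [as_curve()].
#' @param values Monitor values aligned with the curve nodes (defaults to the
#'   evaluated `spec`).
#' @param spec A [monitor_spec()] used when `values` is missing.
#' @return A numeric value >= 1.
#' @export
equidistribution_ratio <- function(curve, values = NULL,
                                   spec = monitor_spec()) {
  curve <- as_curve(curve)
  if (is.null(values)) values <- monitor_values(curve, spec)
  n <- nrow(curve)
  if (length(values) != n) abort("`values` must align with the curve nodes")
  up <- idx_up(n)
  h <- sqrt((curve$x[up] - curve$x)^2 + (curve$y[up] - curve$y)^2)
  w <- (values + values[up]) / 2 * h
  if (any(w == 0)) abort("zero weighted edge in equidistribution ratio")
  max(w) / min(w)
}
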