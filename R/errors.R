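#' Exact solutions for the shrinking circle
#'
#' Under classical curve shortening flow a unit circle stays a circle with
#' radius `r(t) = sqrt(1 - 2 t)` (vanishing at t = 0.5), and the enclosed
#' area of any closed curve decreases at exactly `2 pi` per unit time:
#' `A(t) = A(0) - 2 pi t`.
#'
#' @param t Time (for the radius, `t <= 0.5`).
#' @return Numeric vector of radii / areas.
#' @examples
#' exact_circle_radius(0.25)  # sqrt(0.5)
#' exact_csf_area(pi, 0.25)   # pi / 2
#' @export
exact_circle_radius <- function(t) {
  if (any(t > 0.5)) abort("the shrinking unit circle only exists for t <= 0.5")
  sqrt(1 - 2 * t)
}

#' @rdname exact_circle_radius
#' @param area0 Initial enclosed area A(0).
#' @export
exact_csf_area <- function(area0, t) {
  area0 - 2 * pi * t
}

#' Enclosed-area error of an evolution against a reference
#'
#' Computes the per-step error series `e_h(t^n) = A_h(t^n) - A_ref(t^n)`,
#' its discrete L2([0, T]) norm
#' `sqrt(sum_{n=1}^{N_T} e_h(t^n)^2 dt)`, and the absolute final-time error.
#'
#' @param result A completed `curve_evolution`.
#' @param area_ref Function `t -> exact area` (e.g. built on
#'   [exact_csf_area()]).
#' @return A list of class `area_error_report` with `l2_norm`, `abs_final`
#'   and a tibble `series` (columns `step`, `time`, `area`, `error`).
#' @export
area_error_l2 <- function(result, area_ref) {
  stopifnot(inherits(result, "curve_evolution"))
  if (result$status != "completed") {
    abort(sprintf("evolution did not complete: status '%s' at t = %.6g",
                  result$status, result$t_fail))
  }
  err <- result$area - area_ref(result$times)
  steps <- seq_along(result$times) - 1L
  structure(list(
    l2_norm = sqrt(sum(err[-1]^2) * result$dt),
    abs_final = abs(err[length(err)]),
    series = tibble(step = steps, time = result$times, area = result$area,
                    error = err)
  ), class = "area_error_report")
}

#' @export
print.area_error_report <- function(x, ...) {
  cat(sprintf("# Area error: L2 norm %.6g, |final| %.6g over %d steps\n",
              x$l2_norm, x$abs_final, nrow(x$series) - 1L))
  invisible(x)
}

#' Enclosed-area error against a gold-standard run
#'
#' When no closed-form area is available (forced flow), the error reference
#' is a much finer self-computed solution on the same spatial mesh.  The
#' gold standard's step size must divide the compared run's step size so the
#' time grids nest.
#'
#' @param result A completed `curve_evolution`.
#' @param gold A completed `curve_evolution` with `dt` dividing
#'   `result$dt`.
#' @return An `area_error_report` (see [area_error_l2()]).
#' @export
gold_standard_error <- function(result, gold) {
  stopifnot(inherits(result, "curve_evolution"),
            inherits(gold, "curve_evolution"))
  if (result$status != "completed" || gold$status != "completed") {
    abort("both runs must have completed")
  }
  ratio <- result$dt / gold$dt
  if (abs(ratio - round(ratio)) > 1e-8) {
    abort("gold-standard dt must divide the run's dt")
  }
  ratio <- round(ratio)
  idx <- 1L + (seq_along(result$times) - 1L) * ratio
  if (max(idx) > length(gold$area)) {
    abort("gold standard does not cover the run's time grid")
  }
  area_gs <- gold$area[idx]
  err <- result$area - area_gs
  steps <- seq_along(result$times) - 1L
  structure(list(
    l2_norm = sqrt(sum(err[-1]^2) * result$dt),
    abs_final = abs(err[length(err)]),
    series = tibble(step = steps, time = result$times, area = result$area,
                    error = err)
  ), class = "area_error_report")
}

#' Fitted convergence order from a refinement study
#'
#' Least-squares slope of `log(error)` against `log(resolution)`, negated so
#' that a method whose error decreases under refinement reports a positive
#' order (error ~ resolution^-order).
#'
#' @param resolutions Positive resolutions (e.g. numbers of time steps or
#'   nodes), at least two.
#' @param errors Positive errors, one per resolution.
#' @return The fitted order (single numeric).
#' @examples
#' convergence_order(c(10, 20, 40), c(1e-2, 2.5e-3, 6.25e-4))  # 2
#' @export
convergence_order <- function(resolutions, errors) {
  if (length(resolutions) < 2 || length(resolutions) != length(errors)) {
    abort("need at least two (resolution, error) pairs")
  }
  if (any(errors <= 0) || any(resolutions <= 0)) {
    abort("resolutions and errors must be positive")
  }
  -unname(coef(lm(log(errors) ~ log(resolutions)))[2])
}

#' Picard iteration extremes of a run
#'
#' @param result A `curve_evolution` with at least one completed step.
#' @return Named numeric vector `c(max = ..., min = ...)` of the per-step
#'   Picard iteration counts.
#' @export
picard_stats <- function(result) {
  stopifnot(inherits(result, "curve_evolution"))
  if (result$steps_done < 1) abort("no completed steps to summarise")
  c(max = max(result$picard_iters), min = min(result$picard_iters))
}
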