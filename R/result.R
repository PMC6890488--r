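#' @export
print.curve_evolution <- function(x, ...) {
  cat(sprintf(
    "# Curve evolution: %s scheme, N = %d nodes, %d/%d steps (dt = %.3g)\n",
    toupper(x$config$scheme), x$config$n_nodes, x$steps_done, x$n_steps,
    x$dt))
  cat(sprintf("# status: %s%s\n", x$status,
              if (!is.na(x$t_fail)) sprintf(" at t = %.6g", x$t_fail) else ""))
  if (x$steps_done > 0) {
    cat(sprintf("# area: %.6g -> %.6g; Picard iterations: max %d, min %d\n",
                x$area[1], x$area[length(x$area)],
                max(x$picard_iters), min(x$picard_iters)))
  }
  invisible(x)
}

#' Per-step summary of a curve evolution
#'
#' One row per recorded time level with the time, the enclosed polygon
#' area, and (from the first step on) the Picard iteration count; the edge
#' ratio column is present when it was recorded.
#'
#' @param x A `curve_evolution` from [evolve_curve()].
#' @param ... Unused.
#' @return A tibble with columns `step`, `time`, `area`, `picard_iters`
#'   (NA at step 0) and optionally `edge_ratio`.
#' @method tidy curve_evolution
#' @export
tidy.curve_evolution <- function(x, ...) {
  out <- tibble(
    step = seq_along(x$times) - 1L,
    time = x$times,
    area = x$area,
    picard_iters = c(NA_integer_, x$picard_iters)
  )
  if (!is.null(x$edge_ratio)) out$edge_ratio <- x$edge_ratio
  out
}

#' One-row summary of a curve evolution
#'
#' @inheritParams tidy.curve_evolution
#' @return A tibble with the scheme, resolution, step count, final time
#'   reached, final area, Picard extremes and termination status.
#' @method glance curve_evolution
#' @export
glance.curve_evolution <- function(x, ...) {
  tibble(
    scheme = x$config$scheme,
    n_nodes = x$config$n_nodes,
    n_steps = x$n_steps,
    steps_done = x$steps_done,
    dt = x$dt,
    t_end = x$times[length(x$times)],
    area_final = x$area[length(x$area)],
    picard_max = if (x$steps_done > 0) max(x$picard_iters) else NA_integer_,
    picard_min = if (x$steps_done > 0) min(x$picard_iters) else NA_integer_,
    status = x$status,
    t_fail = x$t_fail
  )
}

#' Extract recorded curve snapshots
#'
#' @param result A `curve_evolution`.
#' @return A tibble with columns `step`, `time`, `x`, `y` stacking all
#'   recorded snapshots.
#' @export
curve_snapshots <- function(result) {
  stopifnot(inherits(result, "curve_evolution"))
  steps <- as.integer(names(result$snapshots))
  dplyr::bind_rows(lapply(seq_along(steps), function(i) {
    s <- result$snapshots[[i]]
    tibble(step = steps[i], time = steps[i] * result$dt, x = s$x, y = s$y)
  }))
}

#' Plot a curve or the snapshots of an evolution
#'
#' `autoplot.curveflow_curve()` draws the closed polygon with its nodes;
#' `autoplot.curve_evolution()` overlays the recorded snapshots coloured by
#' time.
#'
#' @param object A curve or `curve_evolution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot curveflow_curve
#' @export
autoplot.curveflow_curve <- function(object, ...) {
  df <- dplyr::bind_rows(object, object[1, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.curveflow_curve
#' @method autoplot curve_evolution
#' @export
autoplot.curve_evolution <- function(object, ...) {
  snaps <- curve_snapshots(object)
  closed <- snaps |>
    dplyr::group_by(.data$step, .data$time) |>
    dplyr::group_modify(~ dplyr::bind_rows(.x, .x[1, ])) |>
    dplyr::ungroup()
  ggplot2::ggplot(closed,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$step, colour = .data$time)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
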