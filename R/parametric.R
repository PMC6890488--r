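#' Parametric closed curves
#'
#' A parametric curve is a periodic map from `u` in [0, 1] to the plane,
#' wrapped with an optional analytic derivative.  Named generators cover the
#' benchmark shapes used by the convergence studies:
#'
#' * `circle` — the unit circle `(cos 2 pi u, sin 2 pi u)`.
#' * `ellipse` — `(3 cos 2 pi u, sin 2 pi u)`, aspect ratio 3:1.
#' * `nonconvex` — a star-like nonconvex curve with several high-curvature
#'   lobes, a standard test for tangentially stabilised evolvers.
#' * `selfintersect` — `cos(4 pi u) (cos 2 pi u, sin 2 pi u)`, a
#'   self-intersecting curve that develops a geometric singularity in finite
#'   time under curve shortening flow.
#' * `lpball` — the unit l_p ball boundary, radius
#'   `r(u) = (|cos 2 pi u|^p + |sin 2 pi u|^p)^(-1/p)` (default `p = 10`),
#'   a rounded square with four high-curvature corners.
#'
#' All generators traverse counterclockwise.
#'
#' @param fun Function mapping a vector of `u` in [0, 1] to a 2-column
#'   matrix of points, with `fun(0) == fun(1)`.
#' @param deriv Optional analytic derivative `u -> d x / d u` (2-column
#'   matrix); when absent, derivatives are approximated by central
#'   differences on a refined sample.
#' @return A list of class `parametric_curve`.
#' @export
parametric_curve <- function(fun, deriv = NULL) {
  p0 <- fun(0)
  p1 <- fun(1)
  if (max(abs(p0 - p1)) > 1e-8) abort("parametric map must be periodic on [0, 1]")
  structure(list(fun = fun, deriv = deriv), class = "parametric_curve")
}

#' @rdname parametric_curve
#' @param name One of `"circle"`, `"ellipse"`, `"nonconvex"`,
#'   `"selfintersect"`, `"lpball"`.
#' @param p Exponent of the l_p ball (used by `"lpball"` only).
#' @export
curve_generator <- function(name, p = 10) {
  switch(name,
    circle = parametric_curve(
      function(u) cbind(cos(2 * pi * u), sin(2 * pi * u)),
      function(u) cbind(-2 * pi * sin(2 * pi * u), 2 * pi * cos(2 * pi * u))),
    ellipse = parametric_curve(
      function(u) cbind(3 * cos(2 * pi * u), sin(2 * pi * u)),
      function(u) cbind(-6 * pi * sin(2 * pi * u), 2 * pi * cos(2 * pi * u))),
    nonconvex = parametric_curve(function(u) {
      s <- sin(2 * pi * u)
      c <- cos(2 * pi * u)
      cbind(c, 0.5 * s + sin(c) + s * (0.2 + s * sin(6 * pi * u)^2))
    }),
    selfintersect = parametric_curve(function(u) {
      r <- cos(4 * pi * u)
      cbind(r * cos(2 * pi * u), r * sin(2 * pi * u))
    }),
    lpball = parametric_curve(function(u) {
      r <- (abs(cos(2 * pi * u))^p + abs(sin(2 * pi * u))^p)^(-1 / p)
      cbind(r * cos(2 * pi * u), r * sin(2 * pi * u))
    }),
    abort(sprintf("unknown curve name '%s'", name))
  )
}

#' Sample a named benchmark curve to a closed polygon
#'
#' Samples one of the [curve_generator()] shapes at N nodes.  With
#' `mesh = "equidistributed"` (the default) the sample points are placed by
#' the iterated de Boor algorithm so that the chosen monitor function is
#' equidistributed along the polygon (see [equidistribute_curve()]); with
#' `mesh = "uniform_u"` the parameter domain is sampled uniformly.
#'
#' @param name Curve name (see [curve_generator()]) .
#' @param n_nodes Number of nodes N >= 4.
#' @param monitor A [monitor_spec()] driving the equidistributed mesh.
#' @param mesh `"equidistributed"` or `"uniform_u"`.
#' @param p l_p-ball exponent.
#' @param ... Passed to [equidistribute_curve()] (`tol`, `max_iter`).
#' @return A curve tibble (see [as_curve()]).
#' @examples
#' ell <- make_curve("ellipse", 128, monitor_spec("curvature"))
#' edge_length_ratio(ell)  # > 1: nodes cluster at the high-curvature ends
#' @export
make_curve <- function(name, n_nodes, monitor = monitor_spec(),
                       mesh = c("equidistributed", "uniform_u"),
                       p = 10, ...) {
  mesh <- match.arg(mesh)
  pc <- curve_generator(name, p = p)
  if (mesh == "uniform_u") {
    u <- seq(0, 1, length.out = n_nodes + 1)[seq_len(n_nodes)]
    as_curve(pc$fun(u))
  } else {
    equidistribute_curve(pc, n_nodes, monitor, ...)
  }
}
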