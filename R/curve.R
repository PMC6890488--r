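#' Closed polygonal curves
#'
#' A closed curve is represented as a tibble with numeric columns `x` and `y`
#' holding the N unique nodes in order; closure is implicit (the last node
#' connects back to the first, and periodic "ghost" nodes exist only as index
#' arithmetic).  The parameter step is `dxi = 1/N`.  Nodes generated by this
#' package run counterclockwise, for which the normal `n = (t2, -t1)` points
#' outward and the signed curvature of a convex curve is negative, so the
#' curve-shortening velocity `V = kappa` moves the curve inward.
#'
#' @param nodes A data frame (or matrix) with columns/two columns `x`, `y`:
#'   the N distinct nodes of the closed polygon, in order, without a repeated
#'   closing node.
#' @return A tibble of class `curveflow_curve` with columns `x` and `y`.
#' @examples
#' sq <- as_curve(data.frame(x = c(1, 0, -1, 0), y = c(0, 1, 0, -1)))
#' enclosed_area(sq)
#' @export
as_curve <- function(nodes) {
  if (is.matrix(nodes)) {
    nodes <- data.frame(x = nodes[, 1], y = nodes[, 2])
  }
  if (!all(c("x", "y") %in% names(nodes))) {
    abort("`nodes` must have columns `x` and `y`")
  }
  x <- as.numeric(nodes$x)
  y <- as.numeric(nodes$y)
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    # tolerate an explicitly closed polygon by dropping the duplicate
    x <- x[-n]
    y <- y[-n]
    n <- n - 1
  }
  if (n < 4) abort("a closed curve needs at least 4 nodes")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("curve nodes must be finite")
  }
  out <- tibble(x = x, y = y)
  class(out) <- c("curveflow_curve", class(out))
  out
}

# periodic index helpers: i+1 and i-1 with wraparound for 1..n
idx_up <- function(n) c(2:n, 1L)
idx_dn <- function(n) c(n, 1:(n - 1L))

# Core discrete frame on plain coordinate vectors.  Tangent from the central
# chord, normal its clockwise rotation, curvature from the central second
# difference projected on the normal and scaled by the squared chord.
frame_impl <- function(x, y) {
  n <- length(x)
  up <- idx_up(n)
  dn <- idx_dn(n)
  cx <- x[up] - x[dn]
  cy <- y[up] - y[dn]
  chord2 <- cx * cx + cy * cy
  if (any(chord2 == 0)) {
    abort(sprintf("degenerate geometry: zero central chord at node %d",
                  which(chord2 == 0)[1]))
  }
  chord <- sqrt(chord2)
  tx <- cx / chord
  ty <- cy / chord
  nx <- ty
  ny <- -tx
  lx <- x[dn] - 2 * x + x[up]
  ly <- y[dn] - 2 * y + y[up]
  kappa <- 4 * (lx * nx + ly * ny) / chord2
  ex <- x[up] - x
  ey <- y[up] - y
  h <- sqrt(ex * ex + ey * ey)
  if (any(h == 0)) {
    abort(sprintf("degenerate geometry: zero edge length at node %d",
                  which(h == 0)[1]))
  }
  list(tx = tx, ty = ty, nx = nx, ny = ny, kappa = kappa,
       chord = chord, edge_len = h, length = sum(h))
}

#' Discrete geometric frame of a closed curve
#'
#' Computes, per node i of the polygon: the unit tangent
#' `t_i = (x_{i+1} - x_{i-1}) / |x_{i+1} - x_{i-1}|` from the central chord,
#' the unit normal `n_i = (t_2, -t_1)`, the signed curvature
#' `kappa_i = 4 (x_{i-1} - 2 x_i + x_{i+1}) . n_i / |x_{i+1} - x_{i-1}|^2`,
#' the edge length `h_i = |x_{i+1} - x_i|` (edge i joins node i to node i+1,
#' periodic), and the central chord length.  The total polygon length
#' `sum(h)` is attached as attribute `length`.
#'
#' @param curve A curve as accepted by [as_curve()].
#' @return A tibble with one row per node and columns `x`, `y`, `tx`, `ty`,
#'   `nx`, `ny`, `kappa`, `edge_len`, `chord`; attribute `length` holds the
#'   polygon length.
#' @examples
#' sq <- as_curve(data.frame(x = c(1, 0, -1, 0), y = c(0, 1, 0, -1)))
#' curve_frame(sq)$kappa  # constant -2 on this square
#' @export
curve_frame <- function(curve) {
  curve <- as_curve(curve)
  f <- frame_impl(curve$x, curve$y)
  out <- tibble(x = curve$x, y = curve$y,
                tx = f$tx, ty = f$ty, nx = f$nx, ny = f$ny,
                kappa = f$kappa, edge_len = f$edge_len, chord = f$chord)
  attr(out, "length") <- f$length
  out
}

#' Signed enclosed area of a closed polygon
#'
#' The shoelace sum `A = (1/2) sum(x_i y_{i+1} - x_{i+1} y_i)`, positive for
#' counterclockwise orientation.
#'
#' @inheritParams curve_frame
#' @return A single numeric value.
#' @examples
#' unit_sq <- as_curve(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' enclosed_area(unit_sq)
#' @export
enclosed_area <- function(curve) {
  curve <- as_curve(curve)
  x <- curve$x
  y <- curve$y
  up <- idx_up(length(x))
  0.5 * sum(x * y[up] - x[up] * y)
}

#' Total length of a closed polygon
#'
#' @inheritParams curve_frame
#' @return Sum of the edge lengths.
#' @export
curve_length <- function(curve) {
  curve <- as_curve(curve)
  up <- idx_up(nrow(curve))
  sum(sqrt((curve$x[up] - curve$x)^2 + (curve$y[up] - curve$y)^2))
}

#' Ratio of maximal to minimal edge length
#'
#' A mesh-quality diagnostic: 1 for a uniform arc-length mesh, growing as
#' nodes cluster.  Tangential mesh relaxation towards uniform arc-length
#' drives this ratio towards 1 in time.
#'
#' @inheritParams curve_frame
#' @return A numeric value >= 1.
#' @export
edge_length_ratio <- function(curve) {
  curve <- as_curve(curve)
  up <- idx_up(nrow(curve))
  h <- sqrt((curve$x[up] - curve$x)^2 + (curve$y[up] - curve$y)^2)
  max(h) / min(h)
}

#' Read / write a polygon as CSV
#'
#' Plain CSV with header `x,y`, one node per row, implicit closure (the last
#' row is not a repeat of the first).
#'
#' @param file Path to a CSV file.
#' @return `read_curve()` returns a curve tibble.
#' @export
read_curve <- function(file) {
  as_curve(readr::read_csv(file, col_types = readr::cols(
    x = readr::col_double(), y = readr::col_double())))
}

#' @rdname read_curve
#' @param curve A curve as accepted by [as_curve()].
#' @export
write_curve <- function(curve, file) {
  curve <- as_curve(curve)
  readr::write_csv(curve[, c("x", "y")], file)
  invisible(file)
}

#' @export
print.curveflow_curve <- function(x, ...) {
  cat(sprintf("# Closed polygonal curve: %d nodes, length %.6g, area %.6g\n",
              nrow(x), curve_length(x), enclosed_area(x)))
  NextMethod()
}
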