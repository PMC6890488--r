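#' Normal-velocity forcing V = alpha * kappa + beta
#'
#' The curve moves in the normal direction with velocity
#' `V = alpha(x, t) kappa + beta(x, t)`.  `alpha` weights the curvature term
#' and must be nonnegative; `beta` is an external forcing.  Classical curve
#' shortening flow is `alpha = 1`, `beta = 0`.  Each component may be a
#' constant or a function `f(x, y, t)` of the node coordinates and time
#' returning per-node values.
#'
#' @param alpha Nonnegative constant or function `(x, y, t) -> values`.
#' @param beta Constant or function `(x, y, t) -> values`.
#' @return A list of class `curve_forcing`.
#' @examples
#' forcing()           # classical curve shortening flow
#' forcing(beta = 10)  # constant outward forcing
#' @export
forcing <- function(alpha = 1, beta = 0) {
  norm1 <- function(f, name, check_sign = FALSE) {
    if (is.numeric(f) && length(f) == 1) {
      if (check_sign && f < 0) abort("`alpha` must be nonnegative")
      structure(function(x, y, t) f, constant = TRUE, value = f)
    } else if (is.function(f)) {
      structure(f, constant = FALSE)
    } else {
      abort(sprintf("`%s` must be a single number or a function(x, y, t)", name))
    }
  }
  structure(list(alpha = norm1(alpha, "alpha", check_sign = TRUE),
                 beta = norm1(beta, "beta")),
            class = "curve_forcing")
}
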