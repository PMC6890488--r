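# Independent oracles and shared fixtures for the test suite.

# Signed polygon area by fan triangulation from the first vertex:
# sum of signed triangle areas (x1, x_i, x_{i+1}).
fan_triangulation_area <- function(x, y) {
  n <- length(x)
  tot <- 0
  for (i in 2:(n - 1)) {
    tot <- tot + 0.5 * ((x[i] - x[1]) * (y[i + 1] - y[1]) -
                          (x[i + 1] - x[1]) * (y[i] - y[1]))
  }
  tot
}

# Regular N-gon inscribed in the unit circle, counterclockwise.
regular_ngon <- function(n) {
  th <- 2 * pi * (0:(n - 1)) / n
  data.frame(x = cos(th), y = sin(th))
}

# Random simple-ish closed polygon: radial perturbation of a circle.
random_polygon <- function(n, seed) {
  set.seed(seed)
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.5, 1.5)
  data.frame(x = r * cos(th), y = r * sin(th))
}

# One explicit forward-Euler step with all spatial terms at level n:
# normal displacement mu^n (lap x^n . n) + dt beta, tangential displacement
# nu^n (lap x^n . t) + dt P (M_{i+1} - M_{i-1}) / (tau M^2 |chord|).
explicit_euler_oracle <- function(curve, dt, monitor, tau, p_mode,
                                  alpha = 1, beta = 0) {
  fr <- curve_frame(curve)
  n <- nrow(fr)
  up <- c(2:n, 1)
  dn <- c(n, 1:(n - 1))
  m <- monitor_values(curve, monitor)
  p <- if (p_mode == "balanced") m * (fr$chord / (2 / n))^2 else rep(1, n)
  lapx <- fr$x[dn] - 2 * fr$x + fr$x[up]
  lapy <- fr$y[dn] - 2 * fr$y + fr$y[up]
  mu <- 4 * dt * alpha / fr$chord^2
  nu <- 4 * dt * p / (tau * m * fr$chord^2)
  disp_n <- mu * (lapx * fr$nx + lapy * fr$ny) + dt * beta
  disp_t <- nu * (lapx * fr$tx + lapy * fr$ty) +
    dt * p * (m[up] - m[dn]) / (tau * m^2 * fr$chord)
  data.frame(x = fr$x + disp_n * fr$nx + disp_t * fr$tx,
             y = fr$y + disp_n * fr$ny + disp_t * fr$ty)
}
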