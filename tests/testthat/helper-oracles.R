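# Independent oracles used across the test files. These deliberately avoid
# the package's closed-form/analytic code paths: fixed-step RK4 integration
# of the rate equations and grid bisection for curve inversion.

# RK4 value of [PL] at a single time, fixed step.
rk4_complex <- function(p0, l0, kon, koff, t_end, dt = 1e-4) {
  if (t_end == 0) return(0)
  f <- function(c) kon * (p0 - c) * (l0 - c) - koff * c
  n <- ceiling(t_end / dt)
  h <- t_end / n
  c <- 0
  for (i in seq_len(n)) {
    k1 <- f(c)
    k2 <- f(c + h / 2 * k1)
    k3 <- f(c + h / 2 * k2)
    k4 <- f(c + h * k3)
    c <- c + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c
}

# Full RK4 trajectory on a regular grid (for inversion oracles).
rk4_grid <- function(p0, l0, kon, koff, t_max, dt = 1e-3) {
  f <- function(c) kon * (p0 - c) * (l0 - c) - koff * c
  n <- ceiling(t_max / dt)
  out <- numeric(n + 1)
  c <- 0
  for (i in seq_len(n)) {
    k1 <- f(c)
    k2 <- f(c + dt / 2 * k1)
    k3 <- f(c + dt / 2 * k2)
    k4 <- f(c + dt * k3)
    c <- c + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1] <- c
  }
  list(time = seq(0, by = dt, length.out = n + 1), complex = out)
}

# Invert a bound fraction on an RK4 grid by monotone interpolation.
oracle_invert <- function(p0, l0, kon, koff, f_target, t_max, dt = 1e-3) {
  tr <- rk4_grid(p0, l0, kon, koff, t_max, dt)
  stats::approx(tr$complex / p0, tr$time, xout = f_target)$y
}

# Minimal stand-in fit objects for f_test arithmetic checks.
fake_fit <- function(rss, n_points, n_params) {
  structure(list(rss = rss, n_points = n_points, n_params = n_params),
            class = "kinetic_fit")
}

# Shared fixtures
benchmark_timer <- function() {
  timer_system(1e-6, 2e-6, rate_constants(3.6e5, 9.4e-6))
}

nonfusion_record <- function(f_timer, f_analyte, emitter = "E1",
                             burst = "b1", scan = 1L, total = 100) {
  tibble::tibble(
    emitter_id = emitter, burst_id = burst, scan_index = as.integer(scan),
    species = c("timer_apo", "timer_bound", "analyte_apo", "analyte_bound"),
    abundance = total * c(1 - f_timer, f_timer, 1 - f_analyte, f_analyte)
  )
}
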