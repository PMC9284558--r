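# Independent oracles and shared fixtures for the suite.

# Fixed-step classical RK4 integrator, written directly against the network
# definition (mass-action rate law evaluated in plain R). Independent of the
# package's compiled Rosenbrock path; used as the reference solution.
rk4_integrate <- function(net, y0, t0, t1, dt = 0.01) {
  Mre <- tempogate:::.reactant_matrix(net)
  Nn <- tempogate:::.net_matrix(net)
  k <- tempogate:::.internal_rates(net)
  f <- function(y) {
    v <- k * apply(Mre, 2L, function(m) prod(y^m))
    drop(Nn %*% v)
  }
  y <- y0
  n <- round((t1 - t0) / dt)
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2); k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# calibrated rate model, computed once per test run
calibrated_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_rate_model(rate_model())
    cache
  }
})

# ordered two-input schedule helper
ab_schedule <- function(dt, c = 100, t_end = dt + 3600, first = "A",
                        second = "B") {
  injection_schedule(c(first, second), c(0, dt), c(c, c), t_end = t_end)
}

# concentration of one species over time
species_curve <- function(traj, name) {
  traj$conc[, which(traj$species == name)]
}
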