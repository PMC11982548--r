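# Shared fixtures for the test-suite.
#
# Protocol-level tests run on reduced problem sizes so the whole suite stays
# fast: a half-scale AL (10 glomeruli, 50 PNs, 140 LNs) with shortened
# training (10 presentations); the full 100-PN network and 30-presentation
# protocol are exercised in the acceptance tests. Expensive trained networks
# are cached per seed within a session.

compact_network <- function(seed) {
  build_al_network(seed = seed, n_glomeruli = 10L, n_multipolar = 20L)
}

tiny_network <- function(seed = 1L) {
  build_al_network(seed = seed, n_glomeruli = 2L, pn_per_glom = 3L,
                   uln_per_glom = 3L, n_multipolar = 4L)
}

# short, cheap trial configuration for engine-behavior tests
tiny_config <- function(...) {
  do.call(sim_config, utils::modifyList(
    list(trial_ms = 400, t_on = 100, stim_duration = 200), list(...)))
}

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# classical RK4 for scalar/vector ODEs, used as the integration oracle
rk4_integrate <- function(f, y0, t_end, dt) {
  n <- round(t_end / dt)
  y <- y0
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}
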