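test_that("intrinsic currents follow g * m^M * h^N * (V - E)", {
  # zero conductance and reversal-potential zeros
  expect_equal(intrinsic_current(0, 0.7, 3L, 0.2, 1L, -60, 50), 0)
  expect_equal(intrinsic_current(90, 1, 3L, 1, 1L, 50, 50), 0)
  # hand arithmetic: 10 * 0.5^4 * (-60 + 95) = 21.875
  expect_equal(intrinsic_current(10, 0.5, 4L, 1, 0L, -60, -95), 21.875)
  expect_error(intrinsic_current(-1, 0.5, 4L, 1, 0L, -60, -95), "nonnegative")
  expect_error(intrinsic_current(1, 1.5, 4L, 1, 0L, -60, -95), "\\[0, 1\\]")
})

test_that("gating kinetics relax exponentially toward steady state", {
  expect_equal(gating_derivative(0.3, 0.3, 5), 0)
  expect_equal(gating_derivative(0, 1, 2), 0.5)
  expect_error(gating_derivative(0.5, 0.5, 0), "positive")
  # RK4 integration of the linear gate matches the closed form to <= 1e-8
  x <- rk4_integrate(function(t, x) gating_derivative(x, 1, 2),
                     y0 = 0, t_end = 2, dt = 0.04)
  expect_equal(x, 1 - exp(-1), tolerance = 1e-8)
})

test_that("calcium dynamics have the printed equilibrium and time constant", {
  p <- neuron_params("PN")
  expect_equal(calcium_derivative(p$Ca_inf, 0, p), 0)
  # influx scale: at Ca = Ca_inf, I_T = -1 uA gives d[Ca]/dt = A_ca
  expect_equal(calcium_derivative(2.4e-4, -1, p), 5.2e-5)
  # relaxation from 2*Ca_inf with I_T = 0: time constant 5 ms
  ca <- rk4_integrate(function(t, ca) calcium_derivative(ca, 0, p),
                      y0 = 2 * p$Ca_inf, t_end = 5, dt = 0.01)
  expect_equal((ca - p$Ca_inf) / p$Ca_inf, exp(-1), tolerance = 1e-7)
})

test_that("neuron parameter sets match the published values", {
  pn <- neuron_params("PN")
  expect_equal(pn$Cm, 2.9e-4)
  expect_equal(c(pn$gL, pn$gKL, pn$gNa, pn$gK, pn$gA, pn$gT, pn$gh),
               c(0.01, 0.012, 90, 10, 10, 2, 0.02))
  expect_equal(c(pn$EL, pn$EKL, pn$ENa, pn$ECa), c(-70, -95, 50, 140))
  ln <- neuron_params("LN")
  expect_equal(ln$Cm, 1.43e-4)
  expect_equal(c(ln$gL, ln$gKL, ln$gNa, ln$gK, ln$gT),
               c(0.05, 0.018, 100, 10, 1.75))
  # LNs carry no A-current and no h-current
  expect_equal(c(ln$gA, ln$gh), c(0, 0))
  expect_equal(c(pn$A_ca, pn$tau_ca, pn$Ca_inf), c(5.2e-5, 5, 2.4e-4))
  expect_error(neuron_params("PN", bogus = 1), "unknown")
})

test_that("membrane derivative assembles the printed current set", {
  pn0 <- neuron_params("PN", gL = 0, gKL = 0, gNa = 0, gK = 0, gA = 0,
                       gT = 0, gh = 0)
  st <- neuron_rest_state(-60, pn0)
  expect_equal(membrane_derivative(st, pn0), 0)
  # only the two leaks active, V at EL: dV/dt = -gKL*(EL - EKL)/Cm
  pnL <- neuron_params("PN", gNa = 0, gK = 0, gA = 0, gT = 0, gh = 0)
  stL <- neuron_rest_state(pnL$EL, pnL)
  expect_equal(membrane_derivative(stL, pnL),
               -pnL$gKL * pnL$area * (pnL$EL - pnL$EKL) / pnL$Cm)
})

test_that("isolated neurons rest below threshold and spike under a pulse", {
  for (cls in c("PN", "LN")) {
    p <- neuron_params(cls)
    s <- simulate_neuron(p, t_ms = 2000, I_stim = 0)
    n <- length(s$V)
    # stationary resting state after 2 s, below spike threshold
    drift <- abs(s$V[n] - s$V[n - 250]) / (250 * 0.04)
    expect_lt(drift, 1e-4)
    expect_lt(s$V[n], 0)
    expect_length(s$spikes, 0)
  }
  # suprathreshold 500-ms pulse elicits at least one action potential
  pulse <- function(t) ifelse(t >= 100 & t <= 600, 1e-3, 0)
  s <- simulate_neuron(neuron_params("PN"), t_ms = 700, I_stim = pulse)
  expect_gte(length(s$spikes), 1)
  expect_gt(max(s$V), 0)
})

test_that("kinetics table gives bounded steady states and positive taus", {
  kin <- al_kinetics()
  V <- seq(-120, 40, by = 2.5)
  for (cur in names(kin)) {
    expect_true(all(kin[[cur]]$m_inf(V) >= 0 & kin[[cur]]$m_inf(V) <= 1),
                label = paste(cur, "m_inf bounded"))
    expect_true(all(kin[[cur]]$tau_m(V) > 0))
    if (!is.null(kin[[cur]]$h_inf)) {
      expect_true(all(kin[[cur]]$h_inf(V) >= 0 & kin[[cur]]$h_inf(V) <= 1))
      expect_true(all(kin[[cur]]$tau_h(V) > 0))
    }
  }
})
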