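test_that("percept activation profiles are peaked, symmetric Gaussians", {
  pc <- al_percepts(100, 7)
  expect_equal(pc$lo[1], 1)
  expect_equal(pc$hi[7], 100)
  expect_equal(sum(pc$span), 100)
  p1 <- pc[1, ]
  x <- seq(p1$lo - 1, p1$hi, by = 0.01)
  amp <- percept_activation_profile(x, p1, width = 0.5, peak = 2)
  expect_equal(max(amp), 2, tolerance = 1e-4)  # peak at the center
  # symmetry about the center
  a_l <- percept_activation_profile(p1$center - 3, p1, 0.5)
  a_r <- percept_activation_profile(p1$center + 3, p1, 0.5)
  expect_equal(a_l, a_r)
  # wider width activates strictly more positions above any threshold
  xs <- seq_len(100) - 0.5
  wide <- percept_activation_profile(xs, p1, 0.372)
  narrow <- percept_activation_profile(xs, p1, 0.1)
  for (thr in c(0.05, 0.2, 0.5)) {
    expect_gt(sum(wide > thr), sum(narrow > thr))
  }
  expect_error(percept_activation_profile(xs, p1, 0), "positive")
})

test_that("simple odor classes share support and differ in widths", {
  cls_a <- make_odor_class(1:3, list(c(1, 0.7, 0.45), c(0.45, 1, 0.7)),
                           "rewarded", "A")
  expect_length(cls_a, 2)
  expect_equal(which(cls_a[[1]]$widths > 0), 1:3)
  cls_b <- make_odor_class(2:4, list(c(1, 0.7, 0.45)), "habituated", "B")
  shared <- intersect(which(cls_a[[1]]$widths > 0), which(cls_b[[1]]$widths > 0))
  expect_length(shared, 2)  # rewarded {1,2,3} and habituated {2,3,4}
  expect_error(make_odor_class(c(1, 1, 2), list(c(1, 1, 1)), "rewarded"),
               "distinct")
  # identical width vectors give identical odors
  w <- list(c(0.6, 0.6, 0.6), c(0.6, 0.6, 0.6))
  cls <- make_odor_class(1:3, w, "rewarded")
  expect_equal(cls[[1]]$widths, cls[[2]]$widths)
})

test_that("chemical blends map proportions onto percept widths", {
  od <- blend_to_odor(c(0.372, 0.253, 0.141, 0.102, 0.078, 0.054), "rewarded",
                      "PH1")
  expect_equal(od$widths[1], 0.372)
  expect_equal(od$widths[7], 0)
  expect_error(blend_to_odor(rep(0, 6)), "degenerate|sum")
  expect_error(blend_to_odor(c(-0.1, 0.3, 0.3, 0.2, 0.2, 0.1)), "nonnegative")
  expect_error(blend_to_odor(c(0.5, 0.3, 0.3, 0.2, 0.2, 0.1)), "sum")
  # permutation equivariance
  p <- c(0.372, 0.253, 0.141, 0.102, 0.078, 0.054)
  perm <- c(3, 1, 2, 6, 4, 5)
  expect_equal(blend_to_odor(p[perm])$widths[1:6], p[perm])
})

test_that("the stimulus pulse has the printed rise/decay closed forms", {
  expect_equal(stimulus_current(99.9, t_on = 100, peak = 2), 0)
  # at pulse end: peak * (1 - exp(-500/66.7))
  v_end <- stimulus_current(600, t_on = 100, peak = 2)
  expect_equal(v_end / 2, 1 - exp(-500 / 66.7))
  expect_equal(v_end / 2, 0.99945, tolerance = 1e-4)
  # 200 ms after offset the amplitude has dropped by e^-1
  expect_equal(stimulus_current(800, t_on = 100, peak = 2) / v_end, exp(-1))
  # continuous, nonnegative, < 1% of peak within 1 s after offset
  t <- seq(0, 2000, by = 0.5)
  I <- stimulus_current(t, t_on = 100, peak = 2)
  expect_true(all(I >= 0))
  expect_lt(max(abs(diff(I))), 0.02)
  expect_lt(stimulus_current(1600, t_on = 100, peak = 2), 0.01 * 2)
  expect_error(stimulus_current(0, peak = -1), "nonnegative")
})

test_that("background noise is zero-mean Gaussian and seed-reproducible", {
  expect_true(all(background_noise(10, 5, sd = 0, seed = 1) == 0))
  m <- background_noise(2000, 10, sd = 0.5, seed = 2)
  expect_lt(abs(mean(m)), 3 * 0.5 / sqrt(length(m)))
  expect_identical(background_noise(50, 4, 1, seed = 9),
                   background_noise(50, 4, 1, seed = 9))
  expect_error(background_noise(10, 5, sd = -1), "nonnegative")
})

test_that("sensor features map proportionally onto pulse parameters", {
  p1 <- sensor_features_to_pulse(1, 1, 1)
  p2 <- sensor_features_to_pulse(2, 2, 0.5)
  expect_equal(p2$peak, 2 * p1$peak)            # peak ~ dR
  expect_equal(p2$tau_rise, p1$tau_rise / 2)    # tau_rise ~ 1/ema_max
  expect_equal(p2$tau_decay, 2 * p1$tau_decay)  # tau_decay ~ 1/ema_min
  # default constants reproduce the small-network pulse scale at unit features
  expect_equal(p1$tau_rise, 66.7)
  expect_equal(p1$tau_decay, 200)
  expect_error(sensor_features_to_pulse(1, 0, 1), "positive")
})

test_that("the synthetic sensor dataset has the 16x8, 6-odor structure", {
  d <- synthetic_sensor_dataset(seed = 4, n_reps = 10)
  feat_cols <- setdiff(names(d), c("odor", "label"))
  expect_length(feat_cols, 16 * 8)
  expect_equal(nrow(d), 6 * 10)
  expect_equal(sort(unique(d$label)), c("habituated", "rewarded"))
  expect_equal(sum(tapply(d$label, d$odor, function(x) x[1]) == "rewarded"), 3)
  # per-column z-scoring
  n <- normalize_sensor_features(d)
  expect_lt(max(abs(vapply(n[feat_cols], mean, 0))), 1e-12)
  expect_equal(unname(vapply(n[feat_cols], sd, 0)), rep(1, 128))
  # templates of distinct odors differ by much more than the jitter scale
  tpl <- attr(d, "templates")
  dists <- utils::combn(6, 2, function(ij)
    sqrt(mean((tpl[[ij[1]]] - tpl[[ij[2]]])^2)))
  expect_gt(min(dists), 3 * 0.15)
  # reproducibility
  expect_identical(synthetic_sensor_dataset(seed = 4, n_reps = 10),
                   synthetic_sensor_dataset(seed = 4, n_reps = 10))
})

test_that("equal blends produce identical per-neuron input vectors", {
  net <- tiny_network()
  p <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  a <- odor_input_profile(blend_to_odor(p), net)
  b <- odor_input_profile(blend_to_odor(p), net)
  expect_identical(a, b)
  # input amplitudes are nonnegative and peak inside active percepts
  expect_true(all(a$peak >= 0))
  expect_gt(max(a$peak), 0)
})

test_that("sensor odors carry per-percept pulse parameters", {
  d <- synthetic_sensor_dataset(seed = 1, n_reps = 2)
  od <- sensor_odor(d[1, ], reward = "rewarded", label = "o1")
  expect_equal(nrow(od$pulse), 16)
  expect_true(all(od$pulse$peak_scale > 0))
  expect_true(all(od$pulse$tau_rise > 0))
  net <- build_large_network(seed = 1, n_pn = 64, n_ln = 160, p = 0.2)
  inp <- odor_input_profile(od, net, sim_config())
  # only the first half of PNs and LNs receives input
  expect_true(all(inp$peak[33:64] == 0))
  expect_gt(sum(inp$peak[1:32] > 0), 0)
})
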