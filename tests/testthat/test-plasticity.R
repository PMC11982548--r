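test_that("spike facilitation increments follow the printed rule", {
  rule <- plasticity_rule("both")
  # presynaptic spike during a rewarded presentation
  expect_equal(apply_spike_facilitation(1, TRUE, FALSE, rule, "rewarded"), 1.15)
  # postsynaptic spike during a habituated presentation stacks on top
  expect_equal(apply_spike_facilitation(1.15, FALSE, TRUE, rule, "habituated"),
               1.30)
  # plasticity disabled
  off <- plasticity_rule("off")
  expect_equal(apply_spike_facilitation(1, TRUE, TRUE, off, "rewarded"), 1)
  # rule gating: associative increments only during rewarded odors
  expect_equal(apply_spike_facilitation(1, TRUE, FALSE, rule, "habituated"), 1)
  pre <- plasticity_rule("pre_only")
  expect_equal(apply_spike_facilitation(1, FALSE, TRUE, pre, "habituated"), 1)
  expect_error(apply_spike_facilitation(1, TRUE, FALSE, "nope"), "mode")
})

test_that("facilitation forgets exponentially toward baseline", {
  expect_equal(decay_facilitation(1, 1e6), 1)
  expect_equal(decay_facilitation(2, 0), 2)
  # printed tau = 30 s: F = 1.15 decays to 1 + 0.15/e after 30 s
  expect_equal(decay_facilitation(1.15, 30000), 1 + 0.15 * exp(-1))
  expect_equal(decay_facilitation(1.15, 30000), 1.05518, tolerance = 1e-4)
  # monotone non-increasing toward 1
  d <- decay_facilitation(1.8, c(0, 10, 100, 1e4, 1e6))
  expect_true(all(diff(d) < 0) && all(d >= 1))
  expect_error(decay_facilitation(1.5, -1), "nonnegative")
})

test_that("freezing captures decayed multipliers and is idempotent", {
  net <- tiny_network()
  f1 <- freeze_weights(net)
  expect_true(all(f1$edges$ln2pn$F == 1))  # untrained network
  # a facilitated edge decays to the freeze time
  net$edges$ln2pn$F[1] <- 1.6
  net$edges$ln2pn$t_last[1] <- 0
  net$clock_ms <- 30000
  fr <- freeze_weights(net)
  expect_equal(fr$edges$ln2pn$F[1], 1 + 0.6 * exp(-1))
  expect_identical(freeze_weights(fr), fr)
  # freezing mid-training is a state error
  bad <- tiny_network()
  bad$training_active <- TRUE
  expect_error(freeze_weights(bad), "mid-training")
})

test_that("shuffling preserves the weight multiset and totals per class", {
  net <- tiny_network()
  set.seed(42)
  net$edges$ln2pn$F <- 1 + rexp(length(net$edges$ln2pn$F), 2)
  net$edges$ln2ln$F <- 1 + rexp(length(net$edges$ln2ln$F), 2)
  net$frozen <- TRUE
  shuf <- shuffle_weights(net, seed = 7)
  w0 <- weight_table(net); w1 <- weight_table(shuf)
  for (cls in c("ln2pn", "ln2ln")) {
    expect_equal(sort(w1$weight[w1$class == cls]),
                 sort(w0$weight[w0$class == cls]))
    expect_equal(sum(w1$weight[w1$class == cls]),
                 sum(w0$weight[w0$class == cls]))
  }
  expect_false(identical(w1$weight, w0$weight))
  # deterministic under a fixed seed
  expect_identical(shuffle_weights(net, seed = 7)$edges$ln2pn$F,
                   shuf$edges$ln2pn$F)
  unfrozen <- tiny_network()
  expect_error(shuffle_weights(unfrozen), "frozen")
  empty <- build_al_network(seed = 1, n_glomeruli = 2L, pn_per_glom = 2L,
                            uln_per_glom = 2L, n_multipolar = 2L,
                            probs = setNames(rep(0, 10),
                                             names(al_connection_probs())))
  empty$frozen <- TRUE
  expect_error(shuffle_weights(empty), "empty")
})

test_that("training with plasticity off leaves every weight at baseline", {
  net <- tiny_network()
  env <- simple_environment()
  tr <- run_training(net, env, plasticity_rule("off"), tiny_config(),
                     n_presentations = 4L, seed = 3)
  expect_true(all(tr$edges$ln2pn$F == 1))
  expect_true(all(tr$edges$ln2ln$F == 1))
  expect_equal(nrow(attr(tr, "log")), 4L)
})

test_that("environment forgetting follows the tau = 30 s decay", {
  # facilitation acquired in Env1 and untouched during 60 s of Env2
  # training decays by exactly e^-2
  expect_equal(decay_facilitation(1.9, 60000) - 1, 0.9 * exp(-2))
})
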