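# minimal hand-built spike record
fake_record <- function(neuron, time, n_pn = 10, trial_ms = 1000,
                        window = c(200, 700)) {
  structure(list(spikes = data.frame(neuron = neuron, time = time),
                 n_pn = n_pn, n_ln = 0, trial_ms = trial_ms,
                 window = window, odor = "x", reward = "none",
                 stage = "test", seed = 1, V = NULL, v_time = NULL),
            class = "al_spikes")
}

# Poisson raster with given per-PN rates (Hz) over the window
poisson_record <- function(rates, window = c(200, 700), seed = 1) {
  set.seed(seed)
  dur_s <- diff(window) / 1000
  sp <- do.call(rbind, lapply(seq_along(rates), function(i) {
    n <- rpois(1, rates[i] * dur_s)
    if (n == 0) return(NULL)
    data.frame(neuron = i, time = sort(runif(n, window[1], window[2])))
  }))
  if (is.null(sp)) sp <- data.frame(neuron = integer(), time = numeric())
  fake_record(sp$neuron, sp$time, n_pn = length(rates), window = window)
}

test_that("binned counts tile the window and conserve spikes", {
  rec <- fake_record(c(1, 1, 2, 3), c(250, 340, 450, 650))
  m <- binned_counts(rec, bin_ms = 100, normalize = FALSE)
  expect_equal(dim(m), c(10, 5))
  expect_equal(sum(m), 4)          # counting oracle
  expect_equal(m[1, 1], 1)
  expect_equal(m[1, 2], 1)
  expect_equal(m[3, 5], 1)
  # empty record gives the zero matrix
  m0 <- binned_counts(fake_record(integer(), numeric()), 100)
  expect_true(all(m0 == 0))
  # normalization divides by the grand sum
  mn <- binned_counts(rec, 100)
  expect_equal(sum(mn), 1)
  expect_error(binned_counts(rec, 600), "exceeds")
  expect_error(binned_counts(rec, 130), "tile")
})

test_that("representation correlation averages per-bin Pearson", {
  rec <- poisson_record(c(rep(40, 5), rep(5, 5)), seed = 2)
  m <- binned_counts(rec, 100)
  expect_equal(as.numeric(representation_correlation(m, m)), 1)
  m2 <- binned_counts(poisson_record(c(rep(40, 5), rep(5, 5)), seed = 3), 100)
  expect_equal(representation_correlation(m, m2),
               representation_correlation(m2, m))  # symmetric
  expect_error(representation_correlation(m, m[1:5, ]), "equal")
  # degenerate bins are skipped with a counter, not imputed
  ma <- matrix(0, 4, 3); ma[, 1] <- c(1, 2, 3, 4)
  mb <- matrix(0, 4, 3); mb[, 1] <- c(1, 2, 3, 5)
  r <- representation_correlation(ma, mb)
  expect_equal(attr(r, "skipped_bins"), 2)
  expect_gt(as.numeric(r), 0.9)
  expect_warning(representation_correlation(matrix(0, 4, 2), matrix(0, 4, 2)),
                 "degenerate")
})

test_that("permuted PN identities decorrelate exchangeable rasters", {
  # permutation-null oracle: correlations of PN-permuted copies center near 0
  set.seed(11)
  rates <- runif(40, 2, 60)
  rec <- poisson_record(rates, seed = 4)
  m <- binned_counts(rec, 100, normalize = FALSE)
  cors <- vapply(1:30, function(i) {
    as.numeric(representation_correlation(m, m[sample.int(40), ]))
  }, 0)
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("correlation pipeline recovers designed rate structure", {
  # two classes sharing a rate block: between-class correlation is high
  # when the shared block dominates and low when supports are disjoint
  shared <- c(rep(50, 20), rep(2, 20))
  a <- binned_counts(poisson_record(shared, seed = 5), 100)
  b <- binned_counts(poisson_record(pmax(shared + rnorm(40, 0, 2), 0.5),
                                    seed = 6), 100)
  overlap_cor <- as.numeric(representation_correlation(a, b))
  disj <- c(rep(2, 20), rep(50, 20))
  d <- binned_counts(poisson_record(disj, seed = 7), 100)
  disjoint_cor <- as.numeric(representation_correlation(a, d))
  expect_gt(overlap_cor, 0.5)
  expect_lt(disjoint_cor, 0)
  expect_gt(overlap_cor, disjoint_cor)
})

test_that("PCA trajectories behave like a fitted ordination", {
  recs <- lapply(1:4, function(s)
    poisson_record(runif(30, 5, 50), window = c(200, 680), seed = s))
  out <- pca_trajectory(recs, bin_ms = 40, n_components = 2,
                        window = c(200, 680))
  expect_length(out$trajectories, 4)
  expect_equal(ncol(out$trajectories[[1]]), 2)
  expect_true(all(diff(out$explained) <= 1e-12))
  expect_lte(sum(out$explained), 1 + 1e-12)
  # a duplicated trial maps onto an identical trajectory
  out2 <- pca_trajectory(c(recs, recs[1]), bin_ms = 40, window = c(200, 680))
  expect_equal(out2$trajectories[[5]], out2$trajectories[[1]])
  expect_error(pca_trajectory(recs, n_components = 31), "components")
})

test_that("PCA separates artificially distinct response families", {
  fam_a <- lapply(1:5, function(s)
    poisson_record(c(rep(60, 15), rep(3, 15)), seed = s))
  fam_b <- lapply(6:10, function(s)
    poisson_record(c(rep(3, 15), rep(60, 15)), seed = s))
  out <- pca_trajectory(c(fam_a, fam_b), bin_ms = 100, n_components = 2,
                        window = c(200, 700))
  cents <- t(vapply(out$trajectories, colMeans, numeric(2)))
  d_between <- sqrt(sum((colMeans(cents[1:5, ]) - colMeans(cents[6:10, ]))^2))
  spread <- mean(c(apply(cents[1:5, ], 2, sd), apply(cents[6:10, ], 2, sd)))
  expect_gt(d_between, spread)
})

test_that("uniqueness index and change in activity are the printed ratios", {
  expect_equal(uniqueness_index(c(2, 4, 0), c(2, 2, 2)), c(0, 1, -1))
  expect_true(is.na(uniqueness_index(1, 0)))
  expect_equal(change_in_activity(c(2, 3, 0), c(2, 2, 2)), c(0, 0.5, -1))
  expect_true(is.na(change_in_activity(1, 0)))
})

test_that("contrast regression is exact on noiseless lines", {
  ui <- c(-0.5, 0, 0.3, 0.8, 1.5)
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(contrast_regression(ui, 0.4 * ui))
  expect_equal(fit$slope, 0.4)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_units, 5)
  # invariant to unit ordering
  o <- c(3, 1, 5, 2, 4)
  fit2 <- suppressWarnings(contrast_regression(ui[o], 0.4 * ui[o]))
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$r_squared, fit$r_squared)
  # NA units are excluded; fewer than 3 valid units is an error
  fit3 <- suppressWarnings(contrast_regression(c(ui, NA), c(0.4 * ui, 1)))
  expect_equal(fit3$n_units, 5)
  expect_error(contrast_regression(c(1, 2), c(1, 2)), "3 valid units")
})

test_that("shuffled pairings give near-zero explained variance", {
  set.seed(21)
  ui <- rnorm(60)
  change <- 0.5 * ui + rnorm(60, 0, 0.1)
  r2_true <- contrast_regression(ui, change)$r_squared
  r2_shuf <- mean(vapply(1:20, function(i)
    contrast_regression(ui, sample(change))$r_squared, 0))
  expect_gt(r2_true, 0.9)
  expect_lt(r2_shuf, 0.12)
})

test_that("percept activation averages firing rates within blocks", {
  pc <- al_percepts(10, 2)
  rec <- fake_record(c(1, 2, 2, 6), c(250, 300, 400, 500),
                     window = c(200, 700))
  act <- percept_activation(rec, pc)
  # 3 spikes over 5 cells in 0.5 s; 1 spike over 5 cells in 0.5 s
  expect_equal(act, c(3 / 5 / 0.5, 1 / 5 / 0.5))
})

test_that("lfp requires voltages and averages identical traces to itself", {
  rec <- fake_record(1, 300)
  expect_error(lfp(rec), "voltage")
  rec$V <- rbind(sin(1:100), sin(1:100))
  rec$n_pn <- 2
  rec$v_time <- 1:100
  expect_equal(lfp(rec)$lfp, sin(1:100))
})
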