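test_that("AL topology respects the zero-probability rules", {
  net <- build_al_network(seed = 1)
  expect_equal(net$n_pn, 100L)
  expect_equal(net$n_ln, 280L)
  # no unipolar-LN edges onto PNs or LNs of the same glomerulus
  e <- net$edges$ln2pn
  uni <- !net$is_multipolar[e$pre]
  same <- net$glom_of_ln[e$pre] == net$glom_of_pn[e$post]
  expect_equal(sum(uni & same, na.rm = TRUE), 0)
  ell <- net$edges$ln2ln
  uni2 <- !net$is_multipolar[ell$pre]
  same2 <- net$glom_of_ln[ell$pre] == net$glom_of_ln[ell$post]
  expect_equal(sum(uni2 & same2, na.rm = TRUE), 0)
  # no self-connections
  expect_false(any(ell$pre == ell$post))
})

test_that("edge densities match the connection table binomially", {
  # totals over 50 seeds compared with the binomial oracle at 3 sigma
  counts <- vapply(1:50, function(s) {
    net <- build_al_network(seed = s)
    uni_pn <- sum(!net$is_multipolar[net$edges$ln2pn$pre])
    c(pn2ln = length(net$edges$pn2ln$pre),
      uni_pn = uni_pn,
      mln_pn = length(net$edges$ln2pn$pre) - uni_pn,
      ln2ln = length(net$edges$ln2ln$pre))
  }, numeric(4))
  tot <- rowSums(counts)
  check_binom <- function(observed, n_admissible, p) {
    n <- n_admissible * 50
    expect_lt(abs(observed - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9)
  }
  check_binom(tot[["pn2ln"]], 100 * 280, 0.4)
  check_binom(tot[["uni_pn"]], 240 * 95, 0.5)     # other-glomerulus PNs only
  check_binom(tot[["mln_pn"]], 40 * 100, 0.3)
  # LN->LN mixes four group pairs; compare against the summed expectation
  exp_ll <- 240 * 228 * 0.4 + 240 * 40 * 0.3 + 40 * 39 * 0.1 + 40 * 240 * 0.4
  expect_lt(abs(tot[["ln2ln"]] / 50 - exp_ll), 3 * sqrt(exp_ll) / sqrt(50) * 2)
  # expected unipolar-LN out-degree onto PNs: 0.5 * 95 per LN
  expect_equal(tot[["uni_pn"]] / (50 * 240), 0.5 * 95, tolerance = 0.02)
})

test_that("topologies are reproducible under a fixed seed", {
  a <- build_al_network(seed = 11)
  b <- build_al_network(seed = 11)
  expect_identical(a$edges, b$edges)
  c <- build_al_network(seed = 12)
  expect_false(identical(a$edges$ln2pn$pre, c$edges$ln2pn$pre))
})

test_that("the scaled-up network has uniform 0.125 connectivity, no PN-PN", {
  net <- build_large_network(seed = 3)
  expect_equal(net$n_pn, 400L)
  expect_equal(net$n_ln, 1120L)
  # there is no PN->PN synapse class at all
  expect_named(net$edges, c("pn2ln", "ln2pn", "ln2ln"))
  n <- length(net$edges$ln2pn$pre)
  N <- 1120 * 400
  expect_lt(abs(n - N * 0.125), 4 * sqrt(N * 0.125 * 0.875))
  # large-network conductance defaults
  expect_equal(net$g$gaba_ln2pn, 0.019)
  expect_equal(net$g$gaba_ln2ln, 0.024)
  expect_equal(net$g$ach, 0.075)
  expect_identical(build_large_network(seed = 3)$edges, net$edges)
})

test_that("per-edge conductances sum to the class maximum per target", {
  net <- build_al_network(seed = 2)
  g_tot <- tapply(net$edges$ln2pn$g, net$edges$ln2pn$post, sum)
  expect_equal(as.vector(g_tot), rep(0.015, length(g_tot)), tolerance = 1e-12)
  g_ach <- tapply(net$edges$pn2ln$g, net$edges$pn2ln$post, sum)
  expect_equal(as.vector(g_ach), rep(0.3, length(g_ach)), tolerance = 1e-12)
})

test_that("topology export/import round-trips losslessly", {
  net <- build_al_network(seed = 5, n_glomeruli = 3L, n_multipolar = 6L)
  net$edges$ln2pn$F <- 1 + seq_along(net$edges$ln2pn$F) / 100
  path <- tempfile(fileext = ".csv")
  write_topology(net, path)
  back <- read_topology(build_al_network(seed = 99, n_glomeruli = 3L,
                                         n_multipolar = 6L), path)
  for (cls in c("pn2ln", "ln2pn", "ln2ln")) {
    expect_equal(back$edges[[cls]]$pre, net$edges[[cls]]$pre)
    expect_equal(back$edges[[cls]]$post, net$edges[[cls]]$post)
    expect_equal(back$edges[[cls]]$g, net$edges[[cls]]$g)
  }
  expect_equal(back$edges$ln2pn$F, net$edges$ln2pn$F)
})
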