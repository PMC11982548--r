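#' Local field potential
#'
#' Pointwise mean of the recorded PN membrane voltages (run the trial with
#' `record_v = TRUE`).
#'
#' @param record an `al_spikes` record with voltages.
#' @return list with `time` (ms) and `lfp` (mV).
#' @export
lfp <- function(record) {
  if (is.null(record$V) || nrow(record$V) == 0) stop("no voltage traces recorded")
  n <- min(record$n_pn, nrow(record$V))
  list(time = record$v_time, lfp = colMeans(record$V[seq_len(n), , drop = FALSE]))
}

#' Binned PN spike counts over the stimulation window
#'
#' PN-by-time-bin matrix of spike counts within the stimulation window,
#' optionally normalized by the trial's grand sum (rate normalization; the
#' per-bin Pearson correlation used downstream is location/scale invariant,
#' so this choice only affects degenerate-bin bookkeeping).
#'
#' @param record an `al_spikes` record.
#' @param bin_ms bin width (ms); must divide the window length.
#' @param window `c(start, end)` in ms; defaults to the stimulation window.
#' @param normalize divide by the grand sum (when positive)?
#' @return Matrix (`n_pn` x `n_bins`) of (normalized) counts; attribute
#'   `bin_ms`.
#' @export
binned_counts <- function(record, bin_ms = 100, window = record$window,
                          normalize = TRUE) {
  len <- diff(window)
  if (bin_ms > len) stop("bin width exceeds the analysis window")
  if (abs(len / bin_ms - round(len / bin_ms)) > 1e-9)
    stop("bin width must tile the analysis window exactly")
  n_bins <- round(len / bin_ms)
  sp <- record$spikes
  sp <- sp[sp$neuron <= record$n_pn & sp$time > window[1] &
             sp$time <= window[2], ]
  m <- matrix(0, record$n_pn, n_bins)
  if (nrow(sp)) {
    b <- pmin(ceiling((sp$time - window[1]) / bin_ms), n_bins)
    for (i in seq_len(nrow(sp))) m[sp$neuron[i], b[i]] <- m[sp$neuron[i], b[i]] + 1
  }
  raw_sum <- sum(m)
  if (normalize && raw_sum > 0) m <- m / raw_sum
  attr(m, "bin_ms") <- bin_ms
  attr(m, "raw_sum") <- raw_sum
  m
}

#' Correlation between two odor representations
#'
#' Pearson correlation between the PN population vectors of two trials,
#' computed within each time bin and averaged over bins. Bins in which
#' either vector has zero variance are skipped and counted in the
#' `skipped_bins` attribute rather than imputed.
#'
#' @param repA,repB matrices from [binned_counts()] with equal dimensions.
#' @return Mean correlation; attribute `skipped_bins`.
#' @export
representation_correlation <- function(repA, repB) {
  if (!all(dim(repA) == dim(repB)))
    stop("representations must have equal PN count and binning")
  cors <- vapply(seq_len(ncol(repA)), function(b) {
    a <- repA[, b]; bb <- repB[, b]
    if (sd(a) == 0 || sd(bb) == 0) return(NA_real_)
    cor(a, bb)
  }, 0)
  skipped <- sum(is.na(cors))
  if (skipped == ncol(repA)) {
    warning("all time bins degenerate (no spike variance)")
    return(structure(NA_real_, skipped_bins = skipped))
  }
  structure(mean(cors, na.rm = TRUE), skipped_bins = skipped)
}

#' PCA trajectories of population responses
#'
#' Bins each trial's PN spike trains (default 40 ms bins over the full
#' trial), fits a PCA on the pooled PN-by-bin vectors, and returns each
#' trial's trajectory through the leading components.
#'
#' @param records list of `al_spikes` records with identical PN counts.
#' @param bin_ms bin width (ms).
#' @param n_components number of components (must not exceed the PN count).
#' @param window analysis window; defaults to the whole trial.
#' @return list with `trajectories` (one bins-x-components matrix per
#'   trial), `explained` (variance ratios), and the fitted `prcomp` object.
#' @export
pca_trajectory <- function(records, bin_ms = 40, n_components = 2,
                           window = NULL) {
  stopifnot(length(records) >= 1)
  n_pn <- records[[1]]$n_pn
  if (n_components > n_pn) stop("more components than PNs")
  mats <- lapply(records, function(r) {
    w <- window %||% c(0, r$trial_ms)
    t(binned_counts(r, bin_ms, window = w, normalize = FALSE))
  })
  pooled <- do.call(rbind, mats)
  if (nrow(pooled) < 2) stop("need at least two time bins")
  fit <- prcomp(pooled, center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  trj <- lapply(mats, function(m)
    predict(fit, m)[, seq_len(n_components), drop = FALSE])
  list(trajectories = trj, explained = expl[seq_len(n_components)], fit = fit)
}

#' Per-percept activation of a spike record
#'
#' Mean PN firing rate (Hz) over the stimulation window, averaged within
#' each percept's PN block. Any per-unit activation table (e.g. glomerular
#' imaging vectors) can be substituted downstream; this helper computes the
#' model's version.
#'
#' @param record an `al_spikes` record.
#' @param percepts percept table from [al_percepts()].
#' @param window analysis window (ms); defaults to the stimulation window.
#' @return Numeric vector of rates, one per percept.
#' @export
percept_activation <- function(record, percepts, window = record$window) {
  sp <- record$spikes
  sp <- sp[sp$neuron <= record$n_pn & sp$time > window[1] &
             sp$time <= window[2], ]
  dur_s <- diff(window) / 1000
  vapply(seq_len(nrow(percepts)), function(k) {
    n_cells <- percepts$hi[k] - percepts$lo[k] + 1
    sum(sp$neuron >= percepts$lo[k] & sp$neuron <= percepts$hi[k]) /
      (n_cells * dur_s)
  }, 0)
}

#' Uniqueness index
#'
#' Per-unit normalized difference between activation by the rewarded and
#' habituated odors in the naive network:
#' `UI = (act_rew - act_hab) / act_hab`. Units with nonpositive habituated
#' activation are undefined (`NA`) and excluded from downstream regression.
#'
#' @param act_rew,act_hab per-unit activations (equal length).
#' @return UI vector (with `NA` for undefined units).
#' @export
uniqueness_index <- function(act_rew, act_hab) {
  stopifnot(length(act_rew) == length(act_hab))
  ui <- (act_rew - act_hab) / act_hab
  ui[act_hab <= 0] <- NA_real_
  ui
}

#' Change in activity after differential conditioning
#'
#' Per-unit fractional change of the rewarded-odor activation:
#' `(act_trained - act_naive) / act_naive`. Units with nonpositive naive
#' activation are undefined (`NA`).
#'
#' @param act_trained,act_naive per-unit activations (equal length).
#' @return Change vector.
#' @export
change_in_activity <- function(act_trained, act_naive) {
  stopifnot(length(act_trained) == length(act_naive))
  ch <- (act_trained - act_naive) / act_naive
  ch[act_naive <= 0] <- NA_real_
  ch
}

#' Contrast-enhancement regression
#'
#' Ordinary least squares of the per-unit change in activity on the
#' uniqueness index. A positive slope is the contrast-enhancement
#' signature: units unique to the rewarded odors gain activity, shared
#' units lose it.
#'
#' @param ui uniqueness-index vector (`NA` allowed).
#' @param change change-in-activity vector.
#' @return Object of class `al_contrast`: `ui`, `change`, `slope`,
#'   `intercept`, `r_squared`, `p_value` (two-sided t test on the slope),
#'   `n_units`.
#' @export
contrast_regression <- function(ui, change) {
  stopifnot(length(ui) == length(change))
  ok <- is.finite(ui) & is.finite(change)
  if (sum(ok) < 3) stop("need at least 3 valid units for the regression")
  fit <- lm(change[ok] ~ ui[ok])
  sm <- summary(fit)
  structure(list(
    ui = ui, change = change, n_units = sum(ok),
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4]
  ), class = "al_contrast")
}

#' @export
print.al_contrast <- function(x, ...) {
  cat(sprintf(
    "contrast enhancement: slope = %.3f, R^2 = %.3f, p = %.3g (n = %d units)\n",
    x$slope, x$r_squared, x$p_value, x$n_units))
  invisible(x)
}

#' @export
plot.al_contrast <- function(x, ...) {
  ok <- is.finite(x$ui) & is.finite(x$change)
  plot(x$ui[ok], x$change[ok], xlab = "uniqueness index",
       ylab = "change in activity", pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}

#' Full contrast-enhancement experiment
#'
#' The differential-conditioning pipeline on one network: (1) evaluate the
#' naive network's per-percept activation for the rewarded and habituated
#' classes, (2) train with differential conditioning and freeze, (3)
#' re-evaluate the rewarded-class activation, (4) regress the change in
#' activity on the uniqueness index over the environment's active percepts.
#'
#' @param net a naive `al_network`.
#' @param env an [al_environment()] with a rewarded and a habituated class.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param rule plasticity rule for training.
#' @param n_presentations training length.
#' @param n_trials_eval trials averaged per odor in each evaluation.
#' @return An `al_contrast` object; attribute `activations` holds the
#'   per-percept activation table.
#' @export
contrast_experiment <- function(net, env, config = sim_config(), seed = 1L,
                                rule = plasticity_rule("both"),
                                n_presentations = 30L, n_trials_eval = 1L) {
  n_pn_in <- if (net$large) net$n_pn %/% 2L else net$n_pn
  pc <- al_percepts(n_pn_in, env$n_percepts)
  # evaluation trials only need to cover the stimulation window
  eval_cfg <- config
  eval_cfg$trial_ms <- config$t_on + config$stim_duration
  rew_cls <- env$classes[[which(env$rewards == "rewarded")[1]]]
  hab_cls <- env$classes[[which(env$rewards == "habituated")[1]]]
  active <- sort(unique(unlist(lapply(env_odors(env),
                                      function(o) which(o$widths > 0)))))
  class_act <- function(nt, cls, seed0) {
    acts <- lapply(seq_along(cls), function(i) {
      rowMeans(vapply(seq_len(n_trials_eval), function(r) {
        rec <- run_trial(nt, cls[[i]], eval_cfg, seed = seed0 + 31L * i + r)
        percept_activation(rec, pc)
      }, numeric(nrow(pc))))
    })
    Reduce(`+`, acts) / length(acts)
  }
  naive <- freeze_weights(net)
  act_rew_naive <- class_act(naive, rew_cls, seed * 1000L)
  act_hab_naive <- class_act(naive, hab_cls, seed * 1000L + 500L)
  trained <- run_training(net, env, rule, config, n_presentations,
                          seed = seed)
  trained <- freeze_weights(trained)
  act_rew_trained <- class_act(trained, rew_cls, seed * 1000L + 700L)
  ui <- uniqueness_index(act_rew_naive, act_hab_naive)
  ch <- change_in_activity(act_rew_trained, act_rew_naive)
  res <- contrast_regression(ui[active], ch[active])
  attr(res, "activations") <- data.frame(
    percept = seq_len(nrow(pc)),
    act_rew_naive = act_rew_naive, act_hab_naive = act_hab_naive,
    act_rew_trained = act_rew_trained, active = seq_len(nrow(pc)) %in% active)
  attr(res, "trained_net") <- trained
  res
}

#' Between- and within-class decorrelation experiment
#'
#' Evaluates between-class and within-class representation correlations on
#' the naive network and after training, for a given plasticity rule.
#' Optionally also evaluates a weight-shuffled control of the trained
#' network.
#'
#' @param net a naive `al_network`.
#' @param env an [al_environment()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param rule plasticity rule for training.
#' @param n_presentations training length.
#' @param n_eval odors per class in the correlation evaluations.
#' @param shuffle also evaluate the shuffled-weight control?
#' @return data.frame with columns `condition` (naive/trained/shuffled),
#'   `comparison` (between/within), `correlation`.
#' @export
decorrelation_experiment <- function(net, env, config = sim_config(),
                                     seed = 1L,
                                     rule = plasticity_rule("both"),
                                     n_presentations = 30L, n_eval = 2L,
                                     shuffle = FALSE) {
  rew_cls <- env$classes[[which(env$rewards == "rewarded")[1]]]
  hab_cls <- env$classes[[which(env$rewards == "habituated")[1]]]
  eval_net <- function(nt, tag, seed0) {
    between <- class_pair_correlation(nt, rew_cls, hab_cls, config,
                                      seed = seed0, n_eval = n_eval)
    within <- mean(c(
      class_pair_correlation(nt, rew_cls[c(TRUE, FALSE)],
                             rew_cls[c(FALSE, TRUE)], config,
                             seed = seed0 + 1L, n_eval = n_eval),
      class_pair_correlation(nt, hab_cls[c(TRUE, FALSE)],
                             hab_cls[c(FALSE, TRUE)], config,
                             seed = seed0 + 2L, n_eval = n_eval)))
    data.frame(condition = tag, comparison = c("between", "within"),
               correlation = c(between, within), seed = seed)
  }
  out <- eval_net(freeze_weights(net), "naive", seed * 100L)
  trained <- freeze_weights(run_training(net, env, rule, config,
                                         n_presentations, seed = seed))
  out <- rbind(out, eval_net(trained, "trained", seed * 100L + 50L))
  if (shuffle) {
    shuf <- shuffle_weights(trained, seed = seed + 999L)
    out <- rbind(out, eval_net(shuf, "shuffled", seed * 100L + 80L))
  }
  rownames(out) <- NULL
  out
}
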