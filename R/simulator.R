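#' Simulation configuration
#'
#' Bundles the integration, stimulus and recording settings for trials.
#' A trial is a 2 s presentation: the 500 ms stimulus pulse starts at
#' `t_on`, followed by the off-response window. The input amplitudes
#' (`peak_pn`, `peak_ln`) and noise level are calibrated once so that the
#' untrained default network shows odor-evoked PN firing and LFP
#' oscillations during the pulse; see the methods vignette.
#'
#' @param dt integration step (ms).
#' @param trial_ms presentation duration (ms).
#' @param t_on stimulus onset within the trial (ms).
#' @param stim_duration stimulus pulse length (ms).
#' @param tau_rise,tau_decay default pulse time constants (ms).
#' @param peak_pn,peak_ln stimulus peak currents to PNs / input LNs (uA).
#' @param multipolar_input do multipolar LNs receive odor input?
#' @param multipolar_factor amplitude factor for multipolar LNs (relative to
#'   the mean percept activation).
#' @param dc_pn,dc_ln constant background currents (uA).
#' @param noise_sd per-step Gaussian current noise (uA).
#' @param exact_kinetics evaluate the voltage-dependent rate functions
#'   exactly instead of through the tabulated interpolants (slower; used for
#'   convergence verification).
#' @param record_v record membrane voltages?
#' @param v_every_ms voltage sampling interval (ms).
#' @param record which voltages to record, `"pn"` or `"all"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.04, trial_ms = 2000, t_on = 500,
                       stim_duration = 500, tau_rise = 66.7, tau_decay = 200,
                       peak_pn = 1e-3, peak_ln = 5e-5,
                       multipolar_input = TRUE, multipolar_factor = 0.5,
                       dc_pn = 5.5e-4, dc_ln = 0, noise_sd = 5e-4,
                       exact_kinetics = FALSE,
                       record_v = FALSE, v_every_ms = 1, record = "pn") {
  stopifnot(dt > 0, trial_ms > 0, stim_duration > 0)
  structure(list(dt = dt, trial_ms = trial_ms, t_on = t_on,
                 stim_duration = stim_duration, tau_rise = tau_rise,
                 tau_decay = tau_decay, peak_pn = peak_pn, peak_ln = peak_ln,
                 multipolar_input = multipolar_input,
                 multipolar_factor = multipolar_factor,
                 dc_pn = dc_pn, dc_ln = dc_ln, noise_sd = noise_sd,
                 exact_kinetics = exact_kinetics,
                 record_v = record_v, v_every_ms = v_every_ms,
                 record = record), class = "sim_config")
}

#' Per-neuron stimulus parameters for an odor
#'
#' Expands an odor's percept widths (and optional per-percept pulse
#' parameters) into per-neuron peak currents and pulse time constants. PNs
#' are activated through their percept's Gaussian profile; unipolar LNs
#' receive the activation at their glomerulus position; multipolar LNs
#' optionally receive the mean activation at reduced amplitude. In the
#' scaled-up network only the first half of PNs and LNs receives input.
#'
#' @param od an [odor()].
#' @param net an `al_network`.
#' @param config a [sim_config()].
#' @return list with numeric vectors `peak`, `tau_rise`, `tau_decay` of
#'   length `n_pn + n_ln` (PNs first).
#' @export
odor_input_profile <- function(od, net, config = sim_config()) {
  n_pn <- net$n_pn; n_ln <- net$n_ln
  n_pn_in <- if (net$large) n_pn %/% 2L else n_pn
  n_ln_in <- if (net$large) n_ln %/% 2L else n_ln
  n_percepts <- length(od$widths)
  pc <- al_percepts(n_pn_in, n_percepts)
  x_pn <- seq_len(n_pn_in) - 0.5
  amp_pn <- numeric(n_pn_in)
  tr_pn <- rep(config$tau_rise, n_pn_in)
  td_pn <- rep(config$tau_decay, n_pn_in)
  flat <- !is.null(od$pulse)
  active <- if (flat) seq_len(nrow(od$pulse)) else which(od$widths > 0)
  for (k in active) {
    blk <- x_pn >= pc$lo[k] - 1 & x_pn <= pc$hi[k]
    if (flat) {
      amp_pn[blk] <- od$pulse$peak_scale[k]
      tr_pn[blk] <- od$pulse$tau_rise[k]
      td_pn[blk] <- od$pulse$tau_decay[k]
    } else {
      amp_pn <- amp_pn + percept_activation_profile(x_pn, pc[k, ], od$widths[k])
    }
  }
  # LN positions on the same axis
  if (net$large) {
    x_ln <- (seq_len(n_ln_in) - 0.5) * n_pn_in / n_ln_in
  } else {
    x_ln <- ifelse(is.na(net$glom_of_ln),
                   NA_real_,
                   (net$glom_of_ln - 0.5) * net$dims$pn_per_glom)
    x_ln <- x_ln[seq_len(n_ln_in)]
  }
  amp_ln <- numeric(n_ln_in)
  tr_ln <- rep(config$tau_rise, n_ln_in)
  td_ln <- rep(config$tau_decay, n_ln_in)
  pos_ok <- !is.na(x_ln)
  if (any(pos_ok)) {
    ii <- which(pos_ok)
    for (k in active) {
      blk <- ii[x_ln[ii] >= pc$lo[k] - 1 & x_ln[ii] <= pc$hi[k]]
      if (!length(blk)) next
      if (flat) {
        amp_ln[blk] <- od$pulse$peak_scale[k]
        tr_ln[blk] <- od$pulse$tau_rise[k]
        td_ln[blk] <- od$pulse$tau_decay[k]
      } else {
        amp_ln[blk] <- amp_ln[blk] +
          percept_activation_profile(x_ln[blk], pc[k, ], od$widths[k])
      }
    }
  }
  if (any(!pos_ok) && isTRUE(config$multipolar_input)) {
    amp_ln[!pos_ok] <- config$multipolar_factor * mean(amp_pn)
  }
  peak <- c(config$peak_pn * amp_pn, rep(0, n_pn - n_pn_in),
            config$peak_ln * amp_ln, rep(0, n_ln - n_ln_in))
  list(peak = peak,
       tau_rise = c(tr_pn, rep(config$tau_rise, n_pn - n_pn_in),
                    tr_ln, rep(config$tau_rise, n_ln - n_ln_in)),
       tau_decay = c(td_pn, rep(config$tau_decay, n_pn - n_pn_in),
                     td_ln, rep(config$tau_decay, n_ln - n_ln_in)))
}

# internal: run the C++ engine for one presentation
trial_core <- function(net, od, config, seed, df_pre = 0, df_post = 0,
                       plastic = FALSE, t0_abs = net$clock_ms) {
  inp <- odor_input_profile(od, net, config)
  N <- net$n_pn + net$n_ln
  dc <- c(rep(config$dc_pn, net$n_pn), rep(config$dc_ln, net$n_ln))
  rec_n <- if (identical(config$record, "pn")) net$n_pn else N
  .al_run_trial_cpp(
    net$n_pn, net$n_ln,
    net$edges$pn2ln$pre, net$edges$pn2ln$post,
    net$edges$ln2pn$pre, net$edges$ln2pn$post,
    net$edges$ln2ln$pre, net$edges$ln2ln$post,
    net$edges$pn2ln$g * 1e-3, net$edges$ln2pn$g * 1e-3,
    net$edges$ln2ln$g * 1e-3, net$g$slow / net$g$gaba_ln2pn,
    net$edges$ln2pn$F, net$edges$ln2pn$t_last,
    net$edges$ln2ln$F, net$edges$ln2ln$t_last,
    params_vector(neuron_params("PN")), params_vector(neuron_params("LN")),
    inp$peak, inp$tau_rise, inp$tau_decay,
    config$t_on, config$stim_duration,
    dc, config$noise_sd, config$trial_ms, config$dt,
    as.integer(seed), t0_abs,
    df_pre, df_post, net$tau_F, plastic,
    config$record_v, config$v_every_ms, rec_n,
    isTRUE(config$exact_kinetics))
}

params_vector <- function(p) {
  v <- unlist(p[c("Cm", "area", "gL", "gKL", "gNa", "gK", "gA", "gT", "gh",
                  "EL", "EKL", "ENa", "EK", "ECa", "Eh",
                  "A_ca", "tau_ca", "Ca_inf")])
  v
}

new_al_spikes <- function(res, net, od, config, seed, stage = "test") {
  structure(list(
    spikes = data.frame(neuron = res$spike_neuron, time = res$spike_time),
    n_pn = net$n_pn, n_ln = net$n_ln,
    trial_ms = config$trial_ms,
    window = c(config$t_on, config$t_on + config$stim_duration),
    odor = od$label, reward = od$reward, stage = stage, seed = seed,
    V = if (config$record_v) res$V else NULL,
    v_time = if (config$record_v)
      seq(0, config$trial_ms, by = config$v_every_ms) else NULL
  ), class = "al_spikes")
}

#' @export
print.al_spikes <- function(x, ...) {
  pn_sp <- sum(x$spikes$neuron <= x$n_pn)
  cat(sprintf("spike record: odor %s (%s), %d PN spikes, %d LN spikes over %g ms\n",
              x$odor, x$reward, pn_sp, nrow(x$spikes) - pn_sp, x$trial_ms))
  invisible(x)
}

#' Simulate one odor presentation
#'
#' Runs a single trial of the network under one odor. With the default
#' `plastic = FALSE` the synaptic weights are read-only (test phase);
#' training runs use [run_training()].
#'
#' @param net an `al_network`.
#' @param od an [odor()].
#' @param config a [sim_config()].
#' @param seed integer seed for the background-noise stream; identical seeds
#'   and inputs give identical records.
#' @return An `al_spikes` record: per-neuron spike times (ms), the
#'   stimulation window, and optionally sampled voltages.
#' @export
run_trial <- function(net, od, config = sim_config(), seed = 1L) {
  res <- trial_core(net, od, config, seed, plastic = FALSE)
  new_al_spikes(res, net, od, config, seed)
}

#' Train the network on an odor environment
#'
#' Presents a randomized sequence of odors (default 30 presentations of 2 s,
#' 60 s of training). The plasticity rule engaged for each presentation
#' follows the odor's reward class: presynaptic (associative) facilitation
#' during rewarded odors, postsynaptic (nonassociative) facilitation during
#' habituated odors, filtered by the rule's `mode`. Membrane and synaptic
#' kinetic states reset between presentations; facilitation persists and
#' decays with `tau_F` across the whole session.
#'
#' @param net an `al_network`.
#' @param env an [al_environment()].
#' @param rule a [plasticity_rule()].
#' @param config a [sim_config()].
#' @param n_presentations number of presentations.
#' @param seed integer seed (odor order and noise derive from it).
#' @param balanced alternate classes evenly before shuffling (default) or
#'   sample odors with replacement.
#' @return The trained network (training clock advanced, weights live, not
#'   frozen), with attribute `log`: one row per presentation (odor, reward,
#'   spike counts, mean facilitation per class).
#' @export
run_training <- function(net, env, rule = plasticity_rule("both"),
                         config = sim_config(), n_presentations = 30L,
                         seed = 1L, balanced = TRUE) {
  stopifnot(inherits(net, "al_network"), inherits(env, "al_environment"))
  odors <- env_odors(env)
  rewards <- vapply(odors, function(o) o$reward, "")
  set.seed(seed)
  if (balanced) {
    idx <- unlist(lapply(split(seq_along(odors), rewards), function(ii)
      rep_len(ii, ceiling(n_presentations / 2))))
    idx <- sample(idx)[seq_len(n_presentations)]
  } else {
    idx <- sample(seq_along(odors), n_presentations, replace = TRUE)
  }
  net$frozen <- FALSE
  log <- vector("list", n_presentations)
  for (p in seq_len(n_presentations)) {
    od <- odors[[idx[p]]]
    inc <- presentation_increments(rule, od$reward)
    res <- trial_core(net, od, config, seed = seed * 1000L + p,
                      df_pre = inc[["dF_pre"]], df_post = inc[["dF_post"]],
                      plastic = TRUE, t0_abs = net$clock_ms)
    net$edges$ln2pn$F <- res$F_l2p
    net$edges$ln2pn$t_last <- res$Ft_l2p
    net$edges$ln2ln$F <- res$F_l2l
    net$edges$ln2ln$t_last <- res$Ft_l2l
    net$clock_ms <- res$t_end_abs
    log[[p]] <- data.frame(
      presentation = p, odor = od$label, reward = od$reward,
      n_spikes = length(res$spike_neuron),
      mean_F_ln2pn = mean(res$F_l2p), mean_F_ln2ln = mean(res$F_l2l))
  }
  attr(net, "log") <- do.call(rbind, log)
  net
}

#' Two-environment relearning experiment
#'
#' Trains a naive network sequentially on two odor environments (Env1:
#' P rewarded / Q habituated; Env2 per `case`, see
#' [env_case_environments()]) with the slow forgetting decay acting
#' throughout, and evaluates frozen-weight between-class correlations for
#' both environments' class pairs at three stages: naive, after Env1, after
#' Env2.
#'
#' @param case 1-4 (overlap structure of Env2 with Env1).
#' @param env2_reward_sign `"pos"` (consistent with Env1) or `"neg"`
#'   (reversed).
#' @param seeds integer vector; one full experiment per seed.
#' @param config a [sim_config()].
#' @param n_presentations presentations per environment.
#' @param n_odors odors per class.
#' @param n_eval_odors odors per class used in the correlation evaluation.
#' @param net_builder function(seed) producing the naive network.
#' @return data.frame with columns `case`, `sign`, `seed`, `stage`
#'   (naive/env1/env2), `pair` (e.g. "P/Q"), `correlation`.
#' @export
run_environment_experiment <- function(case, env2_reward_sign = "pos",
                                       seeds = 1:5, config = sim_config(),
                                       n_presentations = 30L, n_odors = 10L,
                                       n_eval_odors = 2L,
                                       net_builder = build_al_network) {
  out <- list()
  for (s in seeds) {
    envs <- env_case_environments(case, env2_reward_sign, n_odors = n_odors,
                                  seed = s)
    pairs <- list(env1 = envs$env1, env2 = envs$env2)
    net <- net_builder(seed = s)
    eval_stage <- function(net, stage) {
      fr <- freeze_weights(net)
      do.call(rbind, lapply(names(pairs), function(envnm) {
        env <- pairs[[envnm]]
        cls <- env$classes
        cc <- class_pair_correlation(fr, cls[[1]], cls[[2]], config,
                                     seed = s * 100L + match(stage, c("naive", "env1", "env2")),
                                     n_eval = n_eval_odors)
        data.frame(case = case, sign = env2_reward_sign, seed = s,
                   stage = stage,
                   pair = paste(names(cls), collapse = "/"),
                   correlation = cc)
      }))
    }
    out[[length(out) + 1]] <- eval_stage(net, "naive")
    net <- run_training(net, envs$env1, plasticity_rule("both"), config,
                        n_presentations, seed = s * 7L + 1L)
    out[[length(out) + 1]] <- eval_stage(net, "env1")
    net <- run_training(net, envs$env2, plasticity_rule("both"), config,
                        n_presentations, seed = s * 7L + 2L)
    out[[length(out) + 1]] <- eval_stage(net, "env2")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean between-class representation correlation
#'
#' Runs one frozen-weight test trial per odor (the first `n_eval` odors of
#' each class) and averages the binned-count Pearson correlation over all
#' cross-class odor pairs.
#'
#' @param net a frozen `al_network`.
#' @param class_a,class_b lists of odors.
#' @param config a [sim_config()].
#' @param seed base seed for the evaluation trials.
#' @param n_eval odors evaluated per class.
#' @param bin_ms correlation bin width (ms).
#' @return Mean correlation (scalar).
#' @export
class_pair_correlation <- function(net, class_a, class_b,
                                   config = sim_config(), seed = 1L,
                                   n_eval = 2L, bin_ms = 100) {
  a <- class_a[seq_len(min(n_eval, length(class_a)))]
  b <- class_b[seq_len(min(n_eval, length(class_b)))]
  # the correlation uses only the stimulation window; stop the trial there
  config$trial_ms <- config$t_on + config$stim_duration
  ra <- lapply(seq_along(a), function(i)
    binned_counts(run_trial(net, a[[i]], config, seed = seed * 13L + i)))
  rb <- lapply(seq_along(b), function(i)
    binned_counts(run_trial(net, b[[i]], config, seed = seed * 17L + i)))
  cc <- outer(seq_along(ra), seq_along(rb),
              Vectorize(function(i, j) representation_correlation(ra[[i]], rb[[j]])))
  mean(cc)
}
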