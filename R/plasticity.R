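#' Plasticity rule parameters
#'
#' Spike-triggered facilitation of the inhibitory (LN to PN and LN to LN)
#' synapses. Presynaptic facilitation (`dF_pre`) models the associative,
#' reward-gated pathway and is applied on presynaptic LN spikes during
#' rewarded-odor presentations; postsynaptic facilitation (`dF_post`) models
#' nonassociative habituation and is applied on postsynaptic spikes during
#' habituated-odor presentations. Between spikes `F` decays exponentially
#' back to 1 with time constant `tau_F`.
#'
#' @param mode one of `"both"` (differential conditioning), `"pre_only"`
#'   (associative only / absolute conditioning), `"post_only"`
#'   (nonassociative only), `"off"`.
#' @param dF_pre,dF_post facilitation increments per spike.
#' @param tau_F decay time constant (ms; default 30 s).
#' @return list of class `plasticity_rule`.
#' @export
plasticity_rule <- function(mode = c("both", "pre_only", "post_only", "off"),
                            dF_pre = 0.15, dF_post = 0.15, tau_F = 30000) {
  mode <- match.arg(mode)
  structure(list(mode = mode, dF_pre = dF_pre, dF_post = dF_post,
                 tau_F = tau_F), class = "plasticity_rule")
}

# Increments active for a presentation of the given reward class under a rule.
# Rewarded presentations engage the presynaptic (associative) increment,
# habituated presentations the postsynaptic (nonassociative) one.
presentation_increments <- function(rule, reward) {
  stopifnot(reward %in% c("rewarded", "habituated"))
  pre_on <- rule$mode %in% c("both", "pre_only") && reward == "rewarded"
  post_on <- rule$mode %in% c("both", "post_only") && reward == "habituated"
  c(dF_pre = if (pre_on) rule$dF_pre else 0,
    dF_post = if (post_on) rule$dF_post else 0)
}

#' Spike-triggered facilitation update
#'
#' `F -> F + dF_pre + dF_post`, where each increment applies only if the
#' corresponding spike occurred and the corresponding plasticity mode is
#' active for the current presentation (rewarded presentations engage the
#' presynaptic rule, habituated presentations the postsynaptic rule).
#'
#' @param F_mult facilitation multiplier, `>= 1`.
#' @param is_pre_spike,is_post_spike logical flags for the triggering spike.
#' @param rule a [plasticity_rule()].
#' @param reward reward class of the current presentation, `"rewarded"` or
#'   `"habituated"`.
#' @return Updated multiplier.
#' @export
apply_spike_facilitation <- function(F_mult, is_pre_spike, is_post_spike,
                                     rule = plasticity_rule(),
                                     reward = "rewarded") {
  if (!inherits(rule, "plasticity_rule")) stop("unknown plasticity mode")
  if (any(F_mult < 1)) stop("F must be >= 1")
  inc <- presentation_increments(rule, reward)
  F_mult + is_pre_spike * inc[["dF_pre"]] + is_post_spike * inc[["dF_post"]]
}

#' Exponential forgetting of facilitation
#'
#' `F(t) = 1 + (F - 1) * exp(-dt / tau_F)`: in the absence of spikes the
#' multiplier relaxes back to baseline. This same decay acts continuously
#' during the two-environment experiments ("forgetting").
#'
#' @param F_mult multiplier at the last event, `>= 1`.
#' @param dt_since_event elapsed time (ms), `>= 0`.
#' @param tau_F decay constant (ms).
#' @return Decayed multiplier.
#' @export
decay_facilitation <- function(F_mult, dt_since_event, tau_F = 30000) {
  if (any(dt_since_event < 0)) stop("elapsed time must be nonnegative")
  if (any(F_mult < 1)) stop("F must be >= 1")
  1 + (F_mult - 1) * exp(-dt_since_event / tau_F)
}

#' Freeze trained weights for the testing phase
#'
#' Collapses each plastic synapse's `(F, t_last)` pair to its effective
#' multiplier at time `t_ms` and marks the network as frozen: test-phase
#' trials no longer update weights. Idempotent.
#'
#' @param net an `al_network` (typically returned by [run_training()]).
#' @param t_ms time at which weights are captured (ms); defaults to the
#'   network's training clock.
#' @return The network with static facilitation multipliers.
#' @export
freeze_weights <- function(net, t_ms = NULL) {
  stopifnot(inherits(net, "al_network"))
  if (isTRUE(net$frozen)) return(net)
  if (isTRUE(net$training_active))
    stop("cannot freeze weights mid-training")
  t_ms <- t_ms %||% net$clock_ms
  for (cls in c("ln2pn", "ln2ln")) {
    F <- decay_facilitation(net$edges[[cls]]$F,
                            pmax(t_ms - net$edges[[cls]]$t_last, 0),
                            net$tau_F)
    net$edges[[cls]]$F <- F
    net$edges[[cls]]$t_last <- rep(t_ms, length(F))
  }
  net$frozen <- TRUE
  net
}

#' Shuffle trained weights within synapse classes
#'
#' Control for the structure (rather than the amount) of learned inhibition:
#' permutes the facilitation multipliers across the existing connections of
#' each plastic synapse class (LN to PN, LN to LN), preserving the exact
#' multiset of weights and hence the total inhibitory drive.
#'
#' @param net a frozen, trained `al_network` (see [freeze_weights()]).
#' @param seed integer seed for the permutation.
#' @return The network with permuted multipliers.
#' @export
shuffle_weights <- function(net, seed = 1L) {
  stopifnot(inherits(net, "al_network"))
  if (!isTRUE(net$frozen)) stop("shuffle requires a frozen trained network")
  set.seed(seed)
  for (cls in c("ln2pn", "ln2ln")) {
    e <- net$edges[[cls]]
    n <- length(e$F)
    if (n == 0) stop("empty weight table")
    w <- e$g * e$F                       # effective conductances
    w_perm <- w[sample.int(n)]           # same multiset, new positions
    net$edges[[cls]]$F <- w_perm / e$g
  }
  net
}

#' Weight table of the plastic synapses
#'
#' @param net an `al_network`.
#' @param t_ms evaluate lazily decayed multipliers at this time (default:
#'   network clock).
#' @return data.frame with columns `class`, `pre`, `post`, `g_max` (uS),
#'   `F` (effective multiplier at `t_ms`), `weight` (`g_max * F`).
#' @export
weight_table <- function(net, t_ms = NULL) {
  stopifnot(inherits(net, "al_network"))
  t_ms <- t_ms %||% net$clock_ms
  out <- lapply(c(ln2pn = "ln2pn", ln2ln = "ln2ln"), function(cls) {
    e <- net$edges[[cls]]
    F <- if (isTRUE(net$frozen)) e$F else
      decay_facilitation(e$F, pmax(t_ms - e$t_last, 0), net$tau_F)
    data.frame(class = cls, pre = e$pre, post = e$post,
               g_max = e$g, F = F, weight = e$g * F)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
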