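#' Parameters of a fast synapse class
#'
#' First-order activation scheme parameters for fast GABA-A and nicotinic
#' cholinergic (nACh) synapses. GABA-A transmitter is a sigmoid of the
#' presynaptic voltage; cholinergic transmitter is a 0.3 ms square pulse of
#' amplitude 0.5 triggered by each presynaptic spike.
#'
#' @param kind `"GABA_A"` or `"nACh"`.
#' @param g_max maximal conductance (uS). Defaults: 0.02 (LN to LN GABA-A),
#'   0.015 (LN to PN GABA-A), 0.3 (PN to LN nACh); pass explicitly for the
#'   large-network variants (0.024 / 0.019 / 0.075).
#' @return list with `kind`, `g_max` (uS), `E_syn` (mV), `alpha`, `beta`
#'   (1/ms) and, per kind, `V0`/`sigma` (mV, GABA sigmoid) or `A_T`/`t_max`
#'   (cholinergic pulse).
#' @export
synapse_params <- function(kind = c("GABA_A", "nACh"), g_max = NULL) {
  kind <- match.arg(kind)
  if (kind == "GABA_A") {
    list(kind = kind, g_max = g_max %||% 0.015, E_syn = -70,
         alpha = 10, beta = 0.2, V0 = -20, sigma = 1.5)
  } else {
    list(kind = kind, g_max = g_max %||% 0.3, E_syn = 0,
         alpha = 1, beta = 0.2, A_T = 0.5, t_max = 0.3)
  }
}

#' Parameters of the slow inhibitory (G-protein-coupled) synapse
#'
#' @return list with rate constants `r1` (1/(mM ms)), `r2`, `r3`, `r4`
#'   (1/ms), Hill constant `K` (uM^4), `g_max` (uS) and `E_K` (mV).
#' @export
slow_synapse_params <- function() {
  list(r1 = 0.5, r2 = 0.0013, r3 = 0.1, r4 = 0.033, K = 100,
       g_max = 0.02, E_K = -95)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cholinergic transmitter pulse
#'
#' Square transmitter pulse of amplitude `A_T` lasting `t_max` ms after the
#' last presynaptic spike at `t0` (product of two Heaviside functions).
#'
#' @param t current time (ms).
#' @param t0 time of the last presynaptic spike (ms); `-Inf` if none.
#' @param A_T pulse amplitude (dimensionless concentration).
#' @param t_max pulse duration (ms).
#' @return Transmitter concentration.
#' @export
cholinergic_transmitter <- function(t, t0, A_T = 0.5, t_max = 0.3) {
  ifelse(t >= t0 & t <= t0 + t_max, A_T, 0)
}

#' GABAergic transmitter concentration
#'
#' Sigmoid of the presynaptic membrane potential,
#' `[T] = 1 / (1 + exp(-(V - V0) / sigma))`.
#'
#' @param V_pre presynaptic membrane potential (mV).
#' @param V0 half-activation voltage (mV).
#' @param sigma slope (mV), `> 0`.
#' @return Transmitter concentration in (0, 1).
#' @export
gaba_transmitter <- function(V_pre, V0 = -20, sigma = 1.5) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  1 / (1 + exp(-(V_pre - V0) / sigma))
}

#' Open-channel fraction kinetics of a fast synapse
#'
#' `d[O]/dt = alpha (1 - [O]) [T] - beta [O]`; the fixed point under
#' sustained transmitter `T` is `alpha T / (alpha T + beta)`.
#'
#' @param O open fraction in `[0, 1]`.
#' @param T_conc transmitter concentration.
#' @param alpha binding rate (1/ms).
#' @param beta unbinding rate (1/ms).
#' @return Rate of change (1/ms).
#' @export
fast_open_fraction_derivative <- function(O, T_conc, alpha, beta) {
  if (any(O < 0 | O > 1)) stop("O must lie in [0, 1]")
  alpha * (1 - O) * T_conc - beta * O
}

#' Fast synaptic current
#'
#' `I = g_max * F * [O] * (V_post - E_syn)` with facilitation multiplier `F`.
#'
#' @param O open-channel fraction.
#' @param g_max maximal conductance (uS).
#' @param F_mult facilitation multiplier, `>= 1`.
#' @param V_post postsynaptic potential (mV).
#' @param E_syn reversal potential (mV).
#' @return Current (uS * mV); outward-positive convention.
#' @export
fast_synaptic_current <- function(O, g_max, F_mult = 1, V_post, E_syn) {
  if (any(F_mult < 1)) stop("facilitation multiplier must be >= 1")
  g_max * F_mult * O * (V_post - E_syn)
}

#' Slow inhibitory receptor/G-protein kinetics
#'
#' `d[R]/dt = r1 (1 - [R]) [T] - r2 [R]` and `d[G]/dt = r3 [R] - r4 [G]`.
#'
#' @param R activated-receptor fraction in `[0, 1]`.
#' @param G G-protein concentration, `>= 0`.
#' @param T_conc transmitter concentration (same sigmoidal drive as the fast
#'   GABA synapse).
#' @param params parameter list from [slow_synapse_params()].
#' @return numeric vector `c(dR, dG)`.
#' @export
slow_state_derivatives <- function(R, G, T_conc, params = slow_synapse_params()) {
  if (any(R < 0 | R > 1)) stop("R must lie in [0, 1]")
  if (any(G < 0)) stop("G must be nonnegative")
  c(params$r1 * (1 - R) * T_conc - params$r2 * R,
    params$r3 * R - params$r4 * G)
}

#' Slow inhibitory synaptic current
#'
#' `I = g_max * F * G^4 / (G^4 + K) * (V_post - E_K)`: a Hill-4 function of
#' the G-protein concentration gating a potassium conductance.
#'
#' @param G G-protein concentration, `>= 0`.
#' @param g_max maximal conductance (uS).
#' @param F_mult facilitation multiplier, `>= 1`.
#' @param V_post postsynaptic potential (mV).
#' @param params parameter list from [slow_synapse_params()] (uses `K`, `E_K`).
#' @return Current (uS * mV); outward-positive convention.
#' @export
slow_synaptic_current <- function(G, g_max, F_mult = 1, V_post,
                                  params = slow_synapse_params()) {
  if (any(G < 0)) stop("G must be nonnegative")
  g4 <- G^4
  g_max * F_mult * g4 / (g4 + params$K) * (V_post - params$E_K)
}
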