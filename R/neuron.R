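#' Hodgkin-Huxley parameters for a PN or LN
#'
#' Returns the single-compartment parameter set for one cell class.
#' Conductance densities (mS/cm^2) are the published values; totals are
#' obtained with an implicit membrane area chosen so that the printed total
#' capacitance corresponds to 1 uF/cm^2 (2.9e-4 cm^2 for PNs, 1.43e-4 cm^2
#' for LNs), which puts Cm (uF) and conductances (mS) on a consistent
#' mV/ms/uA scale. LNs carry no A-current and no h-current.
#'
#' @param cell_class `"PN"` or `"LN"`.
#' @param ... named overrides for individual fields (densities, reversals,
#'   calcium constants).
#' @return Object of class `neuron_params`: a list with capacitance `Cm`
#'   (uF), membrane `area` (cm^2), conductance densities `gL`, `gKL`, `gNa`,
#'   `gK`, `gA`, `gT`, `gh` (mS/cm^2; `gA`, `gh` are 0 for LNs), reversal
#'   potentials `EL`, `EKL`, `ENa`, `EK`, `ECa`, `Eh` (mV) and calcium
#'   constants `A_ca` (mM cm^2/(ms uA)), `tau_ca` (ms), `Ca_inf` (mM).
#' @examples
#' neuron_params("PN")$gNa   # 90 mS/cm^2
#' @export
neuron_params <- function(cell_class = c("PN", "LN"), ...) {
  cell_class <- match.arg(cell_class)
  p <- if (cell_class == "PN") {
    list(cell_class = "PN", Cm = 2.9e-4, area = 2.9e-4,
         gL = 0.01, gKL = 0.012, gNa = 90, gK = 10, gA = 10, gT = 2, gh = 0.02)
  } else {
    list(cell_class = "LN", Cm = 1.43e-4, area = 1.43e-4,
         gL = 0.05, gKL = 0.018, gNa = 100, gK = 10, gA = 0, gT = 1.75, gh = 0)
  }
  p <- c(p, list(EL = -70, EKL = -95, ENa = 50, EK = -95, ECa = 140, Eh = -40,
                 A_ca = 5.2e-5, tau_ca = 5, Ca_inf = 2.4e-4))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  structure(p, class = "neuron_params")
}

#' Generic Hodgkin-Huxley intrinsic current
#'
#' Computes `I = g * m^M * h^N * (V - E)`. The sign convention is that a
#' positive value is an outward contribution, i.e. it is subtracted in the
#' membrane equation.
#'
#' @param g maximal conductance (mS, total), `g >= 0`.
#' @param m,h activation and inactivation gates in `[0, 1]`.
#' @param M,N integer gate exponents (use `N = 0` for non-inactivating
#'   currents; `h` is then ignored).
#' @param V membrane potential (mV).
#' @param E reversal potential (mV).
#' @return Current (uA when `g` is in mS and voltages in mV).
#' @examples
#' intrinsic_current(g = 10, m = 0.5, M = 4, h = 1, N = 0, V = -60, E = -95)
#' @export
intrinsic_current <- function(g, m, M, h, N, V, E) {
  if (any(g < 0)) stop("conductance must be nonnegative")
  if (any(m < 0 | m > 1) || (N > 0 && any(h < 0 | h > 1)))
    stop("gating variables must lie in [0, 1]")
  g * m^M * (if (N > 0) h^N else 1) * (V - E)
}

#' First-order gating-variable kinetics
#'
#' `dx/dt = (x_inf - x) / tau_x`, the relaxation form shared by all gating
#' variables of the model.
#'
#' @param x current gate value.
#' @param x_inf voltage-dependent steady state.
#' @param tau_x relaxation time (ms), `> 0`.
#' @return Rate of change (1/ms).
#' @export
gating_derivative <- function(x, x_inf, tau_x) {
  if (any(tau_x <= 0)) stop("tau_x must be positive")
  (x_inf - x) / tau_x
}

#' Intracellular calcium dynamics
#'
#' First-order model `d[Ca]/dt = -A_ca * I_T - (Ca - Ca_inf) / tau_ca`:
#' influx through the low-threshold calcium current and relaxation to the
#' equilibrium concentration.
#'
#' @param Ca intracellular calcium concentration (mM), `> 0`.
#' @param I_T instantaneous low-threshold calcium current (uA; inward
#'   negative, so inward current raises Ca).
#' @param params a [neuron_params()] object (uses `A_ca`, `tau_ca`, `Ca_inf`).
#' @return Rate of change (mM/ms).
#' @export
calcium_derivative <- function(Ca, I_T, params) {
  if (any(Ca <= 0)) stop("Ca must be positive")
  -params$A_ca * I_T - (Ca - params$Ca_inf) / params$tau_ca
}

#' Membrane-potential derivative of a PN or LN
#'
#' Right-hand side of the single-compartment membrane equation divided by
#' `Cm`. For PNs the current set is leak, KL leak, I_Na, I_K, I_A, I_T, I_h
#' plus synaptic (fast GABA-A, slow inhibition, nicotinic) and stimulus
#' terms; LNs omit I_A, I_h and slow inhibition. `I_syn_total` is the summed
#' synaptic current with the same outward-positive convention as
#' [intrinsic_current()]; `I_stim` is depolarizing-positive (added).
#'
#' @param state list with `V` (mV), `gating` (named list of per-current
#'   `m`/`h` values: `na_m`, `na_h`, `k_n`, and for PNs `a_m`, `a_h`,
#'   `t_m`, `t_h`, `h_m`), and `Ca` (mM).
#' @param params a [neuron_params()] object.
#' @param I_syn_total total synaptic current (uA, outward positive).
#' @param I_stim stimulus current (uA, depolarizing positive).
#' @param kinetics kinetics table from [al_kinetics()] (exponents only are
#'   needed here; supplied for interface symmetry).
#' @return `dV/dt` in mV/ms.
#' @export
membrane_derivative <- function(state, params, I_syn_total = 0, I_stim = 0,
                                kinetics = al_kinetics()) {
  if (!params$cell_class %in% c("PN", "LN")) stop("unknown cell class")
  g <- state$gating
  V <- state$V
  a <- params$area
  I <- params$gL * a * (V - params$EL) + params$gKL * a * (V - params$EKL)
  I <- I + intrinsic_current(params$gNa * a, g$na_m, kinetics$na$M, g$na_h, kinetics$na$N, V, params$ENa)
  I <- I + intrinsic_current(params$gK * a, g$k_n, kinetics$k$M, 1, 0L, V, params$EK)
  I <- I + intrinsic_current(params$gT * a, g$t_m, kinetics$t$M, g$t_h, kinetics$t$N, V, params$ECa)
  if (params$cell_class == "PN") {
    I <- I + intrinsic_current(params$gA * a, g$a_m, kinetics$a$M, g$a_h, kinetics$a$N, V, params$EK)
    I <- I + intrinsic_current(params$gh * a, g$h_m, kinetics$h$M, 1, 0L, V, params$Eh)
  }
  (-I - I_syn_total + I_stim) / params$Cm
}

#' Resting gating state for a membrane potential
#'
#' All gates at their voltage-dependent steady state, calcium at equilibrium.
#' Used to initialize simulations and the single-neuron reference integrator.
#'
#' @param V membrane potential (mV).
#' @param params a [neuron_params()] object.
#' @param kinetics kinetics table from [al_kinetics()].
#' @return A `state` list as accepted by [membrane_derivative()].
#' @export
neuron_rest_state <- function(V, params, kinetics = al_kinetics()) {
  gating <- list(
    na_m = kinetics$na$m_inf(V), na_h = kinetics$na$h_inf(V),
    k_n = kinetics$k$m_inf(V),
    t_m = kinetics$t$m_inf(V), t_h = kinetics$t$h_inf(V)
  )
  if (params$cell_class == "PN") {
    gating$a_m <- kinetics$a$m_inf(V); gating$a_h <- kinetics$a$h_inf(V)
    gating$h_m <- kinetics$h$m_inf(V)
  } else {
    gating$a_m <- 0; gating$a_h <- 0; gating$h_m <- 0
  }
  list(V = V, gating = gating, Ca = params$Ca_inf)
}

#' Reference single-neuron integrator (pure R)
#'
#' Classical RK4 integration of one isolated PN or LN under a stimulus
#' current, with the same equations as the C++ network engine. Slow; used
#' for cross-checks and single-cell exploration.
#'
#' @param params a [neuron_params()] object.
#' @param t_ms duration (ms).
#' @param dt time step (ms).
#' @param I_stim either a scalar current (uA) or a function of time `f(t)`.
#' @param V0 initial potential (mV).
#' @param kinetics kinetics table.
#' @return list with `time` (ms), `V` (mV), `Ca` (mM), `spikes` (ms; upward
#'   0 mV crossings, 2 ms refractory).
#' @export
simulate_neuron <- function(params, t_ms = 500, dt = 0.04, I_stim = 0,
                            V0 = -70, kinetics = al_kinetics()) {
  fI <- if (is.function(I_stim)) I_stim else function(t) I_stim
  st <- neuron_rest_state(V0, params, kinetics)
  gates <- c("na_m", "na_h", "k_n", "t_m", "t_h",
             if (params$cell_class == "PN") c("a_m", "a_h", "h_m"))
  pack <- function(s) c(s$V, unlist(s$gating[gates]), s$Ca)
  unpack <- function(y) {
    s <- st
    s$V <- y[1]
    s$gating[gates] <- as.list(y[seq_along(gates) + 1])
    s$Ca <- y[length(y)]
    s
  }
  ginf <- list(na_m = kinetics$na$m_inf, na_h = kinetics$na$h_inf,
               k_n = kinetics$k$m_inf, t_m = kinetics$t$m_inf,
               t_h = kinetics$t$h_inf, a_m = kinetics$a$m_inf,
               a_h = kinetics$a$h_inf, h_m = kinetics$h$m_inf)
  gtau <- list(na_m = kinetics$na$tau_m, na_h = kinetics$na$tau_h,
               k_n = kinetics$k$m_inf, t_m = kinetics$t$tau_m,
               t_h = kinetics$t$tau_h, a_m = kinetics$a$tau_m,
               a_h = kinetics$a$tau_h, h_m = kinetics$h$tau_m)
  gtau$k_n <- kinetics$k$tau_m
  deriv <- function(y, t) {
    s <- unpack(y)
    V <- s$V
    dV <- membrane_derivative(s, params, 0, fI(t), kinetics)
    dg <- vapply(gates, function(nm)
      gating_derivative(s$gating[[nm]], ginf[[nm]](V), gtau[[nm]](V)), 0)
    a <- params$area
    iT <- intrinsic_current(params$gT * a, s$gating$t_m, kinetics$t$M,
                            s$gating$t_h, kinetics$t$N, V, params$ECa)
    c(dV, dg, calcium_derivative(s$Ca, iT, params))
  }
  n <- ceiling(t_ms / dt)
  y <- pack(st)
  Vout <- numeric(n + 1); Vout[1] <- y[1]
  Caout <- numeric(n + 1); Caout[1] <- y[length(y)]
  spikes <- numeric(0); last_sp <- -Inf
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    k1 <- deriv(y, t)
    k2 <- deriv(y + dt / 2 * k1, t + dt / 2)
    k3 <- deriv(y + dt / 2 * k2, t + dt / 2)
    k4 <- deriv(y + dt * k3, t + dt)
    ynew <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ng <- length(gates)
    ynew[2:(1 + ng)] <- pmin(pmax(ynew[2:(1 + ng)], 0), 1)
    if (y[1] < 0 && ynew[1] >= 0 && (i * dt - last_sp) >= 2) {
      spikes <- c(spikes, i * dt); last_sp <- i * dt
    }
    y <- ynew
    Vout[i + 1] <- y[1]; Caout[i + 1] <- y[length(y)]
  }
  list(time = seq(0, n * dt, by = dt), V = Vout, Ca = Caout, spikes = spikes)
}
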