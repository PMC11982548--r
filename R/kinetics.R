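#' Voltage-dependent channel kinetics
#'
#' Steady-state activation/inactivation and relaxation-time functions for the
#' intrinsic currents of AL projection neurons (PNs) and local interneurons
#' (LNs). The forms follow the conductance-based antennal-lobe model lineage:
#' Traub-type sodium and delayed-rectifier potassium kinetics (voltage origin
#' shifted to -50 mV), a Huguenard/McCormick transient A-current, a Destexhe
#' low-threshold calcium current (I_T), and an anomalous rectifier (I_h).
#' The table is returned as a plain list of functions so an alternative
#' parameterization can be swapped in wherever a kinetics argument is
#' accepted.
#'
#' Each element is a list with functions `inf(V)` and `tau(V)` (ms), plus the
#' gate exponents `M` (activation) and `N` (inactivation) used in
#' [intrinsic_current()].
#'
#' @return Named list with elements `na` (m^3 h), `k` (n^4), `a` (m^4 h),
#'   `t` (m^2 h), `h` (m^1), each holding `m_inf`, `tau_m`, and where the
#'   current inactivates `h_inf`, `tau_h`.
#' @examples
#' kin <- al_kinetics()
#' kin$na$m_inf(-50)   # half-ish activation near threshold
#' @export
al_kinetics <- function() {
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))
  # Traub-type fast sodium, voltage origin shifted by -50 mV
  na_am <- function(V) { u <- V + 50; 0.32 * vtrap(13 - u, 4) }
  na_bm <- function(V) { u <- V + 50; 0.28 * vtrap(u - 40, 5) }
  na_ah <- function(V) { u <- V + 50; 0.128 * exp((17 - u) / 18) }
  na_bh <- function(V) { u <- V + 50; 4 / (1 + exp((40 - u) / 5)) }
  # Traub-type delayed rectifier
  k_an <- function(V) { u <- V + 50; 0.032 * vtrap(15 - u, 5) }
  k_bn <- function(V) { u <- V + 50; 0.5 * exp((10 - u) / 40) }

  list(
    na = list(
      M = 3L, N = 1L,
      m_inf = function(V) na_am(V) / (na_am(V) + na_bm(V)),
      tau_m = function(V) 1 / (na_am(V) + na_bm(V)),
      h_inf = function(V) na_ah(V) / (na_ah(V) + na_bh(V)),
      tau_h = function(V) 1 / (na_ah(V) + na_bh(V))
    ),
    k = list(
      M = 4L, N = 0L,
      m_inf = function(V) k_an(V) / (k_an(V) + k_bn(V)),
      tau_m = function(V) 1 / (k_an(V) + k_bn(V))
    ),
    # transient A-type potassium current (PN only)
    a = list(
      M = 4L, N = 1L,
      m_inf = function(V) 1 / (1 + exp(-(V + 60) / 8.5)),
      tau_m = function(V) 0.37 + 1 / (exp((V + 35.8) / 19.7) + exp(-(V + 79.7) / 12.7)),
      h_inf = function(V) 1 / (1 + exp((V + 78) / 6)),
      tau_h = function(V) ifelse(V < -63,
        1 / (exp((V + 46) / 5) + exp(-(V + 238) / 37.5)), 19)
    ),
    # low-threshold transient calcium current
    t = list(
      M = 2L, N = 1L,
      m_inf = function(V) 1 / (1 + exp(-(V + 52) / 7.4)),
      tau_m = function(V) 0.44 + 0.15 / (exp((V + 27) / 10) + exp(-(V + 102) / 15)),
      h_inf = function(V) 1 / (1 + exp((V + 80) / 5)),
      tau_h = function(V) 22.7 + 0.27 / (exp((V + 48) / 4) + exp(-(V + 407) / 50))
    ),
    # anomalous rectifier / hyperpolarization-activated cation current (PN only)
    h = list(
      M = 1L, N = 0L,
      m_inf = function(V) 1 / (1 + exp((V + 75) / 5.5)),
      tau_m = function(V) 1 / (exp(-14.59 - 0.086 * V) + exp(-1.87 + 0.0701 * V))
    )
  )
}
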