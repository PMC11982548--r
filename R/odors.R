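#' Percept tiling of the PN population
#'
#' Percepts (the AL activation footprints of pure volatile chemicals) tile
#' the PN population in contiguous blocks; e.g. with 100 PNs and 7 percepts,
#' percept 1 covers PNs 1-14. Input-receiving LNs are mapped onto the same
#' continuous position axis so that the unipolar LNs of a glomerulus receive
#' the activation of their position.
#'
#' @param n_pn number of PNs covered by the tiling (for the scaled-up
#'   network this is the input-receiving first half).
#' @param n_percepts number of percepts.
#' @return data.frame with one row per percept: `id`, `lo`, `hi` (PN index
#'   bounds, inclusive), `center`, `span` (in PN position units).
#' @export
al_percepts <- function(n_pn = 100L, n_percepts = 7L) {
  bounds <- round(seq(0, n_pn, length.out = n_percepts + 1))
  data.frame(id = seq_len(n_percepts),
             lo = bounds[-length(bounds)] + 1L,
             hi = bounds[-1],
             center = (bounds[-length(bounds)] + bounds[-1]) / 2,
             span = diff(bounds))
}

#' Gaussian activation profile of one percept
#'
#' Per-neuron input amplitudes for one percept:
#' `peak * exp(-(x - center)^2 / (2 * (width * span / 2)^2))` for positions
#' `x` inside the percept's block and 0 outside. The width is expressed as a
#' fraction of the half-span, so wider percept activation recruits strictly
#' more neurons above any fixed threshold.
#'
#' @param x neuron positions (PN index units, e.g. `i - 0.5`).
#' @param percept one row of [al_percepts()].
#' @param width Gaussian standard deviation as a fraction of the percept
#'   span, `> 0`.
#' @param peak maximal amplitude.
#' @return Amplitude per position.
#' @export
percept_activation_profile <- function(x, percept, width, peak = 1) {
  if (width <= 0) stop("width must be positive")
  sd_pos <- width * percept$span / 2
  amp <- peak * exp(-(x - percept$center)^2 / (2 * sd_pos^2))
  amp[x < percept$lo - 1 | x > percept$hi] <- 0
  amp
}

#' Construct an odor
#'
#' An odor is a vector of per-percept Gaussian widths (0 = percept
#' inactive), a reward label, and optionally per-percept pulse parameters
#' (for sensor-feature-derived odors).
#'
#' @param widths numeric vector over percepts; entries in `(0, 1]` activate
#'   the percept with that Gaussian width.
#' @param reward `"rewarded"`, `"habituated"` or `"none"`.
#' @param label odor name.
#' @param pulse optional data.frame (one row per percept) with columns
#'   `peak_scale`, `tau_rise`, `tau_decay` overriding the default stimulus
#'   pulse per percept.
#' @return Object of class `al_odor`.
#' @export
odor <- function(widths, reward = "none", label = "odor", pulse = NULL) {
  stopifnot(all(widths >= 0), any(widths > 0))
  structure(list(widths = widths, reward = reward, label = label,
                 pulse = pulse), class = "al_odor")
}

#' @export
print.al_odor <- function(x, ...) {
  act <- which(x$widths > 0)
  cat(sprintf("odor %s (%s): percepts {%s}, widths {%s}\n", x$label, x$reward,
              paste(act, collapse = ","),
              paste(format(x$widths[act], digits = 2), collapse = ",")))
  invisible(x)
}

#' Build a class of simple odors over three percepts
#'
#' Simple odors activate exactly 3 of the percepts; odors within a class
#' share the percept support and differ in their Gaussian widths.
#'
#' @param percept_ids exactly 3 distinct percept indices.
#' @param widths_per_odor list (or 3-column matrix) of width vectors, one
#'   per odor.
#' @param reward reward label for the class.
#' @param label class name; odors are `label1`, `label2`, ...
#' @param n_percepts total percept count the odors are defined over.
#' @return list of [odor()] objects.
#' @export
make_odor_class <- function(percept_ids, widths_per_odor, reward,
                            label = "A", n_percepts = 7L) {
  if (length(unique(percept_ids)) != 3 || length(percept_ids) != 3)
    stop("a simple odor class uses exactly 3 distinct percepts")
  if (is.matrix(widths_per_odor))
    widths_per_odor <- asplit(widths_per_odor, 1)
  lapply(seq_along(widths_per_odor), function(i) {
    w <- rep(0, n_percepts)
    w[percept_ids] <- widths_per_odor[[i]]
    odor(w, reward, paste0(label, i))
  })
}

#' Convert a chemical-proportion blend into an odor
#'
#' Natural-blend odors assign each of 6 chemical components one percept; the
#' Gaussian width of percept k equals the chemical's proportion in the
#' blend. The 7th percept stays inactive.
#'
#' @param proportions 6 nonnegative fractions summing to 1 (tolerance 0.02).
#' @param reward reward label.
#' @param label odor name.
#' @param n_percepts total percepts (the trailing ones remain inactive).
#' @return An [odor()].
#' @examples
#' blend_to_odor(c(0.372, 0.253, 0.141, 0.102, 0.078, 0.054))$widths[1]
#' @export
blend_to_odor <- function(proportions, reward = "none", label = "blend",
                          n_percepts = 7L) {
  if (length(proportions) != 6) stop("a blend has 6 chemical proportions")
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  if (all(proportions == 0)) stop("degenerate all-zero blend")
  if (abs(sum(proportions) - 1) > 0.02)
    stop("proportions must sum to 1 (tolerance 0.02)")
  odor(c(proportions, rep(0, n_percepts - 6)), reward, label)
}

#' Stimulus current pulse
#'
#' The 500 ms odor input waveform: rises toward `peak` with time constant
#' `tau_rise` while the odor is on, then decays with `tau_decay`; zero
#' before onset.
#'
#' @param t time (ms), vectorized.
#' @param t_on pulse onset (ms).
#' @param peak maximal amplitude (uA), `>= 0`.
#' @param tau_rise,tau_decay rise/decay time constants (ms).
#' @param duration pulse duration (ms).
#' @return Current amplitude at `t`.
#' @export
stimulus_current <- function(t, t_on = 0, peak = 1, tau_rise = 66.7,
                             tau_decay = 200, duration = 500) {
  if (any(peak < 0)) stop("peak must be nonnegative")
  end <- t_on + duration
  i_end <- peak * (1 - exp(-duration / tau_rise))
  out <- ifelse(t < t_on, 0,
         ifelse(t <= end, peak * (1 - exp(-(t - t_on) / tau_rise)),
                i_end * exp(-(t - end) / tau_decay)))
  out
}

#' Gaussian background-noise currents
#'
#' I.i.d. zero-mean Gaussian current per neuron per step, reproducible under
#' a seed. The network engine draws the identical kind of noise internally;
#' this generator provides the module surface for testing and external use.
#'
#' @param n_steps,n_neurons dimensions.
#' @param sd noise amplitude (uA per step), `>= 0`.
#' @param seed integer seed.
#' @return `n_steps x n_neurons` matrix of current increments.
#' @export
background_noise <- function(n_steps, n_neurons, sd = 1, seed = 1L) {
  if (sd < 0) stop("amplitude must be nonnegative")
  set.seed(seed)
  matrix(rnorm(n_steps * n_neurons, 0, sd), n_steps, n_neurons)
}

#' Convert gas-sensor features into stimulus-pulse parameters
#'
#' Maps the three per-sensor response features (response magnitude `dR`,
#' on/off exponential-moving-average extrema) onto pulse parameters: peak
#' proportional to `dR`, rise time constant proportional to `1/ema_max`,
#' decay time constant proportional to `1/ema_min`.
#'
#' @param dR response magnitude.
#' @param ema_max,ema_min EMA extrema, `> 0`.
#' @param const proportionality constants: `peak_per_dR` (uA per unit dR),
#'   `rise_scale` and `decay_scale` (ms, divided by the EMA value). The
#'   defaults reproduce the small-network pulse scale (66.7 / 200 ms and the
#'   default peak) when fed unit-scale features.
#' @return list with `peak`, `tau_rise`, `tau_decay` (vectorized over
#'   sensors).
#' @export
sensor_features_to_pulse <- function(dR, ema_max, ema_min,
                                     const = list(peak_per_dR = 1,
                                                  rise_scale = 66.7,
                                                  decay_scale = 200)) {
  if (any(ema_max <= 0) || any(ema_min <= 0)) stop("ema features must be positive")
  list(peak = const$peak_per_dR * dR,
       tau_rise = const$rise_scale / ema_max,
       tau_decay = const$decay_scale / ema_min)
}

#' Synthetic gas-sensor feature dataset
#'
#' Emulates the structure of a 16-metal-oxide-sensor array responding to 6
#' odors with 8 features per sensor (response magnitude `dR`, its
#' normalized variant, and EMA on/off extrema at three smoothing rates).
#' Each odor has a fixed positive sensor-by-feature template; repetitions
#' add Gaussian jitter. Three odors are labeled rewarded and three
#' habituated. By default the templates carry the unique/shared structure
#' of natural odor sets: a block of sensors responds preferentially to the
#' rewarded group, another to the habituated group, and the remaining
#' sensors respond commonly to every odor (`structure = "random"` gives
#' fully independent templates instead). This is a synthetic stand-in with
#' the same schema as public gas-sensor drift datasets; no external
#' download is required.
#'
#' @param seed integer seed.
#' @param n_odors,n_sensors,n_features,n_reps dataset dimensions.
#' @param jitter_sd rep-level Gaussian jitter (relative to template scale).
#' @param structure `"unique_shared"` (group-selective sensor blocks) or
#'   `"random"` (independent templates).
#' @return data.frame with `odor`, `label` columns and
#'   `n_sensors * n_features` feature columns named `s<sensor>_<feature>`;
#'   attribute `templates` holds the noise-free per-odor templates.
#' @export
synthetic_sensor_dataset <- function(seed = 1L, n_odors = 6L, n_sensors = 16L,
                                     n_features = 8L, n_reps = 25L,
                                     jitter_sd = 0.15,
                                     structure = c("unique_shared",
                                                   "random")) {
  structure_kind <- match.arg(structure)
  set.seed(seed)
  feat_names <- c("dR", "dR_norm", "ema_max_a001", "ema_max_a01",
                  "ema_max_a1", "ema_min_a001", "ema_min_a01", "ema_min_a1")
  feat_names <- feat_names[seq_len(min(n_features, 8L))]
  if (n_features > 8L)
    feat_names <- c(feat_names, paste0("f", seq_len(n_features - 8L)))
  labels_by_odor <- ifelse(seq_len(n_odors) <= n_odors / 2,
                           "rewarded", "habituated")
  n_uniq <- max(1L, n_sensors %/% 3L)
  rew_block <- seq_len(n_uniq)
  hab_block <- n_uniq + seq_len(n_uniq)
  templates <- lapply(seq_len(n_odors), function(o) {
    tpl <- if (structure_kind == "random") {
      matrix(runif(n_sensors * n_features, 0.5, 3), n_sensors, n_features)
    } else {
      # common floor + group-selective sensor block + odor-specific detail
      base <- matrix(runif(n_sensors * n_features, 0.8, 1.6),
                     n_sensors, n_features)
      boost <- if (labels_by_odor[o] == "rewarded") rew_block else hab_block
      base[boost, ] <- base[boost, ] + runif(length(boost) * n_features, 1, 2)
      base + matrix(runif(n_sensors * n_features, 0, 1),
                    n_sensors, n_features)
    }
    dimnames(tpl) <- list(paste0("s", seq_len(n_sensors)), feat_names)
    tpl
  })
  rows <- lapply(seq_len(n_odors), function(o) {
    reps <- lapply(seq_len(n_reps), function(r) {
      v <- pmax(templates[[o]] + rnorm(length(templates[[o]]), 0, jitter_sd),
                0.05)
      as.vector(t(v))
    })
    do.call(rbind, reps)
  })
  X <- do.call(rbind, rows)
  colnames(X) <- as.vector(t(outer(paste0("s", seq_len(n_sensors)),
                                   feat_names, paste, sep = "_")))
  df <- data.frame(odor = rep(seq_len(n_odors), each = n_reps),
                   label = rep(ifelse(seq_len(n_odors) <= n_odors / 2,
                                      "rewarded", "habituated"),
                               each = n_reps))
  out <- cbind(df, as.data.frame(X))
  attr(out, "templates") <- templates
  out
}

#' Z-score sensor features per column
#'
#' Subtracts the mean and divides by the standard deviation of each feature
#' column, using statistics from `ref` (defaults to `x` itself, i.e. the
#' training set).
#'
#' @param x data.frame from [synthetic_sensor_dataset()] (or its feature
#'   columns).
#' @param ref reference data for the normalization statistics.
#' @return `x` with normalized feature columns; attributes `center`/`scale`.
#' @export
normalize_sensor_features <- function(x, ref = x) {
  fc <- setdiff(names(x), c("odor", "label"))
  mu <- vapply(ref[fc], mean, 0)
  sdv <- vapply(ref[fc], sd, 0)
  sdv[sdv == 0] <- 1
  x[fc] <- Map(function(col, m, s) (col - m) / s, x[fc], mu, sdv)
  attr(x, "center") <- mu
  attr(x, "scale") <- sdv
  x
}

#' Build an odor from one repetition of sensor features
#'
#' Each sensor is one percept; the pulse driving the percept's neurons is
#' parameterized from the sensor's `dR`, `ema_max` and `ema_min` features
#' via [sensor_features_to_pulse()]. Widths are 1 (flat percept blocks):
#' sensor odors differ only in pulse amplitude and time constants.
#'
#' @param features named numeric vector of one dataset row's feature columns.
#' @param n_sensors number of sensors/percepts.
#' @param reward,label odor metadata.
#' @param const proportionality constants, see [sensor_features_to_pulse()].
#' @return An [odor()] with per-percept pulse parameters.
#' @export
sensor_odor <- function(features, n_sensors = 16L, reward = "none",
                        label = "sensor", const = list(peak_per_dR = 0.57,
                                                       rise_scale = 116.7,
                                                       decay_scale = 350)) {
  get <- function(f) as.numeric(features[paste0("s", seq_len(n_sensors), "_", f)])
  p <- sensor_features_to_pulse(abs(get("dR")) + 0.05,
                                pmax(get("ema_max_a001"), 0.05),
                                pmax(get("ema_min_a001"), 0.05), const)
  odor(rep(1, n_sensors), reward, label,
       pulse = data.frame(peak_scale = p$peak, tau_rise = p$tau_rise,
                          tau_decay = p$tau_decay))
}
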