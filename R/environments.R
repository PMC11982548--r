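#' Odor environment
#'
#' An environment bundles odor classes (each a list of odors sharing a
#' reward label) and defines the pool a training protocol samples from.
#'
#' @param classes named list of odor lists (from [make_odor_class()] etc.).
#' @param n_percepts percept count the odors are defined over.
#' @return Object of class `al_environment`.
#' @export
al_environment <- function(classes, n_percepts = 7L) {
  rl <- vapply(classes, function(cl) cl[[1]]$reward, "")
  structure(list(classes = classes, n_percepts = n_percepts,
                 rewards = rl), class = "al_environment")
}

#' @export
print.al_environment <- function(x, ...) {
  for (nm in names(x$classes)) {
    cl <- x$classes[[nm]]
    act <- which(cl[[1]]$widths > 0)
    cat(sprintf("class %s (%s): %d odors over percepts {%s}\n", nm,
                cl[[1]]$reward, length(cl), paste(act, collapse = ",")))
  }
  invisible(x)
}

#' Flat list of all odors in an environment
#'
#' @param env an [al_environment()].
#' @return list of [odor()] objects across all classes.
#' @export
env_odors <- function(env) unlist(env$classes, recursive = FALSE)

# deterministic width cycle used for default odor classes; values span the
# narrow-to-wide range used for within-class variation
width_cycle <- function(n, base = c(1.0, 0.7, 0.45), seed = NULL,
                        jitter = 0) {
  w <- lapply(seq_len(n), function(i) {
    v <- base[((seq_along(base) + i - 2) %% length(base)) + 1]
    v
  })
  if (jitter > 0) {
    set.seed(seed)
    w <- lapply(w, function(v) pmin(pmax(v + runif(length(v), -jitter, jitter),
                                         0.3), 1.0))
  }
  w
}

#' Default simple two-class environment
#'
#' The rewarded class activates percepts 1-3 and the habituated class
#' percepts 2-4 (2 of 3 percepts shared). Odors within a class share the
#' percept support and differ in Gaussian widths, cycled over
#' `{1.0, 0.7, 0.45}` (plus optional seeded jitter for larger classes).
#'
#' @param n_odors odors per class.
#' @param n_percepts percept count (default 7).
#' @param rewarded_percepts,habituated_percepts percept triplets.
#' @param seed seed for width jitter when `n_odors > 3`.
#' @return An [al_environment()].
#' @export
simple_environment <- function(n_odors = 3L, n_percepts = 7L,
                               rewarded_percepts = 1:3,
                               habituated_percepts = 2:4, seed = 1L) {
  jit <- if (n_odors > 3) 0.12 else 0
  wA <- width_cycle(n_odors, seed = seed, jitter = jit)
  wB <- width_cycle(n_odors, seed = seed + 1, jitter = jit)
  al_environment(list(
    A = make_odor_class(rewarded_percepts, wA, "rewarded", "A", n_percepts),
    B = make_odor_class(habituated_percepts, wB, "habituated", "B", n_percepts)
  ), n_percepts)
}

#' Synthetic snapdragon-blend proportions
#'
#' Chemical-proportion tables for the two floral blend classes (PH, Pale
#' Hybrid, rewarded; PP, Potomac Pink, habituated). Only the first
#' proportion of PH1 (0.372, the dominant monoterpene) is anchored to the
#' published value; the remaining entries are synthetic stand-ins with the
#' same structure (6 components summing to 1, PH dominated by components
#' 1-2, PP by components 3-4).
#'
#' @return list with matrices `PH` and `PP` (odors x 6 components).
#' @export
ph_pp_proportions <- function() {
  PH <- rbind(
    PH1 = c(0.372, 0.253, 0.141, 0.102, 0.078, 0.054),
    PH2 = c(0.310, 0.289, 0.160, 0.112, 0.071, 0.058),
    PH3 = c(0.402, 0.221, 0.152, 0.095, 0.082, 0.048))
  PP <- rbind(
    PP1 = c(0.061, 0.118, 0.385, 0.236, 0.124, 0.076),
    PP2 = c(0.072, 0.101, 0.352, 0.266, 0.131, 0.078),
    PP3 = c(0.055, 0.131, 0.401, 0.214, 0.118, 0.081))
  list(PH = PH, PP = PP)
}

#' PH/PP blend environment
#'
#' Builds the natural-blend environment: PH odors rewarded, PP habituated,
#' percept widths equal to chemical proportions ([blend_to_odor()]); the 7th
#' percept stays inactive.
#'
#' @param proportions list with `PH` and `PP` matrices, see
#'   [ph_pp_proportions()].
#' @param n_percepts percept count (default 7; 6 active).
#' @return An [al_environment()].
#' @export
ph_pp_environment <- function(proportions = ph_pp_proportions(),
                              n_percepts = 7L) {
  mk <- function(M, reward) {
    lapply(rownames(M), function(nm)
      blend_to_odor(M[nm, ], reward, nm, n_percepts))
  }
  al_environment(list(PH = mk(proportions$PH, "rewarded"),
                      PP = mk(proportions$PP, "habituated")), n_percepts)
}

#' Two-environment experiment definitions
#'
#' Percept assignments for the environment-relearning cases, over a
#' 10-percept tiling. Environment 1 is always P (rewarded, percepts 1-3)
#' vs Q (habituated, percepts 2-4). Environment 2 per case:
#' \itemize{
#'   \item Case 1 - no overlap with Env1: S (5-7) vs T (6-8).
#'   \item Case 2 - complete overlap: M (1-3, = P) vs N (2-4, = Q).
#'   \item Case 3 - rewarded-odor overlap only: M (1-3, = P) vs S (5-7).
#'   \item Case 4 - habituated-odor overlap only: N (2-4, = Q) vs S (5-7).
#' }
#' `env2_reward_sign = "pos"` rewards the first listed Env2 class
#' (consistent with Env1 where classes overlap); `"neg"` reverses it.
#'
#' @param case 1-4.
#' @param env2_reward_sign `"pos"` or `"neg"`.
#' @param n_odors odors per class (default 10).
#' @param seed width-jitter seed.
#' @return list with `env1`, `env2` ([al_environment()]s over 10 percepts)
#'   and `pair_labels` naming the class pairs evaluated per environment.
#' @export
env_case_environments <- function(case, env2_reward_sign = c("pos", "neg"),
                                  n_odors = 10L, seed = 1L) {
  env2_reward_sign <- match.arg(env2_reward_sign)
  if (!case %in% 1:4) stop("invalid case: must be 1, 2, 3 or 4")
  np <- 10L
  p2 <- switch(case,
    list(first = list("S", 5:7), second = list("T", 6:8)),
    list(first = list("M", 1:3), second = list("N", 2:4)),
    list(first = list("M", 1:3), second = list("S", 5:7)),
    list(first = list("N", 2:4), second = list("S", 5:7)))
  rew2 <- if (env2_reward_sign == "pos") c("rewarded", "habituated")
          else c("habituated", "rewarded")
  jit <- 0.12
  env1 <- al_environment(list(
    P = make_odor_class(1:3, width_cycle(n_odors, seed = seed, jitter = jit),
                        "rewarded", "P", np),
    Q = make_odor_class(2:4, width_cycle(n_odors, seed = seed + 1,
                                         jitter = jit),
                        "habituated", "Q", np)), np)
  cls2 <- list(
    make_odor_class(p2$first[[2]],
                    width_cycle(n_odors, seed = seed + 2, jitter = jit),
                    rew2[1], p2$first[[1]], np),
    make_odor_class(p2$second[[2]],
                    width_cycle(n_odors, seed = seed + 3, jitter = jit),
                    rew2[2], p2$second[[1]], np))
  names(cls2) <- c(p2$first[[1]], p2$second[[1]])
  env2 <- al_environment(cls2, np)
  list(env1 = env1, env2 = env2,
       pair_labels = list(env1 = c("P", "Q"), env2 = names(cls2)))
}
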