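#' Connection probabilities of the AL network
#'
#' Bernoulli edge probabilities between the neuron groups. Unipolar LNs make
#' no synapses onto PNs or LNs of their own glomerulus, and there are no
#' PN-PN connections.
#'
#' @return Named numeric vector of probabilities.
#' @export
al_connection_probs <- function() {
  c(pn_uln = 0.4, pn_mln = 0.4,
    uln_pn_same = 0, uln_pn_other = 0.5,
    uln_uln_same = 0, uln_uln_other = 0.4, uln_mln = 0.3,
    mln_pn = 0.3, mln_mln = 0.1, mln_uln = 0.4)
}

# Bernoulli edge draw over an admissibility mask; returns (pre, post) index
# vectors. mask rows = pre, cols = post.
draw_edges <- function(mask, p) {
  if (length(mask) == 0)
    return(list(pre = integer(), post = integer()))
  draws <- matrix(runif(length(mask)) < p, nrow(mask))
  idx <- which(mask & draws, arr.ind = TRUE)
  list(pre = idx[, 1], post = idx[, 2])
}

#' Build the antennal-lobe network topology
#'
#' Constructs the glomerular AL network: `n_glomeruli` glomeruli of
#' `pn_per_glom` PNs and `uln_per_glom` unipolar LNs each, plus
#' `n_multipolar` glomerulus-free multipolar LNs, with random directed
#' connectivity drawn per group pair from [al_connection_probs()]. Defaults
#' give 100 PNs and 280 LNs in 20 glomeruli. Slow inhibitory LN-to-PN
#' synapses share the adjacency of the fast GABA-A LN-to-PN synapses (one
#' anatomical pathway, two receptor types). All facilitation multipliers
#' start at 1.
#'
#' Neuron indexing: PNs `1..n_pn` (glomerulus `floor((i-1)/pn_per_glom)+1`),
#' LNs `1..n_ln` with unipolar LNs first (blocks of `uln_per_glom` per
#' glomerulus) and multipolar LNs last.
#'
#' @param seed integer seed; topologies are reproducible.
#' @param n_glomeruli,pn_per_glom,uln_per_glom,n_multipolar network size.
#' @param g named list of maximal conductances (uS): `gaba_ln2pn`,
#'   `gaba_ln2ln`, `ach`, `slow`.
#' @param probs connection probabilities, see [al_connection_probs()].
#' @return An object of class `al_network`.
#' @examples
#' net <- build_al_network(seed = 1, n_glomeruli = 4, n_multipolar = 8)
#' summary(net)
#' @export
build_al_network <- function(seed = 1L, n_glomeruli = 20L, pn_per_glom = 5L,
                             uln_per_glom = 12L, n_multipolar = 40L,
                             g = list(gaba_ln2pn = 0.015, gaba_ln2ln = 0.02,
                                      ach = 0.3, slow = 0.02),
                             probs = al_connection_probs()) {
  set.seed(seed)
  n_pn <- n_glomeruli * pn_per_glom
  n_uln <- n_glomeruli * uln_per_glom
  n_ln <- n_uln + n_multipolar
  glom_pn <- rep(seq_len(n_glomeruli), each = pn_per_glom)
  glom_ln <- c(rep(seq_len(n_glomeruli), each = uln_per_glom),
               rep(NA_integer_, n_multipolar))
  is_mln <- c(rep(FALSE, n_uln), rep(TRUE, n_multipolar))

  # PN -> LN (cholinergic)
  m1 <- matrix(TRUE, n_pn, n_uln)
  e_pu <- draw_edges(m1, probs[["pn_uln"]])
  m2 <- matrix(TRUE, n_pn, n_multipolar)
  e_pm <- draw_edges(m2, probs[["pn_mln"]])
  pn2ln <- list(pre = c(e_pu$pre, e_pm$pre),
                post = c(e_pu$post, e_pm$post + n_uln))

  # unipolar LN -> PN (other glomerulus only)
  mask_up <- outer(glom_ln[seq_len(n_uln)], glom_pn, "!=")
  e_up <- draw_edges(mask_up, probs[["uln_pn_other"]])
  # multipolar LN -> PN
  e_mp <- draw_edges(matrix(TRUE, n_multipolar, n_pn), probs[["mln_pn"]])
  ln2pn <- list(pre = c(e_up$pre, e_mp$pre + n_uln),
                post = c(e_up$post, e_mp$post))

  # LN -> LN
  mask_uu <- outer(glom_ln[seq_len(n_uln)], glom_ln[seq_len(n_uln)], "!=")
  diag(mask_uu) <- FALSE
  e_uu <- draw_edges(mask_uu, probs[["uln_uln_other"]])
  e_um <- draw_edges(matrix(TRUE, n_uln, n_multipolar), probs[["uln_mln"]])
  mm <- matrix(TRUE, n_multipolar, n_multipolar); diag(mm) <- FALSE
  e_mm <- draw_edges(mm, probs[["mln_mln"]])
  e_mu <- draw_edges(matrix(TRUE, n_multipolar, n_uln), probs[["mln_uln"]])
  ln2ln <- list(pre = c(e_uu$pre, e_um$pre, e_mm$pre + n_uln, e_mu$pre + n_uln),
                post = c(e_uu$post, e_um$post + n_uln, e_mm$post + n_uln,
                         e_mu$post))

  new_al_network(n_pn, n_ln, glom_pn, glom_ln, is_mln, pn2ln, ln2pn, ln2ln,
                 g, seed, large = FALSE,
                 n_glomeruli = n_glomeruli, pn_per_glom = pn_per_glom,
                 uln_per_glom = uln_per_glom, n_multipolar = n_multipolar)
}

#' Build the scaled-up network for sensor-derived odors
#'
#' 400 PNs and 1120 LNs (no glomerular structure): LN-LN, LN-PN and PN-LN
#' connections are each drawn Bernoulli(0.125); there are no PN-PN
#' connections. Large-network conductance defaults apply (0.024 uS LN-LN,
#' 0.019 uS LN-PN, 0.075 uS PN-LN).
#'
#' @param seed integer seed.
#' @param n_pn,n_ln network size.
#' @param p connection probability.
#' @param g maximal conductances (uS), as in [build_al_network()].
#' @return An `al_network`.
#' @export
build_large_network <- function(seed = 1L, n_pn = 400L, n_ln = 1120L,
                                p = 0.125,
                                g = list(gaba_ln2pn = 0.019,
                                         gaba_ln2ln = 0.024,
                                         ach = 0.075, slow = 0.02)) {
  set.seed(seed)
  pn2ln <- draw_edges(matrix(TRUE, n_pn, n_ln), p)
  ln2pn <- draw_edges(matrix(TRUE, n_ln, n_pn), p)
  mm <- matrix(TRUE, n_ln, n_ln); diag(mm) <- FALSE
  ln2ln <- draw_edges(mm, p)
  new_al_network(n_pn, n_ln, glom_pn = rep(NA_integer_, n_pn),
                 glom_ln = rep(NA_integer_, n_ln),
                 is_mln = rep(FALSE, n_ln),
                 pn2ln, ln2pn, ln2ln, g, seed, large = TRUE,
                 n_glomeruli = 0L, pn_per_glom = 0L, uln_per_glom = 0L,
                 n_multipolar = 0L)
}

new_al_network <- function(n_pn, n_ln, glom_pn, glom_ln, is_mln,
                           pn2ln, ln2pn, ln2ln, g, seed, large, ...) {
  # the printed maximal conductances are per-target totals for a synapse
  # class (source-model convention): each edge carries g_max divided by the
  # postsynaptic neuron's afferent count in that class
  per_edge_g <- function(e, g_class) {
    n_aff <- tabulate(e$post, nbins = max(e$post, 1))
    g_class / n_aff[e$post]
  }
  mk_plastic <- function(e, g_class) {
    n <- length(e$pre)
    list(pre = as.integer(e$pre), post = as.integer(e$post),
         g = per_edge_g(e, g_class), F = rep(1, n), t_last = rep(0, n))
  }
  structure(list(
    n_pn = as.integer(n_pn), n_ln = as.integer(n_ln),
    glom_of_pn = glom_pn, glom_of_ln = glom_ln, is_multipolar = is_mln,
    edges = list(
      pn2ln = list(pre = as.integer(pn2ln$pre), post = as.integer(pn2ln$post),
                   g = per_edge_g(pn2ln, g$ach)),
      ln2pn = mk_plastic(ln2pn, g$gaba_ln2pn),
      ln2ln = mk_plastic(ln2ln, g$gaba_ln2ln)
    ),
    g = g, tau_F = 30000, clock_ms = 0, frozen = FALSE,
    training_active = FALSE, seed = as.integer(seed), large = large,
    dims = list(...)
  ), class = "al_network")
}

#' @export
print.al_network <- function(x, ...) {
  cat(sprintf("Antennal-lobe network: %d PNs, %d LNs%s\n", x$n_pn, x$n_ln,
              if (x$large) " (scaled-up variant)" else
                sprintf(" (%d glomeruli, %d multipolar LNs)",
                        x$dims$n_glomeruli, x$dims$n_multipolar)))
  cat(sprintf("  edges: PN->LN %d, LN->PN %d (fast+slow), LN->LN %d\n",
              length(x$edges$pn2ln$pre), length(x$edges$ln2pn$pre),
              length(x$edges$ln2ln$pre)))
  cat(sprintf("  facilitation: mean F(LN->PN) = %.3f, mean F(LN->LN) = %.3f%s\n",
              mean(x$edges$ln2pn$F), mean(x$edges$ln2ln$F),
              if (x$frozen) " [frozen]" else ""))
  invisible(x)
}

#' @export
summary.al_network <- function(object, ...) {
  wt <- weight_table(object)
  out <- list(
    n_pn = object$n_pn, n_ln = object$n_ln,
    edge_counts = vapply(object$edges, function(e) length(e$pre), 0L),
    mean_F = tapply(wt$F, wt$class, mean),
    frozen = object$frozen
  )
  class(out) <- "summary.al_network"
  out
}

#' @export
print.summary.al_network <- function(x, ...) {
  cat(sprintf("AL network: %d PNs + %d LNs; edges:", x$n_pn, x$n_ln), "\n")
  print(x$edge_counts)
  cat("mean facilitation by class:\n")
  print(round(x$mean_F, 4))
  invisible(x)
}

#' Export a topology as an edge-list table
#'
#' Writes one row per directed synapse with columns `class`, `pre`, `post`,
#' `g_max`, `F`. Round-trips losslessly with [read_topology()] given the
#' network dimensions.
#'
#' @param net an `al_network`.
#' @param path CSV file path; if `NULL`, the data.frame is returned only.
#' @return The edge-list data.frame, invisibly when written to file.
#' @export
write_topology <- function(net, path = NULL) {
  e <- net$edges
  df <- rbind(
    data.frame(class = "pn2ln", pre = e$pn2ln$pre, post = e$pn2ln$post,
               g_max = e$pn2ln$g, F = 1),
    data.frame(class = "ln2pn", pre = e$ln2pn$pre, post = e$ln2pn$post,
               g_max = e$ln2pn$g, F = e$ln2pn$F),
    data.frame(class = "ln2ln", pre = e$ln2ln$pre, post = e$ln2ln$post,
               g_max = e$ln2ln$g, F = e$ln2ln$F)
  )
  if (is.null(path)) return(df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Import a topology edge list into an existing network skeleton
#'
#' Replaces the edges (and facilitation multipliers) of `net` with those in
#' the CSV written by [write_topology()].
#'
#' @param net an `al_network` providing dimensions and conductances.
#' @param path CSV file path.
#' @return The network with replaced edges.
#' @export
read_topology <- function(net, path) {
  df <- read.csv(path)
  for (cls in c("pn2ln", "ln2pn", "ln2ln")) {
    d <- df[df$class == cls, ]
    net$edges[[cls]]$pre <- as.integer(d$pre)
    net$edges[[cls]]$post <- as.integer(d$post)
    net$edges[[cls]]$g <- d$g_max
    if (cls != "pn2ln") {
      net$edges[[cls]]$F <- d$F
      net$edges[[cls]]$t_last <- rep(net$clock_ms, nrow(d))
    }
  }
  net
}
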