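# Fixture builders and independent oracles shared across tests.

# small labelled expression profile: genes x (groups defined by `phases`,
# a named vector sample -> phase); values from a supplied matrix
profile_from <- function(values, phases, id = "p1") {
  expression_profile(id, values, phases)
}

# random two-phase profile: `n_genes` genes, `n` samples per phase, genes in
# `shifted` get +delta in the second phase
two_phase_profile <- function(n_genes, n = 5, delta = 0, shifted = integer(),
                              phases = c("early", "middle"), sd = 1,
                              id = "p1") {
  genes <- sprintf("gene%03d", seq_len(n_genes))
  snames <- sprintf("s%02d", seq_len(2 * n))
  ph <- stats::setNames(rep(phases, each = n), snames)
  m <- matrix(stats::rnorm(n_genes * 2 * n, mean = 6, sd = sd),
              nrow = n_genes, dimnames = list(genes, snames))
  m[shifted, ph == phases[2]] <- m[shifted, ph == phases[2]] + delta
  expression_profile(id, m, ph)
}

# a connected Erdos-Renyi-style network on n nodes (caller seeds the RNG)
random_connected_net <- function(n, p = 0.3) {
  repeat {
    em <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(em)) < p
    if (sum(keep) < n - 1) next
    net <- interaction_network(sprintf("n%02d", seq_len(n)),
                               matrix(sprintf("n%02d", em[keep, , drop = FALSE]),
                                      ncol = 2))
    g <- phasenet:::as_igraph(net)
    if (igraph::components(g)$no == 1) return(net)
  }
}

# exhaustive-enumeration oracle: best (calibrated) aggregate score over all
# connected subsets; independent of the greedy search path
enum_connected_best <- function(net, z, calibrated = TRUE) {
  adj <- phasenet:::adjacency_list(net)
  nodes <- net$nodes
  n <- length(nodes)
  kmax <- if (calibrated) n - 1 else n
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > kmax) next
    gs <- nodes[idx]
    if (!phasenet:::is_connected_set(adj, gs)) next
    raw <- sum(z[gs]) / sqrt(length(gs))
    sc <- if (calibrated) {
      nm <- null_moments(z, length(gs))
      (raw - nm[["mean"]]) / nm[["sd"]]
    } else raw
    if (sc > best) best <- sc
  }
  best
}

# brute-force hypergeometric upper tail: enumerate every size-n subset of a
# universe with M marked elements and count overlaps >= x
hyper_tail_enum <- function(N, M, n, x) {
  if (x == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= M) >= x)
}

# concordance-count AUC oracle: fraction of case/control pairs with the
# case scored higher, ties counted one half
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "case"]
  neg <- scores[labels == "control"]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
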