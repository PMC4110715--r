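#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= x)` for the number of known genes in a uniform random draw of
#' `n` genes from a universe of `N` genes of which `M` are known:
#' `1 - sum_{k=0}^{x-1} C(M,k) C(N-M,n-k) / C(N,n)`, evaluated exactly via
#' the hypergeometric distribution function (log-space internally, no
#' normal approximation).
#'
#' @param N universe size.
#' @param M known genes in the universe (`M <= N`).
#' @param n drawn set size (`n <= N`).
#' @param x observed overlap (`0 <= x <= min(M, n)`).
#' @return The tail probability in (0, 1].
#' @examples
#' hypergeom_tail(10, 4, 3, 2)   # 1/3
#' @export
hypergeom_tail <- function(N, M, n, x) {
  stopifnot(length(N) == 1L, length(M) == 1L, length(n) == 1L, length(x) == 1L)
  if (M > N) stop("constraint violated: M <= N")
  if (n > N) stop("constraint violated: n <= N")
  if (x < 0) stop("constraint violated: x >= 0")
  if (x > min(M, n)) stop("constraint violated: x <= min(M, n)")
  if (x == 0) return(1)
  stats::phyper(x - 1, m = M, n = N - M, k = n, lower.tail = FALSE)
}

#' Monte-Carlo random-sampling enrichment p-value
#'
#' Draws `reps` uniform size-`n` subsets of the universe and reports the
#' probability that a draw contains at least `observed` known genes, using
#' the add-one estimator `(b + 1) / (reps + 1)` so a p-value of exactly 0
#' is never reported.
#'
#' @param universe character vector of genes (or an integer universe size,
#'   in which case `known` must be an integer count).
#' @param known character vector of known genes, a subset of `universe`
#'   (or an integer count).
#' @param candidate_size size `n` of each random draw.
#' @param observed observed overlap `x`.
#' @param reps number of random draws; default `1e6`.
#' @param seed integer seed.
#' @return The Monte-Carlo p-value in (0, 1].
#' @export
mc_enrichment <- function(universe, known, candidate_size, observed,
                          reps = 1e6, seed = 1) {
  if (is.numeric(universe) && length(universe) == 1L) {
    N <- as.integer(universe)
    stopifnot(is.numeric(known), length(known) == 1L, known <= N)
    mask <- c(rep(TRUE, as.integer(known)), rep(FALSE, N - as.integer(known)))
  } else {
    universe <- unique(as.character(universe))
    known <- unique(as.character(known))
    off <- setdiff(known, universe)
    if (length(off) > 0L)
      stop("known genes outside the universe: ", paste(off, collapse = ", "))
    N <- length(universe)
    mask <- universe %in% known
  }
  n <- as.integer(candidate_size)
  x <- as.integer(observed)
  stopifnot(n >= 0, n <= N, reps >= 1, x >= 0)
  if (x == 0) return(1)
  b <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(reps)) {
      if (sum(mask[sample.int(N, n)]) >= x) hits <- hits + 1L
    }
    hits
  })
  (b + 1) / (reps + 1)
}

#' Enrichment of a candidate gene set in a known-gene list
#'
#' Convenience wrapper computing the observed counts, the exact
#' hypergeometric tail and (optionally) the Monte-Carlo random-sampling
#' p-value for one candidate set against one known-gene list, both
#' restricted to a gene universe (by default the interaction network's
#' node set, from which the random samples are drawn).
#'
#' @param candidates character vector of candidate genes.
#' @param known character vector of known genes.
#' @param universe character vector of universe genes; candidates and known
#'   genes outside it are ignored.
#' @param reps Monte-Carlo draws (0 to skip the sampling p-value).
#' @param seed integer seed.
#' @return Object of class `enrichment_result` with fields `N`, `M`, `n`,
#'   `x`, `p_hyper`, `p_mc`, `reps`, `seed`.
#' @export
enrich_test <- function(candidates, known, universe, reps = 1e6, seed = 1) {
  universe <- unique(as.character(universe))
  cand <- intersect(unique(as.character(candidates)), universe)
  kn <- intersect(unique(as.character(known)), universe)
  N <- length(universe); M <- length(kn); n <- length(cand)
  x <- length(intersect(cand, kn))
  p_mc <- if (reps > 0)
    mc_enrichment(universe, kn, n, x, reps = reps, seed = seed) else NA_real_
  structure(list(N = N, M = M, n = n, x = x,
                 p_hyper = hypergeom_tail(N, M, n, x),
                 p_mc = p_mc, reps = reps, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: x = %d of n = %d candidates in M = %d known (universe N = %d)\n",
              x$x, x$n, x$M, x$N))
  cat(sprintf("  hypergeometric P(X >= x) = %.3g", x$p_hyper))
  if (!is.na(x$p_mc))
    cat(sprintf("; Monte-Carlo p = %.3g (%g draws)", x$p_mc, x$reps))
  cat("\n")
  invisible(x)
}

#' Annotate candidate genes with known-list, hub and self-loop flags
#'
#' Per candidate gene: membership in each known-gene list, hub status
#' (network degree at least `hub_threshold`) and recorded
#' self-interaction. Candidates absent from the network are flagged and
#' excluded from hub/self-loop statistics. The `"summary"` attribute gives,
#' per known list, the overlap count, the hub fraction among overlapping
#' genes, and the number of self-interacting overlapping genes.
#'
#' @param candidates character vector of candidate genes.
#' @param known_lists named list of character vectors.
#' @param net an [interaction_network()].
#' @param hub_threshold minimum degree for hub status; default 10.
#' @return data.frame with one row per candidate and attribute `summary`.
#' @export
annotate_candidates <- function(candidates, known_lists, net,
                                hub_threshold = 10) {
  candidates <- sort(unique(as.character(candidates)))
  in_net <- candidates %in% net$nodes
  hub_set <- hubs(net, hub_threshold)
  tab <- data.frame(gene = candidates, in_network = in_net,
                    hub = in_net & candidates %in% hub_set,
                    self_loop = in_net & candidates %in% net$self_loops,
                    stringsAsFactors = FALSE)
  summ <- data.frame(list_name = character(), overlap = integer(),
                     hub_fraction = numeric(), self_loops = integer(),
                     stringsAsFactors = FALSE)
  for (nm in names(known_lists)) {
    flag <- candidates %in% known_lists[[nm]]
    tab[[paste0("in_", nm)]] <- flag
    ov <- flag & in_net
    summ <- rbind(summ, data.frame(
      list_name = nm, overlap = sum(flag),
      hub_fraction = if (any(ov)) mean(tab$hub[ov]) else NA_real_,
      self_loops = sum(tab$self_loop[ov]), stringsAsFactors = FALSE))
  }
  attr(tab, "summary") <- summ
  tab
}
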