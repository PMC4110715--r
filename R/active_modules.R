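#' Aggregate z-score of a gene set
#'
#' The module scoring statistic: the sum of member-gene z-scores divided by
#' the square root of the member count. Under independent standard-normal
#' node scores this keeps the null distribution of the score independent of
#' module size.
#'
#' @param scores named numeric vector of node z-scores (see [node_scores()]).
#' @param genes non-empty character vector of member genes, all scored.
#' @return The aggregate score `sum(z) / sqrt(k)`.
#' @export
score_subnetwork <- function(scores, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("cannot score an empty gene set")
  unknown <- setdiff(genes, names(scores))
  if (length(unknown) > 0L)
    stop("unscored gene(s): ", paste(unknown, collapse = ", "))
  sum(scores[genes]) / sqrt(length(genes))
}

#' Monte-Carlo background calibration of the aggregate score
#'
#' Estimates the null mean and standard deviation of [score_subnetwork()]
#' over uniformly random gene sets of size `k` drawn from the scored genes
#' (connectivity is not required under the null). A module's calibrated
#' score is `(z_agg - mean_k) / sd_k`.
#'
#' @inheritParams score_subnetwork
#' @param k gene-set size, between 1 and the number of scored genes.
#' @param reps number of random draws (>= 2).
#' @param seed integer seed for the draws.
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @export
calibrate_scores <- function(scores, k, reps = 1000, seed = 1) {
  n <- length(scores)
  stopifnot(k >= 1, k <= n, reps >= 2)
  z <- unname(scores)
  draws <- with_seed(seed, vapply(seq_len(reps), function(i)
    sum(z[sample.int(n, k)]), numeric(1))) / sqrt(k)
  m <- mean(draws)
  s <- stats::sd(draws)
  if (!is.finite(s) || s == 0)
    stop("degenerate null score distribution (sd = 0) at module size ", k)
  c(mean = m, sd = s)
}

#' Exact null moments of the aggregate score
#'
#' Closed-form mean and standard deviation of [score_subnetwork()] over
#' uniformly random size-`k` gene sets (sampling without replacement from
#' the scored genes): the limit [calibrate_scores()] estimates by
#' Monte-Carlo. `mean_k = sqrt(k) * mean(z)` and
#' `sd_k = sd_pop(z) * sqrt((N - k) / (N - 1))` with the population
#' standard deviation. Used for search decisions, where Monte-Carlo noise
#' in adjacent-size comparisons would otherwise destabilize the greedy
#' improvement test.
#'
#' @inheritParams calibrate_scores
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @export
null_moments <- function(scores, k) {
  n <- length(scores)
  stopifnot(k >= 1, k <= n)
  mu <- mean(scores)
  s2 <- sum((scores - mu)^2) / n         # population variance
  s <- sqrt(s2 * (n - k) / (n - 1))
  if (!is.finite(s) || s == 0)
    stop("degenerate null score distribution (sd = 0) at module size ", k)
  c(mean = sqrt(k) * mu, sd = s)
}

# memoized per-k calibration table; exact closed-form moments by default,
# Monte-Carlo estimates if mc = TRUE
calibration_env <- function(scores, reps, seed, mc = FALSE) {
  env <- new.env(parent = emptyenv())
  function(k) {
    key <- as.character(k)
    if (is.null(env[[key]]))
      env[[key]] <- if (mc)
        calibrate_scores(scores, k, reps = reps, seed = derive_seed(seed, k))
      else null_moments(scores, k)
    env[[key]]
  }
}

#' Greedy search for active subnetworks
#'
#' Seeded greedy search for connected subnetworks with high aggregate
#' z-score, in the style of active-module searches on interaction networks.
#' Seeds are the `n_seeds` highest-z genes (ties broken lexicographically).
#' From each seed the module repeatedly absorbs the neighboring gene that
#' maximally increases the (calibrated) score; it then undergoes
#' `iterations` refinement passes in which each non-seed member whose
#' removal keeps the module connected and increases the score is dropped,
#' and neighbors are re-tested for addition. Identical gene sets are
#' collapsed, modules are ranked by calibrated score, and the `top` ranks
#' are returned.
#'
#' @param net an [interaction_network()].
#' @param scores named numeric node z-scores covering `net$nodes`
#'   (see [node_scores()]).
#' @param n_seeds number of seed genes (default 10).
#' @param iterations number of add/remove refinement passes (default 3).
#' @param top number of ranked modules to return (default 10).
#' @param max_depth search depth for additions (default 2): a candidate
#'   addition is any non-member within `max_depth` hops of the module,
#'   added together with the non-member genes on a shortest connecting
#'   path, and the improvement test scores the whole addition. Depth 1
#'   restricts growth to immediate neighbors; depth 2 lets the search
#'   absorb a strong gene behind one weak connector, which a purely
#'   one-step greedy cannot reach.
#' @param max_size optional cap on module size (default unbounded).
#' @param calibrated use the calibrated score (default); if `FALSE`, rank
#'   by the raw aggregate score.
#' @param calib_mc estimate the calibration by Monte-Carlo
#'   ([calibrate_scores()]) instead of the exact null moments
#'   ([null_moments()], default). The exact moments are the Monte-Carlo
#'   limit; estimating them per size would inject independent sampling
#'   noise into adjacent-size score comparisons and make the improvement
#'   test unstable.
#' @param reps random draws per module size for Monte-Carlo calibration.
#' @param seed integer seed (calibration draws).
#' @param seed_genes optional explicit seed genes overriding the top-z rule.
#' @return List of class `active_module_list`; each element has `genes`
#'   (sorted), `z_agg`, `score_cal`, `rank` and `seed_gene`. The `measured`
#'   attribute of `scores`, if any, is propagated.
#' @export
greedy_search <- function(net, scores, n_seeds = 10, iterations = 3, top = 10,
                          max_depth = 2, max_size = Inf, calibrated = TRUE,
                          calib_mc = FALSE, reps = 1000, seed = 1,
                          seed_genes = NULL) {
  stopifnot(inherits(net, "interaction_network"),
            n_seeds >= 1, iterations >= 0, top >= 1, max_depth >= 1)
  if (length(net$nodes) == 0L) stop("empty network")
  measured <- attr(scores, "measured")
  miss <- setdiff(net$nodes, names(scores))
  if (length(miss) > 0L) {
    scores[miss] <- 0
  }
  scores <- scores[net$nodes]            # nodes are sorted: index order is lexicographic
  attr(scores, "measured") <- measured
  adj <- adjacency_list(net)
  calib <- if (calibrated) calibration_env(scores, reps, seed, mc = calib_mc)
           else NULL
  # a module spanning every scored gene has no calibration null; cap below N
  if (calibrated) max_size <- min(max_size, length(net$nodes) - 1L)
  score_of <- function(genes) {
    raw <- sum(scores[genes]) / sqrt(length(genes))
    if (!calibrated) return(raw)
    cs <- calib(length(genes))
    (raw - cs[["mean"]]) / cs[["sd"]]
  }

  if (is.null(seed_genes)) {
    pos <- names(scores)[scores > 0]
    if (length(pos) == 0L) {
      warning("no gene with positive z-score; no modules found")
      return(structure(list(), class = "active_module_list",
                       measured = attr(scores, "measured")))
    }
    ord <- pos[order(-scores[pos], pos)]
    seed_genes <- utils::head(ord, n_seeds)
  } else {
    unknown <- setdiff(seed_genes, net$nodes)
    if (length(unknown) > 0L)
      stop("seed gene(s) not in network: ", paste(unknown, collapse = ", "))
  }

  nodes <- net$nodes
  nn <- length(nodes)
  adj_idx <- lapply(adj, function(v) match(v, nodes))

  # all non-member genes within `max_depth` hops, each with the non-member
  # genes of a shortest path back to the module (BFS tree, lexicographic
  # traversal order so paths are deterministic)
  reachable_paths <- function(genes) {
    gidx <- match(genes, nodes)
    inside <- logical(nn)
    inside[gidx] <- TRUE
    paths <- vector("list", nn)
    frontier <- sort(gidx)
    hit <- integer(0)
    for (d in seq_len(max_depth)) {
      newly <- integer(0)
      for (v in frontier) for (u in adj_idx[[v]]) {
        if (inside[u]) next
        inside[u] <- TRUE
        paths[[u]] <- c(paths[[v]], u)
        newly <- c(newly, u)
      }
      if (length(newly) == 0L) break
      frontier <- sort(newly)
      hit <- c(hit, frontier)
    }
    hit <- sort(hit)
    stats::setNames(lapply(paths[hit], function(p) nodes[p]), nodes[hit])
  }

  # vectorized scores of `genes` extended by each candidate path;
  # incremental sums, calibration grouped by resulting size
  cand_scores <- function(genes, cand) {
    sumz <- sum(scores[genes])
    psum <- vapply(cand, function(p) sum(scores[p]), numeric(1))
    klen <- lengths(cand)
    raw <- (sumz + psum) / sqrt(length(genes) + klen)
    if (!calibrated) return(raw)
    out <- raw
    for (kk in unique(klen)) {
      cs <- calib(length(genes) + kk)
      i <- klen == kk
      out[i] <- (raw[i] - cs[["mean"]]) / cs[["sd"]]
    }
    out
  }

  # at a stall, tentatively take each of the best few non-improving
  # additions and keep one only if a follow-up addition beats the pre-dip
  # score: a bounded two-ply lookahead that crosses single score dips no
  # one-step improvement can
  lookahead <- function(genes, cur, cand, sc) {
    ord <- order(-sc, names(cand))
    for (j in utils::head(ord, 5L)) {
      tent <- c(genes, cand[[j]])
      if (length(tent) >= max_size) next
      c2 <- reachable_paths(tent)
      c2 <- c2[lengths(c2) <= max_size - length(tent)]
      if (length(c2) == 0L) next
      s2 <- cand_scores(tent, c2)
      b2 <- which.max(s2)
      if (s2[b2] > cur + 1e-12) return(c(tent, c2[[b2]]))
    }
    NULL
  }

  grow <- function(genes) {
    repeat {
      cur <- score_of(genes)
      if (length(genes) >= max_size) break
      cand <- reachable_paths(genes)
      cand <- cand[lengths(cand) <= max_size - length(genes)]
      if (length(cand) == 0L) break
      sc <- cand_scores(genes, cand)
      best <- which.max(sc)              # first max = lexicographically smallest
      if (sc[best] > cur + 1e-12) {
        genes <- c(genes, cand[[best]])
      } else {
        step <- lookahead(genes, cur, cand, sc)
        if (is.null(step)) break
        genes <- step
      }
    }
    list(genes = genes, score = score_of(genes))
  }

  # backward elimination: shrink a starting set by repeatedly removing the
  # member (articulation points excluded, so connectivity is preserved)
  # whose removal maximally increases the score, while removal improves.
  # Complements forward growth: it can reach high-scoring large modules
  # separated from any seed by score dips.
  shrink <- function(genes) {
    repeat {
      k <- length(genes)
      if (k <= 1L) break
      sub <- igraph::induced_subgraph(graph, genes)
      artic <- names(igraph::articulation_points(sub))
      removable <- setdiff(genes, artic)
      forced <- k > max_size
      if (length(removable) == 0L) {
        if (forced) return(NULL)         # cannot legally shrink further
        break
      }
      raw <- (sum(scores[genes]) - scores[removable]) / sqrt(k - 1)
      sc <- if (calibrated) {
        cs <- calib(k - 1L)
        (raw - cs[["mean"]]) / cs[["sd"]]
      } else raw
      best <- order(-sc, removable)[1L]
      if (!forced && sc[best] <= score_of(genes) + 1e-12) break
      genes <- setdiff(genes, removable[best])
    }
    genes
  }

  graph <- as_igraph(net)
  comp <- igraph::components(graph)
  starts <- lapply(seed_genes, function(sg) list(seed = sg, init = sg))
  for (ci in unique(comp$membership[seed_genes])) {
    genes <- shrink(net$nodes[comp$membership == ci])
    if (!is.null(genes) && length(genes) > 0L)
      starts[[length(starts) + 1L]] <-
        list(seed = genes[order(-scores[genes], genes)][1L], init = genes)
  }

  modules <- lapply(starts, function(start) {
    sg <- start$seed
    st <- grow(start$init)
    for (pass in seq_len(iterations)) {
      changed <- FALSE
      for (v in sort(setdiff(st$genes, sg))) {
        if (length(st$genes) <= 1L) break
        rest <- setdiff(st$genes, v)
        if (!is_connected_set(adj, rest)) next
        sc <- score_of(rest)
        if (sc > st$score + 1e-12) {
          st$genes <- rest
          st$score <- sc
          changed <- TRUE
        }
      }
      st2 <- grow(st$genes)
      if (length(st2$genes) != length(st$genes)) changed <- TRUE
      st <- st2
      if (!changed) break
    }
    list(genes = sort(st$genes), z_agg = sum(scores[st$genes]) / sqrt(length(st$genes)),
         score_cal = st$score, seed_gene = sg)
  })

  keys <- vapply(modules, function(m) paste(m$genes, collapse = "\r"), character(1))
  modules <- modules[!duplicated(keys)]
  ord <- order(-vapply(modules, `[[`, numeric(1), "score_cal"),
               vapply(modules, function(m) paste(m$genes, collapse = "\r"),
                      character(1)))
  modules <- utils::head(modules[ord], top)
  for (i in seq_along(modules)) {
    modules[[i]]$rank <- i
    class(modules[[i]]) <- "scored_subnetwork"
  }
  structure(modules, class = "active_module_list",
            measured = attr(scores, "measured"))
}

#' @export
print.scored_subnetwork <- function(x, ...) {
  cat(sprintf("Active module (rank %s): %d genes, z_agg = %.3f, calibrated = %.3f\n",
              if (is.null(x$rank)) "-" else x$rank, length(x$genes),
              x$z_agg, x$score_cal))
  cat("  ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.active_module_list <- function(x, ...) {
  cat(sprintf("%d active module(s)\n", length(x)))
  for (m in x)
    cat(sprintf("  rank %d: k = %d, z_agg = %.3f, calibrated = %.3f\n",
                m$rank, length(m$genes), m$z_agg, m$score_cal))
  invisible(x)
}

#' Merge top-ranked modules into a core subnetwork
#'
#' The per-profile, per-contrast core subnetwork is the union of the
#' top-ranked active modules' gene sets with the network-induced edges;
#' the ranks contributing each gene are retained as provenance.
#'
#' @param modules an `active_module_list` from [greedy_search()].
#' @param net the parent [interaction_network()].
#' @param profile_id,contrast optional provenance labels.
#' @return Object of class `core_subnetwork`: `genes`, `edges`,
#'   `provenance` (data.frame gene/ranks), `measured`, `profile_id`,
#'   `contrast`. An empty module list yields an empty core with a warning.
#' @export
merge_top <- function(modules, net, profile_id = NA_character_,
                      contrast = NA_character_) {
  if (length(modules) == 0L) {
    warning("no modules to merge; returning empty core subnetwork")
    genes <- character()
    prov <- data.frame(gene = character(), ranks = character(),
                       stringsAsFactors = FALSE)
  } else {
    genes <- sort(unique(unlist(lapply(modules, `[[`, "genes"))))
    rk <- lapply(genes, function(g)
      paste(vapply(Filter(function(m) g %in% m$genes, modules), `[[`,
                   numeric(1), "rank"), collapse = ","))
    prov <- data.frame(gene = genes, ranks = unlist(rk),
                       stringsAsFactors = FALSE)
  }
  structure(list(profile_id = profile_id, contrast = contrast, genes = genes,
                 edges = induced_edges(net, genes), provenance = prov,
                 measured = attr(modules, "measured")),
            class = "core_subnetwork")
}

#' @export
print.core_subnetwork <- function(x, ...) {
  cat(sprintf("Core subnetwork [%s / %s]: %d genes, %d interactions\n",
              x$profile_id, x$contrast, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Write an active-module table
#'
#' One row per module: rank, calibrated score, aggregate z, size and the
#' comma-separated member genes.
#'
#' @inheritParams merge_top
#' @param path output TSV path.
#' @export
write_modules <- function(modules, path) {
  d <- data.frame(rank = vapply(modules, `[[`, numeric(1), "rank"),
                  score_cal = vapply(modules, `[[`, numeric(1), "score_cal"),
                  z_agg = vapply(modules, `[[`, numeric(1), "z_agg"),
                  size = vapply(modules, function(m) length(m$genes), integer(1)),
                  genes = vapply(modules, function(m)
                    paste(m$genes, collapse = ","), character(1)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
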