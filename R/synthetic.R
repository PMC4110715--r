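#' Generate a synthetic interaction network
#'
#' Produces an undirected simple network at a chosen scale with a
#' heavy-tailed degree distribution, exact node and edge counts, a
#' near-spanning largest component (at least 95% of nodes, otherwise the
#' network is regenerated from a derived seed) and a requested fraction of
#' self-interacting genes. Two generators are available:
#' `"duplication-divergence"` grows the graph by duplicating a random
#' existing node, retaining each of its interactions independently and
#' always linking the copy to its template (a standard model of how
#' protein interactomes acquire their skewed degrees), then adjusts to the
#' exact edge count by degree-biased additions / random deletions;
#' `"configuration"` samples a fixed number of edges with probability
#' proportional to the product of heavy-tailed node fitness values.
#' When `n_edges == n_nodes - 1` a uniform random tree is built instead,
#' guaranteeing connectivity.
#'
#' @param n_nodes,n_edges requested counts; `n_edges` must lie between
#'   `n_nodes - 1` and `choose(n_nodes, 2)`.
#' @param model `"duplication-divergence"` (default) or `"configuration"`.
#' @param self_loop_rate fraction of genes flagged self-interacting.
#' @param seed integer seed.
#' @return An [interaction_network()] with exactly the requested counts.
#' @export
generate_network <- function(n_nodes, n_edges,
                             model = c("duplication-divergence", "configuration"),
                             self_loop_rate = 0.03, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 2, self_loop_rate >= 0, self_loop_rate <= 1)
  if (n_edges < n_nodes - 1 || n_edges > choose(n_nodes, 2))
    stop("infeasible edge count: need n_nodes - 1 <= n_edges <= choose(n_nodes, 2)")
  nodes <- sprintf("g%04d", seq_len(n_nodes))
  for (attempt in 1:30) {
    em <- with_seed(derive_seed(seed, attempt), {
      if (n_edges == n_nodes - 1) random_tree_edges(n_nodes)
      else if (model == "duplication-divergence") dd_edges(n_nodes, n_edges)
      else fitness_edges(n_nodes, n_edges)
    })
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
    comp <- igraph::components(g)
    if (max(comp$csize) >= 0.95 * n_nodes) {
      loops <- with_seed(derive_seed(seed, "selfloops"),
                         sample(nodes, round(self_loop_rate * n_nodes)))
      return(interaction_network(nodes,
                                 matrix(nodes[em], ncol = 2),
                                 self_loops = loops))
    }
  }
  stop("could not generate a network whose largest component spans 95% of nodes")
}

random_tree_edges <- function(n) {
  cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L), integer(1)))
}

dd_edges <- function(n, m) {
  adj <- vector("list", n)
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  add_edge(1L, 2L)
  if (n >= 3L) add_edge(1L, 3L)
  for (v in seq_len(n)[-(1:3)]) {
    parent <- sample.int(v - 1L, 1L)
    kept <- adj[[parent]][stats::runif(length(adj[[parent]])) < 0.4]
    for (u in unique(c(parent, kept))) add_edge(v, u)
  }
  em <- do.call(rbind, lapply(seq_len(n), function(v) {
    up <- adj[[v]][adj[[v]] > v]
    if (length(up) == 0L) return(NULL)
    cbind(v, up, deparse.level = 0)
  }))
  key <- em[, 1L] * (n + 1) + em[, 2L]
  em <- em[!duplicated(key), , drop = FALSE]
  # trim or top up (degree-biased) to the exact edge count
  if (nrow(em) > m) {
    em <- em[sample.int(nrow(em), m), , drop = FALSE]
  } else if (nrow(em) < m) {
    have <- new.env(parent = emptyenv())
    for (k in em[, 1L] * (n + 1) + em[, 2L]) assign(as.character(k), TRUE, have)
    deg <- tabulate(c(em), nbins = n) + 1
    extra <- matrix(0L, m - nrow(em), 2L)
    got <- 0L
    while (got < nrow(extra)) {
      a <- sample.int(n, 1L, prob = deg)
      b <- sample.int(n, 1L, prob = deg)
      if (a == b) next
      lo <- min(a, b); hi <- max(a, b)
      k <- as.character(lo * (n + 1) + hi)
      if (!is.null(have[[k]])) next
      assign(k, TRUE, have)
      got <- got + 1L
      extra[got, ] <- c(lo, hi)
    }
    em <- rbind(em, extra)
  }
  em
}

fitness_edges <- function(n, m) {
  g <- igraph::sample_fitness(m, fitness.out = (seq_len(n) + 5)^-0.8,
                              loops = FALSE, multiple = FALSE)
  igraph::as_edgelist(g, names = FALSE)
}

#' Plant connected modules with a shared core
#'
#' Grows a connected core gene set by randomized breadth-first expansion
#' inside the network's largest component, then extends it into one
#' connected module per phase contrast. The core is contained in all three
#' modules, emulating genes perturbed across the whole disease course; the
#' module remainders emulate contrast-specific signal.
#'
#' @param net an [interaction_network()].
#' @param sizes integer vector of three module sizes (named or in contrast
#'   order early-middle, middle-late, early-late).
#' @param core_size size of the shared core (`<= min(sizes)`).
#' @param seed integer seed.
#' @param max_tries attempts before giving up on connectivity/size.
#' @return Object of class `synthetic_truth`: `core` and `modules` (named
#'   list of sorted gene vectors), plus the generation `seed`.
#' @export
plant_modules <- function(net, sizes = c(30, 30, 30), core_size = 12,
                          seed = 1, max_tries = 50) {
  stopifnot(length(sizes) == 3L, core_size >= 1, core_size <= min(sizes))
  adj <- adjacency_list(net)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  giant <- net$nodes[comp$membership == which.max(comp$csize)]
  if (max(sizes) > length(giant))
    stop("module sizes exceed the largest connected component")
  grow <- function(genes, target) {
    while (length(genes) < target) {
      frontier <- setdiff(unique(unlist(adj[genes], use.names = FALSE)), genes)
      if (length(frontier) == 0L) return(NULL)
      genes <- c(genes, sample(frontier, 1L))
    }
    genes
  }
  for (attempt in seq_len(max_tries)) {
    res <- with_seed(derive_seed(seed, attempt), {
      core <- grow(sample(giant, 1L), core_size)
      if (is.null(core)) NULL
      else {
        mods <- lapply(sizes, function(s) grow(core, s))
        if (any(vapply(mods, is.null, logical(1)))) NULL
        else list(core = sort(core), modules = lapply(mods, sort))
      }
    })
    if (!is.null(res)) {
      names(res$modules) <- CONTRASTS
      return(structure(list(core = res$core, modules = res$modules,
                            seed = seed),
                       class = "synthetic_truth"))
    }
  }
  stop("could not plant connected modules of the requested sizes")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Planted truth: core of %d genes; module sizes %s\n",
              length(x$core),
              paste(vapply(x$modules, length, integer(1)), collapse = "/")))
  invisible(x)
}

#' Generate multi-platform expression profiles with planted signal
#'
#' Emulates several array platforms profiling the same disease course:
#' per profile, each gene gets a baseline intensity `mu_g ~ Normal(8, 1)`
#' (log scale) and each sample adds phase shifts plus `Normal(0, sigma^2)`
#' noise. A gene planted in the module of contrast `c` is shifted by
#' `+delta * sigma` in the later phase of `c`; shifts compose additively
#' across contrasts, so genes planted for all contrasts separate early
#' from late most strongly. Each platform measures an independent random
#' fraction `coverage` of the genes but always at least 90% of the planted
#' genes. Control samples are drawn at baseline.
#'
#' @param net an [interaction_network()].
#' @param truth a [plant_modules()] result.
#' @param n_profiles number of platforms.
#' @param samples_per_phase samples in each of early/middle/late/control.
#' @param delta effect size in noise-SD units (>= 0).
#' @param sigma noise standard deviation (> 0).
#' @param coverage fraction of genes measured per platform, in (0, 1].
#' @param seed integer seed.
#' @return List of [expression_profile()] objects.
#' @export
generate_profiles <- function(net, truth, n_profiles = 3,
                              samples_per_phase = 10, delta = 2, sigma = 1,
                              coverage = 0.85, seed = 1) {
  stopifnot(samples_per_phase >= 2, delta >= 0, sigma > 0,
            coverage > 0, coverage <= 1, n_profiles >= 1)
  genes <- net$nodes
  truth_genes <- sort(unique(unlist(truth$modules)))
  shift <- matrix(0, length(genes), 4L,
                  dimnames = list(genes, c(PHASES, "control")))
  shift[truth$modules[["early-middle"]], "middle"] <-
    shift[truth$modules[["early-middle"]], "middle"] + delta * sigma
  shift[truth$modules[["middle-late"]], "late"] <-
    shift[truth$modules[["middle-late"]], "late"] + delta * sigma
  shift[truth$modules[["early-late"]], "late"] <-
    shift[truth$modules[["early-late"]], "late"] + delta * sigma
  lapply(seq_len(n_profiles), function(p) {
    pid <- sprintf("profile%d", p)
    with_seed(derive_seed(seed, pid), {
      measured <- genes[stats::runif(length(genes)) < coverage]
      tg_in <- intersect(truth_genes, measured)
      need <- ceiling(0.9 * length(truth_genes)) - length(tg_in)
      if (need > 0L)
        measured <- sort(c(measured,
                           sample(setdiff(truth_genes, measured), need)))
      mu <- stats::rnorm(length(measured), mean = 8, sd = 1)
      phases <- rep(c(PHASES, "control"), each = samples_per_phase)
      snames <- sprintf("%s_%s_%02d", pid, phases,
                        sequence(rep(samples_per_phase, 4L)))
      vals <- matrix(stats::rnorm(length(measured) * length(phases),
                                  sd = sigma),
                     nrow = length(measured),
                     dimnames = list(measured, snames))
      vals <- vals + mu + shift[measured, phases]
      expression_profile(pid, vals, stats::setNames(phases, snames))
    })
  })
}

#' Case/control data from a generated profile
#'
#' Restructures one profile's samples into a labelled case/control set for
#' classifier validation: samples of `case_phase` are cases, `control`
#' samples are controls.
#'
#' @param profile an [expression_profile()].
#' @param case_phase disease phase to use as the case class (default
#'   `"late"`).
#' @return List with `expr` (genes x samples matrix) and `labels`
#'   (`"case"`/`"control"` per sample).
#' @export
case_control_data <- function(profile, case_phase = "late") {
  case_phase <- match.arg(case_phase, PHASES)
  keep <- profile$sample_phases %in% c(case_phase, "control")
  expr <- profile$values[, keep, drop = FALSE]
  labels <- ifelse(profile$sample_phases[keep] == case_phase, "case", "control")
  list(expr = expr, labels = unname(labels))
}

#' Known-gene list with controlled core overlap
#'
#' Builds a validation list mixing a configurable fraction of the planted
#' core with random non-core network genes, so the true enrichment of the
#' recovered candidates is tunable.
#'
#' @param truth a [plant_modules()] result.
#' @param net the parent [interaction_network()].
#' @param size list size.
#' @param core_fraction fraction of the list drawn from the planted core.
#' @param seed integer seed.
#' @return Sorted character vector of genes.
#' @export
make_known_list <- function(truth, net, size = 40, core_fraction = 0.5,
                            seed = 1) {
  stopifnot(size >= 1, core_fraction >= 0, core_fraction <= 1)
  n_core <- min(round(size * core_fraction), length(truth$core))
  with_seed(derive_seed(seed, "known"), {
    sort(c(sample(truth$core, n_core),
           sample(setdiff(net$nodes, truth$core), size - n_core)))
  })
}

#' Recovery of the planted core by a candidate set
#'
#' @param truth a [plant_modules()] result.
#' @param candidates character vector (e.g. the `common` element of
#'   [unique_and_common()]).
#' @return Named numeric vector `c(precision, recall, f1)`; all zero for an
#'   empty candidate set.
#' @export
recovery_metrics <- function(truth, candidates) {
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0L) {
    message("empty candidate set; recovery metrics are 0 by convention")
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  tp <- length(intersect(candidates, truth$core))
  precision <- tp / length(candidates)
  recall <- tp / length(truth$core)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' One-call synthetic study bundle
#'
#' Generates a network, planted truth, multi-platform profiles and a
#' known-gene list under a single master seed — the full synthetic study
#' design used for end-to-end benchmarking. Defaults mirror the scale of a
#' curated disease interactome (edge density about 5.3 edges per node) at
#' desk size.
#'
#' @inheritParams generate_network
#' @inheritParams generate_profiles
#' @inheritParams plant_modules
#' @param known_size,core_fraction see [make_known_list()].
#' @return List with `network`, `truth`, `profiles`, `known_lists` (named
#'   list with one element `"known"`).
#' @export
synthetic_bundle <- function(n_nodes = 300, n_edges = round(5.3 * n_nodes),
                             sizes = c(30, 30, 30), core_size = 12,
                             n_profiles = 3, samples_per_phase = 10,
                             delta = 2, sigma = 1, coverage = 0.85,
                             known_size = 40, core_fraction = 0.5, seed = 1) {
  net <- generate_network(n_nodes, n_edges, seed = derive_seed(seed, "net"))
  truth <- plant_modules(net, sizes = sizes, core_size = core_size,
                         seed = derive_seed(seed, "truth"))
  profiles <- generate_profiles(net, truth, n_profiles = n_profiles,
                                samples_per_phase = samples_per_phase,
                                delta = delta, sigma = sigma,
                                coverage = coverage,
                                seed = derive_seed(seed, "expr"))
  known <- make_known_list(truth, net, size = known_size,
                           core_fraction = core_fraction,
                           seed = derive_seed(seed, "known"))
  list(network = net, truth = truth, profiles = profiles,
       known_lists = list(known = known))
}
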