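#' Overlapping percentage between two gene sets
#'
#' The similarity used to compare core subnetworks across expression
#' profiles: `100 * G / (|A| + |B| - G)` where `G` is the number of shared
#' genes — i.e. the Jaccard index of the two sets as a percentage.
#'
#' @param set_a,set_b character vectors of genes; not both empty.
#' @return Numeric in `[0, 100]`.
#' @export
overlap_percentage <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  g <- length(intersect(a, b))
  denom <- length(a) + length(b) - g
  if (denom == 0L) stop("overlap undefined: both gene sets are empty")
  100 * g / denom
}

#' Pairwise overlap matrix across core subnetworks
#'
#' Diagnostic reported alongside consensus assembly: the overlapping
#' percentage between every pair of profiles' core subnetworks for one
#' contrast.
#'
#' @param cores list of `core_subnetwork` objects.
#' @return Symmetric numeric matrix (percent), `NA` where both cores are
#'   empty.
#' @export
overlap_matrix <- function(cores) {
  ids <- vapply(cores, function(cs) cs$profile_id, character(1))
  m <- matrix(NA_real_, length(cores), length(cores), dimnames = list(ids, ids))
  for (i in seq_along(cores)) for (j in seq_along(cores)) {
    if (length(cores[[i]]$genes) + length(cores[[j]]$genes) > 0L)
      m[i, j] <- overlap_percentage(cores[[i]]$genes, cores[[j]]$genes)
  }
  m
}

#' Consensus genes across profiles' core subnetworks
#'
#' Genes shared by the core subnetworks of (a fraction `tau` of) the
#' profiles for one contrast. With `respect_coverage = TRUE` a profile
#' whose platform never measured a gene is not counted against that gene:
#' membership is required only among the profiles that could have seen it.
#'
#' @param cores list (>= 2) of `core_subnetwork` objects for one contrast.
#' @param tau required membership fraction in (0, 1]; default 1 ("shared by
#'   all").
#' @param respect_coverage see above; requires cores to carry a `measured`
#'   gene vector (absent/`NULL` means full coverage).
#' @return Sorted character vector of consensus genes.
#' @export
consensus_genes <- function(cores, tau = 1, respect_coverage = TRUE) {
  if (length(cores) < 2L) stop("need >= 2 core subnetworks")
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0 || tau > 1)
    stop("tau must be in (0, 1]")
  genes <- sort(unique(unlist(lapply(cores, `[[`, "genes"))))
  if (length(genes) == 0L) return(character())
  in_core <- vapply(cores, function(cs) genes %in% cs$genes,
                    logical(length(genes)))
  in_core <- matrix(in_core, nrow = length(genes))
  eligible <- vapply(cores, function(cs) {
    if (!respect_coverage || is.null(cs$measured)) rep(TRUE, length(genes))
    else genes %in% cs$measured
  }, logical(length(genes)))
  eligible <- matrix(eligible, nrow = length(genes))
  n_eligible <- rowSums(eligible)
  hits <- rowSums(in_core & eligible)
  # a gene no platform measured cannot be a consensus gene
  genes[n_eligible > 0L & hits >= tau * n_eligible]
}

#' Assemble a consensus module
#'
#' Attaches the network-induced interactions to a consensus gene set for
#' one phase contrast.
#'
#' @param genes character vector of consensus genes (subset of network
#'   nodes).
#' @param net the parent [interaction_network()].
#' @param contrast the phase contrast label.
#' @param membership optional data.frame of per-profile membership flags.
#' @return Object of class `consensus_module`: `contrast`, `genes`
#'   (sorted), `edges`, `membership`.
#' @export
build_module <- function(genes, net, contrast, membership = NULL) {
  genes <- sort(unique(as.character(genes)))
  unknown <- setdiff(genes, net$nodes)
  if (length(unknown) > 0L)
    stop("gene(s) not in network: ", paste(unknown, collapse = ", "))
  structure(list(contrast = contrast, genes = genes,
                 edges = induced_edges(net, genes), membership = membership),
            class = "consensus_module")
}

#' @export
print.consensus_module <- function(x, ...) {
  cat(sprintf("Consensus module [%s]: %d genes, %d interactions\n",
              x$contrast, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Unique signatures and common candidate genes
#'
#' From the three phase-contrast consensus modules: a gene unique to one
#' module is a phase-specific signature; a gene present in all three
#' modules is a candidate disease-associated gene. The unique sets and the
#' common set are disjoint by construction.
#'
#' @param modules list of exactly three `consensus_module` objects, one per
#'   phase contrast.
#' @return List with `unique` (named list of sorted character vectors, one
#'   per contrast) and `common` (sorted character vector of class
#'   `candidate_gene_set`).
#' @export
unique_and_common <- function(modules) {
  if (length(modules) != 3L) stop("need exactly three consensus modules")
  contrasts <- vapply(modules, `[[`, character(1), "contrast")
  if (anyDuplicated(contrasts)) stop("duplicate contrasts among modules")
  sets <- lapply(modules, `[[`, "genes")
  names(sets) <- contrasts
  uniq <- lapply(seq_along(sets), function(i)
    sort(setdiff(sets[[i]], unlist(sets[-i]))))
  names(uniq) <- contrasts
  common <- sort(Reduce(intersect, sets))
  list(unique = uniq,
       common = structure(common, class = "candidate_gene_set"))
}

#' @export
print.candidate_gene_set <- function(x, ...) {
  cat(sprintf("%d candidate disease-associated gene(s)\n", length(x)))
  if (length(x) > 0L) cat("  ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}
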