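#' Undirected interaction network
#'
#' Lightweight container for a gene-level protein-protein interaction
#' scaffold: an undirected simple graph plus a set of genes flagged as
#' self-interacting. Self-interactions are kept as gene-level flags and are
#' excluded from adjacency and degree, so connectivity and module scoring
#' operate on a simple graph while the self-interaction summary is preserved.
#'
#' @param nodes character vector of gene identifiers.
#' @param edges two-column character matrix of undirected edges (may have
#'   zero rows); endpoints must be distinct and present in `nodes`.
#' @param self_loops character vector of genes with a recorded
#'   self-interaction; must be a subset of `nodes`.
#' @return An object of class `interaction_network` with elements `nodes`,
#'   `edges` (canonical two-column matrix, endpoints sorted within each row,
#'   rows deduplicated and ordered) and `self_loops`.
#' @export
interaction_network <- function(nodes, edges = matrix(character(), ncol = 2),
                                self_loops = character()) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- canonical_edges(edges)
  self_loops <- sort(unique(as.character(self_loops)))
  if (nrow(edges) > 0L) {
    miss <- setdiff(unique(c(edges)), nodes)
    if (length(miss) > 0L)
      stop("edge endpoints not in node set: ", paste(miss, collapse = ", "))
    if (any(edges[, 1L] == edges[, 2L]))
      stop("edges must join distinct genes; record self-interactions in `self_loops`")
  }
  if (length(setdiff(self_loops, nodes)) > 0L)
    stop("self-loop genes not in node set: ",
         paste(setdiff(self_loops, nodes), collapse = ", "))
  structure(list(nodes = nodes, edges = edges, self_loops = self_loops),
            class = "interaction_network")
}

# canonicalize an edge matrix: character, endpoints sorted within a row,
# duplicate rows collapsed, rows ordered lexicographically
canonical_edges <- function(edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    return(matrix(character(), ncol = 2,
                  dimnames = list(NULL, c("source", "target"))))
  }
  if (ncol(edges) != 2L) stop("edge matrix must have two columns")
  storage.mode(edges) <- "character"
  swap <- edges[, 1L] > edges[, 2L]
  tmp <- edges[swap, 1L]
  edges[swap, 1L] <- edges[swap, 2L]
  edges[swap, 2L] <- tmp
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("source", "target"))
  edges
}

#' Build an interaction network from raw edge records
#'
#' Ingests an edge list as curated from interaction databases: direction is
#' discarded, duplicate pairs (including reversed duplicates) collapse to a
#' single undirected edge, and records whose two endpoints are the same gene
#' are recorded as self-interaction flags rather than edges.
#'
#' @param records data.frame (or two-column matrix) whose first two columns
#'   are the interacting gene identifiers; additional columns (e.g. a
#'   direction flag) are ignored.
#' @return An [interaction_network()].
#' @examples
#' net <- build_network(data.frame(source = c("A", "B", "A", "C"),
#'                                 target = c("B", "A", "A", "D")))
#' net$edges          # one A-B edge, one C-D edge
#' net$self_loops     # "A"
#' @export
build_network <- function(records) {
  records <- as.matrix(as.data.frame(records)[, 1:2])
  storage.mode(records) <- "character"
  if (nrow(records) == 0L) stop("no interaction records supplied")
  bad <- which(is.na(records[, 1L]) | is.na(records[, 2L]) |
                 !nzchar(trimws(records[, 1L])) | !nzchar(trimws(records[, 2L])))
  if (length(bad) > 0L)
    stop("blank gene identifier in record(s): ", paste(bad, collapse = ", "))
  self <- records[, 1L] == records[, 2L]
  interaction_network(nodes = unique(c(records)),
                      edges = records[!self, , drop = FALSE],
                      self_loops = unique(records[self, 1L]))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d genes, %d interactions, %d self-interacting genes\n",
              length(x$nodes), nrow(x$edges), length(x$self_loops)))
  invisible(x)
}

# adjacency list (named list of character vectors), self-loops excluded
adjacency_list <- function(net) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0L) {
    ends <- c(net$edges[, 1L], net$edges[, 2L])
    partners <- c(net$edges[, 2L], net$edges[, 1L])
    got <- split(partners, ends)
    adj[names(got)] <- got
  }
  lapply(adj, function(v) if (is.null(v)) character() else sort(v))
}

# igraph view of the simple graph (no self-loops), vertex names = genes
as_igraph <- function(net) {
  igraph::graph_from_data_frame(as.data.frame(net$edges),
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Node degree (distinct interaction partners)
#'
#' Degree counts distinct partners; a recorded self-interaction does not
#' contribute.
#'
#' @param net an [interaction_network()].
#' @param genes genes to report; default all nodes.
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(net, genes = NULL) {
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges[, 1L], net$edges[, 2L]))
    deg[names(tab)] <- as.integer(tab)
  }
  if (is.null(genes)) return(deg)
  genes <- as.character(genes)
  unknown <- setdiff(genes, net$nodes)
  if (length(unknown) > 0L)
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  deg[genes]
}

#' Hub genes
#'
#' Genes with at least `threshold` distinct interaction partners.
#'
#' @inheritParams node_degree
#' @param threshold minimum degree; default 10.
#' @return Character vector of hub genes (sorted).
#' @export
hubs <- function(net, threshold = 10) {
  stopifnot(length(threshold) == 1L, threshold >= 1)
  deg <- node_degree(net)
  sort(names(deg)[deg >= threshold])
}

#' Read / write an interaction network
#'
#' `read_network()` ingests a two-column tab-separated edge list (optional
#' `source<TAB>target` header) or a SIF file (`geneA<TAB>pp<TAB>geneB`),
#' applying the same deduplication and self-loop rules as [build_network()].
#' `write_network()` writes the canonical edge list; self-interacting genes
#' are emitted as `gene<TAB>gene` rows (or `gene<TAB>pp<TAB>gene` in SIF) so
#' that a read/write round trip is the identity.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @return `read_network()` returns an [interaction_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no interaction records supplied in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (format == "sif") 3L else 2L
  nfield <- lengths(parts)
  start <- 1L
  if (format == "tsv" && identical(tolower(trimws(parts[[1L]][1:2])),
                                   c("source", "target"))) start <- 2L
  if (start > length(parts)) stop("no interaction records supplied in ", path)
  bad <- which(nfield[start:length(parts)] != want) + start - 1L
  if (length(bad) > 0L)
    stop(sprintf("malformed line %d in %s: expected %d tab-separated fields",
                 bad[1L], path, want))
  rec <- do.call(rbind, parts[start:length(parts)])
  if (format == "sif") rec <- rec[, c(1L, 3L), drop = FALSE]
  build_network(rec)
}

#' @rdname read_network
#' @param net an [interaction_network()].
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  e <- net$edges
  if (length(net$self_loops) > 0L)
    e <- rbind(e, cbind(net$self_loops, net$self_loops))
  # isolated nodes are not representable in an edge list; refuse silently
  # dropping them on a round trip
  iso <- setdiff(net$nodes, unique(c(e)))
  if (length(iso) > 0L)
    warning("isolated node(s) not representable in edge-list output: ",
            paste(iso, collapse = ", "))
  lines <- if (format == "sif") paste(e[, 1L], "pp", e[, 2L], sep = "\t")
           else c("source\ttarget", paste(e[, 1L], e[, 2L], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# edges of the subgraph induced by `genes`
induced_edges <- function(net, genes) {
  keep <- net$edges[, 1L] %in% genes & net$edges[, 2L] %in% genes
  net$edges[keep, , drop = FALSE]
}

# is the induced subgraph on `genes` connected? (empty/singleton: TRUE)
is_connected_set <- function(adj, genes) {
  k <- length(genes)
  if (k <= 1L) return(TRUE)
  seen <- stats::setNames(logical(k), genes)
  queue <- genes[1L]
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- intersect(adj[[v]], genes)
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}
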