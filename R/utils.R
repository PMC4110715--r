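# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed from a master seed and a stage tag (string or
# integer); kept within 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- if (is.character(tag)) sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
       else as.numeric(tag)
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587 + 1)
}

#' Read / write gene lists
#'
#' Plain lists have one gene per line; GMT files have one set per line:
#' name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return `read_gene_list()`: character vector. `read_gmt()`: named list of
#'   character vectors.
#' @export
read_gene_list <- function(path) {
  g <- trimws(readLines(path))
  unique(g[nzchar(g)])
}

#' @rdname read_gene_list
#' @param genes character vector of genes.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname read_gene_list
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT line ", bad[1L], ": need name, description, >=1 gene")
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1L))
}

#' @rdname read_gene_list
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}
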