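#' Expression profile container
#'
#' One platform's normalized, log-scale expression matrix together with the
#' disease-phase label of every sample. Phases follow the pooled staging
#' convention used throughout the package: stages I+II form the early phase,
#' stage III the middle phase, stage IV the late phase; unaffected samples
#' are labelled `control`.
#'
#' @param profile_id character scalar naming the platform/series.
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); all values finite.
#' @param sample_phases named character vector mapping every sample to one
#'   of `"early"`, `"middle"`, `"late"`, `"control"`.
#' @return Object of class `expression_profile`.
#' @export
expression_profile <- function(profile_id, values, sample_phases) {
  stopifnot(is.character(profile_id), length(profile_id) == 1L)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in profile ", profile_id)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in profile ", profile_id)
  sample_phases <- vapply(sample_phases, as.character, character(1))
  if (!setequal(colnames(values), names(sample_phases)))
    stop("sample sheet does not match expression columns in profile ", profile_id)
  sample_phases <- sample_phases[colnames(values)]
  bad <- setdiff(unique(sample_phases), c(PHASES, "control"))
  if (length(bad) > 0L)
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite expression values in profile ", profile_id)
  structure(list(profile_id = profile_id, values = values,
                 sample_phases = sample_phases),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  tab <- table(factor(x$sample_phases, levels = c(PHASES, "control")))
  cat(sprintf("Expression profile '%s': %d genes x %d samples (%s)\n",
              x$profile_id, nrow(x$values), ncol(x$values),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

PHASES <- c("early", "middle", "late")
CONTRASTS <- c("early-middle", "middle-late", "early-late")

# split "early-middle" into c("early", "middle"); validates
contrast_phases <- function(contrast) {
  contrast <- match.arg(contrast, CONTRASTS)
  strsplit(contrast, "-", fixed = TRUE)[[1L]]
}

#' Read an expression matrix / sample sheet
#'
#' Expression TSV: first column the gene identifier, remaining columns one
#' per sample. Sample sheet TSV: columns `sample_id` and `phase`.
#'
#' @param path file path.
#' @return `read_expression()`: numeric matrix with gene rownames;
#'   `read_sample_sheet()`: named character vector of phases.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expression table needs a gene column and >=1 sample")
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1L]])
  m
}

#' @rdname read_expression
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phase") %in% names(d)))
    stop("sample sheet needs columns sample_id and phase")
  stats::setNames(as.character(d$phase), as.character(d$sample_id))
}

# Newton solve of trigamma(y) = x, vectorized; x > 0
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Method-of-moments empirical-Bayes prior (d0, s0^2) from per-gene sample
# variances s2 with common residual df. Uses the log-variance moments:
# E log s2 = log s0^2 + digamma(df/2) - log(df/2) - digamma(d0/2) + log(d0/2)
# Var log s2 = trigamma(df/2) + trigamma(d0/2).
estimate_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(z)
  excess <- ev - trigamma(df / 2)
  if (!is.finite(excess)) {
    warning("empirical-Bayes moment estimator non-finite; no shrinkage applied")
    return(list(d0 = 0, s02 = NA_real_))
  }
  if (excess <= 0) {
    # observed variances no more dispersed than sampling alone: complete
    # shrinkage to the common value
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(mean(e) - digamma(d0 / 2) + log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-sample t-test between two disease phases
#'
#' Per-gene two-group comparison with empirical-Bayes variance moderation:
#' the pooled within-group variance of each gene is shrunk toward a prior
#' variance estimated across genes by the method of moments on
#' log-variances, and the t statistic uses the posterior variance with
#' augmented degrees of freedom. With `d0 = 0` this is the ordinary pooled
#' t-test; as `d0 -> Inf` every gene's denominator uses the prior variance.
#'
#' @param profile an [expression_profile()].
#' @param contrast one of `"early-middle"`, `"middle-late"`, `"early-late"`.
#' @param d0 optional prior degrees of freedom; `NULL` (default) estimates
#'   `(d0, s0^2)` from the data; may be `0` or `Inf`.
#' @param s02 optional prior variance, required when `d0` is given and
#'   positive.
#' @return data.frame with one row per gene: `gene`, `effect` (mean of the
#'   later phase minus mean of the earlier), `t_mod`, `df_total`, `p_raw`,
#'   `p_adj` (Benjamini-Hochberg). Attributes `d0`, `s02`, `contrast`,
#'   `profile_id` record the fit.
#' @export
moderated_t_test <- function(profile, contrast, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(profile, "expression_profile"))
  ph <- contrast_phases(contrast)
  a <- names(profile$sample_phases)[profile$sample_phases == ph[1L]]
  b <- names(profile$sample_phases)[profile$sample_phases == ph[2L]]
  for (i in 1:2) {
    n <- length(list(a, b)[[i]])
    if (n < 2L)
      stop(sprintf("phase '%s' has %d sample(s) in profile '%s'; need >= 2",
                   ph[i], n, profile$profile_id))
  }
  xa <- profile$values[, a, drop = FALSE]
  xb <- profile$values[, b, drop = FALSE]
  complete <- stats::complete.cases(xa) & stats::complete.cases(xb)
  if (!all(complete)) {
    message(sum(!complete), " gene(s) with missing values dropped from contrast ",
            contrast)
    xa <- xa[complete, , drop = FALSE]
    xb <- xb[complete, , drop = FALSE]
  }
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  df <- na + nb - 2L
  s2 <- (ssa + ssb) / df
  if (all(s2 == 0))
    stop("degenerate input: every gene has zero residual variance")
  if (is.null(d0)) {
    prior <- estimate_prior(s2, df)
    d0 <- prior$d0; s02 <- prior$s02
  } else {
    stopifnot(length(d0) == 1L, d0 >= 0)
    if (d0 > 0 && is.null(s02)) stop("s02 must be supplied when d0 > 0")
  }
  if (is.infinite(d0)) {
    s2_post <- rep.int(s02, length(s2))
    df_tot <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_tot <- df
  } else {
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_tot <- d0 + df
  }
  effect <- mb - ma                      # later phase minus earlier
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  t_mod <- effect / se
  p_raw <- if (is.infinite(df_tot)) 2 * stats::pnorm(-abs(t_mod))
           else 2 * stats::pt(-abs(t_mod), df = df_tot)
  res <- data.frame(gene = rownames(xa), effect = effect, t_mod = t_mod,
                    df_total = df_tot, p_raw = p_raw,
                    p_adj = bh_adjust(p_raw), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  attr(res, "contrast") <- contrast
  attr(res, "profile_id") <- profile$profile_id
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in (0, 1].
#' @export
bh_adjust <- function(p) {
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad) > 0L)
    stop("p-value outside (0, 1] at index ", bad[1L])
  stats::p.adjust(p, method = "BH")
}

#' Convert a p-value to a significance z-score
#'
#' `z = qnorm(1 - p)` with `p` clamped into `[1e-16, 1 - 1e-16]` so the
#' result is always finite; smaller p gives larger z, `p = 0.5` gives 0.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Numeric vector of z-scores.
#' @export
p_to_z <- function(p) {
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad) > 0L)
    stop("p-value outside (0, 1] at index ", bad[1L])
  stats::qnorm(1 - pmin(pmax(p, 1e-16), 1 - 1e-16))
}

#' Node z-scores over a network
#'
#' Maps a differential-expression table onto a network's node set: genes
#' measured by the platform get `z = p_to_z(p)` from the chosen p-value
#' column; network genes the platform never measured get `z = 0` and are
#' recorded in the `"measured"` attribute (they may be traversed by the
#' module search but dilute the aggregate score).
#'
#' @param de a data.frame from [moderated_t_test()].
#' @param net an [interaction_network()].
#' @param use `"p_adj"` (default) or `"p_raw"`.
#' @return Named numeric vector over `net$nodes` with attribute `measured`
#'   (character vector of network genes present in `de`).
#' @export
node_scores <- function(de, net, use = c("p_adj", "p_raw")) {
  use <- match.arg(use)
  z <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  hit <- de$gene %in% net$nodes
  z[de$gene[hit]] <- p_to_z(de[[use]][hit])
  attr(z, "measured") <- sort(de$gene[hit])
  z
}
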