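#' Stratified cross-validation fold assignment
#'
#' @param labels factor or character vector of class labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..folds), one per sample, with each
#'   class spread as evenly as possible across folds.
#' @export
make_folds <- function(labels, folds = 5, seed = 1) {
  labels <- as.character(labels)
  stopifnot(folds >= 2)
  small <- names(which(table(labels) < folds))
  if (length(small) > 0L)
    stop("class '", small[1L], "' has fewer samples than folds = ", folds,
         "; use fewer folds")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Out-of-fold decision scores from cross-validated classification
#'
#' Fits the classifier on the training folds and emits continuous decision
#' scores for the held-out samples, so that every sample is scored exactly
#' once out-of-fold. Features are standardized with training-fold statistics
#' only (no leakage); higher scores indicate the case class.
#'
#' @param x numeric matrix, samples in rows, panel genes in columns.
#' @param labels vector with values `"case"` / `"control"` (or a factor
#'   whose second level is the case class).
#' @param folds number of stratified folds (default 5) or an integer vector
#'   of precomputed fold ids.
#' @param model `"svm"` (linear-kernel support vector machine, default) or
#'   `"logistic"`.
#' @param seed integer seed (fold assignment).
#' @return Numeric vector of out-of-fold scores with attribute `fold`.
#' @export
cv_scores <- function(x, labels, folds = 5, model = c("svm", "logistic"),
                      seed = 1) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- normalize_labels(labels)
  stopifnot(nrow(x) == length(y))
  fold <- if (length(folds) == 1L) make_folds(y, folds, seed) else as.integer(folds)
  scores <- numeric(nrow(x))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xt <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
    if (model == "svm") {
      fit <- e1071::svm(xt[tr, , drop = FALSE], factor(y[tr], levels = c("control", "case")),
                        kernel = "linear", scale = FALSE)
      dv <- attr(stats::predict(fit, xt[!tr, , drop = FALSE],
                                decision.values = TRUE), "decision.values")
      # orient so larger = more case-like, whatever svm's internal order
      sgn <- if (grepl("^case/", colnames(dv)[1L])) 1 else -1
      scores[!tr] <- sgn * dv[, 1L]
    } else {
      d <- as.data.frame(xt)
      fit <- stats::glm(y ~ ., family = stats::binomial(),
                        data = cbind(y = as.integer(y == "case"), d)[tr, , drop = FALSE])
      scores[!tr] <- stats::predict(fit, d[!tr, , drop = FALSE], type = "link")
    }
  }
  attr(scores, "fold") <- fold
  scores
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) {
    stopifnot(nlevels(labels) == 2L)
    y <- ifelse(labels == levels(labels)[2L], "case", "control")
  } else {
    y <- as.character(labels)
    if (!all(y %in% c("case", "control")))
      stop("labels must be 'case'/'control' or a two-level factor")
  }
  if (length(unique(y)) < 2L) stop("both classes must be present")
  y
}

#' ROC curve and AUC
#'
#' ROC points by sweeping a threshold over the distinct scores; AUC by the
#' rank statistic (fraction of case/control pairs ranked concordantly, ties
#' counted one half), which equals the trapezoidal area under the ROC.
#'
#' @param scores numeric decision scores, higher = more case-like.
#' @param labels `"case"`/`"control"` vector (or two-level factor).
#' @return Object of class `roc_result`: `roc` (data.frame `fpr`, `tpr`,
#'   from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  pos <- scores[y == "case"]
  neg <- scores[y == "control"]
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(roc = roc, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC with %d points, AUC = %.4f\n", nrow(x$roc), x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Cross-validated AUC of a biomarker panel
#'
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @param labels `"case"`/`"control"` per sample (in column order).
#' @param panel character vector of panel genes (rows of `expr`).
#' @inheritParams cv_scores
#' @return An `roc_result` with attributes `dropped` (panel genes not
#'   measured) and `fold`.
#' @export
cv_auc <- function(expr, labels, panel, folds = 5, model = "svm", seed = 1) {
  panel <- unique(as.character(panel))
  have <- intersect(panel, rownames(expr))
  if (length(have) == 0L)
    stop("panel has no overlap with the measured genes")
  dropped <- setdiff(panel, have)
  if (length(dropped) > 0L)
    message(length(dropped), " panel gene(s) not measured; dropped")
  sc <- cv_scores(t(expr[have, , drop = FALSE]), labels, folds = folds,
                  model = model, seed = seed)
  out <- roc_auc(sc, labels)
  attr(out, "dropped") <- dropped
  attr(out, "fold") <- attr(sc, "fold")
  out
}

#' Head-to-head comparison of two biomarker panels
#'
#' Evaluates both panels with identical stratified fold assignments on the
#' same samples and reports per-panel ROC/AUC and the AUC difference.
#'
#' @param panel_a,panel_b character vectors of panel genes.
#' @inheritParams cv_auc
#' @return Object of class `panel_comparison`: `a`, `b` (each an
#'   `roc_result` with `dropped` attribute), `auc_diff` (a minus b),
#'   `fold`, `seed`.
#' @export
compare_panels <- function(panel_a, panel_b, expr, labels, folds = 5,
                           model = "svm", seed = 1) {
  panels <- list(a = panel_a, b = panel_b)
  for (nm in names(panels)) {
    if (length(intersect(unique(as.character(panels[[nm]])), rownames(expr))) == 0L)
      stop("panel '", nm, "' has no overlap with the measured genes")
  }
  fold <- make_folds(normalize_labels(labels), folds, seed)
  ra <- cv_auc(expr, labels, panel_a, folds = fold, model = model, seed = seed)
  rb <- cv_auc(expr, labels, panel_b, folds = fold, model = model, seed = seed)
  structure(list(a = ra, b = rb, auc_diff = ra$auc - rb$auc, fold = fold,
                 seed = seed),
            class = "panel_comparison")
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat(sprintf("Panel comparison: AUC(a) = %.4f, AUC(b) = %.4f, difference = %+.4f\n",
              x$a$auc, x$b$auc, x$auc_diff))
  invisible(x)
}
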