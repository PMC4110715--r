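#' Integrative phase-module analysis
#'
#' The package's main fitting function: runs the full integrative analysis
#' on an interaction network and a list of expression profiles. For every
#' surviving profile and every phase contrast, genes are tested by the
#' empirical-Bayes moderated t-test, adjusted p-values are converted to
#' z-scores, and the greedy active-module search extracts the top-ranked
#' connected subnetworks, merged into a per-profile core subnetwork. Per
#' contrast, a consensus module collects the genes shared across profiles
#' (with pairwise overlap percentages reported as a diagnostic); genes
#' unique to one contrast's module are phase-specific signatures and genes
#' common to all three are the candidate disease-associated genes. If
#' known-gene lists are supplied the candidates are validated by exact
#' hypergeometric and Monte-Carlo enrichment against the network universe;
#' if case/control data are supplied the candidate panel is validated by
#' cross-validated SVM classification (ROC/AUC).
#'
#' A profile for which differential testing fails (e.g. a phase with fewer
#' than two samples) is dropped with a warning; the run aborts if fewer
#' than two profiles survive.
#'
#' @param net an [interaction_network()].
#' @param profiles list of [expression_profile()] objects.
#' @param known_lists named list of character vectors for enrichment
#'   validation (optional).
#' @param case_control optional list with `expr` (genes x samples) and
#'   `labels` (`"case"`/`"control"`) for classifier validation, e.g. from
#'   [case_control_data()].
#' @param contrasts phase contrasts to analyse; default all three.
#' @param tau consensus membership fraction in (0, 1]; default 1.
#' @param respect_coverage do not count a platform against a gene it never
#'   measured (default `TRUE`).
#' @param n_seeds,iterations,top,calibrated,calib_reps greedy-search
#'   parameters, see [greedy_search()].
#' @param use p-value column converted to z-scores: `"p_adj"` (default) or
#'   `"p_raw"`.
#' @param enrich_reps Monte-Carlo draws per enrichment test (0 disables the
#'   sampling p-value).
#' @param cv_folds folds for classifier validation.
#' @param hub_threshold minimum degree for hub annotation.
#' @param seed master seed; every random stage uses a sub-seed derived from
#'   it and the stage name, so identical inputs give identical results.
#' @return Object of class `phasenet`: a list with elements `de`,
#'   `modules`, `cores` (nested per contrast / profile), `overlap`
#'   (per-contrast overlap percentage matrices), `consensus`, `signatures`,
#'   `candidates`, `annotation`, `enrichment`, `classifier`, `params`.
#' @examples
#' \donttest{
#' bundle <- synthetic_bundle(n_nodes = 150, seed = 7)
#' fit <- phasenet(bundle$network, bundle$profiles,
#'                 known_lists = bundle$known_lists, enrich_reps = 1e4,
#'                 seed = 7)
#' summary(fit)
#' recovery_metrics(bundle$truth, fit$candidates)
#' }
#' @export
phasenet <- function(net, profiles, known_lists = list(),
                     case_control = NULL, contrasts = CONTRASTS, tau = 1,
                     respect_coverage = TRUE, n_seeds = 10, iterations = 3,
                     top = 10, max_depth = 2, calibrated = TRUE, calib_reps = 1000,
                     use = "p_adj", enrich_reps = 1e5, cv_folds = 5,
                     hub_threshold = 10, seed = 1) {
  stopifnot(inherits(net, "interaction_network"), length(profiles) >= 2L)
  contrasts <- match.arg(contrasts, CONTRASTS, several.ok = TRUE)

  ## differential expression per profile x contrast; drop failing profiles
  de <- list()
  surviving <- list()
  for (pr in profiles) {
    res <- tryCatch(
      lapply(stats::setNames(contrasts, contrasts),
             function(ct) moderated_t_test(pr, ct)),
      error = function(e) {
        warning("profile '", pr$profile_id, "' dropped: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      de[[pr$profile_id]] <- res
      surviving[[pr$profile_id]] <- pr
    }
  }
  if (length(surviving) < 2L)
    stop("fewer than two profiles survived differential testing")

  ## active-module search and per-profile cores, per contrast
  modules <- list()
  cores <- list()
  for (ct in contrasts) {
    modules[[ct]] <- list()
    cores[[ct]] <- list()
    for (pid in names(surviving)) {
      z <- node_scores(de[[pid]][[ct]], net, use = use)
      mods <- greedy_search(net, z, n_seeds = n_seeds,
                            iterations = iterations, top = top,
                            max_depth = max_depth,
                            calibrated = calibrated, reps = calib_reps,
                            seed = derive_seed(seed, paste0("search/", pid, "/", ct)))
      modules[[ct]][[pid]] <- mods
      cores[[ct]][[pid]] <- merge_top(mods, net, profile_id = pid,
                                      contrast = ct)
    }
  }

  ## consensus per contrast
  overlap <- lapply(cores, overlap_matrix)
  consensus <- lapply(stats::setNames(contrasts, contrasts), function(ct) {
    genes <- consensus_genes(cores[[ct]], tau = tau,
                             respect_coverage = respect_coverage)
    memb <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (pid in names(cores[[ct]]))
      memb[[pid]] <- genes %in% cores[[ct]][[pid]]$genes
    build_module(genes, net, ct, membership = memb)
  })

  ## signatures and candidates (only defined over the full triplet)
  if (length(contrasts) == 3L) {
    uc <- unique_and_common(unname(consensus))
    signatures <- uc$unique
    candidates <- uc$common
  } else {
    signatures <- NULL
    candidates <- structure(sort(Reduce(intersect,
                                        lapply(consensus, `[[`, "genes"))),
                            class = "candidate_gene_set")
  }

  annotation <- annotate_candidates(candidates, known_lists, net,
                                    hub_threshold = hub_threshold)
  enrichment <- lapply(stats::setNames(names(known_lists), names(known_lists)),
                       function(nm)
                         enrich_test(candidates, known_lists[[nm]],
                                     universe = net$nodes, reps = enrich_reps,
                                     seed = derive_seed(seed, paste0("mc/", nm))))

  classifier <- NULL
  if (!is.null(case_control) && length(candidates) > 0L) {
    classifier <- cv_auc(case_control$expr, case_control$labels,
                         panel = unclass(candidates), folds = cv_folds,
                         seed = derive_seed(seed, "cv"))
  }

  structure(list(de = de, modules = modules, cores = cores,
                 overlap = overlap, consensus = consensus,
                 signatures = signatures, candidates = candidates,
                 annotation = annotation, enrichment = enrichment,
                 classifier = classifier,
                 params = list(contrasts = contrasts, tau = tau,
                               respect_coverage = respect_coverage,
                               n_seeds = n_seeds, iterations = iterations,
                               top = top, max_depth = max_depth,
                               calibrated = calibrated,
                               calib_reps = calib_reps, use = use,
                               enrich_reps = enrich_reps,
                               cv_folds = cv_folds,
                               hub_threshold = hub_threshold, seed = seed,
                               profiles = names(surviving))),
            class = "phasenet")
}

#' @export
print.phasenet <- function(x, ...) {
  cat("Phase-specific network module analysis\n")
  cat(sprintf("  profiles: %s\n", paste(x$params$profiles, collapse = ", ")))
  for (ct in x$params$contrasts)
    cat(sprintf("  consensus module [%s]: %d genes, %d interactions\n", ct,
                length(x$consensus[[ct]]$genes),
                nrow(x$consensus[[ct]]$edges)))
  cat(sprintf("  candidate disease-associated genes: %d\n",
              length(x$candidates)))
  invisible(x)
}

#' @export
summary.phasenet <- function(object, ...) {
  print(object)
  if (!is.null(object$signatures)) {
    for (ct in names(object$signatures))
      cat(sprintf("  unique signatures [%s]: %d genes\n", ct,
                  length(object$signatures[[ct]])))
  }
  for (nm in names(object$enrichment)) {
    e <- object$enrichment[[nm]]
    cat(sprintf("  enrichment vs '%s': x = %d/%d, p_hyper = %.3g%s\n", nm,
                e$x, e$n, e$p_hyper,
                if (is.na(e$p_mc)) "" else sprintf(", p_mc = %.3g", e$p_mc)))
  }
  if (!is.null(object$classifier))
    cat(sprintf("  candidate-panel cross-validated AUC: %.4f\n",
                object$classifier$auc))
  invisible(object)
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults, rejects unknown keys and
#' range-checks every parameter before any computation. Recognised keys:
#' `network`, `profiles` (list of `id`/`expression`/`samples` path
#' triplets), `known_lists` (named paths), `contrasts`, `tau`,
#' `respect_coverage`, `n_seeds`, `iterations`, `top`, `calibrated`,
#' `calib_reps`, `use`, `enrich_reps`, `cv_folds`, `hub_threshold`, `seed`,
#' `outdir`.
#'
#' @param path YAML file path, or an equivalent named list.
#' @return Named list of validated configuration values.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(network = NULL, profiles = NULL, known_lists = list(),
                   contrasts = CONTRASTS, tau = 1, respect_coverage = TRUE,
                   n_seeds = 10, iterations = 3, top = 10, max_depth = 2,
                   calibrated = TRUE,
                   calib_reps = 1000, use = "p_adj", enrich_reps = 1e6,
                   cv_folds = 5, hub_threshold = 10, seed = 1,
                   outdir = "phasenet_out")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$network) || is.null(cfg$profiles))
    stop("configuration must name a network file and >= 2 profiles")
  chk <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi)
      stop(sprintf("configuration key '%s' out of range [%s, %s]", key, lo, hi))
  }
  if (cfg$tau <= 0 || cfg$tau > 1) stop("configuration key 'tau' out of range (0, 1]")
  chk("n_seeds", 1, Inf); chk("iterations", 1, Inf); chk("top", 1, Inf)
  chk("max_depth", 1, Inf)
  chk("calib_reps", 2, Inf); chk("enrich_reps", 0, Inf)
  chk("cv_folds", 2, Inf); chk("hub_threshold", 1, Inf)
  cfg$use <- match.arg(cfg$use, c("p_adj", "p_raw"))
  cfg$contrasts <- match.arg(cfg$contrasts, CONTRASTS, several.ok = TRUE)
  for (f in c(cfg$network, unlist(cfg$known_lists),
              unlist(lapply(cfg$profiles, function(p)
                c(p$expression, p$samples))))) {
    if (!file.exists(f)) stop("configured input file not found: ", f)
  }
  cfg
}

#' Run the analysis from a configuration file
#'
#' File-driven front end over [phasenet()]: reads the network, the
#' expression profiles with their sample sheets and the known-gene lists
#' named in the configuration, runs the full analysis and writes every
#' stage's artifacts under `outdir` (differential tables, module tables,
#' core/consensus gene and edge lists, signature and candidate lists, and
#' a JSON report).
#'
#' @param config path to a YAML configuration, or the list returned by
#'   [validate_config()].
#' @param outdir optional override of the configured output directory.
#' @return The [phasenet()] fit, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  net <- read_network(cfg$network)
  profiles <- lapply(cfg$profiles, function(p)
    expression_profile(p$id, read_expression(p$expression),
                       read_sample_sheet(p$samples)))
  known <- lapply(cfg$known_lists, read_gene_list)
  fit <- phasenet(net, profiles, known_lists = known,
                  contrasts = cfg$contrasts, tau = cfg$tau,
                  respect_coverage = cfg$respect_coverage,
                  n_seeds = cfg$n_seeds, iterations = cfg$iterations,
                  top = cfg$top, max_depth = cfg$max_depth,
                  calibrated = cfg$calibrated,
                  calib_reps = cfg$calib_reps, use = cfg$use,
                  enrich_reps = cfg$enrich_reps, cv_folds = cfg$cv_folds,
                  hub_threshold = cfg$hub_threshold, seed = cfg$seed)
  write_report(fit, cfg$outdir)
  invisible(fit)
}

#' Write all stage artifacts of a fit
#'
#' @param fit a [phasenet()] object.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(fit, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, paste0(...))
  for (pid in names(fit$de)) for (ct in names(fit$de[[pid]]))
    utils::write.table(fit$de[[pid]][[ct]], p("de_", pid, "_", ct, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (ct in names(fit$modules)) for (pid in names(fit$modules[[ct]])) {
    if (length(fit$modules[[ct]][[pid]]) > 0L)
      write_modules(fit$modules[[ct]][[pid]], p("modules_", pid, "_", ct, ".tsv"))
    core <- fit$cores[[ct]][[pid]]
    write_gene_list(core$genes, p("core_", pid, "_", ct, "_genes.txt"))
  }
  for (ct in names(fit$consensus)) {
    m <- fit$consensus[[ct]]
    utils::write.table(m$membership, p("consensus_", ct, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(m$edges, p("consensus_", ct, "_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fit$signatures))
    write_gmt(c(lapply(fit$signatures, function(g)
                  if (length(g) == 0L) "-" else g),
                list(candidates = if (length(fit$candidates) == 0L) "-"
                     else unclass(fit$candidates))),
              p("signatures.gmt"))
  write_gene_list(unclass(fit$candidates), p("candidates.txt"))
  utils::write.table(fit$annotation, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(params = fit$params,
                 overlap = lapply(fit$overlap, function(m)
                   as.data.frame(as.table(m))),
                 candidates = as.character(fit$candidates),
                 enrichment = lapply(fit$enrichment, unclass),
                 classifier_auc = if (is.null(fit$classifier)) NULL
                                  else fit$classifier$auc)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(outdir)
}
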