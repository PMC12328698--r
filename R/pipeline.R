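#' Pipeline configuration
#'
#' Collects every stage's parameters in one validated list. Input paths
#' may be omitted in synthetic mode, where the cohort generator supplies
#' the abundance and annotation tables.
#'
#' @param abundance,annotation,gmt Input paths (`NULL` in synthetic mode;
#'   `gmt` may be a path or a named list of gene sets).
#' @param output_dir Directory for stage outputs.
#' @param synthetic `NULL` or a [cohort_config()] for synthetic mode.
#' @param presence_threshold Group-presence filter threshold.
#' @param fdr_cut,fc_cut DAP thresholds.
#' @param panel Panel-selection parameters (`alpha`, `folds`, `split`,
#'   `tol`, `cap`, `min_daps`, `seed`).
#' @param gsea GSEA parameters (`n_perm`, `min_size`, `max_size`,
#'   `fdr_cut`, `seed`).
#' @param surv Survival-screen parameters (`n_boot`, `fdr_cut`,
#'   `boot_p_cut`, `max_proteins`, `seed`).
#' @param target_groups Histotypes analyzed in one-vs-rest stages;
#'   defaults to the four main carcinoma histotypes when present.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(abundance = NULL, annotation = NULL, gmt = NULL,
                            output_dir = tempfile("histoprot_run_"),
                            synthetic = NULL,
                            presence_threshold = 0.70,
                            fdr_cut = 0.05, fc_cut = 1.5,
                            panel = list(), gsea = list(), surv = list(),
                            target_groups = NULL) {
  stopifnot(presence_threshold > 0, presence_threshold <= 1,
            fdr_cut > 0, fdr_cut < 1, fc_cut >= 1)
  panel <- utils::modifyList(
    list(alpha = 0.5, folds = 5, split = 0.8, tol = 0.01, cap = 5,
         min_daps = 2, seed = 1L), panel)
  gsea <- utils::modifyList(
    list(n_perm = 1000, min_size = 10, max_size = 500, fdr_cut = 0.05,
         seed = 1L), gsea)
  surv <- utils::modifyList(
    list(n_boot = 1000, fdr_cut = 0.05, boot_p_cut = 0.2,
         max_proteins = Inf, seed = 1L), surv)
  if (is.null(synthetic) &&
      (is.null(abundance) || is.null(annotation))) {
    stop("either input paths or a synthetic cohort config is required")
  }
  structure(list(abundance = abundance, annotation = annotation, gmt = gmt,
                 output_dir = output_dir, synthetic = synthetic,
                 presence_threshold = presence_threshold,
                 fdr_cut = fdr_cut, fc_cut = fc_cut, panel = panel,
                 gsea = gsea, surv = surv, target_groups = target_groups),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the
#'   [pipeline_config()] arguments; a `synthetic` block is forwarded to
#'   [cohort_config()].
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(cohort_config, y$synthetic)
  }
  do.call(pipeline_config, y)
}

#' Run the full stratification pipeline
#'
#' ingest -> differential abundance (one-vs-rest + pairwise DAP counts) ->
#' biomarker panels -> enrichment (GSEA + ORA) -> survival screen, writing
#' per-stage TSV outputs and a JSON manifest (parameters, seeds, row
#' counts) under `config$output_dir`. Failure of one comparison's panel
#' search is logged and does not abort the other comparisons.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of
#'   `c("da", "panels", "gsea", "ora", "survival")` to execute after
#'   ingest.
#' @return Invisible list with all in-memory stage results (`matrix`,
#'   `annotation`, `da`, `panels`, `gsea`, `ora`, `survival`, `manifest`).
#' @export
run_pipeline <- function(config,
                         stages = c("da", "panels", "gsea", "ora",
                                    "survival")) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[histoprot] ", sprintf(...))
  manifest <- list(parameters = config[setdiff(names(config),
                                               c("synthetic"))],
                   stages = list())

  # ---- ingest -------------------------------------------------------
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    raw <- cohort$abundance
    annotation <- cohort$annotation
    manifest$stages$ingest <- list(mode = "synthetic",
                                   seed = config$synthetic$seed)
  } else {
    raw <- read_abundance_table(config$abundance)
    annotation <- utils::read.table(config$annotation, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    manifest$stages$ingest <- list(mode = "files")
  }
  n_raw <- nrow(raw$values)
  filtered <- filter_by_group_presence(raw, annotation,
                                       config$presence_threshold)
  mat <- log2_transform(filtered)
  log_msg("ingest: %d proteins quantified, %d retained by the %.0f%% rule",
          n_raw, nrow(mat$values), 100 * config$presence_threshold)
  manifest$stages$ingest$n_proteins_raw <- n_raw
  manifest$stages$ingest$n_proteins_filtered <- nrow(mat$values)
  utils::write.table(annotation,
                     file.path(config$output_dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- group_lookup(annotation, sample_ids(mat))
  targets <- config$target_groups
  if (is.null(targets)) {
    main <- c("HGSC", "EC", "MC", "CCC")
    targets <- if (any(main %in% groups)) intersect(main, unique(groups))
               else unique(groups)
  }
  out <- list(matrix = mat, annotation = annotation)

  # ---- differential abundance --------------------------------------
  da <- NULL
  if ("da" %in% stages || any(c("panels", "gsea", "ora") %in% stages)) {
    da <- one_vs_rest_contrasts(mat, annotation, targets,
                                fdr_cut = config$fdr_cut,
                                fc_cut = config$fc_cut)
    for (g in names(da)) {
      utils::write.table(
        da[[g]], file.path(config$output_dir,
                           sprintf("da_%s_vs_rest.tsv", g)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$da <- lapply(da, function(d) {
      list(n_tested = nrow(d), n_up = sum(d$dap_flag == "up"),
           n_down = sum(d$dap_flag == "down"))
    })
    log_msg("differential abundance: %s",
            paste(sprintf("%s %d DAPs", names(da),
                          vapply(da, function(d)
                            sum(d$dap_flag != "none"), 0L)),
                  collapse = ", "))
    out$da <- da
  }

  # ---- biomarker panels --------------------------------------------
  if ("panels" %in% stages) {
    panels <- list()
    for (g in names(da)) {
      daps <- da[[g]]$protein[da[[g]]$dap_flag != "none"]
      if (length(daps) < config$panel$min_daps) {
        log_msg("panels: %s skipped (insufficient DAPs for SVM modeling)", g)
        manifest$stages$panels[[g]] <- list(skipped = "insufficient DAPs")
        next
      }
      labels <- factor(ifelse(groups == g, g, "rest"),
                       levels = c("rest", g))
      res <- try({
        cand <- lasso_prefilter(subset_abundance(mat, proteins = daps),
                                labels, alpha = config$panel$alpha,
                                folds = config$panel$folds,
                                seed = config$panel$seed)
        stepwise_svm_panel(mat, labels, cand,
                           split = config$panel$split,
                           tol = config$panel$tol, cap = config$panel$cap,
                           seed = config$panel$seed)
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        log_msg("panels: %s failed (%s)", g,
                trimws(conditionMessage(attr(res, "condition"))))
        manifest$stages$panels[[g]] <- list(failed = TRUE)
        next
      }
      panels[[g]] <- res
      manifest$stages$panels[[g]] <- list(
        panel = res$proteins, auc = res$auc_test,
        n_candidates = length(res$candidate_pool))
      log_msg("panels: %s -> {%s} AUC %.3f", g,
              paste(res$proteins, collapse = ", "), res$auc_test)
    }
    if (length(panels) > 0) {
      summ <- do.call(rbind, lapply(names(panels), function(g) {
        data.frame(comparison = paste0(g, "_vs_rest"),
                   panel = paste(panels[[g]]$proteins, collapse = ","),
                   auc = panels[[g]]$auc_test,
                   sensitivity = panels[[g]]$sensitivity,
                   specificity = panels[[g]]$specificity,
                   stringsAsFactors = FALSE)
      }))
      utils::write.table(summ,
                         file.path(config$output_dir, "panel_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out$panels <- panels
  }

  # ---- enrichment ---------------------------------------------------
  collection <- NULL
  if (!is.null(config$gmt)) {
    collection <- if (is.character(config$gmt)) read_gmt(config$gmt)
                  else config$gmt
  }
  if (!is.null(collection) && "gsea" %in% stages) {
    gsea_out <- list()
    for (g in names(da)) {
      ranked <- rank_by_logfc(da[[g]])
      gr <- try(gsea_preranked(ranked, collection,
                               n_perm = config$gsea$n_perm,
                               seed = config$gsea$seed,
                               min_size = config$gsea$min_size,
                               max_size = config$gsea$max_size,
                               fdr_cut = config$gsea$fdr_cut),
                silent = TRUE)
      if (inherits(gr, "try-error")) {
        log_msg("gsea: %s skipped (%s)", g,
                trimws(conditionMessage(attr(gr, "condition"))))
        next
      }
      gsea_out[[g]] <- gr
      utils::write.table(
        gr[, setdiff(names(gr), "leading_edge")],
        file.path(config$output_dir, sprintf("gsea_%s.tsv", g)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out$gsea <- gsea_out
  }
  if (!is.null(collection) && "ora" %in% stages) {
    ora_out <- list()
    for (g in names(da)) {
      daps <- unique(da[[g]]$symbol[da[[g]]$dap_flag != "none"])
      if (length(daps) == 0) next
      or <- try(ora_hypergeometric(daps, unique(da[[g]]$symbol),
                                   collection),
                silent = TRUE)
      if (inherits(or, "try-error")) next
      ora_out[[g]] <- or
      utils::write.table(or,
                         file.path(config$output_dir,
                                   sprintf("ora_%s.tsv", g)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out$ora <- ora_out
  }

  # ---- survival -----------------------------------------------------
  if ("survival" %in% stages &&
      all(c("os_time", "os_event") %in% names(annotation))) {
    surv_out <- list()
    for (g in targets) {
      keep <- sample_ids(mat)[groups == g]
      if (length(keep) < 15) next
      sub <- subset_abundance(mat, samples = keep)
      ann <- annotation[annotation$sample_id %in% keep, ]
      for (epn in c("os", "dss")) {
        res <- try(survival_screen(
          sub, ann, epn, n_boot = config$surv$n_boot,
          fdr_cut = config$surv$fdr_cut,
          boot_p_cut = config$surv$boot_p_cut,
          seed = config$surv$seed,
          max_proteins = config$surv$max_proteins), silent = TRUE)
        if (inherits(res, "try-error")) next
        key <- paste(g, epn, sep = "_")
        surv_out[[key]] <- res
        utils::write.table(res,
                           file.path(config$output_dir,
                                     sprintf("survival_%s.tsv", key)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$stages$survival[[key]] <- list(
          n_candidates = nrow(res),
          n_classified = sum(res$risk_class != "inconclusive"))
      }
    }
    out$survival <- surv_out
  }

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  out$manifest <- manifest
  invisible(out)
}
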