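#!/usr/bin/env Rscript
# Build minimal biomarker panels separating each main histotype from the
# rest: elastic-net (alpha 0.5) prefilter of the histotype's DAPs, then
# stepwise SVM forward selection on one stratified 80/20 split with the
# 1%-point AUC tolerance and the five-protein cap.

suppressPackageStartupMessages(library(histoprot))

raw <- read_abundance_table("results/cohort/abundance.tsv")
annotation <- read.table("results/cohort/annotation.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
mat <- log2_transform(filter_by_group_presence(raw, annotation, 0.70))
groups <- annotation$group[match(colnames(mat$values),
                                 annotation$sample_id)]

dir.create("results/panels", showWarnings = FALSE, recursive = TRUE)
summary_rows <- list()
for (g in c("HGSC", "EC", "MC", "CCC")) {
  d <- read.table(sprintf("results/diffabund/da_%s_vs_rest.tsv", g),
                  header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  daps <- d$protein[d$dap_flag != "none"]
  if (length(daps) < 2) {
    cat(sprintf("%s: insufficient DAPs for SVM modeling, skipped\n", g))
    next
  }
  labels <- factor(ifelse(groups == g, g, "rest"), levels = c("rest", g))
  cand <- lasso_prefilter(subset_abundance(mat, proteins = daps), labels,
                          alpha = 0.5, folds = 5, seed = 1)
  pm <- stepwise_svm_panel(mat, labels, cand, seed = 1)
  cat(sprintf("%s: %d DAPs -> %d LASSO candidates -> panel {%s}, AUC %.3f\n",
              g, length(daps), length(cand),
              paste(pm$proteins, collapse = ", "), pm$auc_test))
  jsonlite::write_json(
    list(comparison = paste0(g, "_vs_rest"), candidates = cand,
         panel = pm$proteins, auc = pm$auc_test,
         sensitivity = pm$sensitivity, specificity = pm$specificity,
         roc = pm$roc),
    sprintf("results/panels/panel_%s.json", g),
    auto_unbox = TRUE, digits = NA)
  summary_rows[[g]] <- data.frame(
    comparison = paste0(g, "_vs_rest"),
    panel = paste(pm$proteins, collapse = ","),
    n_panel = length(pm$proteins), auc = round(pm$auc_test, 3),
    sensitivity = round(pm$sensitivity, 3),
    specificity = round(pm$specificity, 3))
}
summ <- do.call(rbind, summary_rows)
write.table(summ, "results/panels/panel_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summ, row.names = FALSE)
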