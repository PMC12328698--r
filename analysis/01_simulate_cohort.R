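#!/usr/bin/env Rscript
# Simulate the default 300-patient ovarian-tumor cohort: 11 histotype /
# tissue groups, 1000 proteins, planted histotype markers, DIA-style
# intensity-dependent missingness, and Weibull OS/DSS endpoints.
# Writes the wide abundance TSV, the sample annotation and the ground
# truth under results/cohort/.

suppressPackageStartupMessages(library(histoprot))

seed <- 1L
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)

write_abundance_table(cohort$abundance, "results/cohort/abundance.tsv")
write.table(cohort$annotation, "results/cohort/annotation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(true_daps = cohort$truth$true_daps,
       true_prognostic = as.list(cohort$truth$true_prognostic),
       seed = seed),
  "results/cohort/ground_truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d proteins x %d samples, %.1f%% cells missing\n",
            nrow(cohort$abundance$values), ncol(cohort$abundance$values),
            100 * mean(is.na(cohort$abundance$values))))
print(table(cohort$annotation$group))
cat(sprintf("planted DA effects: %d; prognostic proteins: %s\n",
            nrow(cohort$truth$true_daps),
            paste(names(cohort$truth$true_prognostic), collapse = ", ")))
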