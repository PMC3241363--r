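#!/usr/bin/env Rscript
# Metabolite-level interpretation of the discovery cohort: per-metabolite
# pooled-variance t-tests with p(corr) from the contrast's OPLS-DA model,
# a Table-1-style increased/decreased partition, and truncated standard-score
# heat-map matrices (control-referenced for RA vs control, PsoA-referenced
# for RA vs PsoA), columns sorted by p(corr).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "00_common.R"))
opts <- parse_args()
data_dir <- file.path(opts$out, "data")
out <- file.path(opts$out, "report")

st1 <- read_feature_table(file.path(data_dir, "study1_intensities.csv"),
                          file.path(data_dir, "study1_samples.csv"),
                          file.path(data_dir, "study1_metabolites.csv"))
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (contrast in list(list(groups = c("RA", "CONTROL"), ref = "CONTROL",
                           label = "ra_vs_control"),
                      list(groups = c("RA", "PSOA"), ref = "PSOA",
                           label = "ra_vs_psoa"))) {
  sub <- subset_groups(st1$table, st1$meta, contrast$groups)
  model <- fit_oplsda(sub$table, sub$meta, positive = "RA", n_orth = 1)
  tt <- ttest_table(sub$table, sub$meta, group_a = "RA",
                    group_b = contrast$ref, model = model)
  utils::write.csv(tt, file.path(out, paste0(contrast$label, "_ttests.csv")),
                   row.names = FALSE)
  t1 <- render_table1(tt)
  message(sprintf("%s: %d increased, %d decreased at P < %.2f (uncorrected)",
                  contrast$label, nrow(t1$increased), nrow(t1$decreased),
                  t1$alpha))
  sink(file.path(out, paste0(contrast$label, "_table1.txt")))
  print(t1)
  sink()

  hm <- build_heatmap(sub$table, sub$meta, model, reference = contrast$ref,
                      limit = 2)
  utils::write.table(
    round(hm$z, 4), file.path(out, paste0(contrast$label, "_heatmap.tsv")),
    sep = "\t", quote = FALSE, col.names = NA)
}
write_provenance(out, list(seed = opts$seed, alpha = 0.05, truncation = 2))
message("reports written under ", out)
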