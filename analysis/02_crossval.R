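#!/usr/bin/env Rscript
# Sevenfold cross-validated diagnosis on the discovery cohort written by
# 01_simulate.R: RA vs healthy controls and RA vs PsoA, each with its own
# OPLS-DA model (all metabolites, and identified-only for the RA-vs-control
# contrast). Writes per-sample predictions and a metrics JSON.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "00_common.R"))
opts <- parse_args()
data_dir <- file.path(opts$out, "data")
out <- file.path(opts$out, "crossval")

st1 <- read_feature_table(file.path(data_dir, "study1_intensities.csv"),
                          file.path(data_dir, "study1_samples.csv"),
                          file.path(data_dir, "study1_metabolites.csv"))

run <- function(groups, table, label) {
  sub <- subset_groups(table, st1$meta, groups)
  cv <- crossval_predict(sub$table, sub$meta, k = 7, n_orth = 1,
                         seed = opts$seed)
  message(sprintf("%-28s sensitivity %3.0f%%  specificity %3.0f%%  Q2 %.3f",
                  label, 100 * cv$sensitivity, 100 * cv$specificity, cv$q2))
  utils::write.csv(cv$samples,
                   file.path(out, paste0(label, "_predictions.csv")),
                   row.names = FALSE)
  list(sensitivity = cv$sensitivity, specificity = cv$specificity,
       q2 = cv$q2, confusion = as.list(cv$confusion))
}

dir.create(out, showWarnings = FALSE, recursive = TRUE)
metrics <- list(
  ra_vs_control = run(c("RA", "CONTROL"), st1$table, "ra_vs_control"),
  ra_vs_psoa = run(c("RA", "PSOA"), st1$table, "ra_vs_psoa"),
  ra_vs_control_identified = run(c("RA", "CONTROL"),
                                 select_identified(st1$table),
                                 "ra_vs_control_identified")
)
jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                     auto_unbox = TRUE, digits = NA)
write_provenance(out, list(seed = opts$seed, k = 7, n_orth = 1,
                           scaling = "uv", log = TRUE))
message("metrics written to ", file.path(out, "metrics.json"))
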