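#!/usr/bin/env Rscript
# External validation: one OPLS-DA model built on the discovery cohort
# restricted to the shared identified metabolites (nine training observations
# per group), used to predict the diagnosis of every validation-cohort
# sample. Writes per-sample predictions, the serialized model and a metrics
# JSON.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "00_common.R"))
opts <- parse_args()
data_dir <- file.path(opts$out, "data")
out <- file.path(opts$out, "validation")

st1 <- read_feature_table(file.path(data_dir, "study1_intensities.csv"),
                          file.path(data_dir, "study1_samples.csv"),
                          file.path(data_dir, "study1_metabolites.csv"))
st2 <- read_feature_table(file.path(data_dir, "study2_intensities.csv"),
                          file.path(data_dir, "study2_samples.csv"),
                          file.path(data_dir, "study2_metabolites.csv"))

val <- external_validate(st1$table, st1$meta, st2$table, st2$meta,
                         balance = 9, seed = opts$seed, n_orth = 1)

dir.create(out, showWarnings = FALSE, recursive = TRUE)
utils::write.csv(val$samples, file.path(out, "predictions.csv"),
                 row.names = FALSE)
write_oplsda(val$model, file.path(out, "model.json"))
jsonlite::write_json(
  list(sensitivity = val$sensitivity, specificity = val$specificity,
       q2 = val$q2, confusion = as.list(val$confusion),
       n_shared = length(val$shared_identified), n_train = val$n_train),
  file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
write_provenance(out, list(seed = opts$seed, balance = 9, n_orth = 1))

message(sprintf(
  "validation on %d shared metabolites (%d training samples): sensitivity %.0f%%, specificity %.0f%%",
  length(val$shared_identified), val$n_train,
  100 * val$sensitivity, 100 * val$specificity))
message("artefacts written under ", out)
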