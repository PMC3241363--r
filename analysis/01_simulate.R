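#!/usr/bin/env Rscript
# Generate the synthetic study pair: a discovery cohort (21 RA / 9 controls /
# 17 PsoA, 267 putative metabolites, 83 identified) and a validation cohort
# (14 RA / 20 controls, 240 putative metabolites) sharing 52 identified
# metabolite names, with the planted marker effects of the default catalogue.
# Writes delimited feature tables under <out>/data/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "00_common.R"))
opts <- parse_args()
out <- file.path(opts$out, "data")

cfg <- sim_config(seed = opts$seed)
pair <- generate_study_pair(cfg)

write_feature_table(pair$table_a, pair$meta_a, out, prefix = "study1")
write_feature_table(pair$table_b, pair$meta_b, out, prefix = "study2")
write_provenance(out, c(unclass(cfg)[setdiff(names(unclass(cfg)), "effects")],
                        list(seed = opts$seed)))

n1 <- table(pair$meta_a$group)
n2 <- table(pair$meta_b$group)
message(sprintf(
  "study 1: %d RA / %d controls / %d PsoA, %d metabolites (%d identified)",
  n1[["RA"]], n1[["CONTROL"]], n1[["PSOA"]],
  ncol(pair$table_a$intensities), sum(pair$table_a$identified)))
message(sprintf(
  "study 2: %d RA / %d controls, %d metabolites (%d identified)",
  n2[["RA"]], n2[["CONTROL"]],
  ncol(pair$table_b$intensities), sum(pair$table_b$identified)))
message(sprintf("shared identified metabolites: %d",
                length(pair$shared_identified)))
message("tables written under ", out)
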