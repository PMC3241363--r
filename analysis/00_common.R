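# shared helpers for the analysis drivers: argument parsing and provenance
suppressPackageStartupMessages({
  library(rametab)
  library(jsonlite)
})

parse_args <- function(defaults = list(seed = 1, out = "results")) {
  if (requireNamespace("optparse", quietly = TRUE)) {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--seed", type = "integer", default = defaults$seed),
      optparse::make_option("--out", type = "character", default = defaults$out)
    )))
    opts[c("seed", "out")]
  } else {
    args <- commandArgs(trailingOnly = TRUE)
    get <- function(flag, default) {
      i <- which(args == flag)
      if (length(i)) args[i + 1] else default
    }
    list(seed = as.integer(get("--seed", defaults$seed)),
         out = get("--out", defaults$out))
  }
}

# every driver writes the resolved configuration next to its outputs so a run
# is reproducible from the artefacts alone
write_provenance <- function(dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config[!vapply(config, is.function, logical(1))]
  jsonlite::write_json(cfg, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
}
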