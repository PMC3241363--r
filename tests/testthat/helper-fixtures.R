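# small programmatic fixtures

toy_table <- function(n = 3, K = 2, seed = 1, identified = NULL) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n * K, 5, 1)), n, K,
              dimnames = list(sprintf("S%d", 1:n), sprintf("M%d", 1:K)))
  feature_table(x, identified = identified)
}

toy_meta <- function(table, groups) {
  sample_meta(sample_ids(table), groups)
}

# a small-but-realistic generator config used where the full design would be
# wasteful
small_config <- function(...) {
  sim_config(n_ra = 8, n_control = 6, n_psoa = 6,
             n_metabolites = 40, n_identified = 30,
             n_shared_second_study = 28,
             n_ra_second = 6, n_control_second = 8,
             n_metabolites_second = 36, n_identified_second = 29,
             ...)
}
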