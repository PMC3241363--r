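#' Planted group-effect catalogue for the synthetic cohorts
#'
#' Returns the default set of planted markers: nine metabolites shifted in RA
#' relative to healthy controls (three increased, six decreased) and nineteen
#' shifted in RA relative to PsoA patients (ten increased, nine decreased),
#' with the direction each marker moves in RA. The reported two-sided P values
#' from the originating univariate screen are carried as metadata only; they
#' are never used as simulation targets. The shift magnitude is expressed in
#' natural-log units of intensity and defaults to 0.8 for every marker.
#'
#' @param magnitude log-scale mean shift applied to each planted marker.
#' @return `data.frame` with columns `metabolite_id`, `contrast`
#'   (`"RA_vs_CONTROL"` or `"RA_vs_PSOA"`), `direction` (`"increased"` /
#'   `"decreased"` in RA), `magnitude`, and `p_reported`.
#' @export
default_effects <- function(magnitude = 0.8) {
  stopifnot(is.numeric(magnitude), magnitude >= 0)
  ra_ctrl <- data.frame(
    metabolite_id = c("Glyceric acid", "D-ribofuranose", "Hypoxanthine",
                      "Histidine", "Threonic acid", "Methionine",
                      "Cholesterol", "Asparagine", "Threonine"),
    direction = c(rep("increased", 3), rep("decreased", 6)),
    p_reported = c(0.029436, 0.018080, 0.048579,
                   0.000109, 0.000784, 0.011428,
                   0.023463, 0.024166, 0.046816),
    stringsAsFactors = FALSE
  )
  ra_ctrl$contrast <- "RA_vs_CONTROL"
  ra_psoa <- data.frame(
    metabolite_id = c("Glutamine", "Heptanoic acid", "Succinate",
                      "Pseudouridine", "Inosine", "Guanosine", "Arabitol",
                      "Cystine", "Cysteine", "Phosphoric acid",
                      "Aspartic acid", "Glutamic acid", "Glutamate",
                      "Histidine", "Serine", "Arachidonic acid",
                      "Cholesterol", "Threonic acid", "1-Monooleoylglycerol"),
    direction = c(rep("increased", 10), rep("decreased", 9)),
    p_reported = c(0.030049, 0.008232, 0.005375, 0.030814, 0.032232,
                   0.023726, 0.004232, 0.009069, 0.000118, 0.010883,
                   0.000090, 0.000248, 0.001000, 0.007315, 0.008824,
                   0.038373, 0.027836, 0.002215, 0.002369),
    stringsAsFactors = FALSE
  )
  ra_psoa$contrast <- "RA_vs_PSOA"
  eff <- rbind(ra_ctrl, ra_psoa)
  eff$magnitude <- magnitude
  eff[, c("metabolite_id", "contrast", "direction", "magnitude", "p_reported")]
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design the pipeline targets: 21 RA / 9 control /
#' 17 PsoA samples with complete data, 267 putative metabolites of which 83
#' carry positive identifications, and a second (validation) cohort of
#' 14 RA / 20 controls with 240 putative metabolites sharing exactly 52
#' identified names with the first.
#'
#' @param n_ra,n_control,n_psoa group sizes of the first cohort. `n_psoa = 0`
#'   drops the PsoA arm; any present group needs at least 2 samples.
#' @param n_metabolites,n_identified number of putative metabolites and how
#'   many of them are identified (planted markers are always identified).
#' @param n_shared_second_study number of identified metabolite names common
#'   to both studies of a [generate_study_pair()] call.
#' @param effects planted marker catalogue, as from [default_effects()];
#'   `NULL` plants nothing.
#' @param nuisance_sd standard deviation of the per-sample nuisance latent
#'   (orthogonal variation: sex, age, sampling, experimental issues).
#' @param noise_sd standard deviation of the residual log-scale noise.
#' @param baseline_log_mean,baseline_log_sd distribution of per-metabolite
#'   baseline log intensities, drawn once per generator call.
#' @param missing_rate probability that an entry is missing at random
#'   (0 disables missingness).
#' @param n_ra_second,n_control_second,n_metabolites_second,n_identified_second
#'   design of the second study used by [generate_study_pair()].
#' @param seed integer seed making every draw reproducible.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_ra = 21, n_control = 9, n_psoa = 17,
                       n_metabolites = 267, n_identified = 83,
                       n_shared_second_study = 52,
                       effects = default_effects(),
                       nuisance_sd = 0.5, noise_sd = 0.3,
                       baseline_log_mean = 5, baseline_log_sd = 1,
                       missing_rate = 0,
                       n_ra_second = 14, n_control_second = 20,
                       n_metabolites_second = 240, n_identified_second = 58,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_ra, cfg$n_control, cfg$n_psoa,
              cfg$n_ra_second, cfg$n_control_second)
  if (any(counts < 0)) stop("group sizes must be non-negative")
  if (any(counts > 0 & counts < 2))
    stop("every generated group needs at least 2 samples")
  if (cfg$n_ra < 2 || cfg$n_control < 2)
    stop("the RA and control groups of the first study are required")
  if (!(cfg$n_shared_second_study <= cfg$n_identified &&
        cfg$n_identified <= cfg$n_metabolites))
    stop("need n_shared_second_study <= n_identified <= n_metabolites")
  if (cfg$n_shared_second_study > cfg$n_identified_second ||
      cfg$n_identified_second > cfg$n_metabolites_second)
    stop("need n_shared_second_study <= n_identified_second <= n_metabolites_second")
  if (cfg$nuisance_sd < 0 || cfg$noise_sd < 0)
    stop("nuisance_sd and noise_sd must be non-negative")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (!is.null(cfg$effects)) {
    eff <- cfg$effects
    need <- c("metabolite_id", "contrast", "direction", "magnitude")
    if (!all(need %in% colnames(eff))) stop("malformed effects table")
    if (any(eff$magnitude < 0)) stop("effect magnitudes must be >= 0")
    if (!all(eff$contrast %in% c("RA_vs_CONTROL", "RA_vs_PSOA")))
      stop("unknown contrast in effects table")
    if (!all(eff$direction %in% c("increased", "decreased")))
      stop("unknown direction in effects table")
    if (length(unique(eff$metabolite_id)) > cfg$n_identified)
      stop("more planted markers than identified metabolites")
  }
  invisible(cfg)
}

# run code with a private RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# metabolite naming: planted markers keep their compound names, the remaining
# identified metabolites are CPD-### (shared pool across studies), and
# unidentified features get a study-specific U<study>-### tag.
metabolite_catalog <- function(cfg, study_tag = "1",
                               n_metabolites = cfg$n_metabolites,
                               n_identified = cfg$n_identified,
                               shared_cpd = NULL) {
  planted <- if (is.null(cfg$effects)) character(0) else
    unique(cfg$effects$metabolite_id)
  n_cpd <- n_identified - length(planted)
  if (n_cpd < 0) stop("more planted markers than identified metabolites")
  cpd <- if (is.null(shared_cpd)) sprintf("CPD-%03d", seq_len(n_cpd))
         else shared_cpd
  stopifnot(length(cpd) == n_cpd)
  n_unid <- n_metabolites - n_identified
  unid <- if (n_unid > 0) sprintf("U%s-%03d", study_tag, seq_len(n_unid))
          else character(0)
  ids <- c(planted, cpd, unid)
  data.frame(metabolite_id = ids,
             identified = c(rep(TRUE, n_identified), rep(FALSE, n_unid)),
             stringsAsFactors = FALSE)
}

# per-group mean shift on the log scale for each metabolite: controls sit at
# the baseline, RA is moved by the RA-vs-control effects, and PsoA sits at the
# RA level minus the RA-vs-PsoA effects, so that each pairwise contrast
# differs exactly by its own planted markers.
effect_shifts <- function(ids, effects) {
  d_ra <- stats::setNames(numeric(length(ids)), ids)
  d_psoa <- d_ra
  if (!is.null(effects) && nrow(effects)) {
    sgn <- ifelse(effects$direction == "increased", 1, -1) * effects$magnitude
    ec <- effects$contrast == "RA_vs_CONTROL"
    for (i in which(ec)) d_ra[effects$metabolite_id[i]] <-
      d_ra[effects$metabolite_id[i]] + sgn[i]
    for (i in which(!ec)) d_psoa[effects$metabolite_id[i]] <-
      d_psoa[effects$metabolite_id[i]] - sgn[i]
    d_psoa <- d_psoa + d_ra
  }
  list(RA = d_ra, CONTROL = stats::setNames(numeric(length(ids)), ids),
       PSOA = d_psoa)
}

#' Generate a synthetic serum-metabolome cohort
#'
#' Log intensities follow a log-normal abundance model: for sample \eqn{i} and
#' metabolite \eqn{k},
#' \deqn{\log x_{ik} = \mu_k + \delta_{g(i),k} + \lambda_k z_i + \varepsilon_{ik},}
#' where \eqn{\mu_k} is a metabolite baseline drawn once per call,
#' \eqn{\delta_{g,k}} is the planted group shift (controls at baseline, RA
#' moved by the RA-vs-control effects, PsoA at the RA level minus the
#' RA-vs-PsoA effects), \eqn{z_i} is a rank-1 nuisance latent shared by all
#' metabolites with loadings \eqn{\lambda_k}, and
#' \eqn{\varepsilon_{ik} \sim N(0, \sigma^2)} is residual noise. The latent
#' \eqn{z} is residualised against the group factor so the nuisance is
#' orthogonal variation in the strict sense: it never carries class
#' information, on any subset of groups. Sex and age covariates are derived
#' from \eqn{z} so the nuisance has a concrete interpretation. Intensities are
#' returned on the natural (exponentiated) scale.
#'
#' @param config a [sim_config()]
#' @param study study id written into the metadata.
#' @param seed overrides `config$seed`.
#' @param second_study generate with the second-study design (group sizes,
#'   metabolite counts) of `config`.
#' @param baselines optional named vector fixing \eqn{\mu_k} for a subset of
#'   metabolites (used to share baselines between the studies of a pair).
#' @return list with `table` (a [feature_table()]) and `meta`.
#' @export
generate_cohort <- function(config, study = "study1", seed = config$seed,
                            second_study = FALSE, baselines = NULL) {
  validate_sim_config(config)
  with_seed(seed, {
    if (second_study) {
      sizes <- c(RA = config$n_ra_second, CONTROL = config$n_control_second,
                 PSOA = 0)
      cat_df <- metabolite_catalog(
        config, study_tag = "2",
        n_metabolites = config$n_metabolites_second,
        n_identified = config$n_identified_second
      )
    } else {
      sizes <- c(RA = config$n_ra, CONTROL = config$n_control,
                 PSOA = config$n_psoa)
      cat_df <- metabolite_catalog(config)
    }
    sizes <- sizes[sizes > 0]
    group <- rep(names(sizes), sizes)
    n <- length(group)
    ids <- cat_df$metabolite_id
    K <- length(ids)

    mu <- stats::rnorm(K, config$baseline_log_mean, config$baseline_log_sd)
    names(mu) <- ids
    if (!is.null(baselines)) {
      fix <- intersect(names(baselines), ids)
      mu[fix] <- baselines[fix]
    }
    lambda <- stats::rnorm(K)
    z <- stats::rnorm(n, 0, config$nuisance_sd)
    z <- z - stats::ave(z, group)        # orthogonal to every group contrast

    shifts <- effect_shifts(ids, config$effects)
    delta <- do.call(rbind, lapply(group, function(g) shifts[[g]]))

    logx <- matrix(mu, n, K, byrow = TRUE) + delta + outer(z, lambda) +
      matrix(stats::rnorm(n * K, 0, config$noise_sd), n, K)
    x <- exp(logx)
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(n * K) < config$missing_rate, n, K)
      # never blank out a whole metabolite
      full <- colSums(!mask) == 0
      mask[1, full] <- FALSE
      x[mask] <- NA_real_
    }
    sid <- sprintf("%s_%s_%02d", study, group, stats::ave(seq_len(n), group,
                                                          FUN = seq_along))
    dimnames(x) <- list(sid, ids)

    platform <- sample(c("GC", "LC"), K, replace = TRUE, prob = c(0.6, 0.4))
    meta <- sample_meta(
      sid, group, study = study,
      sex = ifelse(z > 0, "F", "M"),
      age = round(52 + 8 * z / max(config$nuisance_sd, 1e-8) +
                    stats::rnorm(n, 0, 4))
    )
    list(table = feature_table(x, identified = cat_df$identified,
                               platform = platform),
         meta = meta)
  })
}

#' Generate a linked pair of studies for external validation
#'
#' Both cohorts share the planted effect model and the baselines of their
#' shared metabolites, but have independent noise and nuisance draws. The
#' identified metabolite sets overlap in exactly
#' `config$n_shared_second_study` names (the planted markers plus the first
#' shared compounds); the second study additionally carries its own
#' identified and unidentified features.
#'
#' @param config a [sim_config()]
#' @return a `study_pair` (see [intersect_studies()]) whose `meta_a`,
#'   `meta_b` elements hold the two cohorts' metadata.
#' @export
generate_study_pair <- function(config) {
  validate_sim_config(config)
  planted <- if (is.null(config$effects)) character(0) else
    unique(config$effects$metabolite_id)
  n_shared_cpd <- config$n_shared_second_study - length(planted)
  if (n_shared_cpd < 0)
    stop("n_shared_second_study smaller than the number of planted markers")

  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, 3))
  shared_cpd <- sprintf("CPD-%03d", seq_len(n_shared_cpd))
  shared_ids <- c(planted, shared_cpd)
  shared_mu <- with_seed(seeds[1], {
    stats::setNames(stats::rnorm(length(shared_ids), config$baseline_log_mean,
                                 config$baseline_log_sd), shared_ids)
  })

  a <- generate_cohort(config, study = "study1", seed = seeds[2],
                       baselines = shared_mu)
  # second-study catalogue: shared identified names first, then its own
  cfg_b <- config
  n_own_ident <- config$n_identified_second - config$n_shared_second_study
  b <- with_seed(seeds[3], {
    cat_b <- data.frame(
      metabolite_id = c(
        shared_ids,
        if (n_own_ident > 0) sprintf("CPD2-%03d", seq_len(n_own_ident)),
        sprintf("U2-%03d",
                seq_len(config$n_metabolites_second - config$n_identified_second))
      ),
      identified = c(rep(TRUE, config$n_identified_second),
                     rep(FALSE,
                         config$n_metabolites_second - config$n_identified_second)),
      stringsAsFactors = FALSE
    )
    generate_cohort_with_catalog(cfg_b, cat_b, study = "study2",
                                 baselines = shared_mu)
  })
  intersect_studies(a$table, b$table, meta_a = a$meta, meta_b = b$meta)
}

# second-study generation shares the intensity model of generate_cohort but
# uses an explicit catalogue; runs inside the caller's seeded stream.
generate_cohort_with_catalog <- function(config, cat_df, study, baselines) {
  sizes <- c(RA = config$n_ra_second, CONTROL = config$n_control_second)
  sizes <- sizes[sizes > 0]
  group <- rep(names(sizes), sizes)
  n <- length(group)
  ids <- cat_df$metabolite_id
  K <- length(ids)
  mu <- stats::rnorm(K, config$baseline_log_mean, config$baseline_log_sd)
  names(mu) <- ids
  fix <- intersect(names(baselines), ids)
  mu[fix] <- baselines[fix]
  lambda <- stats::rnorm(K)
  z <- stats::rnorm(n, 0, config$nuisance_sd)
  z <- z - stats::ave(z, group)
  shifts <- effect_shifts(ids, config$effects)
  delta <- do.call(rbind, lapply(group, function(g) shifts[[g]]))
  logx <- matrix(mu, n, K, byrow = TRUE) + delta + outer(z, lambda) +
    matrix(stats::rnorm(n * K, 0, config$noise_sd), n, K)
  x <- exp(logx)
  sid <- sprintf("%s_%s_%02d", study, group,
                 stats::ave(seq_len(n), group, FUN = seq_along))
  dimnames(x) <- list(sid, ids)
  platform <- sample(c("GC", "LC"), K, replace = TRUE, prob = c(0.6, 0.4))
  meta <- sample_meta(sid, group, study = study,
                      sex = ifelse(z > 0, "F", "M"),
                      age = round(52 + 8 * z / max(config$nuisance_sd, 1e-8) +
                                    stats::rnorm(n, 0, 4)))
  list(table = feature_table(x, identified = cat_df$identified,
                             platform = platform),
       meta = meta)
}
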