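#' Construct a feature table of metabolite intensities
#'
#' A feature table holds a samples-by-metabolites matrix of semiquantitative
#' intensities together with per-metabolite annotation: whether the metabolite
#' carries a positive identification and which analytical platform it was
#' measured on. Samples are always rows and metabolites columns; this
#' orientation is fixed throughout the package.
#'
#' @param intensities numeric matrix, samples in rows, metabolites in columns.
#'   Row names are sample ids, column names metabolite ids; both must be
#'   unique and non-empty. Entries are non-negative intensities or `NA`
#'   (missing measurements are carried explicitly, never as zero).
#' @param identified logical vector, one flag per metabolite, `TRUE` where the
#'   metabolite has a positive identification. Defaults to all `TRUE`.
#' @param platform character vector, one tag per metabolite (e.g. `"GC"`,
#'   `"LC"`). Defaults to `NA`.
#' @return An object of class `feature_table`.
#' @examples
#' x <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("His", "Met")))
#' ft <- feature_table(x, identified = c(TRUE, FALSE))
#' metabolite_ids(ft)
#' @export
feature_table <- function(intensities, identified = NULL, platform = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix (samples x metabolites)")
  sid <- rownames(intensities)
  mid <- colnames(intensities)
  if (is.null(sid) || is.null(mid))
    stop("`intensities` must carry sample ids as row names and metabolite ids as column names")
  if (anyDuplicated(sid)) stop("duplicate sample ids: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyDuplicated(mid)) stop("duplicate metabolite ids: ",
                               paste(unique(mid[duplicated(mid)]), collapse = ", "))
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  all_na <- colSums(!is.na(intensities)) == 0
  if (any(all_na))
    stop("metabolite(s) with no observed values: ",
         paste(mid[all_na], collapse = ", "))
  if (is.null(identified)) identified <- rep(TRUE, ncol(intensities))
  if (is.null(platform)) platform <- rep(NA_character_, ncol(intensities))
  stopifnot(length(identified) == ncol(intensities),
            length(platform) == ncol(intensities))
  identified <- as.logical(identified)
  if (anyNA(identified)) stop("`identified` flags must be TRUE/FALSE")
  names(identified) <- mid
  platform <- as.character(platform)
  names(platform) <- mid
  structure(
    list(intensities = intensities, identified = identified, platform = platform),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d metabolites (%d identified)\n",
              nrow(x$intensities), ncol(x$intensities), sum(x$identified)))
  invisible(x)
}

#' Sample and metabolite ids of a feature table
#' @param x a `feature_table`
#' @return character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$intensities)

#' @rdname sample_ids
#' @export
metabolite_ids <- function(x) colnames(x$intensities)

#' Build and validate a sample metadata table
#'
#' @param sample_id character vector of unique sample ids.
#' @param group group labels, one of `"RA"`, `"CONTROL"`, `"PSOA"`.
#' @param study study identifier (recycled if scalar).
#' @param sex,age optional nuisance covariates.
#' @return A `data.frame` with validated columns.
#' @export
sample_meta <- function(sample_id, group, study = "study1",
                        sex = NA_character_, age = NA_real_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  group <- toupper(as.character(group))
  bad <- setdiff(unique(group), group_levels())
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected RA, CONTROL or PSOA)")
  data.frame(
    sample_id = sample_id,
    group = factor(group, levels = group_levels()),
    study = rep_len(as.character(study), length(sample_id)),
    sex = rep_len(as.character(sex), length(sample_id)),
    age = rep_len(as.numeric(age), length(sample_id)),
    stringsAsFactors = FALSE
  )
}

group_levels <- function() c("RA", "CONTROL", "PSOA")

#' Check that a metadata table covers a feature table
#'
#' Every sample of the feature table must have exactly one metadata row. The
#' metadata is returned re-ordered to the feature table's sample order.
#'
#' @param table a `feature_table`
#' @param meta a metadata `data.frame` as from [sample_meta()]
#' @return the metadata aligned to `table`'s samples.
#' @export
align_meta <- function(table, meta) {
  stopifnot(inherits(table, "feature_table"), is.data.frame(meta))
  idx <- match(sample_ids(table), meta$sample_id)
  if (anyNA(idx)) {
    missing <- sample_ids(table)[is.na(idx)]
    stop("no metadata for sample(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  meta[idx, , drop = FALSE]
}

#' Restrict a feature table to a subset of samples or metabolites
#'
#' @param table a `feature_table`
#' @param samples,metabolites character vectors of ids to keep (order is the
#'   order given). `NULL` keeps everything.
#' @return a `feature_table`.
#' @export
subset_table <- function(table, samples = NULL, metabolites = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(x))
    if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    x <- x[samples, , drop = FALSE]
  }
  if (!is.null(metabolites)) {
    miss <- setdiff(metabolites, colnames(x))
    if (length(miss)) stop("unknown metabolite id(s): ", paste(miss, collapse = ", "))
    x <- x[, metabolites, drop = FALSE]
  }
  feature_table(x, table$identified[colnames(x)], table$platform[colnames(x)])
}

#' Keep the samples belonging to given groups
#'
#' @param table a `feature_table`
#' @param meta metadata covering `table`
#' @param groups character vector of group labels to keep
#' @return list with the restricted `table` and aligned `meta`.
#' @export
subset_groups <- function(table, meta, groups) {
  meta <- align_meta(table, meta)
  keep <- meta$sample_id[meta$group %in% groups]
  if (!length(keep)) stop("no samples in group(s): ", paste(groups, collapse = ", "))
  list(table = subset_table(table, samples = keep),
       meta = droplevels(meta[meta$sample_id %in% keep, , drop = FALSE]))
}

#' Keep only positively identified metabolites
#'
#' Mirrors the reporting convention of presenting identified metabolites only:
#' the returned sub-table contains exactly the metabolites flagged as
#' identified, with the sample set unchanged.
#'
#' @param table a `feature_table`
#' @return a `feature_table` with only identified metabolites.
#' @export
select_identified <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  keep <- metabolite_ids(table)[table$identified]
  if (!length(keep)) stop("no identified metabolites in table")
  subset_table(table, metabolites = keep)
}

# Matching key for cross-study metabolite identity: exact name after trimming
# and case folding. No synonym or fuzzy matching.
match_key <- function(ids) tolower(trimws(ids))

#' Intersect the identified metabolites of two studies
#'
#' Cross-study validation requires the variables of both studies to be
#' identical, so the two tables are matched on their identified metabolite
#' names (trimmed, case-insensitive) and the shared set is ordered
#' alphabetically. The pair keeps the full tables; [aligned_tables()] gives
#' the two sub-tables restricted to the shared metabolites in a common column
#' order.
#'
#' @param a,b `feature_table`s from the two studies.
#' @param meta_a,meta_b optional metadata carried along with the pair.
#' @return an object of class `study_pair` with elements `table_a`, `table_b`,
#'   `shared_identified` (ids as spelled in `a`), `meta_a`, `meta_b`.
#' @export
intersect_studies <- function(a, b, meta_a = NULL, meta_b = NULL) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  ia <- metabolite_ids(a)[a$identified]
  ib <- metabolite_ids(b)[b$identified]
  ka <- match_key(ia); kb <- match_key(ib)
  shared_keys <- intersect(ka, kb)
  if (!length(shared_keys))
    stop("the identified metabolite sets of the two studies are disjoint")
  shared <- ia[match(shared_keys, ka)]
  shared <- shared[order(match_key(shared))]
  structure(
    list(table_a = a, table_b = b, shared_identified = shared,
         meta_a = meta_a, meta_b = meta_b),
    class = "study_pair"
  )
}

#' @export
print.study_pair <- function(x, ...) {
  cat(sprintf("<study_pair> %d x %d and %d x %d; %d shared identified metabolites\n",
              nrow(x$table_a$intensities), ncol(x$table_a$intensities),
              nrow(x$table_b$intensities), ncol(x$table_b$intensities),
              length(x$shared_identified)))
  invisible(x)
}

#' Sub-tables of a study pair aligned on the shared identified metabolites
#'
#' @param pair a `study_pair`
#' @return list of two `feature_table`s with identical column order.
#' @export
aligned_tables <- function(pair) {
  stopifnot(inherits(pair, "study_pair"))
  ids_a <- pair$shared_identified
  key <- match_key(ids_a)
  ids_b <- metabolite_ids(pair$table_b)
  ids_b <- ids_b[match(key, match_key(ids_b))]
  ta <- subset_table(pair$table_a, metabolites = ids_a)
  tb <- subset_table(pair$table_b, metabolites = ids_b)
  # present the b-side under the a-side spelling so columns align exactly
  colnames(tb$intensities) <- ids_a
  names(tb$identified) <- ids_a
  names(tb$platform) <- ids_a
  list(table_a = ta, table_b = tb)
}
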