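#' Standard scores against a reference group
#'
#' For every sample (reference group included), each metabolite value is
#' centred by the reference group's mean and divided by the reference group's
#' sample standard deviation (n - 1 denominator):
#' `z = (x - mean_ref) / sd_ref`. Scores are computed on raw intensities,
#' independent of any model scaling, so they read as relative concentration
#' versus the reference mean. A metabolite with zero reference SD gets z = 0
#' with a warning.
#'
#' @param table a `feature_table`
#' @param meta metadata covering `table`
#' @param reference reference group (default `"CONTROL"`; use `"PSOA"` for
#'   the RA-versus-PsoA display convention).
#' @return numeric matrix, samples x metabolites.
#' @export
standard_scores <- function(table, meta, reference = "CONTROL") {
  stopifnot(inherits(table, "feature_table"))
  meta <- align_meta(table, meta)
  ref <- meta$group == reference
  if (sum(ref) < 2)
    stop("reference group ", reference, " needs at least 2 samples")
  X <- table$intensities
  m <- colMeans(X[ref, , drop = FALSE], na.rm = TRUE)
  s <- apply(X[ref, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  zero <- s == 0
  z <- sweep(X, 2, m)
  if (any(zero)) {
    warning("zero reference SD, z set to 0 for: ",
            paste(colnames(X)[zero], collapse = ", "))
    z[, zero] <- 0
    s[zero] <- 1
  }
  sweep(z, 2, s, "/")
}

#' Clamp standard scores for display
#'
#' @param z numeric matrix (or vector) of standard scores.
#' @param limit truncation limit (> 0; default 2, the usual display window).
#' @return `z` with every entry clamped to `[-limit, limit]`.
#' @export
truncate_scores <- function(z, limit = 2) {
  stopifnot(is.numeric(limit), limit > 0)
  pmin(pmax(z, -limit), limit)
}

#' Heat-map matrix of truncated standard scores, ordered by p(corr)
#'
#' Builds the matrix behind the metabolic-pattern heat maps: standard scores
#' against the reference group, truncated for display, with samples grouped
#' by class (reference group first) and metabolites sorted by their
#' correlation to the positive class from the largest negative to the largest
#' positive p(corr). By default only identified metabolites are shown.
#'
#' @param table a `feature_table`
#' @param meta metadata covering `table`
#' @param model the fitted `oplsda` model of the same contrast (its p(corr)
#'   values order the columns).
#' @param reference reference group for the scores.
#' @param limit truncation limit.
#' @param identified_only restrict to identified metabolites (default TRUE).
#' @return object of class `heatmap_matrix`: `z` (ordered, truncated),
#'   `pcorr` (in column order), `row_groups`, `limit`.
#' @export
build_heatmap <- function(table, meta, model, reference = "CONTROL",
                          limit = 2, identified_only = TRUE) {
  stopifnot(inherits(model, "oplsda"))
  meta <- align_meta(table, meta)
  pc <- pcorr(model)
  if (identified_only) table <- select_identified(table)
  ids <- intersect(metabolite_ids(table), names(pc))
  if (!length(ids)) stop("model and table share no metabolites")
  table <- subset_table(table, metabolites = ids)
  z <- standard_scores(table, meta, reference = reference)
  ord <- ids[order(pc[ids])]               # largest negative -> largest positive
  z <- truncate_scores(z[, ord, drop = FALSE], limit)
  row_ord <- order(meta$group != reference) # reference block first
  z <- z[meta$sample_id[row_ord], , drop = FALSE]
  structure(
    list(z = z, pcorr = pc[ord],
         row_groups = as.character(meta$group[row_ord]), limit = limit),
    class = "heatmap_matrix"
  )
}

#' Render a heat-map matrix (optional, needs pheatmap)
#'
#' @param hm a `heatmap_matrix` from [build_heatmap()]
#' @param filename optional output file passed to `pheatmap`.
#' @param ... further arguments to `pheatmap::pheatmap`.
#' @return the pheatmap object, invisibly.
#' @export
plot_heatmap <- function(hm, filename = NA, ...) {
  stopifnot(inherits(hm, "heatmap_matrix"))
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_heatmap needs the pheatmap package")
  ann <- data.frame(group = hm$row_groups, row.names = rownames(hm$z))
  p <- pheatmap::pheatmap(
    hm$z, cluster_rows = FALSE, cluster_cols = FALSE,
    annotation_row = ann,
    breaks = seq(-hm$limit, hm$limit, length.out = 101),
    filename = filename, ...
  )
  invisible(p)
}

#' Per-metabolite univariate report for a two-group contrast
#'
#' Two-sided Student's t-tests for samples with equal variance (pooled
#' variance), one per metabolite on raw intensities, with group means and
#' SDs, the direction of change in the first group relative to the second,
#' and the model's p(corr) when a fitted model is supplied. No correction for
#' multiple testing is applied; P values illustrate the impact of each
#' metabolite individually. A metabolite with zero pooled variance gets
#' t = 0, p = 1 with a warning.
#'
#' @param table a `feature_table`
#' @param meta metadata covering `table`
#' @param group_a first group (the disease group; default `"RA"`).
#' @param group_b reference group (default `"CONTROL"`).
#' @param model optional `oplsda` model providing p(corr).
#' @param identified_only report identified metabolites only (default TRUE).
#' @param alpha significance threshold for the `significant` flag.
#' @return `data.frame` with one row per metabolite: `metabolite_id`,
#'   `pcorr`, `mean_ra`, `sd_ra`, `mean_ref`, `sd_ref`, `t_stat`, `p_value`,
#'   `direction`, `significant`.
#' @export
ttest_table <- function(table, meta, group_a = "RA", group_b = "CONTROL",
                        model = NULL, identified_only = TRUE, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (identified_only) table <- select_identified(table)
  meta <- align_meta(table, meta)
  ia <- meta$group == group_a
  ib <- meta$group == group_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("both groups need at least 2 samples")
  X <- table$intensities
  pc <- if (!is.null(model)) pcorr(model)

  res <- lapply(colnames(X), function(k) {
    a <- X[ia, k]; b <- X[ib, k]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (stats::var(a) + stats::var(b) == 0) {
      warning("zero pooled variance for ", k, "; t = 0, p = 1")
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    data.frame(
      metabolite_id = k,
      pcorr = if (!is.null(pc) && k %in% names(pc)) unname(pc[k]) else NA_real_,
      mean_ra = mean(a), sd_ra = stats::sd(a),
      mean_ref = mean(b), sd_ref = stats::sd(b),
      t_stat = unname(tt$statistic), p_value = tt$p.value,
      direction = if (mean(a) > mean(b)) "increased" else "decreased",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < alpha
  out
}

#' Partition a univariate report into increased/decreased sections
#'
#' Renders the report in the style of a concentration-difference table:
#' significant metabolites (p below `alpha`, uncorrected) split into
#' increased and decreased sections, each sorted by ascending P value.
#'
#' @param reports a `data.frame` from [ttest_table()]
#' @param alpha significance threshold (default 0.05).
#' @return object of class `table1_report` with `increased` and `decreased`
#'   data frames and the `alpha` used.
#' @export
render_table1 <- function(reports, alpha = 0.05) {
  stopifnot(is.data.frame(reports))
  sig <- reports[reports$p_value < alpha, , drop = FALSE]
  up <- sig[sig$direction == "increased", , drop = FALSE]
  down <- sig[sig$direction == "decreased", , drop = FALSE]
  structure(
    list(increased = up[order(up$p_value), , drop = FALSE],
         decreased = down[order(down$p_value), , drop = FALSE],
         alpha = alpha),
    class = "table1_report"
  )
}

#' @export
print.table1_report <- function(x, ...) {
  fmt <- function(df, label) {
    cat(label, "\n")
    if (!nrow(df)) { cat("  (none)\n"); return(invisible()) }
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-24s %8.6f\n", df$metabolite_id[i], df$p_value[i]))
  }
  cat(sprintf("Metabolites at P < %g (uncorrected)\n", x$alpha))
  fmt(x$increased, "Increased")
  fmt(x$decreased, "Decreased")
  invisible(x)
}
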