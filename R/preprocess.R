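#' Half-minimum imputation of missing intensities
#'
#' Missing entries are replaced column-wise by half the smallest observed
#' value of that metabolite, the conventional rule for values below the
#' detection limit. When `half_min` is supplied (the training half-minima of
#' a fitted scaler) those values are used instead of recomputing them, so
#' held-out data are imputed with training parameters only.
#'
#' @param X numeric matrix, samples x metabolites.
#' @param half_min optional named vector of per-metabolite half-minima.
#' @return the matrix with no missing entries.
#' @export
impute_missing <- function(X, half_min = NULL) {
  stopifnot(is.matrix(X))
  if (!anyNA(X)) return(X)
  if (is.null(half_min)) {
    obs <- colSums(!is.na(X))
    if (any(obs == 0))
      stop("metabolite(s) with no observed values: ",
           paste(colnames(X)[obs == 0], collapse = ", "))
    half_min <- apply(X, 2, min, na.rm = TRUE) / 2
  }
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- half_min[j]
  }
  X
}

#' Fit a centering/scaling transform on training data
#'
#' Computes per-metabolite centers and scales on the training matrix only:
#' unit-variance (`"uv"`, centre by the mean and divide by the sample SD),
#' pareto (divide by the square root of the SD) or centring only. An optional
#' natural-log transform precedes the statistics; it requires strictly
#' positive data. Missing values are imputed by the half-minimum rule before
#' anything else, and the training half-minima are stored so that held-out
#' data are treated identically. Metabolites with zero training variance get
#' scale 1 with a warning.
#'
#' @param X training intensity matrix (samples x metabolites, named columns).
#' @param mode `"uv"`, `"pareto"` or `"center_only"`.
#' @param log apply `log()` before centring/scaling.
#' @return an object of class `met_scaler`.
#' @export
fit_scaler <- function(X, mode = c("uv", "pareto", "center_only"), log = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(X), nrow(X) >= 2)
  if (is.null(colnames(X))) stop("X must have metabolite ids as column names")
  obs <- colSums(!is.na(X))
  if (any(obs == 0))
    stop("metabolite(s) with no observed values: ",
         paste(colnames(X)[obs == 0], collapse = ", "))
  half_min <- apply(X, 2, function(v) min(v, na.rm = TRUE) / 2)
  X <- impute_missing(X, half_min)
  if (log) {
    if (any(X <= 0)) stop("log transform requires strictly positive intensities")
    X <- base::log(X)
  }
  center <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  zero <- s == 0
  if (any(zero)) {
    warning("zero-variance metabolite(s), scale set to 1: ",
            paste(colnames(X)[zero], collapse = ", "))
    s[zero] <- 1
  }
  scale <- switch(mode, uv = s, pareto = sqrt(s),
                  center_only = rep(1, length(s)))
  scale[scale == 0] <- 1
  structure(
    list(center = center, scale = stats::setNames(scale, colnames(X)),
         mode = mode, log = log,
         half_min = half_min, metabolite_ids = colnames(X)),
    class = "met_scaler"
  )
}

#' Apply a fitted scaler to (new) data
#'
#' Imputes with the training half-minima, applies the log transform if the
#' scaler was fitted with one, then `(x - center) / scale` per column. The
#' column set and order must match the training matrix exactly.
#'
#' @param scaler a `met_scaler` from [fit_scaler()]
#' @param X intensity matrix with the same columns as the training matrix.
#' @return the scaled matrix.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "met_scaler"), is.matrix(X))
  if (is.null(colnames(X)) || !identical(colnames(X), scaler$metabolite_ids))
    stop("column set/order of X does not match the fitted scaler")
  X <- impute_missing(X, scaler$half_min)
  if (scaler$log) {
    if (any(X <= 0)) stop("log transform requires strictly positive intensities")
    X <- base::log(X)
  }
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Invert a scaler transform
#'
#' Maps a scaled matrix back to the (possibly imputed) intensity scale:
#' `x * scale + center`, then `exp()` if the scaler log-transformed.
#'
#' @param scaler a `met_scaler`
#' @param Xs scaled matrix as produced by [apply_scaler()].
#' @return matrix on the original intensity scale.
#' @export
invert_scaler <- function(scaler, Xs) {
  stopifnot(inherits(scaler, "met_scaler"), is.matrix(Xs))
  if (is.null(colnames(Xs)) || !identical(colnames(Xs), scaler$metabolite_ids))
    stop("column set/order of Xs does not match the fitted scaler")
  X <- sweep(sweep(Xs, 2, scaler$scale, "*"), 2, scaler$center, "+")
  if (scaler$log) X <- exp(X)
  X
}
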