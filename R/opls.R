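#' Encode a two-class contrast as a binary response
#'
#' Builds the +1/-1 response for a discriminant model: the positive class
#' (by convention the RA patients, kept at positive values for visual
#' clarity) is coded +1, the other class -1. The training mean of the
#' response (`y_center`) doubles as the decision threshold of the fitted
#' model.
#'
#' @param labels vector of group labels with exactly two distinct values.
#' @param positive the label coded +1.
#' @return object of class `class_coding`: `positive`, `negative`, `y`,
#'   `y_center`.
#' @export
encode_classes <- function(labels, positive) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2)
    stop("need exactly two distinct groups, got: ", paste(lev, collapse = ", "))
  if (!positive %in% lev)
    stop("positive class '", positive, "' absent from labels")
  y <- ifelse(labels == positive, 1, -1)
  structure(
    list(positive = positive, negative = setdiff(lev, positive),
         y = y, y_center = mean(y)),
    class = "class_coding"
  )
}

#' Fit a single-response OPLS model by NIPALS
#'
#' Splits the predictor variation into one predictive component (correlated
#' with the response) and `n_orth` orthogonal components (uncorrelated with
#' it). Each orthogonal round computes the predictive weight
#' `w = X'y / y'y` (normalised), its score `t = Xw` and loading
#' `p = X't/t't`, extracts the orthogonal weight
#' `w_orth = p - (w'p)w` (normalised) with score `t_orth = X w_orth` and
#' loading `p_orth = X' t_orth / t_orth' t_orth`, and deflates
#' `X <- X - t_orth p_orth'`. The final predictive component is computed on
#' the filtered matrix, with response loading `c = t'y / t't`. All steps are
#' closed form; no convergence loop is needed for a single response.
#'
#' @param Xs column-centred (typically unit-variance scaled) predictor matrix.
#' @param y numeric response; it is centred internally and its mean stored as
#'   `y_center`. For discriminant use pass the +1/-1 coding of
#'   [encode_classes()].
#' @param n_orth number of orthogonal components (>= 0).
#' @return object of class `opls` with weights `w`, loadings `p`, response
#'   loading `c`, orthogonal weights/loadings/scores `W_orth`, `P_orth`,
#'   `T_orth`, predictive scores `t`, the filtered training matrix `Xf`,
#'   explained-variation fractions `r2x_pred`, `r2x_orth`, `r2y`, and
#'   `y_center`.
#' @export
fit_opls <- function(Xs, y, n_orth = 1) {
  stopifnot(is.matrix(Xs), is.numeric(y), length(y) == nrow(Xs))
  if (n_orth < 0) stop("n_orth must be >= 0")
  if (nrow(Xs) <= n_orth + 1)
    stop("need more samples than n_orth + 1")
  y_center <- mean(y)
  yc <- y - y_center
  if (sum(yc^2) < 1e-12) stop("response is constant")

  ss_total <- sum(Xs^2)
  X <- Xs
  W_orth <- matrix(0, ncol(Xs), 0)
  P_orth <- matrix(0, ncol(Xs), 0)
  T_orth <- matrix(0, nrow(Xs), 0)
  for (j in seq_len(n_orth)) {
    w <- drop(crossprod(X, yc)) / sum(yc^2)
    w <- w / l2norm(w)
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    w_orth <- p - sum(w * p) * w
    nrm <- l2norm(w_orth)
    if (nrm < 1e-12) {
      warning("no orthogonal variation left; stopping at ", j - 1, " components")
      break
    }
    w_orth <- w_orth / nrm
    t_orth <- drop(X %*% w_orth)
    p_orth <- drop(crossprod(X, t_orth)) / sum(t_orth^2)
    X <- X - tcrossprod(t_orth, p_orth)
    W_orth <- cbind(W_orth, w_orth)
    P_orth <- cbind(P_orth, p_orth)
    T_orth <- cbind(T_orth, t_orth)
  }
  w <- drop(crossprod(X, yc)) / sum(yc^2)
  w <- w / l2norm(w)
  t <- drop(X %*% w)
  p <- drop(crossprod(X, t)) / sum(t^2)
  cc <- sum(t * yc) / sum(t^2)

  ss_orth <- if (ncol(T_orth)) sum(vapply(seq_len(ncol(T_orth)), function(j)
    sum(T_orth[, j]^2) * sum(P_orth[, j]^2), numeric(1))) else 0
  ss_pred <- sum(t^2) * sum(p^2)
  model <- structure(
    list(w = stats::setNames(w, colnames(Xs)),
         p = stats::setNames(p, colnames(Xs)), c = cc,
         W_orth = W_orth, P_orth = P_orth,
         t = t, T_orth = T_orth, n_orth = ncol(T_orth),
         Xf = X, y_center = y_center,
         r2x_pred = ss_pred / ss_total,
         r2x_orth = ss_orth / ss_total,
         r2y = 1 - sum((yc - t * cc)^2) / sum(yc^2)),
    class = "opls"
  )
  model
}

l2norm <- function(v) sqrt(sum(v^2))

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("<opls> 1 predictive + %d orthogonal component(s); R2X(pred)=%.3f R2X(orth)=%.3f R2Y=%.3f\n",
              x$n_orth, x$r2x_pred, x$r2x_orth, x$r2y))
  invisible(x)
}

# score new (already scaled) rows: remove each fitted orthogonal component,
# then project on the predictive weight
opls_scores <- function(model, Xs_new) {
  T_orth_new <- matrix(0, nrow(Xs_new), model$n_orth)
  for (j in seq_len(model$n_orth)) {
    t_orth <- drop(Xs_new %*% model$W_orth[, j])
    Xs_new <- Xs_new - tcrossprod(t_orth, model$P_orth[, j])
    T_orth_new[, j] <- t_orth
  }
  list(t = drop(Xs_new %*% model$w), T_orth = T_orth_new)
}

#' Predict the response for scaled rows with a fitted `opls` model
#'
#' @param object an `opls` model
#' @param Xs_new scaled matrix with the training column order.
#' @param ... unused
#' @return list with `y_hat` (predicted response, on the original response
#'   scale), predictive scores `t` and orthogonal scores `T_orth`.
#' @export
predict.opls <- function(object, Xs_new, ...) {
  stopifnot(is.matrix(Xs_new), ncol(Xs_new) == length(object$w))
  sc <- opls_scores(object, Xs_new)
  list(y_hat = sc$t * object$c + object$y_center,
       t = sc$t, T_orth = sc$T_orth)
}

#' Fit an OPLS-DA diagnosis model on a feature table
#'
#' Convenience wrapper tying together preprocessing and the OPLS core: the
#' two-group subset is encoded as +1/-1, a scaler is fitted on the training
#' intensities (unit variance on log intensities by default), and an OPLS
#' model with `n_orth` orthogonal components is fitted. The decision
#' threshold is the training mean of the coded response; samples with a
#' predicted response at or above it are called positive.
#'
#' @param table a [feature_table()] containing exactly the samples to train on.
#' @param meta metadata covering `table`; exactly two groups must be present.
#' @param positive group coded +1 (default `"RA"`).
#' @param n_orth number of orthogonal components.
#' @param mode,log preprocessing options, see [fit_scaler()].
#' @return object of class `oplsda`: the core `opls` model plus `scaler`,
#'   `coding`, `threshold` and the training ids.
#' @export
fit_oplsda <- function(table, meta, positive = "RA", n_orth = 1,
                       mode = "uv", log = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  meta <- align_meta(table, meta)
  groups <- unique(as.character(meta$group))
  if (length(groups) != 2)
    stop("training data must contain exactly two groups, got: ",
         paste(groups, collapse = ", "))
  coding <- encode_classes(meta$group, positive)
  scaler <- fit_scaler(table$intensities, mode = mode, log = log)
  Xs <- apply_scaler(scaler, table$intensities)
  core <- fit_opls(Xs, coding$y, n_orth = n_orth)
  structure(
    list(core = core, scaler = scaler, coding = coding,
         threshold = coding$y_center,
         metabolite_ids = metabolite_ids(table),
         sample_ids = sample_ids(table)),
    class = "oplsda"
  )
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("<oplsda> %s (+1) vs %s (-1), %d training samples, %d metabolites\n",
              x$coding$positive, x$coding$negative,
              length(x$coding$y), length(x$metabolite_ids)))
  print(x$core)
  invisible(x)
}

#' Predict the diagnosis of new samples
#'
#' New raw intensities are scaled with the training scaler, the fitted
#' orthogonal variation is removed, and the predictive score is converted to
#' a predicted response. Samples at or above the decision threshold (the
#' training response mean; ties count as positive) are assigned the positive
#' class.
#'
#' @param object an `oplsda` model
#' @param newdata a `feature_table` or raw intensity matrix whose columns
#'   match the training metabolites.
#' @param ... unused
#' @return `data.frame` with `sample_id`, `y_hat`, `score` (predictive
#'   score), and `predicted` class label.
#' @export
predict.oplsda <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$intensities else newdata
  stopifnot(is.matrix(X))
  Xs <- apply_scaler(object$scaler, X)
  pr <- predict(object$core, Xs)
  predicted <- ifelse(pr$y_hat >= object$threshold,
                      object$coding$positive, object$coding$negative)
  data.frame(
    sample_id = rownames(X) %||% paste0("sample", seq_len(nrow(X))),
    y_hat = pr$y_hat, score = pr$t, predicted = predicted,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation loadings p(corr) of a fitted model
#'
#' p(corr) is the Pearson correlation between the predictive score vector and
#' each metabolite's column of the orthogonality-filtered training matrix: a
#' scale-free measure in [-1, 1] of how strongly each metabolite
#' discriminates the two classes. Metabolites whose filtered column has zero
#' variance get p(corr) 0 with a warning.
#'
#' @param model an `opls` or `oplsda` model.
#' @return named numeric vector, one value per metabolite.
#' @export
pcorr <- function(model) {
  if (inherits(model, "oplsda")) model <- model$core
  stopifnot(inherits(model, "opls"))
  Xf <- model$Xf
  sds <- apply(Xf, 2, stats::sd)
  out <- rep(0, ncol(Xf))
  ok <- sds > 0
  if (any(!ok))
    warning("zero-variance filtered column(s), p(corr) set to 0: ",
            paste(colnames(Xf)[!ok], collapse = ", "))
  out[ok] <- drop(stats::cor(Xf[, ok, drop = FALSE], model$t))
  stats::setNames(out, colnames(Xf))
}

#' Choose the number of orthogonal components by cross-validated Q2
#'
#' For each candidate count in `0..max_orth`, computes the k-fold
#' cross-validated Q2 = 1 - PRESS/SS(y) (training folds are re-centred;
#' the response of held-out rows is predicted with the fold model) and
#' returns the count with the largest Q2, ties resolved toward fewer
#' components.
#'
#' @param Xs scaled predictor matrix.
#' @param y numeric response (e.g. +1/-1 coding).
#' @param max_orth largest candidate count.
#' @param folds number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @return the selected count; the Q2 profile is attached as attribute `q2`.
#' @export
select_n_orth <- function(Xs, y, max_orth = 3, folds = 7, seed = 1) {
  stopifnot(max_orth >= 0)
  if (max_orth == 0) return(structure(0L, q2 = NA_real_))
  labels <- if (length(unique(y)) == 2) as.character(y) else
    rep("all", length(y))
  fold <- assign_folds(labels, k = folds, seed = seed,
                       stratify = length(unique(labels)) == 2)
  q2 <- vapply(0:max_orth, function(j) {
    press <- 0
    for (f in unique(fold)) {
      tr <- fold != f
      ctr <- colMeans(Xs[tr, , drop = FALSE])
      Xtr <- sweep(Xs[tr, , drop = FALSE], 2, ctr)
      Xte <- sweep(Xs[!tr, , drop = FALSE], 2, ctr)
      m <- fit_opls(Xtr, y[tr], n_orth = j)
      press <- press + sum((y[!tr] - predict(m, Xte)$y_hat)^2)
    }
    1 - press / sum((y - mean(y))^2)
  }, numeric(1))
  structure(as.integer(which.max(q2) - 1L), q2 = q2)
}

#' Serialize an OPLS-DA model to JSON
#'
#' Writes every quantity needed for refit-free prediction (weights, loadings,
#' scaler parameters, class coding, threshold) to a plain-text JSON file.
#'
#' @param model an `oplsda` model
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_oplsda <- function(model, path) {
  stopifnot(inherits(model, "oplsda"))
  core <- model$core
  obj <- list(
    metabolite_ids = model$metabolite_ids,
    w = unname(core$w), p = unname(core$p), c = core$c,
    W_orth = unname(as.matrix(core$W_orth)),
    P_orth = unname(as.matrix(core$P_orth)),
    n_orth = core$n_orth, y_center = core$y_center,
    r2x_pred = core$r2x_pred, r2x_orth = core$r2x_orth, r2y = core$r2y,
    scaler = list(center = unname(model$scaler$center),
                  scale = unname(model$scaler$scale),
                  half_min = unname(model$scaler$half_min),
                  mode = model$scaler$mode, log = model$scaler$log),
    coding = list(positive = model$coding$positive,
                  negative = model$coding$negative,
                  y_center = model$coding$y_center),
    threshold = model$threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an OPLS-DA model from JSON
#'
#' @param path file written by [write_oplsda()]
#' @return an `oplsda` model usable with [predict.oplsda()] (training scores
#'   and the filtered matrix are not stored, so [pcorr()] is unavailable on a
#'   deserialized model).
#' @export
read_oplsda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- obj$metabolite_ids
  as_mat <- function(m) {
    m <- as.matrix(m)
    if (length(m) == 0) matrix(0, length(ids), 0) else m
  }
  core <- structure(
    list(w = stats::setNames(obj$w, ids), p = stats::setNames(obj$p, ids),
         c = obj$c, W_orth = as_mat(obj$W_orth), P_orth = as_mat(obj$P_orth),
         t = NULL, T_orth = NULL, n_orth = obj$n_orth, Xf = NULL,
         y_center = obj$y_center, r2x_pred = obj$r2x_pred,
         r2x_orth = obj$r2x_orth, r2y = obj$r2y),
    class = "opls"
  )
  scaler <- structure(
    list(center = stats::setNames(obj$scaler$center, ids),
         scale = stats::setNames(obj$scaler$scale, ids),
         mode = obj$scaler$mode, log = obj$scaler$log,
         half_min = stats::setNames(obj$scaler$half_min, ids),
         metabolite_ids = ids),
    class = "met_scaler"
  )
  coding <- structure(
    list(positive = obj$coding$positive, negative = obj$coding$negative,
         y = NULL, y_center = obj$coding$y_center),
    class = "class_coding"
  )
  structure(
    list(core = core, scaler = scaler, coding = coding,
         threshold = obj$threshold, metabolite_ids = ids, sample_ids = NULL),
    class = "oplsda"
  )
}
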