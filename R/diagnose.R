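#' Assign cross-validation folds
#'
#' By default folds are stratified by class: within each class, shuffled
#' samples are dealt round-robin over the k folds, so per-class fold sizes
#' differ by at most one and (for classes with at least k members) every fold
#' contains every class. The non-stratified variant is a plain random
#' partition. Any assignment that would leave some training fold without one
#' of the classes is an error.
#'
#' @param labels class label per sample.
#' @param k number of folds (default 7).
#' @param seed seed making the assignment deterministic.
#' @param stratify stratify by class (default TRUE).
#' @return integer vector of fold indices in `1..k`.
#' @export
assign_folds <- function(labels, k = 7, seed = NULL, stratify = TRUE) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("more folds than samples")
  draw <- function() {
    fold <- integer(n)
    if (stratify) {
      for (g in unique(labels)) {
        idx <- sample(which(labels == g))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  }
  fold <- if (is.null(seed)) draw() else with_seed(seed, draw())
  for (f in seq_len(k)) {
    train_classes <- unique(labels[fold != f])
    if (!setequal(train_classes, unique(labels)))
      stop("fold ", f, " would leave a training set without class ",
           paste(setdiff(unique(labels), train_classes), collapse = ", "))
  }
  fold
}

#' Classification metrics from true and predicted labels
#'
#' Sensitivity is the fraction of positive-class samples called positive,
#' TP/(TP+FN); specificity the fraction of negative samples called negative,
#' TN/(TN+FP). Fractions are kept at full precision; rounding to whole
#' percentages happens only in rendered reports.
#'
#' @param truth true group labels.
#' @param predicted predicted group labels (same length).
#' @param positive the positive (disease) class.
#' @return list with `sensitivity`, `specificity` and the `confusion` counts
#'   `c(TP, FP, TN, FN)`.
#' @export
confusion_metrics <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  pos <- truth == positive
  if (!any(pos)) stop("no positive samples; sensitivity undefined")
  if (all(pos)) stop("no negative samples; specificity undefined")
  pred_pos <- predicted == positive
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       confusion = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' Sevenfold cross-validated diagnosis
#'
#' Reproduces the left-out prediction design: the samples are split into k
#' stratified folds; for each fold a scaler and an OPLS-DA model are fitted
#' on the remaining folds only (no information from held-out samples enters
#' preprocessing or model fitting) and the held-out samples are predicted.
#' Out-of-fold predicted responses are classified against each fold model's
#' own threshold and aggregated into sensitivity, specificity and
#' Q2 = 1 - PRESS/SS(y).
#'
#' @param table a `feature_table` restricted to the two groups of the
#'   contrast.
#' @param meta metadata covering `table` (exactly two groups).
#' @param k number of folds (default 7; `k = n` gives leave-one-out).
#' @param n_orth orthogonal components per fold model.
#' @param seed fold-assignment seed.
#' @param positive the positive class (default `"RA"`).
#' @param mode,log preprocessing, see [fit_scaler()].
#' @param leaky_scaling fit the scaler once on the full matrix instead of
#'   per training fold (reproduces whole-matrix scaling for comparison;
#'   default FALSE, the honest design).
#' @param stratify stratified folds (default TRUE).
#' @param keep_models keep the per-fold `oplsda` models in the result.
#' @return object of class `cv_result`: per-sample table `samples`
#'   (`sample_id`, `group`, `fold`, `y_hat`, `predicted`), `sensitivity`,
#'   `specificity`, `q2`, `confusion`, and optionally `fold_models`.
#' @export
crossval_predict <- function(table, meta, k = 7, n_orth = 1, seed = NULL,
                             positive = "RA", mode = "uv", log = TRUE,
                             leaky_scaling = FALSE, stratify = TRUE,
                             keep_models = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  meta <- align_meta(table, meta)
  groups <- unique(as.character(meta$group))
  if (length(groups) != 2)
    stop("cross-validation needs exactly two groups, got: ",
         paste(groups, collapse = ", "))
  labels <- as.character(meta$group)
  fold <- assign_folds(labels, k = k, seed = seed, stratify = stratify)
  X <- table$intensities
  n <- nrow(X)
  y_hat <- numeric(n)
  predicted <- character(n)
  y <- ifelse(labels == positive, 1, -1)
  press <- 0
  global_scaler <- if (leaky_scaling) fit_scaler(X, mode = mode, log = log)
  fold_models <- if (keep_models) vector("list", k)

  for (f in sort(unique(fold))) {
    tr <- fold != f
    scaler <- if (leaky_scaling) global_scaler else
      fit_scaler(X[tr, , drop = FALSE], mode = mode, log = log)
    Xs_tr <- apply_scaler(scaler, X[tr, , drop = FALSE])
    core <- fit_opls(Xs_tr, y[tr], n_orth = n_orth)
    Xs_te <- apply_scaler(scaler, X[!tr, , drop = FALSE])
    pr <- predict(core, Xs_te)
    y_hat[!tr] <- pr$y_hat
    # threshold of this fold's model: its own training response mean
    predicted[!tr] <- ifelse(pr$y_hat >= core$y_center, positive,
                             setdiff(groups, positive))
    press <- press + sum((y[!tr] - pr$y_hat)^2)
    if (keep_models) fold_models[[f]] <- list(scaler = scaler, core = core)
  }
  met <- confusion_metrics(labels, predicted, positive)
  structure(
    list(samples = data.frame(sample_id = meta$sample_id, group = labels,
                              fold = fold, y_hat = y_hat,
                              predicted = predicted,
                              stringsAsFactors = FALSE),
         sensitivity = met$sensitivity, specificity = met$specificity,
         q2 = 1 - press / sum((y - mean(y))^2),
         confusion = met$confusion,
         positive = positive, k = k, n_orth = n_orth,
         fold_models = fold_models),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV: sensitivity %.0f%%, specificity %.0f%%, Q2 = %.3f\n",
              x$k, round(100 * x$sensitivity), round(100 * x$specificity), x$q2))
  invisible(x)
}

#' Validate a diagnosis model on an external study
#'
#' Mirrors the follow-up validation design: both studies are restricted to
#' their shared identified metabolites (matched by name, common column
#' order), the training study is optionally subsampled to `balance`
#' observations per group (with a fixed seed), a single OPLS-DA model is
#' fitted on the training study, and every sample of the test study is
#' predicted and scored against its true label.
#'
#' @param train,train_meta the model-building study (e.g. study 1).
#' @param test,test_meta the external validation study.
#' @param positive positive class, default `"RA"`.
#' @param balance training observations per group (default 9); `NULL`
#'   disables subsampling.
#' @param seed seed for the balancing subsample.
#' @param n_orth,mode,log model and preprocessing options.
#' @return object of class `validation_result`: the fitted `model`,
#'   `shared_identified`, per-sample `samples` table, `sensitivity`,
#'   `specificity`, `q2`, `confusion`.
#' @export
external_validate <- function(train, train_meta, test, test_meta,
                              positive = "RA", balance = 9, seed = 1,
                              n_orth = 1, mode = "uv", log = TRUE) {
  pair <- intersect_studies(train, test)
  al <- aligned_tables(pair)
  train_meta <- align_meta(al$table_a, train_meta)
  test_meta <- align_meta(al$table_b, test_meta)
  contrast_groups <- unique(as.character(test_meta$group))
  if (length(contrast_groups) != 2)
    stop("the test study must contain exactly two groups, got: ",
         paste(contrast_groups, collapse = ", "))

  # the model is built on the test study's contrast only
  tr <- subset_groups(al$table_a, train_meta, contrast_groups)
  tab_tr <- tr$table
  train_meta <- tr$meta
  if (!is.null(balance)) {
    keep <- with_seed(seed, {
      unlist(lapply(split(train_meta$sample_id, train_meta$group, drop = TRUE),
                    function(ids) {
                      if (length(ids) < balance)
                        stop("balance (", balance,
                             ") exceeds a training group size (", length(ids), ")")
                      sample(ids, balance)
                    }), use.names = FALSE)
    })
    keep <- train_meta$sample_id[train_meta$sample_id %in% keep]
    tab_tr <- subset_table(tab_tr, samples = keep)
    train_meta <- align_meta(tab_tr, train_meta)
  }
  model <- fit_oplsda(tab_tr, train_meta, positive = positive,
                      n_orth = n_orth, mode = mode, log = log)
  pred <- predict(model, al$table_b)
  truth <- as.character(test_meta$group)
  met <- confusion_metrics(truth, pred$predicted, positive)
  y_test <- ifelse(truth == positive, 1, -1)
  structure(
    list(model = model, shared_identified = pair$shared_identified,
         samples = data.frame(sample_id = test_meta$sample_id, group = truth,
                              y_hat = pred$y_hat, predicted = pred$predicted,
                              stringsAsFactors = FALSE),
         sensitivity = met$sensitivity, specificity = met$specificity,
         q2 = 1 - sum((y_test - pred$y_hat)^2) /
           sum((y_test - mean(y_test))^2),
         confusion = met$confusion, positive = positive,
         n_train = nrow(tab_tr$intensities)),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %d shared metabolites, %d training samples: sensitivity %.0f%%, specificity %.0f%%\n",
              length(x$shared_identified), x$n_train,
              round(100 * x$sensitivity), round(100 * x$specificity)))
  invisible(x)
}
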