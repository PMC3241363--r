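test_that("fold assignment partitions the samples with balanced, stratified folds", {
  labels <- rep("A", 7)
  f <- assign_folds(labels, k = 7, seed = 1)
  expect_identical(sort(unique(f)), 1:7)
  expect_true(all(tabulate(f, 7) == 1))

  labels <- c(rep("RA", 21), rep("CONTROL", 9))
  for (seed in 1:20) {
    f <- assign_folds(labels, k = 7, seed = seed)
    expect_identical(length(f), 30L)
    expect_true(all(f %in% 1:7))
    # every fold contains both classes at these group sizes
    for (k in 1:7)
      expect_setequal(unique(labels[f == k]), c("RA", "CONTROL"))
    # per-class fold sizes differ by at most one
    for (g in c("RA", "CONTROL")) {
      sz <- tabulate(f[labels == g], 7)
      expect_lte(diff(range(sz)), 1)
    }
  }
  expect_identical(assign_folds(labels, k = 7, seed = 5),
                   assign_folds(labels, k = 7, seed = 5))
  expect_error(assign_folds(c("RA", rep("CONTROL", 9)), k = 5), "without class")
})

test_that("confusion metrics reproduce the textbook arithmetic", {
  truth <- c(rep("RA", 14), rep("CONTROL", 20))
  pred <- c(rep("RA", 13), "CONTROL", rep("CONTROL", 14), rep("RA", 6))
  met <- confusion_metrics(truth, pred, positive = "RA")
  expect_equal(met$sensitivity, 13 / 14)
  expect_equal(met$specificity, 14 / 20)
  expect_identical(unname(met$confusion), c(13L, 6L, 14L, 1L))

  met2 <- confusion_metrics(truth, truth, positive = "RA")
  expect_identical(c(met2$sensitivity, met2$specificity), c(1, 1))
  met3 <- confusion_metrics(truth, rep("RA", 34), positive = "RA")
  expect_identical(c(met3$sensitivity, met3$specificity), c(1, 0))
  expect_error(confusion_metrics(rep("RA", 3), rep("RA", 3), "RA"),
               "no negative")
  expect_error(confusion_metrics(rep("CONTROL", 3), rep("RA", 3), "RA"),
               "no positive")
})

test_that("cross-validation predicts each sample exactly once, also at leave-one-out", {
  co <- generate_cohort(small_config(seed = 23))
  sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
  n <- nrow(sub$table$intensities)
  cv <- crossval_predict(sub$table, sub$meta, k = n, seed = 1,
                         stratify = FALSE)
  expect_identical(nrow(cv$samples), n)
  expect_identical(sort(unique(cv$samples$fold)), seq_len(n))
  expect_identical(sum(cv$confusion), n)
  cv7 <- crossval_predict(sub$table, sub$meta, k = 7, seed = 1)
  expect_identical(sort(unique(cv7$samples$fold)), 1:7)
  expect_equal(cv7$sensitivity,
               unname(cv7$confusion["TP"] /
                        (cv7$confusion["TP"] + cv7$confusion["FN"])))
})

test_that("held-out samples never influence the fold models", {
  co <- generate_cohort(small_config(seed = 29))
  sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
  cv1 <- crossval_predict(sub$table, sub$meta, k = 4, seed = 3,
                          keep_models = TRUE)
  # corrupt one held-out sample of fold 1 and re-run with the same folds
  victim <- cv1$samples$sample_id[cv1$samples$fold == 1][1]
  tab2 <- sub$table
  tab2$intensities[victim, ] <- tab2$intensities[victim, ] * 1000
  cv2 <- crossval_predict(tab2, sub$meta, k = 4, seed = 3,
                          keep_models = TRUE)
  expect_identical(cv1$samples$fold, cv2$samples$fold)
  m1 <- cv1$fold_models[[1]]
  m2 <- cv2$fold_models[[1]]
  expect_equal(m1$core$w, m2$core$w, tolerance = 1e-12)
  expect_equal(m1$scaler$center, m2$scaler$center, tolerance = 1e-12)
  # and the other held-out samples of fold 1 keep their predictions
  others <- setdiff(cv1$samples$sample_id[cv1$samples$fold == 1], victim)
  expect_equal(cv1$samples$y_hat[cv1$samples$sample_id %in% others],
               cv2$samples$y_hat[cv2$samples$sample_id %in% others],
               tolerance = 1e-12)
})

test_that("metrics are invariant to sample order", {
  co <- generate_cohort(small_config(seed = 31))
  sub <- subset_groups(co$table, co$meta, c("RA", "PSOA"))
  cv1 <- crossval_predict(sub$table, sub$meta, k = 5, seed = 2)
  # the metric definition must not depend on sample order
  met1 <- confusion_metrics(cv1$samples$group, cv1$samples$predicted, "RA")
  ord <- order(cv1$samples$sample_id, decreasing = TRUE)
  met2 <- confusion_metrics(cv1$samples$group[ord],
                            cv1$samples$predicted[ord], "RA")
  expect_identical(met1, met2)
})

test_that("the two disease contrasts are modelled independently", {
  co <- generate_cohort(sim_config(seed = 37))
  rc <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
  rp <- subset_groups(co$table, co$meta, c("RA", "PSOA"))
  m_rc <- fit_oplsda(rc$table, rc$meta)
  m_rp <- fit_oplsda(rp$table, rp$meta)
  expect_identical(m_rc$coding$negative, "CONTROL")
  expect_identical(m_rp$coding$negative, "PSOA")
  expect_false(identical(m_rc$core$w, m_rp$core$w))
  # RA-vs-control markers discriminate in their own model, not the other
  pc_rc <- pcorr(m_rc)
  pc_rp <- pcorr(m_rp)
  expect_gt(abs(pc_rc["Methionine"]), abs(pc_rp["Methionine"]))
  expect_gt(abs(pc_rp["Glutamine"]), abs(pc_rc["Glutamine"]))
})

test_that("external validation restricts to shared metabolites and balances the training set", {
  pair <- generate_study_pair(sim_config(seed = 41))
  val <- external_validate(pair$table_a, pair$meta_a,
                           pair$table_b, pair$meta_b, balance = 9, seed = 1)
  expect_identical(length(val$shared_identified), 52L)
  expect_identical(val$n_train, 18L)
  expect_identical(length(val$model$metabolite_ids), 52L)
  expect_identical(nrow(val$samples), 34L)
  expect_error(
    external_validate(pair$table_a, pair$meta_a, pair$table_b, pair$meta_b,
                      balance = 50),
    "exceeds"
  )
})

test_that("validating a study against itself reproduces resubstitution metrics", {
  co <- generate_cohort(small_config(seed = 43))
  sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
  val <- external_validate(sub$table, sub$meta, sub$table, sub$meta,
                           balance = NULL)
  m <- fit_oplsda(select_identified(sub$table), sub$meta)
  resub <- predict(m, select_identified(sub$table))
  met <- confusion_metrics(sub$meta$group, resub$predicted, "RA")
  expect_equal(val$sensitivity, met$sensitivity)
  expect_equal(val$specificity, met$specificity)
})
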