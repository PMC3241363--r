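test_that("class encoding follows the +1 disease convention", {
  cc <- encode_classes(c("RA", "RA", "CONTROL"), positive = "RA")
  expect_identical(cc$y, c(1, 1, -1))
  expect_equal(cc$y_center, 1 / 3)
  expect_equal(encode_classes(c("RA", "CONTROL"), "RA")$y_center, 0)
  expect_error(encode_classes(c("RA", "RA"), "RA"), "two distinct")
  expect_error(encode_classes(c("RA", "CONTROL", "PSOA"), "RA"), "two distinct")
  expect_error(encode_classes(c("RA", "CONTROL"), "PSOA"), "absent")
})

test_that("a single perfectly predictive column gives a saturated model", {
  y <- rep(c(1, -1), 5)
  Xs <- matrix(2 * (y - mean(y)), ncol = 1, dimnames = list(NULL, "m1"))
  m <- fit_opls(Xs, y, n_orth = 0)
  expect_equal(m$r2y, 1, tolerance = 1e-10)
  expect_equal(predict(m, Xs)$y_hat, y, tolerance = 1e-10)
  expect_equal(unname(pcorr(m)), 1, tolerance = 1e-12)
})

test_that("with no orthogonal components the fit reduces to one-component PLS1", {
  for (seed in 1:10) {
    inst <- rand_instance(n = 20, K = 15, seed = seed)
    m <- fit_opls(inst$Xs, inst$y, n_orth = 0)
    o <- pls1_oracle(inst$Xs, inst$y)
    expect_lt(max(abs(unname(m$w) - o$w)), 1e-10)
    expect_lt(max(abs(m$t - o$t)), 1e-10)
    expect_lt(max(abs(unname(m$p) - o$p)), 1e-10)
    expect_lt(abs(m$c - o$c), 1e-10)
  }
})

test_that("fitted models satisfy the orthogonality and variance-decomposition invariants", {
  for (seed in 1:10) {
    inst <- rand_instance(seed = seed)
    m <- fit_opls(inst$Xs, inst$y, n_orth = 2)
    yc <- inst$y - mean(inst$y)
    expect_lt(abs(sum(m$w^2) - 1), 1e-10)
    for (j in seq_len(m$n_orth)) {
      expect_lt(abs(sum(m$w * m$W_orth[, j])), 1e-8)
      expect_lt(abs(cor(m$T_orth[, j], yc)), 1e-8)
      expect_lt(abs(sum(m$t * m$T_orth[, j])) /
                  (l2 <- sqrt(sum(m$t^2) * sum(m$T_orth[, j]^2))), 1e-8)
    }
    ss <- sum(inst$Xs^2)
    resid <- m$Xf - tcrossprod(m$t, m$p)
    parts <- sum(tcrossprod(m$t, m$p)^2) + sum(resid^2) +
      sum(vapply(seq_len(m$n_orth), function(j)
        sum(tcrossprod(m$T_orth[, j], m$P_orth[, j])^2), numeric(1)))
    expect_lt(abs(ss - parts) / ss, 1e-8)
    expect_lte(m$r2x_pred + m$r2x_orth, 1 + 1e-8)
  }
})

test_that("prediction is self-consistent on training rows and centred at the origin", {
  inst <- rand_instance(seed = 99)
  m <- fit_opls(inst$Xs, inst$y, n_orth = 1)
  pr <- predict(m, inst$Xs)
  expect_equal(pr$y_hat, m$t * m$c + m$y_center, tolerance = 1e-10)
  # a sample at the training column means (all zeros in scaled space)
  origin <- matrix(0, 1, ncol(inst$Xs),
                   dimnames = list("new", colnames(inst$Xs)))
  expect_equal(unname(predict(m, origin)$y_hat), m$y_center, tolerance = 1e-12)
})

test_that("predictions ignore the fitted orthogonal variation in new samples", {
  inst <- rand_instance(seed = 7)
  m <- fit_opls(inst$Xs, inst$y, n_orth = 2)
  x0 <- inst$Xs[3, , drop = FALSE]
  base <- predict(m, x0)$y_hat
  for (j in seq_len(m$n_orth)) {
    dir <- matrix(m$P_orth[, j], 1)
    for (alpha in c(-10, 1, 10)) {
      moved <- predict(m, x0 + alpha * dir)$y_hat
      expect_lt(abs(moved - base), 1e-8)
    }
  }
})

test_that("rescaling a raw metabolite column leaves predictions unchanged under uv scaling", {
  co <- generate_cohort(small_config(seed = 13))
  sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
  m1 <- fit_oplsda(sub$table, sub$meta)
  tab2 <- sub$table
  tab2$intensities[, 5] <- tab2$intensities[, 5] * 37.5
  m2 <- fit_oplsda(tab2, sub$meta)
  p1 <- predict(m1, sub$table)$y_hat
  p2 <- predict(m2, tab2)$y_hat
  expect_lt(max(abs(p1 - p2)), 1e-8)
})

test_that("degenerate fits are rejected", {
  inst <- rand_instance(n = 10, K = 5, seed = 2)
  expect_error(fit_opls(inst$Xs, rep(1, 10)), "constant")
  expect_error(fit_opls(inst$Xs, inst$y, n_orth = -1), ">= 0")
  expect_error(fit_opls(inst$Xs, inst$y, n_orth = 9), "more samples")
})

test_that("p(corr) is a bounded correlation and flags degenerate columns", {
  for (seed in 1:5) {
    inst <- rand_instance(seed = seed)
    m <- fit_opls(inst$Xs, inst$y, n_orth = 1)
    pc <- pcorr(m)
    expect_true(all(abs(pc) <= 1 + 1e-12))
  }
  inst <- rand_instance(n = 12, K = 4, seed = 3)
  Xs <- cbind(inst$Xs, dead = 0)
  m <- fit_opls(Xs, inst$y, n_orth = 0)
  expect_warning(pc <- pcorr(m), "dead")
  expect_identical(unname(pc["dead"]), 0)
})

test_that("p(corr) recovers the planted marker directions (RA coded +1)", {
  eff <- default_effects()
  rc <- eff[eff$contrast == "RA_vs_CONTROL", ]
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(sim_config(seed = s))
    sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
    m <- fit_oplsda(sub$table, sub$meta)
    pc <- pcorr(m)[rc$metabolite_id]
    all(sign(pc) == ifelse(rc$direction == "increased", 1, -1))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the orthogonal-component count is selected by cross-validated Q2", {
  expect_identical(as.integer(select_n_orth(rand_instance()$Xs,
                                            rand_instance()$y, max_orth = 0)), 0L)
  picks <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 24; K <- 12
    y <- rep(c(1, -1), length.out = n)
    # predictive structure plus isotropic noise only: no orthogonal structure
    X <- outer(y, rnorm(K, 0, 0.8)) + matrix(rnorm(n * K), n, K)
    colnames(X) <- sprintf("V%d", 1:K)
    as.integer(select_n_orth(scale(X), y, max_orth = 2, seed = seed))
  }, integer(1))
  expect_gt(mean(picks == 0), 0.5)
  expect_true(all(picks <= 2))
})

test_that("serialized models predict identically after a JSON round trip", {
  co <- generate_cohort(small_config(seed = 17))
  sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
  m <- fit_oplsda(sub$table, sub$meta, n_orth = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_oplsda(m, path)
  m2 <- read_oplsda(path)
  p1 <- predict(m, sub$table)
  p2 <- predict(m2, sub$table)
  expect_equal(p2$y_hat, p1$y_hat, tolerance = 1e-12)
  expect_identical(p2$predicted, p1$predicted)
})
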