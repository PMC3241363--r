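test_that("standard scores are referenced to the control group's mean and SD", {
  x <- matrix(c(1, 3, 4,
                2, 2, 5), 3, 2,
              dimnames = list(c("C1", "C2", "R1"), c("m1", "m2")))
  tab <- feature_table(x)
  meta <- sample_meta(rownames(x), c("CONTROL", "CONTROL", "RA"))
  z <- suppressWarnings(standard_scores(tab, meta, reference = "CONTROL"))
  expect_equal(z["R1", "m1"], (4 - 2) / sqrt(2))
  # a reference sample at the reference mean scores zero
  expect_warning(z2 <- standard_scores(tab, meta), "zero reference SD")
  expect_true(all(z2[, "m2"][c("C1", "C2")] == 0))

  # reference-group scores average to zero for every metabolite
  for (seed in 1:5) {
    co <- generate_cohort(small_config(seed = seed))
    z <- standard_scores(co$table, co$meta, reference = "CONTROL")
    ref <- co$meta$sample_id[co$meta$group == "CONTROL"]
    expect_lt(max(abs(colMeans(z[ref, , drop = FALSE]))), 1e-10)
  }
})

test_that("display truncation clamps symmetrically and leaves in-range values alone", {
  expect_identical(truncate_scores(3.5, 2), 2)
  expect_identical(truncate_scores(-2.7, 2), -2)
  z <- matrix(c(-1.2, 0, 1.9), 1)
  expect_identical(truncate_scores(z, 2), z)
  expect_error(truncate_scores(z, 0), "limit > 0")
})

test_that("heat-map columns follow the p(corr) order from most negative to most positive", {
  co <- generate_cohort(sim_config(seed = 47))
  sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
  m <- fit_oplsda(sub$table, sub$meta)
  hm <- build_heatmap(sub$table, sub$meta, m, reference = "CONTROL")
  expect_true(all(abs(hm$z) <= 2))
  expect_false(is.unsorted(hm$pcorr))
  expect_identical(colnames(hm$z), names(hm$pcorr))
  # identified metabolites only, all samples present, controls first
  expect_identical(ncol(hm$z), 83L)
  expect_identical(nrow(hm$z), 30L)
  expect_identical(unique(hm$row_groups), c("CONTROL", "RA"))
  # decreased markers sit on the negative end of the ordering
  expect_lt(match("Histidine", colnames(hm$z)),
            match("Glyceric acid", colnames(hm$z)))

  # PsoA reference convention
  rp <- subset_groups(co$table, co$meta, c("RA", "PSOA"))
  m2 <- fit_oplsda(rp$table, rp$meta)
  hm2 <- build_heatmap(rp$table, rp$meta, m2, reference = "PSOA")
  expect_identical(unique(hm2$row_groups), c("PSOA", "RA"))
  ref <- rp$meta$sample_id[rp$meta$group == "PSOA"]
  # z referenced to the PsoA mean: PsoA rows centre near zero
  expect_lt(abs(mean(hm2$z[ref, ])), 0.2)
})

test_that("t statistics and P values match the pooled-variance oracle", {
  o <- ttest_oracle(c(1, 2, 3), c(2, 3, 4))
  expect_equal(o$t, -1.224745, tolerance = 1e-6)
  expect_equal(o$p, 0.287864, tolerance = 1e-5)

  x <- matrix(c(1, 2, 3, 2, 3, 4), 6, 1, dimnames = list(sprintf("S%d", 1:6), "m1"))
  tab <- feature_table(x)
  meta <- sample_meta(rownames(x), rep(c("RA", "CONTROL"), each = 3))
  tt <- ttest_table(tab, meta)
  expect_equal(tt$t_stat, o$t, tolerance = 1e-12)
  expect_equal(tt$p_value, o$p, tolerance = 1e-12)
  expect_identical(tt$direction, "decreased")

  # identical groups: no effect, p = 1
  x2 <- matrix(rep(c(5, 6, 7), 2), 6, 1,
               dimnames = list(sprintf("S%d", 1:6), "m1"))
  tt2 <- ttest_table(feature_table(x2), meta)
  expect_equal(tt2$t_stat, 0)
  expect_equal(tt2$p_value, 1)

  # zero pooled variance
  x3 <- matrix(5, 6, 1, dimnames = list(sprintf("S%d", 1:6), "m1"))
  expect_warning(tt3 <- ttest_table(feature_table(x3), meta), "pooled")
  expect_identical(c(tt3$t_stat, tt3$p_value), c(0, 1))
})

test_that("t-statistic sign always agrees with the group mean difference", {
  set.seed(53)
  for (i in 1:50) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    o <- ttest_oracle(a, b)
    expect_identical(sign(o$t), sign(mean(a) - mean(b)))
  }
})

test_that("the univariate report recovers planted markers with their directions", {
  eff <- default_effects()
  rc <- eff[eff$contrast == "RA_vs_CONTROL", ]
  recovered <- vapply(1:9, function(s) {
    co <- generate_cohort(sim_config(seed = s))
    sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
    tt <- ttest_table(sub$table, sub$meta)
    rows <- tt[match(rc$metabolite_id, tt$metabolite_id), ]
    sum(rows$significant & rows$direction == rc$direction)
  }, numeric(1))
  expect_gte(median(recovered), 7)
})

test_that("report rendering partitions by direction and survives the empty case", {
  df <- data.frame(metabolite_id = c("a", "b", "c"),
                   p_value = c(0.049, 0.2, 0.001),
                   direction = c("increased", "increased", "decreased"),
                   stringsAsFactors = FALSE)
  rep1 <- render_table1(df)
  expect_identical(rep1$increased$metabolite_id, "a")
  expect_identical(rep1$decreased$metabolite_id, "c")
  rep0 <- render_table1(df[df$p_value > 1, ])
  expect_identical(nrow(rep0$increased), 0L)
  expect_output(print(rep0), "none")
})

test_that("heat-map ordering and the report use the same p(corr) values", {
  co <- generate_cohort(small_config(seed = 59))
  sub <- subset_groups(co$table, co$meta, c("RA", "CONTROL"))
  m <- fit_oplsda(sub$table, sub$meta)
  hm <- build_heatmap(sub$table, sub$meta, m)
  tt <- ttest_table(sub$table, sub$meta, model = m)
  shared <- intersect(tt$metabolite_id, names(hm$pcorr))
  expect_equal(tt$pcorr[match(shared, tt$metabolite_id)],
               unname(hm$pcorr[shared]), tolerance = 1e-12)
})
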