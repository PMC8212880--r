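test_that("median normalization equalizes sample medians as derived by hand", {
  # medians 10 and 20, global median 15 -> scale factors 1.5 and 0.75
  tab <- make_table(cbind(c(5, 10, 15), c(10, 20, 30)),
                    conditions = c("IVC", "NEO"))
  norm <- normalize_median(tab)
  expect_equal(unname(apply(norm$values, 2, median)), c(15, 15))
  expect_equal(unname(norm$values[, 1]), c(5, 10, 15) * 1.5)
  expect_equal(unname(norm$values[, 2]), c(10, 20, 30) * 0.75)
  # already-equal medians: identity; single sample: identity
  same <- make_table(cbind(c(1, 2, 3), c(3, 2, 1)), c("A", "B"))
  expect_equal(normalize_median(same)$values, same$values)
  single <- make_table(cbind(c(1, 5, 9)), "A")
  expect_equal(normalize_median(single)$values, single$values)
})

test_that("normalization preserves within-sample rank order", {
  withr::with_seed(7, {
    for (i in 1:20) {
      vals <- matrix(stats::rlnorm(40, 3, 1), 10, 4)
      tab <- make_table(vals, conditions = rep(c("A", "B"), 2))
      norm <- normalize_median(tab)
      for (j in 1:4)
        expect_equal(order(norm$values[, j]), order(vals[, j]))
    }
  })
})

test_that("one-way ANOVA matches the closed-form worked example and oneway.test", {
  tab <- make_table(rbind(c(1, 2, 3, 2, 3, 4, 3, 4, 5)),
                    conditions = rep(c("A", "B", "C"), each = 3))
  res <- anova_filter(tab, fdr = 0.05, log2 = FALSE)
  expect_equal(res$records$statistic, 3.0)
  expect_equal(res$records$df1, 2)
  expect_equal(res$records$df2, 6)
  expect_equal(res$records$p, pf(3, 2, 6, lower.tail = FALSE))
  # random data: agree with stats::oneway.test(var.equal = TRUE) per protein
  withr::with_seed(11, {
    vals <- matrix(2^rnorm(60, 10, 1), 5, 12)
    groups <- rep(c("G1", "G2", "G3"), each = 4)
    tab2 <- make_table(vals, conditions = groups)
    res2 <- anova_filter(tab2, log2 = TRUE)
    for (i in 1:5) {
      ref <- stats::oneway.test(log2(vals[i, ]) ~ factor(groups),
                                var.equal = TRUE)
      expect_equal(res2$records$statistic[i], unname(ref$statistic),
                   tolerance = 1e-10)
      expect_equal(res2$records$p[i], ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("ANOVA drops constants and skips undersized designs with warnings", {
  vals <- rbind(rep(4, 6), c(1, 2, 3, 4, 5, 6))
  tab <- make_table(vals, conditions = rep(c("A", "B"), each = 3))
  expect_warning(res <- anova_filter(tab, log2 = FALSE), "constant")
  expect_equal(res$records$protein_id, "PR02")
  # a protein observed in only one group is skipped, not an error
  vals2 <- rbind(c(1, 2, 3, NA, NA, NA), c(1, 2, 3, 4, 5, 6))
  tab2 <- make_table(vals2, conditions = rep(c("A", "B"), each = 3))
  expect_warning(res2 <- anova_filter(tab2, log2 = FALSE), "lacking 2 groups")
  expect_true(is.na(res2$records$q[1]))
  expect_false("PR01" %in% res2$retained)
})

test_that("Welch t matches the hand-derived example and flips with labels", {
  tab <- make_table(rbind(c(1, 2, 3, 4, 5, 6)),
                    conditions = rep(c("T", "C"), each = 3))
  labels <- c(S01 = "test", S02 = "test", S03 = "test",
              S04 = "control", S05 = "control", S06 = "control")
  res <- ttest_two_group(tab, labels, log2 = FALSE)
  expect_equal(res$statistic, -3/sqrt(2/3), tolerance = 1e-3)  # -3.674
  expect_equal(res$df, 4)
  flipped <- c(S01 = "control", S02 = "control", S03 = "control",
               S04 = "test", S05 = "test", S06 = "test")
  res2 <- ttest_two_group(tab, flipped, log2 = FALSE)
  expect_equal(res2$statistic, -res$statistic)
  expect_equal(res2$p, res$p)
  # identical groups: t = 0, p = 1
  same <- make_table(rbind(c(1, 2, 3, 1, 2, 3)),
                     conditions = rep(c("T", "C"), each = 3))
  res3 <- ttest_two_group(same, labels, log2 = FALSE)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p, 1)
  # agreement with stats::t.test on random data
  withr::with_seed(3, {
    vals <- matrix(2^rnorm(48, 8, 1), 6, 8)
    tabr <- make_table(vals, conditions = rep(c("T", "C"), each = 4))
    labr <- stats::setNames(rep(c("test", "control"), each = 4),
                            colnames(tabr$values))
    resr <- ttest_two_group(tabr, labr)
    for (i in 1:6) {
      ref <- stats::t.test(log2(vals[i, 1:4]), log2(vals[i, 5:8]))
      expect_equal(resr$statistic[i], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(resr$p[i], ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("two-group ANOVA F equals t squared under equal variances", {
  withr::with_seed(5, {
    vals <- matrix(2^rnorm(40, 8, 1), 5, 8)
    tab <- make_table(vals, conditions = rep(c("T", "C"), each = 4))
    f_res <- anova_filter(tab)$records$statistic
    labels <- stats::setNames(rep(c("test", "control"), each = 4),
                              colnames(tab$values))
    # pooled t: with equal group sizes Welch == pooled only when variances
    # match, so compare against the pooled statistic directly
    t_pooled <- vapply(1:5, function(i) {
      unname(stats::t.test(log2(vals[i, 1:4]), log2(vals[i, 5:8]),
                           var.equal = TRUE)$statistic)
    }, 0)
    expect_equal(f_res, t_pooled^2, tolerance = 1e-9)
  })
})

test_that("BH adjustment reproduces the step-up worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.017), 0.017)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "graftnet_parameter_error")
  expect_error(bh_adjust(c(0.5, -0.1)), class = "graftnet_parameter_error")
})

test_that("BH adjustment is monotone in p", {
  withr::with_seed(21, {
    for (i in 1:25) {
      p <- runif(50)
      q <- bh_adjust(p)
      ord <- order(p)
      expect_true(all(diff(q[ord]) >= -1e-15))
      expect_true(all(q >= p - 1e-15))
      expect_true(all(q <= 1))
    }
  })
})

test_that("bipartition splits a separable design and orients by control", {
  # 10 proteins high in IVC, 10 high in NEO, noiseless
  high <- 2^12; low <- 2^8
  vals <- rbind(matrix(rep(c(high, high, low, low), each = 10), 10),
                matrix(rep(c(low, low, high, high), each = 10), 10))
  tab <- make_table(vals, conditions = c("IVC", "IVC", "NEO", "NEO"))
  cl <- bipartition_proteins(tab, rownames(tab$values))
  expect_setequal(cl$cluster1, sprintf("PR%02d", 1:10))
  expect_setequal(cl$cluster2, sprintf("PR%02d", 11:20))
  # relabelling which condition is control swaps the orientation
  cl2 <- bipartition_proteins(tab, rownames(tab$values),
                              control_condition = "NEO")
  expect_setequal(cl2$cluster1, cl$cluster2)
  expect_setequal(cl2$cluster2, cl$cluster1)
  expect_error(bipartition_proteins(tab, "PR01"),
               class = "graftnet_data_error")
})

test_that("bipartition recovers planted directions on synthetic data", {
  synth <- synth_static_proteome(groups = c(IVC = 3, NEO = 3, ADV = 3),
                                 n_proteins = 300, frac_differential = 0.3,
                                 effect_log2 = 2, noise_sd = 0.25, seed = 42)
  norm <- normalize_median(synth$table)
  res <- anova_filter(norm, fdr = 0.05)
  cl <- bipartition_proteins(norm, res$retained)
  truth <- synth$truth
  up_lesion <- truth$protein_id[!is.na(truth$direction) &
                                  truth$direction == "up_lesion"]
  up_control <- truth$protein_id[!is.na(truth$direction) &
                                   truth$direction == "up_control"]
  hits <- length(intersect(cl$cluster2, up_lesion)) +
    length(intersect(cl$cluster1, up_control))
  expect_gte(hits / length(c(up_lesion, up_control)), 0.95)
})
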