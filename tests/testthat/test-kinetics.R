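test_that("fractional normalization follows the arithmetic rules", {
  expect_equal(fractional_normalize(c(2, 2, 2, 2)), rep(0.25, 4))
  expect_equal(fractional_normalize(c(1, 3, 4, 2)), c(0.1, 0.3, 0.4, 0.2))
  expect_warning(out <- fractional_normalize(c(0, 0, 0, 0)), "all-zero")
  expect_null(out)
  # scale invariance: any positive rescaling leaves the profile unchanged
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- stats::rgamma(4, 2)
      c_ <- stats::runif(1, 0.1, 100)
      expect_equal(fractional_normalize(c_ * x), fractional_normalize(x))
    }
  })
})

test_that("profile building averages replicates then normalizes per condition", {
  synth <- synth_kinetic_proteome(n_proteins = 20, noise_sd = 0, seed = 9)
  prof <- kinetic_profiles(synth$table)
  expect_equal(ncol(prof$fractions), 4)
  expect_equal(nrow(prof$fractions), 40)  # VG and IVC per protein
  # noiseless: every profile equals its planted template exactly
  truth <- synth$truth$assignments
  key <- paste(prof$protein, prof$condition)
  tmpl_id <- truth$template_id[match(key, paste(truth$protein_id,
                                                truth$condition))]
  expect_equal(unname(prof$fractions),
               unname(synth$truth$templates[tmpl_id, ]), tolerance = 1e-12)
})

test_that("EM clustering separates noiseless templates perfectly and is deterministic", {
  synth <- synth_kinetic_proteome(n_proteins = 100, noise_sd = 0, seed = 4)
  prof <- kinetic_profiles(synth$table)
  model <- fit_kinetic_clusters(prof, K = 10, seed = 1, restarts = 5)
  truth <- synth$truth$assignments
  key <- paste(prof$protein, prof$condition)
  tmpl_id <- truth$template_id[match(key, paste(truth$protein_id,
                                                truth$condition))]
  expect_equal(adjusted_rand_index(model$assignment, tmpl_id), 1.0)
  model2 <- fit_kinetic_clusters(prof, K = 10, seed = 1, restarts = 5)
  expect_identical(model$assignment, model2$assignment)
  expect_identical(model$centroids, model2$centroids)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  synth <- synth_kinetic_proteome(n_proteins = 150, noise_sd = 0.05, seed = 6)
  prof <- kinetic_profiles(synth$table)
  model <- fit_kinetic_clusters(prof, K = 6, seed = 3, restarts = 2)
  expect_true(model$monotone)
  expect_gte(length(model$ll_trace), 2)
})

test_that("EM assignments agree with an independent mixture fit on separated data", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  synth <- synth_kinetic_proteome(n_proteins = 200, noise_sd = 0.02, seed = 8,
                                  templates = default_kinetic_templates()[c(1, 5), ])
  prof <- kinetic_profiles(synth$table)
  model <- fit_kinetic_clusters(prof, K = 2, seed = 1)
  ref <- mclust::Mclust(prof$fractions[, 1:3], G = 2, modelNames = "VVI",
                        verbose = FALSE)
  expect_equal(adjusted_rand_index(model$assignment, ref$classification), 1.0)
})

test_that("phase classification applies the centroid shape rules", {
  model <- structure(list(K = 3L,
                          centroids = rbind(c(0.45, 0.35, 0.10, 0.10),
                                            c(0.25, 0.25, 0.25, 0.25),
                                            c(0.10, 0.10, 0.30, 0.50)),
                          assignment = c(1L, 2L, 3L),
                          protein = c("A", "B", "C"),
                          condition = c("VG", "VG", "VG"),
                          timepoints = c("D1", "D3", "W2", "W4"),
                          phase = NULL),
                     class = "cluster_model")
  out <- classify_phase(model, early_timepoints = c("D1", "D3"),
                        late_timepoints = c("W2", "W4"), flat_range = 0.10)
  expect_equal(out$phase, c("early", "flat", "late"))
  expect_error(classify_phase(model, early_timepoints = character(0),
                              late_timepoints = c("D1", "D3", "W2", "W4")),
               class = "graftnet_parameter_error")
  expect_error(classify_phase(model, early_timepoints = c("D1", "D3", "W2"),
                              late_timepoints = c("W2", "W4")),
               class = "graftnet_parameter_error")
})

test_that("condition filter keeps only kept-condition profiles of non-flat clusters", {
  model <- structure(list(K = 3L,
                          centroids = rbind(c(0.5, 0.3, 0.1, 0.1),
                                            c(0.1, 0.1, 0.3, 0.5),
                                            c(0.25, 0.25, 0.25, 0.25)),
                          assignment = c(1L, 3L, 3L, 2L, 1L, 1L),
                          protein = c("A", "A", "B", "B", "C", "D"),
                          condition = c("VG", "IVC", "VG", "IVC", "IVC", "VG"),
                          timepoints = c("D1", "D3", "W2", "W4"),
                          phase = c("early", "late", "flat")),
                     class = "cluster_model")
  sets <- condition_filter(model, keep_condition = "VG")
  # A: VG early, IVC flat -> early set; B: VG flat -> neither;
  # C: only IVC -> nothing; D: VG early -> early
  expect_setequal(sets$early, c("A", "D"))
  expect_length(sets$late, 0)
  expect_length(intersect(sets$early, sets$late), 0)
  expect_error(condition_filter(model, keep_condition = "XX"),
               class = "graftnet_parameter_error")
})

test_that("set concordance performs exact set algebra", {
  out <- set_concordance(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(out[c("n_common", "n_only_a", "n_only_b", "jaccard")],
               list(n_common = 2L, n_only_a = 1L, n_only_b = 1L,
                    jaccard = 0.5))
  expect_equal(set_concordance(c("X", "Y"), c("X", "Y"))$jaccard, 1)
  expect_equal(set_concordance(c("X"), c("Y"))$jaccard, 0)
})
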