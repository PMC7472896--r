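test_that("BH step-up flags match the hand rule", {
  expect_identical(bh_fdr(c(0.001, 0.2, 0.9), 0.05), c(TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(bh_fdr(rep(0, 5), 0.05), rep(TRUE, 5))
  # monotone in q; agrees with the literal oracle on random inputs
  set.seed(71)
  for (r in 1:20) {
    p <- runif(30)^2
    f1 <- bh_fdr(p, 0.05)
    expect_identical(f1, bh_oracle(p, 0.05))
    f2 <- bh_fdr(p, 0.01)
    expect_true(all(!f2 | f1))
  }
})

test_that("Fisher mass-univariate mapping equals the enumeration oracle", {
  set.seed(72)
  for (r in 1:15) {
    n <- sample(10:24, 1)
    V <- sample(8:20, 1)
    L <- matrix(rbinom(n * V, 1, runif(1, 0.2, 0.6)), n)
    y <- rbinom(n, 1, 0.5)
    if (sd(y) == 0) y[1] <- 1 - y[1]
    lm1 <- matrix_as_lesion_matrix(L)
    res <- fisher_mass_univariate(lm1, y, fdr_q = 0.05)
    K <- sum(y)
    p_ref <- vapply(seq_len(V), function(j)
      fisher_oracle_p(sum(L[, j] * y), sum(L[, j]), K, n), 0)
    expect_equal(res$p_values, pmin(p_ref, 1), tolerance = 1e-12)
    expect_identical(res$significant, bh_oracle(res$p_values, 0.05))
    # label symmetry: swapping deficit classes leaves p-values unchanged
    res_sw <- fisher_mass_univariate(lm1, 1 - y, fdr_q = 0.05)
    expect_equal(res_sw$p_values, res$p_values, tolerance = 1e-12)
  }
})

test_that("extreme 2x2 tables behave as the hypergeometric dictates", {
  # (10,0;0,10) at the defining voxel: p = 2 / choose(20, 10)
  y <- rep(c(1, 0), each = 10)
  L <- cbind(y, matrix(0.0, 20, 3))
  L[, 3] <- 1                                   # damaged in everyone: p = 1
  lm1 <- matrix_as_lesion_matrix(L)
  res <- fisher_mass_univariate(lm1, y, fdr_q = 0.01)
  expect_equal(res$p_values[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(which.min(res$p_values), 1L)
  expect_equal(res$p_values[3], 1)
  expect_error(fisher_mass_univariate(lm1, rep(1, 20)), "single-class")
})

test_that("Welch t-test matches the closed-form evaluation", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  res <- welch_ttest(a, b)
  # hand evaluation of Welch's formulas
  se2 <- var(a) / 4 + var(b) / 4
  t_ref <- (mean(a) - mean(b)) / sqrt(se2)
  df_ref <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(res$t, t_ref, tolerance = 1e-12)
  expect_equal(res$df, df_ref, tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_equal(res$p, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-12)
  # antisymmetry and the degenerate identical case
  sw <- welch_ttest(b, a)
  expect_equal(sw$t, -res$t)
  expect_equal(sw$p, res$p)
  same <- welch_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_ttest(c(1, 1), c(2, 2)), "zero variance")
})

test_that("sparse CCA limits: unpenalized covariance and planted recovery", {
  set.seed(73)
  n <- 30; V <- 80
  X <- matrix(runif(n * V), n)
  lm1 <- matrix_as_lesion_matrix(X, center = TRUE)
  y <- rnorm(n)
  r1 <- sparse_cca(lm1, y, sccan_config(sparseness = 1))
  cv <- as.numeric(crossprod(lm1$values, y - mean(y)))
  expect_lt(max(abs(abs(r1$weights) - abs(cv) / sqrt(sum(cv^2)))), 1e-6)
  # fixed default sparseness keeps ceiling(0.045 V) voxels
  r2 <- sparse_cca(lm1, y, sccan_config())
  expect_equal(sum(r2$weights != 0), ceiling(0.045 * V))
  # single informative voxel at sparseness 1/V
  y2 <- 3 * X[, 41]
  r3 <- sparse_cca(lm1, y2, sccan_config(sparseness = 1 / V))
  expect_equal(which(r3$weights != 0), 41L)
  expect_equal(abs(r3$cancor), 1, tolerance = 1e-10)
  # CV mode returns a table over the configured bounds
  r4 <- sparse_cca(lm1, y2, sccan_config(cv_grid_length = 5), cv = TRUE)
  expect_equal(nrow(r4$cv_table), 5)
  expect_true(all(r4$cv_table$sparseness >= 0.005 - 1e-12 &
                    r4$cv_table$sparseness <= 0.9 + 1e-12))
  expect_error(sparse_cca(lm1, rep(1, n)), "constant")
})

test_that("a uniquely informative voxel is localized with zero displacement", {
  set.seed(74)
  n <- 20; V <- 40
  # defining voxel damaged in exactly half the cohort; all other voxels
  # damaged in at most 3 patients (ineligible and rarely significant)
  L <- matrix(0, n, V)
  L[1:10, 5] <- 1
  for (j in setdiff(1:V, 5)) L[sample(n, 3), j] <- 1
  lm1 <- matrix_as_lesion_matrix(L)
  res <- displacement_experiment(lm1, list(kind = "voxel"),
                                 ground_truth_spec(seed = 1))
  expect_equal(nrow(res$records), 1)        # only voxel 5 is eligible
  expect_equal(res$records$truth_id, "voxel_5")
  expect_true(res$records$localized)
  expect_equal(res$records$displacement, 0)
  expect_equal(res$records$n_significant, 1)
  expect_equal(res$summary$mean, 0)
})

test_that("eligibility requires strictly more than min_damaged_patients", {
  L <- matrix(0, 12, 6)
  L[1:3, 2] <- 1                             # exactly 3 damaged: ineligible
  L[1:5, 4] <- 1                             # 5 damaged: eligible
  lm1 <- matrix_as_lesion_matrix(L)
  res <- displacement_experiment(lm1, list(kind = "voxel"),
                                 ground_truth_spec(seed = 2))
  expect_equal(res$records$truth_id, "voxel_4")
  L2 <- matrix(0, 12, 6); L2[1:2, 1] <- 1
  expect_error(displacement_experiment(matrix_as_lesion_matrix(L2),
                                       list(kind = "voxel"),
                                       ground_truth_spec(seed = 3)),
               "zero eligible")
})

test_that("atlas-model displacement uses the damage-fraction rule per region", {
  sc <- small_vascular_cohort(n_patients = 30, n_terr = 4, seed = 75,
                              noise = 0, jitter = 0, internal_weight = 0)
  bin <- lapply(sc$lesions, function(v)
    volume(array(as.numeric(v$data > 0.5), dim(v$data)), v$affine,
           tag = "binary"))
  lmb <- assemble_lesion_matrix(bin, sc$mask, center = FALSE)
  res <- displacement_experiment(lmb, list(kind = "atlas", atlas = sc$atlas),
                                 ground_truth_spec(seed = 4))
  expect_gte(nrow(res$records), 2)
  expect_true(all(res$records$displacement[res$records$localized] >= 0))
  # label_draws multiplies the truth count
  res3 <- displacement_experiment(lmb, list(kind = "atlas", atlas = sc$atlas),
                                  ground_truth_spec(seed = 4, label_draws = 3))
  expect_equal(nrow(res3$records), 3 * nrow(res$records))
})

test_that("method comparison scores five methods per ground-truth region", {
  sc <- small_vascular_cohort(n_patients = 40, n_terr = 4, seed = 76,
                              noise = 0.01, jitter = 0, internal_weight = 0)
  bin <- lapply(sc$lesions, function(v)
    volume(array(as.numeric(v$data > 0.5), dim(v$data)), v$affine,
           tag = "binary"))
  lmb <- assemble_lesion_matrix(bin, sc$mask, center = FALSE)
  terr_mask <- function(l) volume(array(as.numeric(sc$atlas$data == l),
                                        dim(sc$atlas$data)),
                                  sc$affine, tag = "binary")
  regions <- list(territory_1 = terr_mask(1),
                  composite_23 = volume(
                    array(pmax(terr_mask(2)$data, terr_mask(3)$data),
                          dim(sc$atlas$data)), sc$affine, tag = "binary"))
  rec <- method_comparison_experiment(
    lmb, regions, k = 4,
    spec = ground_truth_spec(deficit_prob = 1, seed = 5),
    mapping_cfg = mapping_config(regression_map_z_cut = 1.5,
                                 regression_map_min_cluster = 5),
    scca_cfg = sccan_config(cv_grid_length = 4, cv_folds = 3),
    component_z_cut = 1.5, component_min_cluster_mm3 = 500)
  expect_equal(nrow(rec), 2 * 5)
  expect_setequal(unique(rec$method),
                  c("mass-univariate", "sparse-cca-fixed", "sparse-cca-cv",
                    "pca-regression", "pca-correlation"))
  expect_true(all(rec$dice >= 0 & rec$dice <= 1))
  # with a planted single-territory truth and deterministic labels every
  # method finds signal overlapping the truth
  expect_true(all(rec$dice[rec$truth_id == "territory_1"] > 0))
})
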