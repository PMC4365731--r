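cs <- build_condition_set()

test_that("second-order correlation hits the identity and antipodal bounds", {
  m <- complexity_type_model(cs)
  d <- m$dissim
  d[is.na(d)] <- 0
  data <- toy_rdm(d[upper.tri(d)], 12, condition_labels(cs))
  expect_equal(rdm_correlation(data, m, "spearman"), 1)
  anti <- toy_rdm(2 - d[upper.tri(d)], 12, condition_labels(cs))
  expect_equal(rdm_correlation(anti, m, "spearman"), -1)
})

test_that("correlations use only model-constrained cells", {
  # two data RDMs differing only on detector-unconstrained cells
  set.seed(51)
  m <- detector_model(cs, "inflected")
  base <- activation_rdm(random_pattern(30, 12, condition_labels(cs)))
  mod <- base
  free <- is.na(m$dissim) & upper.tri(m$dissim)
  mod$dissim[free] <- runif(sum(free), 0, 2)
  mod$dissim[lower.tri(mod$dissim)] <- t(mod$dissim)[lower.tri(mod$dissim)]
  for (method in c("spearman", "kendall_tau_a", "pearson")) {
    expect_equal(rdm_correlation(base, m, method),
                 rdm_correlation(mod, m, method))
  }
  # and match a brute-force recomputation on the constrained subset
  keep <- upper.tri(m$dissim) & !is.na(m$dissim)
  expect_equal(rdm_correlation(base, m, "spearman"),
               oracle_spearman(base$dissim[keep], m$dissim[keep]))
})

test_that("kendall tau-a matches the exhaustive pair-count oracle with ties", {
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    k <- n * (n - 1) / 2
    mvals <- sample(c(0, 0.5, 1), k, replace = TRUE)
    if (length(unique(mvals)) < 2) mvals[1:2] <- c(0, 1)
    m <- toy_model(mvals, n)
    data <- activation_rdm(random_pattern(10, n))
    keep <- upper.tri(m$dissim) & !is.na(m$dissim)
    expect_equal(rdm_correlation(data, m, "kendall_tau_a"),
                 oracle_tau_a(data$dissim[keep], m$dissim[keep]))
  }
})

test_that("degenerate model vectors are rejected", {
  data <- activation_rdm(random_pattern(10, 4))
  expect_error(rdm_correlation(data, toy_model(c(0, 1, NA, NA, NA, NA), 4)),
               "fewer than 3")
  constant <- structure(list(name = "const",
                             dissim = toy_model(rep(0.5, 6), 4)$dissim),
                        class = "model_rdm")
  expect_error(rdm_correlation(data, constant), "constant model")
})

test_that("a perfect model fit yields the minimal attainable p-value", {
  m <- complexity_type_model(cs)
  d <- m$dissim
  d[is.na(d)] <- 0
  data <- toy_rdm(d[upper.tri(d)], 12, condition_labels(cs))
  pt <- permutation_test(data, m, "spearman", n_perm = 999, seed = 7)
  expect_equal(pt$statistic, 1)
  expect_true(all(pt$null <= 1 + 1e-12))
  expect_equal(pt$p_value, 1 / 1000)
})

test_that("permutation tests are reproducible given a seed", {
  set.seed(53)
  data <- activation_rdm(random_pattern(40, 12, condition_labels(cs)))
  m <- general_complexity_model(cs)
  a <- permutation_test(data, m, n_perm = 200, seed = 99)
  b <- permutation_test(data, m, n_perm = 200, seed = 99)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$null, b$null)
  expect_gte(a$p_value, 1 / 201)
})

test_that("identical models compare as indistinguishable", {
  set.seed(54)
  subj <- lapply(1:5, function(i)
    activation_rdm(random_pattern(30, 12, condition_labels(cs))))
  m <- complexity_type_model(cs)
  cmp <- compare_models(subj, m, m)
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_models(subj[1], m, general_complexity_model(cs)),
               ">= 2 subjects")
})

test_that("four subjects enumerate exactly 16 sign flips", {
  set.seed(55)
  subj <- lapply(1:4, function(i)
    activation_rdm(random_pattern(30, 12, condition_labels(cs))))
  cmp <- compare_models(subj, complexity_type_model(cs),
                        general_complexity_model(cs))
  expect_true(cmp$exhaustive)
  expect_equal(cmp$n_flips, 16L)
})

test_that("the planted model wins comparisons at high SNR", {
  set.seed(56)
  mA <- complexity_type_model(cs)
  mB <- general_complexity_model(cs)
  wins <- 0L
  for (r in 1:20) {
    pats <- simulate_roi_patterns(mA, n_voxels = 100, n_subjects = 8,
                                  snr = 5, seed = NULL)
    subj <- lapply(pats, activation_rdm)
    cmp <- compare_models(subj, mA, mB)
    if (cmp$p_value < 0.05 && cmp$mean_difference > 0) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("storey q-values behave at the boundaries", {
  res <- storey_qvalues(rep(0.001, 22))
  expect_true(all(res$qvalues <= 0.022 + 1e-12))
  expect_lte(res$pi0, 1)
  single <- storey_qvalues(1.0)
  expect_equal(single$qvalues, 1.0)
  expect_equal(single$pi0, 1.0)
  expect_error(storey_qvalues(numeric(0)), "empty")
  expect_error(storey_qvalues(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("pi0 is consistent for uniform p-values and q is monotone in p", {
  set.seed(57)
  p <- runif(10000)
  p[p == 0] <- 1e-12
  res <- storey_qvalues(p)
  expect_gte(res$pi0, 0.9)
  expect_lte(res$pi0, 1.1)
  ord <- order(p)
  expect_true(all(diff(res$qvalues[ord]) >= -1e-12))
  # q never below the BH-adjusted value scaled by pi0
  bh <- p.adjust(p, method = "BH")
  expect_true(all(res$qvalues >= bh * res$pi0 - 1e-9))
})

test_that("BH step-up rejections match the hand-computed rule", {
  expect_equal(bh_fdr(c(0.001, 0.2, 0.9), alpha = 0.05), 1L)
  expect_length(bh_fdr(rep(1, 5), alpha = 0.05), 0)
  set.seed(58)
  p <- c(runif(20, 0, 0.01), runif(20))
  shuf <- sample(40)
  expect_setequal(shuf[bh_fdr(p[shuf], 0.1)], bh_fdr(p, 0.1))
})
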