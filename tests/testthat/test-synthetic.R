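cs <- build_condition_set()
labels <- condition_labels(cs)

test_that("similarity covariance interpolates identity and model geometry", {
  m <- complexity_type_model(cs)
  expect_equal(unname(similarity_covariance(m, alpha = 0)), diag(12))
  s <- similarity_covariance(m, alpha = 0.5)
  expect_equal(s, t(s))
  expect_true(all(eigen(s, symmetric = TRUE, only.values = TRUE)$values >=
                    -1e-10))
  # similarity ordering follows the model on constrained cells
  keep <- upper.tri(m$dissim) & !is.na(m$dissim)
  within <- m$dissim == 0 & keep
  between <- m$dissim == 1 & keep
  expect_gt(min(s[which(within)]), max(s[which(between)]))
  expect_error(similarity_covariance(m, alpha = 1.5), "alpha")
})

test_that("simulated patterns are seed-reproducible and respect SNR zero", {
  m <- detector_model(cs, "phrase")
  a <- simulate_roi_patterns(m, 50, n_subjects = 3, snr = 5, seed = 81)
  b <- simulate_roi_patterns(m, 50, n_subjects = 3, snr = 5, seed = 81)
  expect_identical(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))
  expect_equal(a[[1]]$subject_id, "S01")
  # pure-noise generation ignores the model
  n1 <- simulate_roi_patterns("noise", 50, n_subjects = 1, snr = 99,
                              seed = 82)
  n2 <- simulate_roi_patterns("noise", 50, n_subjects = 1, snr = 0,
                              seed = 82)
  expect_identical(n1[[1]]$values, n2[[1]]$values)
  expect_error(simulate_roi_patterns(m, 5, 1, 1), "n_voxels")
})

test_that("null model correlations center on zero at snr = 0", {
  set.seed(83)
  m <- complexity_type_model(cs)
  stats <- replicate(300, {
    p <- simulate_roi_patterns("noise", 40, n_subjects = 1, seed = NULL)[[1]]
    rdm_correlation(activation_rdm(p), m, "spearman")
  })
  expect_lt(abs(mean(stats)), 0.025)
})

test_that("the planted model is recovered as the best fit at high SNR", {
  set.seed(84)
  models <- standard_models(cs)
  wins <- 0L
  n_runs <- 40L
  for (r in seq_len(n_runs)) {
    p <- simulate_roi_patterns(models$detector_inflected, 200,
                               n_subjects = 1, snr = 5, seed = NULL)[[1]]
    rd <- activation_rdm(p)
    stats <- vapply(models, function(m) rdm_correlation(rd, m, "spearman"),
                    numeric(1))
    if (names(which.max(stats)) == "detector_inflected") wins <- wins + 1L
  }
  expect_gte(wins / n_runs, 0.95)
})

test_that("mean model correlation is non-decreasing in SNR", {
  m <- complexity_type_model(cs)
  mean_stat <- vapply(c(0, 0.5, 2, 8), function(snr) {
    set.seed(85)
    mean(replicate(40, {
      p <- simulate_roi_patterns(if (snr == 0) "noise" else m, 60,
                                 n_subjects = 1, snr = snr, seed = NULL)[[1]]
      rdm_correlation(activation_rdm(p), m, "spearman")
    }))
  }, numeric(1))
  expect_true(all(diff(mean_stat) > -0.02))
  expect_gt(mean_stat[4], mean_stat[1] + 0.5)
})

test_that("a default-shaped study has the full roster and is deterministic", {
  s1 <- simulate_study(n_subjects = 3, snr = 2, seed = 86)
  s2 <- simulate_study(n_subjects = 3, snr = 2, seed = 86)
  expect_length(s1$patterns, 22)
  expect_equal(s1$n_subjects, 3L)
  expect_setequal(names(s1$patterns), default_roi_roster()$roi_id)
  expect_true(all(s1$n_voxels >= 50 & s1$n_voxels <= 500))
  for (roi in c("L_BA44", "R_TP")) {
    expect_identical(s1$patterns[[roi]]$S02$values,
                     s2$patterns[[roi]]$S02$values)
    expect_equal(ncol(s1$patterns[[roi]]$S01$values), 12)
  }
  planted <- s1$truth[s1$truth != "noise"]
  expect_setequal(names(planted),
                  c("L_BA44", "L_pSTG", "L_aITG", "L_aSTG", "R_aSTG",
                    "L_aMTG", "R_aMTG", "L_pMTG"))
  expect_error(simulate_study(n_subjects = 3), "seed")
  expect_error(simulate_study(n_subjects = 3, seed = 1,
                              scenario = c(L_BA44 = "not_a_model")),
               "unknown planted model")
})

test_that("NIfTI export round-trips the generator's patterns", {
  scen <- c(roiA = "detector_phrase", roiB = "noise")
  study <- simulate_study(n_subjects = 2, scenario = scen, snr = 3,
                          voxel_range = c(50, 80), seed = 87)
  dir <- withr::local_tempdir()
  out <- export_study_nifti(study, dir)
  rois <- read_roi_catalogue(out$catalogue)
  expect_setequal(names(rois), c("roiA", "roiB"))
  for (roi in names(rois)) {
    for (sub in names(out$images)) {
      pm <- extract_patterns(out$images[[sub]], rois[[roi]],
                             subject_id = sub)
      expect_equal(unname(pm$values),
                   unname(study$patterns[[roi]][[sub]]$values),
                   tolerance = 1e-6)  # float32 storage
    }
  }
  truth <- jsonlite::read_json(out$truth, simplifyVector = TRUE)
  expect_equal(truth$roiA, "detector_phrase")
  expect_equal(truth$roiB, "noise")
})
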