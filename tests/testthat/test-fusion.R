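# Fusion: concatenation, AUC-proportional weights, late and hybrid
# prediction, branch-AUC estimation.

test_that("early fusion concatenates latents first, biomarkers second", {
  lat <- seq_len(15) / 10
  pan <- -seq_len(18) / 10
  v <- early_fuse(lat, pan)
  expect_length(v, 33)
  expect_equal(v[1], lat[1])
  expect_equal(v[16], pan[1])
  expect_equal(early_fuse(rep(0, 15), rep(0, 18)), rep(0, 33))
  M <- early_fuse(matrix(lat, 2, 15, byrow = TRUE),
                  matrix(pan, 2, 18, byrow = TRUE))
  expect_equal(dim(M), c(2, 33))
  expect_error(early_fuse(c(1, NA), c(1, 2)), "non-finite")
})

test_that("fusion weights are proportional to branch AUCs and sum to one", {
  w <- compute_auc_weights(0.8, 0.2)
  expect_equal(c(w$w_image, w$w_biomarker), c(0.8, 0.2))
  w <- compute_auc_weights(0.7, 0.7)
  expect_equal(c(w$w_image, w$w_biomarker), c(0.5, 0.5))
  w <- compute_auc_weights(0.6, 0.9)
  expect_equal(c(w$w_image, w$w_biomarker), c(0.4, 0.6))
  expect_error(compute_auc_weights(-0.1, 0.5), "nonnegative")
  expect_error(compute_auc_weights(1.1, 0.5), "at most 1")
})

test_that("weights are valid over the whole AUC grid including both-zero", {
  for (a in seq(0, 1, by = 0.25)) for (b in seq(0, 1, by = 0.25)) {
    w <- if (a == 0 && b == 0) {
      expect_warning(compute_auc_weights(a, b), "equal weights")
      suppressWarnings(compute_auc_weights(a, b))
    } else compute_auc_weights(a, b)
    expect_gte(w$w_image, 0)
    expect_gte(w$w_biomarker, 0)
    expect_equal(w$w_image + w$w_biomarker, 1, tolerance = 1e-12)
    if (a + b > 0) expect_equal(w$w_image * (a + b), a, tolerance = 1e-12)
  }
})

test_that("late fusion averages with weights and thresholds inclusively", {
  w <- compute_auc_weights(0.5, 0.5)
  pr <- late_fuse_predict(0.9, 0.1, w)
  expect_equal(pr$probability_pmf, 0.5)
  expect_equal(pr$label, 1L)  # threshold is inclusive
  w2 <- compute_auc_weights(0.75, 0.25)
  expect_equal(late_fuse_predict(0.8, 0.2, w2)$probability_pmf, 0.65)
  # boundary weight reproduces the image branch exactly
  w_img <- compute_auc_weights(1, 0)
  p <- runif(20)
  expect_equal(late_fuse_predict(p, runif(20), w_img)$probability_pmf, p)
})

test_that("late fusion is monotone in both input probabilities", {
  set.seed(41)
  w <- compute_auc_weights(0.6, 0.8)
  for (rep in 1:50) {
    p1 <- runif(1); p2 <- runif(1)
    base <- late_fuse_predict(p1, p2, w)$probability_pmf
    up1 <- late_fuse_predict(min(1, p1 + 0.1), p2, w)$probability_pmf
    up2 <- late_fuse_predict(p1, min(1, p2 + 0.1), w)$probability_pmf
    expect_gte(up1, base)
    expect_gte(up2, base)
  }
})

test_that("hybrid schemes agree where they must", {
  q <- c(0.3, 0.8)
  expect_equal(hybrid_fuse_predict(q, q, scheme = "mean")$probability_pmf, q)
  expect_equal(hybrid_fuse_predict(q, q, auc_early = 0.7, auc_late = 0.9,
                                   scheme = "auc_proportional")$probability_pmf,
               q)
  expect_equal(hybrid_fuse_predict(0.6, 0.8)$probability_pmf, 0.7)
  expect_equal(
    hybrid_fuse_predict(0.6, 0.8, auc_early = 0.8, auc_late = 0.8,
                        scheme = "auc_proportional")$probability_pmf,
    hybrid_fuse_predict(0.6, 0.8, scheme = "mean")$probability_pmf)
  expect_error(hybrid_fuse_predict(0.5, 0.5, scheme = "vote"))
})

test_that("branch AUCs rank an image-signal-only construction correctly", {
  spec <- classifier_spec("rf", seed = 1, quick = TRUE)
  wins <- 0
  for (s in 1:6) {
    co <- small_cohort(seed = 400 + s, n_patients = 30, image_effect = 2,
                       biomarker_effect = 0)
    f <- filter_markers_by_missingness(co)$cohort
    ba <- estimate_branch_aucs(f$features, f$markers, f$samples$label,
                               f$samples$patient_id, spec, seed = s,
                               n_components = 10)
    expect_equal(ba$n_subfolds, 3)
    if (ba$auc_image > ba$auc_biomarker) wins <- wins + 1
  }
  expect_gte(wins, 5)
})

test_that("branch AUCs hover near chance when labels carry no signal", {
  spec <- classifier_spec("rf", seed = 2, quick = TRUE)
  co <- small_cohort(seed = 77, n_patients = 40, image_effect = 0,
                     biomarker_effect = 0)
  f <- filter_markers_by_missingness(co)$cohort
  ba <- estimate_branch_aucs(f$features, f$markers, f$samples$label,
                             f$samples$patient_id, spec, seed = 3,
                             n_components = 10)
  expect_lt(abs(ba$auc_image - 0.5), 0.12)
  expect_lt(abs(ba$auc_biomarker - 0.5), 0.12)
})

test_that("identical inputs to both branches give near-identical AUCs", {
  # both branches see the same information; the image branch still applies
  # its full-rank latent transform, so a small residual gap remains
  spec <- classifier_spec("svm", seed = 5,
                          grid = data.frame(C = 1, kernel = "linear",
                                            gamma = "scale",
                                            stringsAsFactors = FALSE))
  co <- small_cohort(seed = 88, n_patients = 60, image_effect = 1.5,
                     biomarker_effect = 1.5)
  f <- filter_markers_by_missingness(co)$cohort
  M <- f$markers
  M[is.na(M)] <- 0
  ba <- estimate_branch_aucs(M, M, f$samples$label, f$samples$patient_id,
                             spec, seed = 4, n_components = 18)
  expect_lte(abs(ba$auc_image - ba$auc_biomarker), 0.04)
})

test_that("branch estimation refuses cohorts with too few patients", {
  spec <- classifier_spec("rf", quick = TRUE)
  co <- small_cohort(seed = 9, n_patients = 4)
  f <- filter_markers_by_missingness(co)$cohort
  expect_error(
    estimate_branch_aucs(f$features, f$markers, f$samples$label,
                         f$samples$patient_id, spec, n_subfolds = 3),
    "patients per class")
})
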