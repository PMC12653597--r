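# Fold planning, nested tuning, metrics, AUC, aggregation, Wilcoxon, and
# the CV driver.

# cohort with one sample per patient and given labels
unit_cohort <- function(labels, ids = NULL) {
  ids <- ids %||% sprintf("u%02d", seq_along(labels))
  df <- tiny_manifest_df(length(labels), patients = ids)
  df$label <- c("SS", "PMF")[labels + 1]
  load_cohort(write_tiny_manifest(df))
}

test_that("balanced unit cohort yields one patient per class per fold", {
  co <- unit_cohort(rep(0:1, 5))
  plan <- plan_folds(co, k = 5, seed = 1)
  expect_true(plan$stratified)
  per_fold <- split(names(plan$assignments), plan$assignments)
  expect_length(per_fold, 5)
  y <- co$samples$label[match(names(plan$assignments),
                              co$samples$patient_id)]
  for (f in 1:5) {
    lab <- y[plan$assignments == f]
    expect_equal(sort(lab), c(0, 1))
  }
})

test_that("stratification falls back to plain group K-fold when infeasible", {
  co <- unit_cohort(c(rep(0, 6), rep(1, 6)))
  expect_true(plan_folds(co, k = 5, seed = 2)$stratified)
  co2 <- unit_cohort(c(rep(0, 4), rep(1, 5)))
  plan2 <- plan_folds(co2, k = 5, seed = 2)
  expect_false(plan2$stratified)
  expect_length(unique(plan2$assignments), 5)
  expect_error(plan_folds(unit_cohort(0:1), k = 5), "at least k")
})

test_that("no patient ever appears in both train and test of a fold", {
  for (s in 1:20) {
    co <- small_cohort(seed = 500 + s, n_patients = 25,
                       progression_prob = 0.4)
    plan <- plan_folds(co, k = 5, seed = s)
    pats <- co$samples$patient_id
    for (f in 1:5) {
      te_pat <- unique(pats[pats %in% names(plan$assignments)[plan$assignments == f]])
      tr_pat <- unique(pats[!pats %in% te_pat])
      expect_length(intersect(te_pat, tr_pat), 0)
    }
    expect_setequal(names(plan$assignments), unique(pats))
  }
})

test_that("grid search shortcuts singletons and breaks ties by order", {
  spec1 <- classifier_spec("rf", quick = TRUE)
  out <- nested_grid_search(matrix(rnorm(40), 20, 2), rep(0:1, 10),
                            paste0("p", 1:20), spec1)
  expect_equal(out$params, spec1$grid[1, , drop = FALSE])
  expect_null(out$table)
  # duplicated candidates: the first listed row must win
  grid <- default_grid("rf", quick = TRUE)[c(1, 1), ]
  spec2 <- classifier_spec("rf", grid = grid, seed = 3)
  set.seed(51)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(0:1, 30)
  out2 <- nested_grid_search(X, y, paste0("p", 1:60), spec2, seed = 5)
  expect_equal(rownames(out2$params), "1")
})

test_that("grid search recovers a planted optimal regularization", {
  wins <- 0
  for (s in 1:5) {
    set.seed(600 + s)
    n <- 48
    y <- rep(0:1, n / 2)
    X <- cbind(rnorm(n, 2.5 * y), rnorm(n))
    grid <- data.frame(C = c(1e-6, 10), kernel = "linear", gamma = "scale",
                       stringsAsFactors = FALSE)
    spec <- classifier_spec("svm", grid = grid, seed = s)
    out <- nested_grid_search(X, y, paste0("p", 1:n), spec, seed = s)
    if (out$params$C == 10) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("confusion metrics implement the four formulas and conventions", {
  m <- confusion_metrics(TP = 3, TN = 2, FP = 1, FN = 1)
  expect_equal(unname(m), c(5 / 7, 0.75, 0.75, 0.75))
  m2 <- confusion_metrics(TP = 4, TN = 6, FP = 0, FN = 0)
  expect_equal(unname(m2), c(1, 1, 1, 1))
  expect_warning(m3 <- confusion_metrics(TP = 0, TN = 3, FP = 0, FN = 2),
                 "precision")
  expect_equal(unname(m3), c(0.6, 0, 0, 0))
  expect_error(confusion_metrics(TP = -1, TN = 1, FP = 1, FN = 1),
               "nonnegative")
})

test_that("metric formulas agree with brute-force counting", {
  set.seed(61)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    cc <- c(TP = sum(pred & truth), TN = sum(!pred & !truth),
            FP = sum(pred & !truth), FN = sum(!pred & truth))
    got <- suppressWarnings(confusion_metrics(cc))
    expect_equal(unname(got), unname(brute_metrics(pred, truth)))
  }
})

test_that("rank AUC equals the pairwise Mann-Whitney probability", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rank_auc(rep(0.4, 6), rep(0:1, 3)), 0.5)
  expect_equal(rank_auc(c(0.7, 0.4, 0.6, 0.3), c(1, 0, 1, 0)), 1.0)
  expect_equal(rank_auc(c(0.7, 0.6, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(rank_auc(runif(4), rep(1, 4)), "both classes")
  set.seed(62)
  for (rep in 1:50) {
    n <- sample(4:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(rank_auc(s, y), brute_auc(s, y))
  }
})

test_that("fold aggregation gives t-intervals truncated to the unit range", {
  agg <- aggregate_folds(data.frame(auc = rep(0.8, 5)))
  expect_equal(agg$mean, 0.8)
  expect_equal(agg$ci_lower, 0.8)
  expect_equal(agg$ci_upper, 0.8)
  agg2 <- aggregate_folds(data.frame(auc = c(0.8, 0.9)))
  hw <- qt(0.975, 1) * sd(c(0.8, 0.9)) / sqrt(2)
  expect_equal(agg2$mean, 0.85)
  expect_equal(agg2$ci_upper, min(1, 0.85 + hw))
  expect_equal(agg2$ci_lower, max(0, 0.85 - hw))
  set.seed(63)
  for (rep in 1:20) {
    v <- runif(5)
    a <- aggregate_folds(data.frame(m = v))
    expect_lte(a$ci_lower, a$mean)
    expect_gte(a$ci_upper, a$mean)
  }
  one <- aggregate_folds(data.frame(m = 0.7)[1, , drop = FALSE])
  expect_true(is.na(one$ci_lower))
})

test_that("exact Wilcoxon matches enumeration and the classic conventions", {
  expect_warning(r0 <- wilcoxon_paired_auc(c(0.7, 0.8), c(0.7, 0.8)),
                 "zero")
  expect_equal(r0$p_value, 1)
  r1 <- wilcoxon_paired_auc(c(0.6, 0.7, 0.6, 0.8, 0.7),
                            c(0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(r1$p_value, 2 / 2^5)  # all five differences positive
  r2 <- wilcoxon_paired_auc(c(0.5, 0.5, 0.5, 0.5, 0.5),
                            c(0.6, 0.7, 0.6, 0.8, 0.7))
  expect_equal(r2$p_value, r1$p_value)  # two-sided symmetry
  set.seed(64)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    a <- round(runif(n), 2)
    b <- round(runif(n), 2)
    d <- (a - b)[a != b]
    if (length(d) < 1) next
    got <- suppressWarnings(wilcoxon_paired_auc(a, b))$p_value
    expect_equal(got, enum_signrank_p(d))
    if (!any(duplicated(abs(d))) ) {
      ref <- wilcox.test(d, exact = TRUE)$p.value
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("cross-validation reuses one plan and keeps strategies paired", {
  co <- small_cohort(seed = 91, n_patients = 24, image_effect = 1.5,
                     biomarker_effect = 1.0)
  spec <- classifier_spec("rf", seed = 2, quick = TRUE)
  ex <- silicastage:::run_cv(co, c("image_only", "late"), spec, seed = 2)
  expect_named(ex$results, c("image_only", "late"))
  for (s in names(ex$results)) {
    pf <- ex$results[[s]]$per_fold
    expect_equal(nrow(pf), 5)
    expect_equal(sum(pf$TP + pf$TN + pf$FP + pf$FN), n_samples(co))
    expect_true(all(pf[, c("accuracy", "precision", "recall", "f1")] >= 0 &
                      pf[, c("accuracy", "precision", "recall", "f1")] <= 1))
  }
  # identical fold plans make the AUC vectors paired
  expect_identical(ex$results$image_only$predictions$sample_id,
                   ex$results$late$predictions$sample_id)
  # per-fold weights were recorded for the late branch
  w <- ex$fold_meta[[1]]$weights
  expect_s3_class(w, "fusion_weights")
  expect_equal(w$w_image + w$w_biomarker, 1, tolerance = 1e-12)
})

test_that("run_experiment is deterministic for a fixed seed", {
  co <- small_cohort(seed = 92, n_patients = 20)
  spec <- classifier_spec("rf", seed = 5, quick = TRUE)
  r1 <- run_experiment(co, "late", spec, seed = 5)
  r2 <- run_experiment(co, "late", spec, seed = 5)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$metrics, r2$metrics)
})
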