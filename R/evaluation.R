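# Patient-aware stratified 5-fold outer cross-validation with nested
# group-aware grid search, confusion-matrix metrics, rank-based AUC, fold
# aggregation with 95% confidence intervals, and exact Wilcoxon
# signed-rank comparison of paired fold AUCs.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Greedy stratified patient-grouped assignment over samples; shared by the
# outer plan and the inner tuning/sub-fold splits. patients/labels are
# per-sample vectors.
.group_fold_plan <- function(patients, labels, k, seed = 1) {
  tab <- table(patients, factor(labels, levels = 0:1))
  ids <- rownames(tab)
  n0 <- tab[, 1]; n1 <- tab[, 2]; tot <- n0 + n1
  if (length(ids) < k) {
    stop("need at least k = ", k, " patients, have ", length(ids))
  }
  per_class_patients <- c(sum(n0 > 0), sum(n1 > 0))
  jitter <- .with_private_seed(seed, stats::runif(length(ids)))
  ord <- order(-tot, jitter)
  stratified <- all(per_class_patients >= k)
  assign_greedy <- function() {
    f0 <- numeric(k); f1 <- numeric(k); fs <- numeric(k)
    a <- integer(length(ids))
    for (i in ord) {
      cost <- vapply(seq_len(k), function(f) {
        c0 <- f0; c1 <- f1
        c0[f] <- c0[f] + n0[i]; c1[f] <- c1[f] + n1[i]
        stats::sd(c0) + stats::sd(c1)
      }, numeric(1))
      cand <- which(cost == min(cost))
      f <- cand[which.min(fs[cand])]
      a[i] <- f
      f0[f] <- f0[f] + n0[i]; f1[f] <- f1[f] + n1[i]
      fs[f] <- fs[f] + tot[i]
    }
    a
  }
  assign_plain <- function() {
    fs <- numeric(k)
    a <- integer(length(ids))
    for (i in ord) {
      f <- which.min(fs)
      a[i] <- f
      fs[f] <- fs[f] + tot[i]
    }
    a
  }
  if (stratified) {
    a <- assign_greedy()
    fold_c0 <- vapply(seq_len(k), function(f) sum(n0[a == f]), numeric(1))
    fold_c1 <- vapply(seq_len(k), function(f) sum(n1[a == f]), numeric(1))
    single <- (fold_c0 + fold_c1 > 0) & (fold_c0 == 0 | fold_c1 == 0)
    if (any(fold_c0 + fold_c1 == 0) || any(single)) stratified <- FALSE
  }
  if (!stratified) a <- assign_plain()
  structure(list(k = k, assignments = stats::setNames(a, ids),
                 stratified = stratified, seed = seed),
            class = "fold_plan")
}

#' Plan patient-aware stratified folds
#'
#' Assigns every patient (with all of their longitudinal samples) to
#' exactly one of `k` folds. The primary strategy is a greedy stratified
#' group assignment: patients, ordered by decreasing sample count, are
#' placed in the fold that best balances the per-fold sample-level class
#' counts. If either class is carried by fewer than `k` patients, or the
#' greedy result leaves a fold single-class, the plan falls back to a
#' plain group K-fold (size-balanced, class-blind) and records
#' `stratified = FALSE`. Patients with mixed SS/PMF sample sets
#' (progressors) contribute their full label multiset to the balance.
#'
#' @param cohort A `silica_cohort`.
#' @param k Number of folds (default 5).
#' @param seed Seed breaking assignment ties.
#' @return A `fold_plan`: `k`, named `assignments` (patient -> fold),
#'   `stratified` flag.
#' @export
plan_folds <- function(cohort, k = 5, seed = 1) {
  stopifnot(inherits(cohort, "silica_cohort"))
  .group_fold_plan(cohort$samples$patient_id, cohort$samples$label,
                   k = k, seed = seed)
}

# Sample membership of one fold's test set.
.fold_test_mask <- function(plan, patients) {
  lapply(seq_len(plan$k), function(f) {
    patients %in% names(plan$assignments)[plan$assignments == f]
  })
}

#' Group-aware nested grid search
#'
#' Evaluates every candidate row of the spec's grid by mean held-out AUC
#' over `inner_k` patient-grouped folds of the training set; ties are
#' broken by grid order (first listed wins). A single-row grid is returned
#' without any inner split. The caller refits the winner on the full
#' training set.
#'
#' @param features Training feature matrix.
#' @param labels 0/1 vector.
#' @param patients Patient id per training sample.
#' @param spec A `classifier_spec`.
#' @param inner_k Inner fold count (default 3).
#' @param seed Seed for the inner fold plan.
#' @return List: `params` (winning row), `mean_auc`, `table` (per-candidate
#'   mean AUCs; `NULL` for the single-candidate shortcut).
#' @export
nested_grid_search <- function(features, labels, patients, spec,
                               inner_k = 3, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  grid <- spec$grid
  if (nrow(grid) == 1) {
    return(list(params = grid[1, , drop = FALSE], mean_auc = NA_real_,
                table = NULL))
  }
  X <- as.matrix(features)
  y <- as.numeric(labels)
  plan <- .group_fold_plan(patients, y, k = inner_k, seed = seed)
  masks <- .fold_test_mask(plan, patients)
  feasible <- vapply(masks, function(te) {
    length(unique(y[te])) == 2 && length(unique(y[!te])) == 2
  }, logical(1))
  if (!any(feasible)) stop("no feasible inner split: every inner fold is ",
                           "single-class")
  mean_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(which(feasible), function(f) {
      te <- masks[[f]]
      m <- fit_modality_model(X[!te, , drop = FALSE], y[!te], spec,
                              grid[g, , drop = FALSE])
      rank_auc(predict_prob(m, X[te, , drop = FALSE]), y[te])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(mean_auc)  # ties: first listed wins
  list(params = grid[best, , drop = FALSE], mean_auc = mean_auc[best],
       table = cbind(grid, mean_auc = mean_auc))
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, precision, recall and F1 from the four confusion counts with
#' PMF as the positive class. Precision is reported as 0 with a warning
#' when no positive call was made (`TP + FP = 0`), recall likewise when no
#' positive case exists; F1 is 0 when precision + recall is 0.
#'
#' @param TP,TN,FP,FN Nonnegative integer counts (or a list/vector with
#'   those names as first argument).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.list(TP) || (is.numeric(TP) && length(TP) == 4 && !is.null(names(TP)))) {
    cc <- TP; TP <- cc[["TP"]]; TN <- cc[["TN"]]
    FP <- cc[["FP"]]; FN <- cc[["FN"]]
  }
  cnt <- c(TP, TN, FP, FN)
  if (any(cnt < 0)) stop("confusion counts must be nonnegative")
  if (sum(cnt) == 0) stop("no evaluated samples")
  accuracy <- (TP + TN) / sum(cnt)
  if (TP + FP == 0) {
    warning("no positive prediction; precision reported as 0")
    precision <- 0
  } else precision <- TP / (TP + FP)
  if (TP + FN == 0) {
    warning("no positive case; recall reported as 0")
    recall <- 0
  } else recall <- TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the empirical ROC curve via the rank-sum formulation, with
#' tied scores counted 0.5 — the probability that a random PMF sample
#' outranks a random SS sample.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Aggregate per-fold metrics with 95% confidence intervals
#'
#' Mean across folds with a t-interval (k - 1 degrees of freedom),
#' truncated to `[0, 1]`. With a single fold the mean is returned and the
#' interval flagged unavailable.
#'
#' @param per_fold Data frame or matrix of per-fold metric values (one row
#'   per fold, one column per metric).
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `metric`, `mean`, `ci_lower`, `ci_upper`,
#'   `n_folds`.
#' @export
aggregate_folds <- function(per_fold, conf = 0.95) {
  M <- as.matrix(per_fold)
  k <- nrow(M)
  out <- data.frame(metric = colnames(M), mean = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_, n_folds = k,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(M))) {
    v <- M[, j][!is.na(M[, j])]
    m <- mean(v)
    out$mean[j] <- m
    if (length(v) >= 2) {
      hw <- stats::qt(1 - (1 - conf) / 2, length(v) - 1) *
        stats::sd(v) / sqrt(length(v))
      out$ci_lower[j] <- max(0, m - hw)
      out$ci_upper[j] <- min(1, m + hw)
    }
  }
  out
}

# Exact null distribution of the signed-rank statistic by shift
# convolution over the (doubled, hence integer) ranks; equivalent to full
# 2^n sign enumeration.
.signrank_exact_p <- function(W, ranks) {
  r2 <- as.integer(round(2 * ranks))
  S <- sum(r2)
  f <- numeric(S + 1)
  f[1] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1):(S + 1)] <- g[(ri + 1):(S + 1)] + f[1:(S + 1 - ri)]
    f <- g
  }
  tot <- 2^length(r2)
  W2 <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(W2 + 1)]) / tot
  p_ge <- sum(f[(W2 + 1):(S + 1)]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Exact Wilcoxon signed-rank comparison of paired fold AUCs
#'
#' Two-sided signed-rank test on the per-fold AUC differences of two
#' models evaluated on the identical fold plan. Zero differences are
#' dropped before ranking (classic convention); absolute differences are
#' midranked, and for n <= 25 the p-value is exact — the statistic's full
#' sign-flip null distribution (equivalent to enumerating all 2^n sign
#' patterns) — with a normal approximation beyond.
#'
#' @param aucs_a,aucs_b Equal-length (>= 2) paired fold AUC vectors.
#' @param model_a,model_b Run identifiers for the report.
#' @param alpha Significance threshold reported alongside (default 0.05).
#' @return A `comparison_result`: `model_a`, `model_b`,
#'   `paired_auc_diffs`, `statistic` (W+), `p_value`, `significant`.
#' @export
wilcoxon_paired_auc <- function(aucs_a, aucs_b, model_a = "A", model_b = "B",
                                alpha = 0.05) {
  if (length(aucs_a) != length(aucs_b)) stop("paired vectors differ in length")
  if (length(aucs_a) < 2) stop("need at least 2 paired folds")
  d <- aucs_a - aucs_b
  d <- d[!is.na(d)]
  dnz <- d[d != 0]
  if (length(dnz) == 0) {
    warning("all paired AUC differences are zero; p = 1")
    p <- 1
    W <- 0
  } else {
    r <- rank(abs(dnz))
    W <- sum(r[dnz > 0])
    n <- length(dnz)
    if (n <= 25) {
      p <- .signrank_exact_p(W, r)
    } else {
      mu <- n * (n + 1) / 4
      ties <- table(r)
      sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(ties^3 - ties) / 48
      p <- min(1, 2 * stats::pnorm(-abs(W - mu) / sqrt(sig2)))
    }
  }
  structure(list(model_a = model_a, model_b = model_b,
                 paired_auc_diffs = d, statistic = W, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: %s vs %s | W+ = %.1f, p = %.4f%s\n",
              x$model_a, x$model_b, x$statistic, x$p_value,
              if (x$significant) sprintf(" (< %.2f)", x$alpha) else ""))
  invisible(x)
}

# ---- outer cross-validation driver --------------------------------------

.strategies_all <- c("image_only", "biomarker_only", "early", "late",
                     "hybrid")

# Deterministic per-fold sub-seed expansion from the run seed.
.fold_seed <- function(seed, fold) ((seed %% 1000003L) * 97L + fold) %% 2147483647L

# One shared pass computing every requested strategy on a common fold
# plan. Returns per-strategy cv results plus fold artifacts.
run_cv <- function(cohort, strategies, spec, k_outer = 5, k_inner = 3,
                   n_subfolds = 3, n_components = 15,
                   missingness_threshold = 0.20,
                   hybrid_scheme = c("mean", "auc_proportional"),
                   threshold = 0.5, seed = 1, fold_plan = NULL,
                   backbone = NULL, seg_backend = NULL) {
  hybrid_scheme <- match.arg(hybrid_scheme)
  strategies <- match.arg(strategies, .strategies_all, several.ok = TRUE)
  filt <- filter_markers_by_missingness(cohort, missingness_threshold)
  cohort <- filt$cohort
  feats <- cohort_features(cohort, backbone, seg_backend)
  y <- cohort$samples$label
  patients <- cohort$samples$patient_id
  if (min(table(factor(y, levels = 0:1))) == 0) {
    stop("cohort must contain both classes")
  }
  plan <- fold_plan %||% plan_folds(cohort, k = k_outer, seed = seed)
  masks <- .fold_test_mask(plan, patients)
  k <- plan$k
  need_img <- any(strategies %in% c("image_only", "late", "hybrid"))
  need_bio <- any(strategies %in% c("biomarker_only", "late", "hybrid"))
  need_early <- any(strategies %in% c("early", "hybrid"))
  need_branch <- any(strategies %in% c("late", "hybrid"))
  probs <- lapply(strategies, function(s) vector("list", k))
  names(probs) <- strategies
  fold_meta <- vector("list", k)
  for (f in seq_len(k)) {
    te <- masks[[f]]; tr <- !te
    if (length(unique(y[tr])) < 2) {
      stop("outer fold ", f, " has a single-class training set")
    }
    fseed <- .fold_seed(seed, f)
    trans <- suppressWarnings(
      fit_image_transformer(feats[tr, , drop = FALSE], y[tr],
                            n_components = n_components))
    Ltr <- trans$train_scores
    Lte <- transform_image_features(trans, feats[te, , drop = FALSE])
    prep <- .fit_marker_prep(cohort$markers[tr, , drop = FALSE])
    Mtr <- .apply_marker_prep(prep, cohort$markers[tr, , drop = FALSE])
    Mte <- .apply_marker_prep(prep, cohort$markers[te, , drop = FALSE])
    meta <- list(fold = f)
    p_img <- p_bio <- p_early <- NULL
    params_img <- params_bio <- params_early <- NULL
    if (need_img) {
      params_img <- nested_grid_search(Ltr, y[tr], patients[tr], spec,
                                       inner_k = k_inner,
                                       seed = fseed)$params
      m <- fit_modality_model(Ltr, y[tr], spec, params_img)
      p_img <- predict_prob(m, Lte)
      meta$params_image <- params_img
    }
    if (need_bio) {
      params_bio <- nested_grid_search(Mtr, y[tr], patients[tr], spec,
                                       inner_k = k_inner,
                                       seed = fseed)$params
      m <- fit_modality_model(Mtr, y[tr], spec, params_bio)
      p_bio <- predict_prob(m, Mte)
      meta$params_biomarker <- params_bio
    }
    if (need_early) {
      Etr <- early_fuse(Ltr, Mtr); Ete <- early_fuse(Lte, Mte)
      params_early <- nested_grid_search(Etr, y[tr], patients[tr], spec,
                                         inner_k = k_inner,
                                         seed = fseed)$params
      m <- fit_modality_model(Etr, y[tr], spec, params_early)
      p_early <- predict_prob(m, Ete)
      meta$params_early <- params_early
    }
    if (need_branch) {
      branch <- .inner_branch_aucs(
        feats[tr, , drop = FALSE], cohort$markers[tr, , drop = FALSE],
        y[tr], patients[tr], spec,
        params_img = params_img, params_bio = params_bio,
        params_early = params_early, n_subfolds = n_subfolds,
        seed = fseed, n_components = n_components,
        want_early = "hybrid" %in% strategies &&
          hybrid_scheme == "auc_proportional")
      weights <- compute_auc_weights(branch)
      p_late <- late_fuse_predict(p_img, p_bio, weights,
                                  threshold)$probability_pmf
      meta$branch_aucs <- branch
      meta$weights <- weights
    }
    for (s in strategies) {
      probs[[s]][[f]] <- switch(s,
        image_only = p_img,
        biomarker_only = p_bio,
        early = p_early,
        late = p_late,
        hybrid = hybrid_fuse_predict(
          p_early, p_late,
          auc_early = branch$auc_early, auc_late = branch$auc_late,
          scheme = hybrid_scheme, threshold = threshold)$probability_pmf
      )
    }
    fold_meta[[f]] <- meta
  }
  results <- lapply(strategies, function(s) {
    per_fold <- data.frame(fold = seq_len(k), TP = NA_integer_,
                           TN = NA_integer_, FP = NA_integer_,
                           FN = NA_integer_, accuracy = NA_real_,
                           precision = NA_real_, recall = NA_real_,
                           f1 = NA_real_, auc = NA_real_)
    preds <- vector("list", k)
    for (f in seq_len(k)) {
      te <- masks[[f]]
      p <- probs[[s]][[f]]
      lab <- as.integer(p >= threshold)
      yt <- y[te]
      per_fold$TP[f] <- sum(lab == 1 & yt == 1)
      per_fold$TN[f] <- sum(lab == 0 & yt == 0)
      per_fold$FP[f] <- sum(lab == 1 & yt == 0)
      per_fold$FN[f] <- sum(lab == 0 & yt == 1)
      met <- suppressWarnings(confusion_metrics(
        per_fold$TP[f], per_fold$TN[f], per_fold$FP[f], per_fold$FN[f]))
      per_fold[f, names(met)] <- met
      per_fold$auc[f] <- if (length(unique(yt)) == 2) rank_auc(p, yt)
                         else NA_real_
      preds[[f]] <- data.frame(
        sample_id = cohort$samples$sample_id[te],
        patient_id = cohort$samples$patient_id[te], fold = f,
        label = yt, probability = p, prediction = lab,
        stringsAsFactors = FALSE)
    }
    structure(list(
      strategy = s,
      per_fold = per_fold,
      metrics = aggregate_folds(per_fold[, c("accuracy", "precision",
                                             "recall", "f1", "auc")]),
      predictions = do.call(rbind, preds)
    ), class = "cv_result")
  })
  names(results) <- strategies
  structure(list(results = results, fold_plan = plan, fold_meta = fold_meta,
                 spec = spec, removed_markers = filt$removed, seed = seed),
            class = "experiment_result")
}

#' Run one fusion strategy through nested patient-aware cross-validation
#'
#' For every outer fold: the image transformer, biomarker
#' imputation/scaling and all hyperparameters are fitted on the training
#' patients only; the tuned model is refitted on the full outer training
#' set and evaluated on the held-out patients. Late and hybrid strategies
#' additionally estimate branch AUCs on 3 internal patient-grouped
#' sub-folds of each training set to derive the fusion weights.
#'
#' @param cohort A `silica_cohort` (markers are filtered for missingness
#'   internally).
#' @param strategy One of `"image_only"`, `"biomarker_only"`, `"early"`,
#'   `"late"`, `"hybrid"`.
#' @param spec A `classifier_spec`.
#' @param k_outer,k_inner Outer/inner fold counts (defaults 5 and 3).
#' @param n_subfolds Internal sub-folds for branch-AUC estimation.
#' @param n_components PLS-DA latent components (default 15).
#' @param missingness_threshold Marker exclusion cutoff (default 0.20).
#' @param hybrid_scheme `"mean"` or `"auc_proportional"`.
#' @param threshold Decision threshold (default 0.5).
#' @param seed Run seed; expands deterministically into per-fold seeds.
#' @param fold_plan Optional pre-computed `fold_plan`, reused across
#'   strategies for paired comparison.
#' @param backbone,seg_backend Needed only for image-file cohorts (see
#'   [make_stub_backbone()], [oracle_backend()]).
#' @return A `cv_result`: per-fold confusion counts and metrics, the
#'   aggregate metric table with 95% CIs, and held-out predictions. The
#'   fold plan is attached as attribute `fold_plan`.
#' @export
run_experiment <- function(cohort, strategy, spec, k_outer = 5, k_inner = 3,
                           n_subfolds = 3, n_components = 15,
                           missingness_threshold = 0.20,
                           hybrid_scheme = "mean", threshold = 0.5,
                           seed = 1, fold_plan = NULL, backbone = NULL,
                           seg_backend = NULL) {
  strategy <- match.arg(strategy, .strategies_all)
  ex <- run_cv(cohort, strategy, spec, k_outer = k_outer, k_inner = k_inner,
               n_subfolds = n_subfolds, n_components = n_components,
               missingness_threshold = missingness_threshold,
               hybrid_scheme = hybrid_scheme, threshold = threshold,
               seed = seed, fold_plan = fold_plan, backbone = backbone,
               seg_backend = seg_backend)
  res <- ex$results[[strategy]]
  attr(res, "fold_plan") <- ex$fold_plan
  attr(res, "fold_meta") <- ex$fold_meta
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$strategy, "\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-9s %.4f [%.4f-%.4f]\n", m$metric[i], m$mean[i],
                m$ci_lower[i], m$ci_upper[i]))
  }
  invisible(x)
}
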