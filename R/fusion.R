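# The three fusion architectures over the probabilistic-classifier
# contract: early (feature concatenation), late (AUC-proportional
# probability averaging), hybrid (combining the early- and late-branch
# probabilities).

# Fold-local biomarker preparation: mean imputation of residual missing
# values followed by standardization, both fitted on training samples only.
.fit_marker_prep <- function(M) {
  M <- as.matrix(M)
  mu <- colMeans(M, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  Mi <- M
  for (j in seq_len(ncol(M))) Mi[is.na(Mi[, j]), j] <- mu[j]
  list(impute_means = mu, scaler = .fit_scaler(Mi))
}

.apply_marker_prep <- function(prep, M) {
  M <- if (is.matrix(M)) M else matrix(M, nrow = 1)
  for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- prep$impute_means[j]
  .apply_scaler(prep$scaler, M)
}

#' Early fusion: concatenate latent image scores and biomarker vector
#'
#' Image latents come first, then the standardized biomarkers; no
#' re-scaling is applied after concatenation. Under the defaults (15
#' latent components, 18 retained markers) the fused vector has length 33.
#'
#' @param latent Latent score vector/matrix from
#'   [transform_image_features()].
#' @param panel_values Fold-standardized (and imputed) biomarker
#'   vector/matrix.
#' @return Fused vector, or row-wise fused matrix for matrix inputs.
#' @export
early_fuse <- function(latent, panel_values) {
  if (is.matrix(latent) || is.matrix(panel_values)) {
    latent <- if (is.matrix(latent)) latent else matrix(latent, nrow = 1)
    panel_values <- if (is.matrix(panel_values)) panel_values
                    else matrix(panel_values, nrow = 1)
    if (nrow(latent) != nrow(panel_values)) {
      stop("latent and biomarker row counts differ")
    }
    out <- cbind(latent, panel_values)
  } else {
    out <- c(latent, panel_values)
  }
  if (any(!is.finite(out))) stop("fused vector contains non-finite values")
  unname(out)
}

#' AUC-proportional fusion weights
#'
#' Decision-level weights assigned in direct proportion to each branch's
#' internal-validation AUC:
#' `w_image = AUC_image / (AUC_image + AUC_biomarker)` and symmetrically
#' for the biomarker branch. The degenerate both-zero input falls back to
#' equal weights with a warning rather than failing the fold.
#'
#' @param auc_image,auc_biomarker Branch AUCs in `[0, 1]`, or a
#'   `branch_aucs` object as first argument.
#' @return A `fusion_weights` list: `w_image`, `w_biomarker` (nonnegative,
#'   summing to 1).
#' @export
compute_auc_weights <- function(auc_image, auc_biomarker = NULL) {
  if (inherits(auc_image, "branch_aucs")) {
    auc_biomarker <- auc_image$auc_biomarker
    auc_image <- auc_image$auc_image
  }
  if (auc_image < 0 || auc_biomarker < 0) stop("AUCs must be nonnegative")
  if (auc_image > 1 || auc_biomarker > 1) stop("AUCs must be at most 1")
  s <- auc_image + auc_biomarker
  if (s == 0) {
    warning("both branch AUCs are zero; falling back to equal weights")
    w <- c(0.5, 0.5)
  } else {
    w <- c(auc_image, auc_biomarker) / s
  }
  structure(list(w_image = w[1], w_biomarker = w[2]),
            class = "fusion_weights")
}

#' Late fusion of per-modality probabilities
#'
#' Weighted average of the two modality probabilities followed by the 0.5
#' decision threshold (inclusive: a fused probability exactly at the
#' threshold is called PMF).
#'
#' @param p_image,p_biomarker Probability vectors in `[0, 1]`.
#' @param weights A `fusion_weights` object.
#' @param threshold Decision threshold (default 0.5).
#' @return Data frame with `probability_pmf` and `label`.
#' @export
late_fuse_predict <- function(p_image, p_biomarker, weights,
                              threshold = 0.5) {
  stopifnot(inherits(weights, "fusion_weights"))
  if (any(p_image < 0 | p_image > 1) || any(p_biomarker < 0 | p_biomarker > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  p <- weights$w_image * p_image + weights$w_biomarker * p_biomarker
  data.frame(probability_pmf = p, label = as.integer(p >= threshold))
}

#' Hybrid fusion of the early- and late-branch probabilities
#'
#' Combines the early-fusion classifier's probability with the late-fusion
#' branch's fused score. Scheme `"mean"` (default) averages the two;
#' scheme `"auc_proportional"` weights the two branches in proportion to
#' their AUCs on the same internal sub-folds that produced the late-branch
#' modality weights.
#'
#' @param p_early,p_late Probability vectors in `[0, 1]`.
#' @param auc_early,auc_late Branch AUCs, required for
#'   `scheme = "auc_proportional"`.
#' @param scheme `"mean"` or `"auc_proportional"`.
#' @param threshold Decision threshold (default 0.5, inclusive).
#' @return Data frame with `probability_pmf` and `label`.
#' @export
hybrid_fuse_predict <- function(p_early, p_late, auc_early = NULL,
                                auc_late = NULL,
                                scheme = c("mean", "auc_proportional"),
                                threshold = 0.5) {
  scheme <- match.arg(scheme)
  if (any(p_early < 0 | p_early > 1) || any(p_late < 0 | p_late > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  p <- if (scheme == "mean") {
    (p_early + p_late) / 2
  } else {
    if (is.null(auc_early) || is.null(auc_late)) {
      stop("auc_proportional scheme needs auc_early and auc_late")
    }
    s <- auc_early + auc_late
    if (s == 0) (p_early + p_late) / 2
    else (auc_early * p_early + auc_late * p_late) / s
  }
  data.frame(probability_pmf = p, label = as.integer(p >= threshold))
}

# One pass over the patient-grouped internal sub-folds of a training set,
# returning the mean held-out AUC of every branch requested. The late
# branch fuses the sub-fold image/biomarker probabilities with weights from
# the sub-fold mean branch AUCs (the same quantities that parameterize the
# outer-fold late fusion).
.inner_branch_aucs <- function(features, markers, y, patients, spec,
                               params_img = NULL, params_bio = NULL,
                               params_early = NULL, n_subfolds = 3,
                               seed = 1, n_components = 15,
                               want_early = FALSE) {
  per_class <- vapply(0:1, function(cl) {
    length(unique(patients[y == cl]))
  }, integer(1))
  if (any(per_class < n_subfolds)) {
    stop("branch AUC estimation needs at least ", n_subfolds,
         " patients per class (have ", min(per_class), ")")
  }
  plan <- .group_fold_plan(patients, y, k = n_subfolds, seed = seed)
  auc_i <- auc_b <- auc_e <- rep(NA_real_, n_subfolds)
  p_img_all <- p_bio_all <- vector("list", n_subfolds)
  y_te_all <- vector("list", n_subfolds)
  for (f in seq_len(n_subfolds)) {
    te <- patients %in% names(plan$assignments)[plan$assignments == f]
    tr <- !te
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) next
    trans <- suppressWarnings(
      fit_image_transformer(features[tr, , drop = FALSE], y[tr],
                            n_components = n_components))
    Ltr <- trans$train_scores
    Lte <- transform_image_features(trans, features[te, , drop = FALSE])
    prep <- .fit_marker_prep(markers[tr, , drop = FALSE])
    Mtr <- .apply_marker_prep(prep, markers[tr, , drop = FALSE])
    Mte <- .apply_marker_prep(prep, markers[te, , drop = FALSE])
    m_img <- fit_modality_model(Ltr, y[tr], spec, params_img)
    m_bio <- fit_modality_model(Mtr, y[tr], spec, params_bio)
    p_img <- predict_prob(m_img, Lte)
    p_bio <- predict_prob(m_bio, Mte)
    auc_i[f] <- rank_auc(p_img, y[te])
    auc_b[f] <- rank_auc(p_bio, y[te])
    p_img_all[[f]] <- p_img; p_bio_all[[f]] <- p_bio; y_te_all[[f]] <- y[te]
    if (want_early) {
      m_early <- fit_modality_model(early_fuse(Ltr, Mtr), y[tr], spec,
                                    params_early)
      auc_e[f] <- rank_auc(predict_prob(m_early, early_fuse(Lte, Mte)),
                           y[te])
    }
  }
  if (all(is.na(auc_i))) stop("no internal sub-fold had both classes held out")
  res <- list(auc_image = mean(auc_i, na.rm = TRUE),
              auc_biomarker = mean(auc_b, na.rm = TRUE),
              n_subfolds = n_subfolds)
  w <- compute_auc_weights(res$auc_image, res$auc_biomarker)
  auc_l <- rep(NA_real_, n_subfolds)
  for (f in seq_len(n_subfolds)) {
    if (is.null(y_te_all[[f]])) next
    fused <- w$w_image * p_img_all[[f]] + w$w_biomarker * p_bio_all[[f]]
    auc_l[f] <- rank_auc(fused, y_te_all[[f]])
  }
  res$auc_late <- mean(auc_l, na.rm = TRUE)
  if (want_early) res$auc_early <- mean(auc_e, na.rm = TRUE)
  structure(res, class = "branch_aucs")
}

#' Estimate per-branch AUCs on internal sub-folds of a training set
#'
#' Splits the training samples into `n_subfolds` patient-grouped sub-folds,
#' trains a unimodal image model (with its own fold-local PLS-DA
#' transformer) and a unimodal biomarker model (fold-local
#' imputation/scaling) on each sub-training set, and returns each branch's
#' mean held-out AUC. These means parameterize the late-fusion weights of
#' [compute_auc_weights()].
#'
#' @param features `n x D` matrix of raw backbone features for the
#'   training samples.
#' @param markers `n x m` biomarker matrix (raw scale; missing values
#'   allowed).
#' @param labels 0/1 vector.
#' @param patients Patient identifier per sample (grouping unit).
#' @param spec A `classifier_spec`.
#' @param params_img,params_bio Hyperparameter rows for the two unimodal
#'   models; defaults to the first grid row.
#' @param n_subfolds Number of internal sub-folds (default 3).
#' @param seed Seed for the sub-fold plan.
#' @param n_components Latent components for the sub-fold transformers.
#' @return A `branch_aucs` object: `auc_image`, `auc_biomarker`,
#'   `auc_late`, `n_subfolds`.
#' @export
estimate_branch_aucs <- function(features, markers, labels, patients, spec,
                                 params_img = NULL, params_bio = NULL,
                                 n_subfolds = 3, seed = 1,
                                 n_components = 15) {
  .inner_branch_aucs(as.matrix(features), as.matrix(markers),
                     as.numeric(labels), as.character(patients), spec,
                     params_img = params_img, params_bio = params_bio,
                     n_subfolds = n_subfolds, seed = seed,
                     n_components = n_components)
}
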