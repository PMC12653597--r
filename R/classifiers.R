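# Uniform probabilistic-classifier contract over the three shallow model
# families used by every fusion strategy: support vector machine (libsvm
# with Platt-calibrated probabilities), random forest (ranger probability
# forest) and gradient-boosted decision trees (xgboost, Bernoulli-style
# subsampling at rate 0.8).

#' Default hyperparameter grids
#'
#' Grid candidates per family, in the order they are searched (first listed
#' wins ties):
#' * `svm`: cost `C` in 0.1/1/10, kernel RBF or linear, `gamma` the
#'   scale heuristic (`1 / (n_features * var(X))`) or 0.01 or 0.001. The
#'   two numeric gamma candidates are package conventions; only the C and
#'   kernel candidates are externally fixed.
#' * `rf`: 100/200 trees, max depth 0 (unlimited)/10/20, min node size
#'   2/5, min terminal-bucket size 1/2.
#' * `gbdt`: 100/200 boosting rounds, learning rate 0.01/0.1, depth
#'   4/6/8, L2 leaf regularization 1/3/5; subsample fixed at 0.8.
#'
#' `quick = TRUE` returns a single-candidate grid per family for fast
#' smoke-profile runs.
#'
#' @param family One of `"svm"`, `"rf"`, `"gbdt"`.
#' @param quick Reduced single-row grid.
#' @return Data frame, one row per candidate.
#' @export
default_grid <- function(family = c("svm", "rf", "gbdt"), quick = FALSE) {
  family <- match.arg(family)
  if (quick) {
    return(switch(family,
      svm = data.frame(C = 1, kernel = "rbf", gamma = "scale",
                       stringsAsFactors = FALSE),
      rf = data.frame(num_trees = 100, max_depth = 0, min_node_size = 2,
                      min_bucket = 1),
      gbdt = data.frame(nrounds = 100, eta = 0.1, max_depth = 4, lambda = 1)
    ))
  }
  switch(family,
    svm = expand.grid(C = c(0.1, 1, 10), kernel = c("rbf", "linear"),
                      gamma = c("scale", "0.01", "0.001"),
                      stringsAsFactors = FALSE),
    rf = expand.grid(num_trees = c(100, 200), max_depth = c(0, 10, 20),
                     min_node_size = c(2, 5), min_bucket = c(1, 2)),
    gbdt = expand.grid(nrounds = c(100, 200), eta = c(0.01, 0.1),
                       max_depth = c(4, 6, 8), lambda = c(1, 3, 5))
  )
}

#' Classifier specification
#'
#' Bundles a model family, its candidate hyperparameter grid and the seed
#' controlling every stochastic element of fitting.
#'
#' @param family `"svm"`, `"rf"` or `"gbdt"`.
#' @param grid Candidate grid (default [default_grid()]).
#' @param seed Integer seed.
#' @param quick Use the reduced default grid.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "rf", "gbdt"), grid = NULL,
                            seed = 1L, quick = FALSE) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family, quick = quick)
  if (nrow(grid) == 0) stop("hyperparameter grid must be non-empty")
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit one probabilistic classifier
#'
#' Trains a model of the spec's family with the given parameter row.
#' Probability outputs for the positive (PMF) class are available for
#' every family; forests and boosted trees are bit-reproducible given the
#' seed.
#'
#' @param features `n x p` numeric matrix.
#' @param labels 0/1 vector (both classes required).
#' @param spec A `classifier_spec`.
#' @param params One-row data frame from the spec's grid; default first
#'   row.
#' @return A `modality_model` handle for [predict_prob()].
#' @export
fit_modality_model <- function(features, labels, spec, params = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(features)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("cannot fit on single-class labels")
  if (is.null(params)) params <- spec$grid[1, , drop = FALSE]
  set.seed(spec$seed)
  fit <- switch(spec$family,
    svm = {
      g <- params$gamma
      gval <- if (identical(g, "scale")) {
        v <- stats::var(as.vector(X))
        if (!is.finite(v) || v == 0) v <- 1
        1 / (ncol(X) * v)
      } else as.numeric(g)
      e1071::svm(x = X, y = factor(y, levels = 0:1),
                 kernel = if (params$kernel == "rbf") "radial" else "linear",
                 cost = params$C, gamma = gval, probability = TRUE,
                 scale = FALSE)
    },
    rf = ranger::ranger(
      x = X, y = factor(y, levels = 0:1), probability = TRUE,
      num.trees = params$num_trees,
      max.depth = if (params$max_depth == 0) NULL else params$max_depth,
      min.node.size = params$min_node_size,
      min.bucket = params$min_bucket,
      num.threads = 1, seed = spec$seed, verbose = FALSE),
    gbdt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth, lambda = params$lambda,
                    subsample = 0.8, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0)
  )
  structure(list(family = spec$family, fit = fit, params = params,
                 p = ncol(X)), class = "modality_model")
}

#' Positive-class probability predictions
#'
#' @param model A `modality_model` from [fit_modality_model()].
#' @param features `n x p` matrix on the same feature space the model was
#'   fitted on.
#' @return Numeric vector of PMF probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "modality_model"))
  X <- as.matrix(features)
  if (ncol(X) != model$p) {
    stop("feature dimension ", ncol(X), " does not match the fitted ",
         model$p)
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  switch(model$family,
    svm = {
      pr <- attr(stats::predict(model$fit, X, probability = TRUE),
                 "probabilities")
      unname(pr[, "1"])
    },
    rf = unname(stats::predict(model$fit, data = X,
                               num.threads = 1)$predictions[, "1"]),
    gbdt = as.numeric(stats::predict(model$fit,
                                     xgboost::xgb.DMatrix(X, nthread = 1)))
  )
}
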