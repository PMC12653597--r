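# Imaging-modality representation: frozen-backbone feature extraction
# ending in global average pooling, then the fold-fitted three-phase
# transform standardize -> PLS-DA latent projection -> standardize.

#' Global average pooling of a convolutional feature map
#'
#' Collapses an `h x w x C` final feature map to a length-`C` vector by
#' taking the spatial mean of each channel — for the reference backbone, a
#' `7 x 7 x 1280` map becomes the 1280-dimensional radiograph descriptor.
#'
#' @param feature_map 3-D numeric array, channels last.
#' @return Numeric vector of per-channel spatial means.
#' @export
gap_pool <- function(feature_map) {
  if (length(dim(feature_map)) != 3) {
    stop("gap_pool expects an h x w x C feature map")
  }
  apply(feature_map, 3, mean)
}

# Run `expr` under a private RNG stream so frozen components never disturb
# (or depend on) the caller's random state.
.with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Frozen random-projection backbone stub
#'
#' A stateless, deterministic stand-in honouring the frozen-backbone
#' contract: the same image always maps to the same fixed-length feature
#' vector and nothing is ever trained. The stub block-averages the first
#' channel of the preprocessed image to a `pool x pool` grid and applies a
#' fixed Gaussian random projection drawn once from `seed`. A pretrained
#' convolutional backbone (1280-dimensional output) can be plugged in
#' through the same contract by supplying its own `extract` closure via
#' [backbone_contract()].
#'
#' @param output_dim Feature dimension D (default 64).
#' @param seed Seed freezing the projection.
#' @param pool Side of the pooling grid; must divide the image size.
#' @return A `backbone` object with fields `name`, `output_dim`, `extract`.
#' @export
make_stub_backbone <- function(output_dim = 64, seed = 42, pool = 16) {
  W <- .with_private_seed(seed, matrix(
    stats::rnorm(output_dim * pool * pool) / sqrt(pool * pool),
    nrow = output_dim))
  extract <- function(tensor) {
    side <- dim(tensor)[1]
    if (side %% pool != 0) stop("image size must be a multiple of ", pool)
    f <- side %/% pool
    ch <- tensor[, , 1]
    pooled <- vapply(seq_len(pool), function(j) {
      vapply(seq_len(pool), function(i) {
        mean(ch[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
      }, numeric(1))
    }, numeric(pool))
    as.numeric(W %*% c(pooled))
  }
  backbone_contract("stub", output_dim, extract)
}

#' @rdname make_stub_backbone
#' @param name Backbone identifier.
#' @param extract Function mapping a preprocessed `size x size x 3` tensor
#'   to a numeric vector of length `output_dim`.
#' @export
backbone_contract <- function(name, output_dim, extract) {
  stopifnot(is.function(extract), output_dim >= 1)
  structure(list(name = name, output_dim = as.integer(output_dim),
                 extract = extract), class = "backbone")
}

#' Extract a fixed-length feature vector from a preprocessed image
#'
#' @param image Preprocessed tensor from [preprocess()].
#' @param backbone A `backbone` object; see [make_stub_backbone()].
#' @return Numeric vector of length `backbone$output_dim`.
#' @export
extract_features <- function(image, backbone) {
  if (missing(backbone) || is.null(backbone)) {
    stop("no feature backbone registered; use make_stub_backbone() or ",
         "supply a pretrained backbone via backbone_contract()")
  }
  v <- backbone$extract(image)
  if (length(v) != backbone$output_dim || any(!is.finite(v))) {
    stop("backbone '", backbone$name, "' violated its output contract")
  }
  v
}

# ---- standard scaler (population sd; constant dimensions get sd 1) ------

.fit_scaler <- function(X) {
  X <- as.matrix(X)
  m <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, m)^2))
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = m, sd = s)
}

.apply_scaler <- function(sc, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  sweep(sweep(X, 2, sc$mean), 2, sc$sd, "/")
}

# ---- PLS-DA via NIPALS (PLS1 against the 0/1 label) ---------------------
#
# Deflation on X only; per-component sign fixed so the largest-magnitude
# loading is positive, making cross-implementation comparison well-posed.
.fit_nipals_pls <- function(X, y, ncomp, tol = 1e-10, maxit = 500) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  W <- matrix(0, d, ncomp); P <- matrix(0, d, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- yc
    w_old <- rep(0, d)
    for (it in seq_len(maxit)) {
      w <- drop(crossprod(Xc, u))
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) {
        stop("PLS component ", a, " has no remaining covariance with the label")
      }
      w <- w / nw
      tt <- drop(Xc %*% w)
      qq <- sum(yc * tt) / sum(tt^2)
      u_new <- yc * qq
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
      u <- u_new
    }
    p <- drop(crossprod(Xc, tt)) / sum(tt^2)
    j <- which.max(abs(p))
    if (p[j] < 0) { w <- -w; p <- -p; tt <- -tt; qq <- -qq }
    W[, a] <- w; P[, a] <- p; Tm[, a] <- tt; q[a] <- qq
    Xc <- Xc - tcrossprod(tt, p)
  }
  rotation <- W %*% solve(crossprod(P, W))
  list(x_center = x_center, y_center = y_center, weights = W, loadings = P,
       scores = Tm, y_loadings = q, rotation = rotation, ncomp = ncomp)
}

.project_pls <- function(pls, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  sweep(X, 2, pls$x_center) %*% pls$rotation
}

#' Fit the fold-local image-feature transformer
#'
#' Three phases, each fitted exclusively on the training fold so no test
#' statistic leaks into any parameter:
#' 1. standardize the D-dimensional backbone features;
#' 2. fit a PLS-DA model (NIPALS, single 0/1 response, deflation on X
#'    only) and keep `n_components` latent components;
#' 3. standardize the training latent scores.
#'
#' The double standardization keeps latent scales uniform across folds
#' before fusion. `n_components` is capped at `min(n - 1, D)` with a
#' warning when the training fold is too small for the requested value.
#'
#' @param train_features `n x D` matrix of backbone features.
#' @param train_labels Binary 0/1 vector of length `n` (both classes
#'   required).
#' @param n_components Number of latent components (default 15).
#' @param tol,maxit NIPALS convergence tolerance and iteration cap.
#' @return An `image_transformer` with elements `scaler1`, `pls`,
#'   `scaler2`, `n_components`, and the training scores.
#' @export
fit_image_transformer <- function(train_features, train_labels,
                                  n_components = 15,
                                  tol = 1e-10, maxit = 500) {
  X <- as.matrix(train_features)
  y <- as.numeric(train_labels)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class; PLS-DA needs both")
  }
  cap <- min(nrow(X) - 1L, ncol(X))
  if (n_components > cap) {
    warning("n_components reduced from ", n_components, " to the admissible ",
            "maximum ", cap)
    n_components <- cap
  }
  if (n_components < 1) stop("no admissible latent component")
  scaler1 <- .fit_scaler(X)
  Xs <- .apply_scaler(scaler1, X)
  pls <- .fit_nipals_pls(Xs, y, n_components, tol = tol, maxit = maxit)
  scaler2 <- .fit_scaler(pls$scores)
  structure(list(scaler1 = scaler1, pls = pls, scaler2 = scaler2,
                 n_components = n_components,
                 train_scores = .apply_scaler(scaler2, pls$scores)),
            class = "image_transformer")
}

#' Project backbone features into the standardized latent space
#'
#' Pure function of the fitted parameters: applies the feature scaler, the
#' PLS-DA rotation, then the latent scaler.
#'
#' @param transformer An `image_transformer` from
#'   [fit_image_transformer()].
#' @param features Numeric vector of length D or an `n x D` matrix.
#' @return Matrix of latent scores (`n x n_components`).
#' @export
transform_image_features <- function(transformer, features) {
  stopifnot(inherits(transformer, "image_transformer"))
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != length(transformer$scaler1$mean)) {
    stop("feature dimension ", ncol(X), " does not match the fitted ",
         length(transformer$scaler1$mean))
  }
  Xs <- .apply_scaler(transformer$scaler1, X)
  scores <- .project_pls(transformer$pls, Xs)
  .apply_scaler(transformer$scaler2, scores)
}

# Features for a whole cohort: synthetic cohorts carry a pre-registered
# feature matrix; image-backed cohorts run the preprocessing pipeline and
# the backbone per sample.
cohort_features <- function(cohort, backbone = NULL, seg_backend = NULL,
                            size = 224) {
  if (!is.null(cohort$features)) return(cohort$features)
  if (is.null(backbone) || is.null(seg_backend)) {
    stop("cohort has no registered features; supply a backbone and a ",
         "segmentation backend to extract them from the images")
  }
  if (any(cohort$samples$image_absent)) {
    stop("cannot extract image features: ",
         sum(cohort$samples$image_absent), " sample(s) have no image")
  }
  out <- matrix(NA_real_, n_samples(cohort), backbone$output_dim)
  for (i in seq_len(n_samples(cohort))) {
    img <- read_gray_image(cohort$samples$image_path[i])
    tens <- preprocess(img, seg_backend, cohort$samples$image_path[i],
                       size = size)
    out[i, ] <- extract_features(tens, backbone)
  }
  out
}
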