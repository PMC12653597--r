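# Independent oracles, coded separately from the package's own paths, plus
# small fixture builders shared across test files.

# AUC by brute force over all positive/negative pairs (ties count 0.5).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Classification metrics by direct counting over prediction lists.
brute_metrics <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  c(accuracy = (tp + tn) / length(pred),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn),
    f1 = {
      pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
      if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    })
}

# Exact two-sided signed-rank p-value by full enumeration of all 2^n sign
# patterns (zero differences already removed by the caller).
enum_signrank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  W_all <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    W_all[m + 1] <- sum(r[signs])
  }
  min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
}

# Reference NIPALS PLS1 scores (deflation on X only), coded independently
# of the package's fitting routine; no sign convention applied.
reference_pls_scores <- function(X, y, ncomp) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  Tm <- matrix(0, nrow(X), ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w)
    p <- drop(crossprod(Xc, t)) / sum(t^2)
    Tm[, a] <- t
    Xc <- Xc - outer(t, p)
  }
  Tm
}

# Population-sd standardization, independent of the package scaler.
pop_standardize <- function(X) {
  m <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, m)^2))
  s[s == 0] <- 1
  sweep(sweep(X, 2, m), 2, s, "/")
}

# A tiny fully-observed manifest data frame for loader tests.
tiny_manifest_df <- function(n = 4, patients = NULL) {
  set.seed(99)
  patients <- patients %||% paste0("pat", rep(seq_len(ceiling(n / 2)),
                                              each = 2))[seq_len(n)]
  df <- data.frame(
    patient_id = patients,
    label = rep(c("SS", "PMF"), length.out = n),
    image = "",
    leukocytes = runif(n, 5, 9), platelets = runif(n, 180, 300),
    neutrophils_abs = runif(n, 2, 6), eosinophils_abs = runif(n, 0.1, 0.4),
    basophils_abs = runif(n, 0.02, 0.08), monocytes_abs = runif(n, 0.3, 0.8),
    lymphocytes_abs = runif(n, 1, 3),
    neutrophils_pct = runif(n, 40, 70), eosinophils_pct = runif(n, 1, 4),
    basophils_pct = runif(n, 0.2, 1), monocytes_pct = runif(n, 4, 10),
    lymphocytes_pct = runif(n, 20, 40),
    ALP = runif(n, 50, 120), LDH = runif(n, 120, 250), ACE = runif(n, 20, 60),
    stringsAsFactors = FALSE
  )
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tiny_manifest <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# A small cohort with planted class structure in both modalities.
small_cohort <- function(seed = 1, n_patients = 30, image_effect = 1.5,
                         biomarker_effect = 1.0, ...) {
  generate_cohort(simulation_config(n_patients = n_patients,
                                    image_effect = image_effect,
                                    biomarker_effect = biomarker_effect,
                                    ...),
                  seed = seed)$cohort
}
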