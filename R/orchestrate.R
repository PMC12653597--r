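# Reproducible study runs: every (strategy x classifier family) pair on a
# shared fold plan, paper-style "mean [95% CI]" metric tables, pairwise
# Wilcoxon comparisons, and YAML-configured command-line entry points.

#' Run a full staging study on a shared fold plan
#'
#' Executes [run_experiment()] for every combination of fusion strategy
#' and classifier family on one common patient-aware fold plan, so all
#' per-fold AUC vectors are paired, then computes pairwise Wilcoxon
#' signed-rank comparisons between strategies within each family.
#'
#' @param cohort A `silica_cohort`.
#' @param strategies Strategy subset (default all five).
#' @param families Classifier families (default `"svm"`, `"rf"`,
#'   `"gbdt"`).
#' @param quick Use reduced single-candidate grids.
#' @param seed Run seed.
#' @param out_dir Optional run directory; when given, the config snapshot,
#'   fold plan, metric tables, predictions and comparisons are written as
#'   delimited text/JSON.
#' @inheritParams run_experiment
#' @return A `study_result`: `results[[family]][[strategy]]` cv results,
#'   `comparisons` data frame, `fold_plan`, and the metric summary table.
#' @export
run_study <- function(cohort,
                      strategies = c("image_only", "biomarker_only",
                                     "early", "late", "hybrid"),
                      families = c("svm", "rf", "gbdt"), quick = FALSE,
                      k_outer = 5, k_inner = 3, n_subfolds = 3,
                      n_components = 15, missingness_threshold = 0.20,
                      hybrid_scheme = "mean", threshold = 0.5, seed = 1,
                      out_dir = NULL, backbone = NULL, seg_backend = NULL) {
  plan <- plan_folds(cohort, k = k_outer, seed = seed)
  results <- list()
  for (fam in families) {
    spec <- classifier_spec(fam, seed = seed, quick = quick)
    ex <- run_cv(cohort, strategies, spec, k_outer = k_outer,
                 k_inner = k_inner, n_subfolds = n_subfolds,
                 n_components = n_components,
                 missingness_threshold = missingness_threshold,
                 hybrid_scheme = hybrid_scheme, threshold = threshold,
                 seed = seed, fold_plan = plan, backbone = backbone,
                 seg_backend = seg_backend)
    results[[fam]] <- ex$results
  }
  summary_rows <- list()
  for (fam in families) for (s in strategies) {
    m <- results[[fam]][[s]]$metrics
    summary_rows[[paste(fam, s)]] <- data.frame(
      family = fam, strategy = s,
      metric = m$metric, mean = m$mean, ci_lower = m$ci_lower,
      ci_upper = m$ci_upper, stringsAsFactors = FALSE)
  }
  summary_tab <- do.call(rbind, c(summary_rows, make.row.names = FALSE))
  comparisons <- NULL
  if (length(strategies) >= 2) {
    rows <- list()
    pairs <- utils::combn(strategies, 2, simplify = FALSE)
    for (fam in families) for (pr in pairs) {
      a <- results[[fam]][[pr[1]]]$per_fold$auc
      b <- results[[fam]][[pr[2]]]$per_fold$auc
      cmp <- suppressWarnings(wilcoxon_paired_auc(a, b, pr[1], pr[2]))
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, model_a = pr[1], model_b = pr[2],
        mean_auc_a = mean(a, na.rm = TRUE), mean_auc_b = mean(b, na.rm = TRUE),
        p_value = cmp$p_value, stringsAsFactors = FALSE)
    }
    comparisons <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  out <- structure(list(results = results, summary = summary_tab,
                        comparisons = comparisons, fold_plan = plan,
                        seed = seed),
                   class = "study_result")
  if (!is.null(out_dir)) .write_study(out, cohort, out_dir,
                                      strategies, families, quick,
                                      k_outer, k_inner, n_components,
                                      missingness_threshold, hybrid_scheme,
                                      threshold)
  out
}

.write_study <- function(study, cohort, out_dir, strategies, families,
                         quick, k_outer, k_inner, n_components,
                         missingness_threshold, hybrid_scheme, threshold) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  snapshot <- list(strategies = strategies, families = families,
                   quick = quick, k_outer = k_outer, k_inner = k_inner,
                   n_components = n_components,
                   missingness_threshold = missingness_threshold,
                   hybrid_scheme = hybrid_scheme, threshold = threshold,
                   seed = study$seed)
  yaml::write_yaml(snapshot, file.path(out_dir, "config_snapshot.yaml"))
  plan_df <- data.frame(patient_id = names(study$fold_plan$assignments),
                        fold = unname(study$fold_plan$assignments))
  utils::write.csv(plan_df, file.path(out_dir, "fold_plan.csv"),
                   row.names = FALSE)
  utils::write.csv(study$summary, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$summary, file.path(out_dir, "metrics.json"),
                       dataframe = "rows", digits = NA)
  if (!is.null(study$comparisons)) {
    utils::write.csv(study$comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  for (fam in names(study$results)) {
    for (s in names(study$results[[fam]])) {
      utils::write.csv(study$results[[fam]][[s]]$predictions,
                       file.path(out_dir,
                                 sprintf("predictions_%s_%s.csv", fam, s)),
                       row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> seed", x$seed, "\n")
  auc <- x$summary[x$summary$metric == "auc", ]
  for (i in seq_len(nrow(auc))) {
    cat(sprintf("  %-5s %-15s AUC %.3f [%.3f-%.3f]\n", auc$family[i],
                auc$strategy[i], auc$mean[i], auc$ci_lower[i],
                auc$ci_upper[i]))
  }
  invisible(x)
}

#' Load and validate a YAML run configuration
#'
#' Recognized keys (defaults in parentheses): `cohort` (either
#' `manifest`/`image_root` or a `synthetic:` block of
#' [simulation_config()] fields), `strategies` (all five), `families`
#' (svm, rf, gbdt), `k_outer` (5), `k_inner` (3), `n_subfolds` (3),
#' `n_components` (15), `missingness_threshold` (0.20), `threshold`
#' (0.5), `hybrid_scheme` (mean), `quick` (false), `seed`, `out_dir`.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(strategies = .strategies_all,
                   families = c("svm", "rf", "gbdt"), k_outer = 5,
                   k_inner = 3, n_subfolds = 3, n_components = 15,
                   missingness_threshold = 0.20, threshold = 0.5,
                   hybrid_scheme = "mean", quick = FALSE, seed = 1,
                   out_dir = NULL)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  bad <- setdiff(names(cfg), c(names(defaults), "cohort"))
  if (length(bad) > 0) stop("unknown config key(s): ",
                            paste(bad, collapse = ", "))
  cfg
}

.cohort_from_config <- function(cfg) {
  cc <- cfg$cohort
  if (!is.null(cc$manifest)) {
    load_cohort(cc$manifest, image_root = cc$image_root)
  } else if (!is.null(cc$synthetic)) {
    sc <- do.call(simulation_config,
                  cc$synthetic[setdiff(names(cc$synthetic), "seed")])
    generate_cohort(sc, seed = cc$synthetic$seed %||% cfg$seed)$cohort
  } else {
    stop("config must name either cohort: manifest: or cohort: synthetic:")
  }
}

#' Command-line style entry points
#'
#' `cli_run()` executes a full study from a YAML config and writes metric
#' tables, predictions and comparisons to the output directory;
#' `cli_simulate()` generates a synthetic cohort, writes its manifest,
#' fixture images/masks and ground-truth sidecar. Both are the functions
#' behind the `inst/cli/silicastage` script and return invisibly an exit
#' code (0 on success).
#'
#' @param config_path Path to a YAML config (see [load_run_config()]).
#' @param seed Optional seed overriding the config's.
#' @param out Optional output directory overriding the config's.
#' @return Invisible integer exit code.
#' @export
cli_run <- function(config_path, seed = NULL, out = NULL) {
  cfg <- load_run_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out)) cfg$out_dir <- out
  cohort <- .cohort_from_config(cfg)
  run_study(cohort, strategies = cfg$strategies, families = cfg$families,
            quick = cfg$quick, k_outer = cfg$k_outer, k_inner = cfg$k_inner,
            n_subfolds = cfg$n_subfolds, n_components = cfg$n_components,
            missingness_threshold = cfg$missingness_threshold,
            hybrid_scheme = cfg$hybrid_scheme, threshold = cfg$threshold,
            seed = cfg$seed, out_dir = cfg$out_dir)
  invisible(0L)
}

#' @rdname cli_run
#' @param paper_shape Use the exact study-shaped fixture
#'   ([make_paper_shaped_fixture()]) instead of a stochastic draw.
#' @param images Also render fixture images and masks.
#' @export
cli_simulate <- function(config_path, seed = NULL, out = NULL,
                         paper_shape = FALSE, images = FALSE) {
  cfg <- load_run_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out_dir <- out %||% cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc_args <- cfg$cohort$synthetic %||% list()
  sc <- do.call(simulation_config, sc_args[setdiff(names(sc_args), "seed")])
  if (paper_shape) {
    cohort <- make_paper_shaped_fixture(seed = cfg$seed, config = sc)
    truth <- attr(cohort, "truth")
  } else {
    g <- generate_cohort(sc, seed = cfg$seed)
    cohort <- g$cohort; truth <- g$truth
  }
  if (images) {
    cohort <- generate_fixture_images(cohort, file.path(out_dir, "images"),
                                      seed = cfg$seed)
  }
  write_manifest(cohort, file.path(out_dir, "manifest.csv"))
  utils::write.csv(
    data.frame(patient_id = sprintf("P%03d",
                                    seq_along(truth$n_samples_per_patient)),
               n_samples = truth$n_samples_per_patient,
               n_pmf = truth$n_pmf_per_patient),
    file.path(out_dir, "ground_truth_patients.csv"), row.names = FALSE)
  utils::write.csv(data.frame(signal_direction = truth$signal_direction),
                   file.path(out_dir, "ground_truth_signal.csv"),
                   row.names = FALSE)
  yaml::write_yaml(c(sc_args, list(seed = cfg$seed)),
                   file.path(out_dir, "config_snapshot.yaml"))
  invisible(0L)
}
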