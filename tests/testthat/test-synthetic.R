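# Synthetic-cohort generator: shape calibration, determinism, progression
# dynamics, fixture images, orchestration round trip.

test_that("generation is bit-reproducible for a fixed config and seed", {
  g1 <- generate_cohort(simulation_config(n_patients = 15), seed = 42)
  g2 <- generate_cohort(simulation_config(n_patients = 15), seed = 42)
  expect_identical(g1$cohort$markers, g2$cohort$markers)
  expect_identical(g1$cohort$features, g2$cohort$features)
  expect_identical(g1$cohort$samples, g2$cohort$samples)
  expect_identical(g1$truth$signal_direction, g2$truth$signal_direction)
  g3 <- generate_cohort(simulation_config(n_patients = 15), seed = 43)
  expect_false(identical(g1$cohort$markers, g3$cohort$markers))
})

test_that("default shape calibration tracks the study cohort", {
  tots <- numeric(20); fracs <- numeric(20)
  for (s in 1:20) {
    co <- generate_cohort(seed = 1000 + s)$cohort
    tots[s] <- n_samples(co)
    fracs[s] <- mean(co$samples$label)
    expect_equal(n_patients(co), 94)
    expect_true(all(table(co$samples$patient_id) >= 1 &
                      table(co$samples$patient_id) <= 10))
  }
  expect_lt(abs(mean(tots) - 341), 40)
  expect_lt(abs(mean(fracs) - 154 / 341), 0.05)
})

test_that("disease progression is monotone: PMF never reverts to SS", {
  for (s in 1:5) {
    co <- generate_cohort(simulation_config(n_patients = 40,
                                            progression_prob = 0.5),
                          seed = 200 + s)$cohort
    for (p in unique(co$samples$patient_id)) {
      rows <- co$samples[co$samples$patient_id == p, ]
      lab <- rows$label[order(rows$sample_index)]
      expect_true(all(diff(lab) >= 0))
    }
  }
})

test_that("PMF class raises the planted inflammation markers", {
  co <- generate_cohort(simulation_config(n_patients = 80,
                                          biomarker_effect = 1.5,
                                          progression_prob = 0),
                        seed = 7)$cohort
  y <- co$samples$label
  for (v in c("NLR", "SII", "SIRI", "AISI")) {
    expect_gt(median(co$markers[y == 1, v], na.rm = TRUE),
              median(co$markers[y == 0, v], na.rm = TRUE))
  }
})

test_that("planted-direction oracle AUC matches the Gaussian closed form", {
  cfg <- simulation_config(n_patients = 94, image_effect = 2,
                           patient_sd = 0.5)
  g <- generate_cohort(cfg, seed = 13)
  proj <- g$cohort$features %*% g$truth$signal_direction
  auc <- rank_auc(proj, g$cohort$samples$label)
  # closed form: Phi(d / sqrt(2 * (1 + patient_sd^2))) ~ 0.90
  expect_gt(auc, 0.85)
  expect_lt(auc, 0.96)
})

test_that("fixture images are non-empty, reproducible, and feed the pipeline", {
  g <- generate_cohort(simulation_config(n_patients = 5), seed = 3)
  d1 <- tempfile("imga"); d2 <- tempfile("imgb")
  co1 <- generate_fixture_images(g$cohort, d1, seed = 9)
  co2 <- generate_fixture_images(g$cohort, d2, seed = 9)
  for (i in seq_len(n_samples(co1))) {
    m <- png::readPNG(sub("\\.png$", "_mask.png", co1$samples$image_path[i]))
    expect_gt(sum(m), 0)
    expect_identical(readBin(co1$samples$image_path[i], "raw", 1e6),
                     readBin(co2$samples$image_path[i], "raw", 1e6))
  }
  bb <- make_stub_backbone(output_dim = 16)
  feats <- silicastage:::cohort_features(
    structure(c(co1[names(co1) != "features"], list(features = NULL)),
              class = "silica_cohort"),
    backbone = bb, seg_backend = oracle_backend())
  expect_equal(dim(feats), c(n_samples(co1), 16))
  expect_true(all(is.finite(feats)))
})

test_that("simulate-then-run round trip works through the config interface", {
  out_dir <- tempfile("study")
  cfg_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    cohort = list(synthetic = list(n_patients = 30, image_effect = 1.5)),
    strategies = c("image_only", "late"), families = "rf", quick = TRUE,
    seed = 4, out_dir = out_dir), cfg_path)
  expect_identical(cli_run(cfg_path), 0L)
  expect_true(file.exists(file.path(out_dir, "metrics.csv")))
  expect_true(file.exists(file.path(out_dir, "fold_plan.csv")))
  expect_true(file.exists(file.path(out_dir, "comparisons.csv")))
  expect_true(file.exists(file.path(out_dir, "config_snapshot.yaml")))
  met <- read.csv(file.path(out_dir, "metrics.csv"))
  expect_setequal(unique(met$strategy), c("image_only", "late"))
  # rerun reproduces the metric table exactly
  out_dir2 <- tempfile("study2")
  cli_run(cfg_path, out = out_dir2)
  expect_identical(readLines(file.path(out_dir, "metrics.csv")),
                   readLines(file.path(out_dir2, "metrics.csv")))
  # simulate verb writes a loadable manifest
  sim_dir <- tempfile("sim")
  cli_simulate(cfg_path, out = sim_dir)
  co <- load_cohort(file.path(sim_dir, "manifest.csv"))
  expect_equal(n_patients(co), 30)
})
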