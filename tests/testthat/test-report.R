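test_that("a null-truth cohort yields a null-leaning report row", {
  pr <- generative_priors(ate_mean = 0, ate_sd = 0)
  ds <- draw_raw_cohort(cohort_presets()$elbow_flexor_55, pr, n = 120,
                        seed = 201)
  rep <- run_trial_analysis(list(ef55 = ds), quiet = TRUE)
  expect_lt(abs(rep$estimate) / rep$sd_pooled, 0.15)
  expect_lt(rep$bf10, 1)
  expect_match(rep$evidence, "H0")
  expect_true(rep$cri_low <= rep$estimate & rep$estimate <= rep$cri_high)
})

test_that("a large fixed effect is detected in most seeded replicates", {
  pr <- generative_priors(ate_mean = 0.8, ate_sd = 0)
  hits <- sapply(1:11, function(s) {
    ds <- draw_raw_cohort(cohort_presets()$ten_rm_full, pr, n = 25, seed = s)
    run_trial_analysis(list(rm = ds), quiet = TRUE)$prob_positive > 0.95
  })
  expect_gt(mean(hits), 0.5)
})

test_that("report descriptives reproduce the preset baselines", {
  set.seed(203)
  presets <- cohort_presets()
  ds <- lapply(presets, draw_raw_cohort, n = 60)
  rep <- run_trial_analysis(ds, quiet = TRUE)
  for (i in seq_len(nrow(rep))) {
    p <- presets[[rep$outcome[i]]]
    se <- p$pre_sd / sqrt(60)
    expect_lt(abs(rep$pre_mean_prom[i] - p$pre_mean), 4 * se)
    expect_lt(abs(rep$pre_mean_from[i] - p$pre_mean), 4 * se)
    expect_gt(rep$post_mean_prom[i], rep$pre_mean_prom[i] - 2 * se)
  }
  expect_named(presets, c("elbow_flexor_55", "elbow_flexor_45",
                          "elbow_extensor_55", "elbow_extensor_45",
                          "ten_rm_full", "ten_rm_partial"))
})

test_that("reports are invariant to row order and to the data scale", {
  ds <- draw_raw_cohort(cohort_presets()$elbow_flexor_45, n = 25, seed = 207)
  shuffled <- ds[sample(nrow(ds)), ]
  for (a in c("scale", "unit_label", "class"))
    attr(shuffled, a) <- attr(ds, a)
  r1 <- run_trial_analysis(list(x = ds), quiet = TRUE)
  r2 <- run_trial_analysis(list(x = shuffled), quiet = TRUE)
  expect_equal(as.data.frame(r1), as.data.frame(r2))

  # scale equivariance: the rescaled prior makes bf10 and prob_positive
  # identical whether the fit is run in mm or in SD units
  std <- standardize_changes(ds)
  r3 <- run_trial_analysis(list(x = std), quiet = TRUE)
  expect_equal(r3$bf10, r1$bf10, tolerance = 1e-8)
  expect_equal(r3$prob_positive, r1$prob_positive, tolerance = 1e-8)
  expect_equal(r3$estimate * attr(std, "standardization")$sd_pooled,
               r1$estimate, tolerance = 1e-8)
})

test_that("report rows restate the fit and evidence without recomputation", {
  ds <- draw_raw_cohort(cohort_presets()$ten_rm_partial, n = 20, seed = 211)
  rep <- run_trial_analysis(list(rm = ds), quiet = TRUE)
  sdp <- pooled_baseline_sd(ds)
  pr <- fitting_prior(mean = 0, sd = 0.4 * sdp)
  fit <- fit_ate(ds, pr)
  ev <- bayes_factor(paired_differences(ds), pr)
  expect_equal(rep$estimate, fit$mean)
  expect_equal(rep$cri_low, fit$cri_low)
  expect_equal(rep$bf10, ev$bf10)
  expect_identical(rep$evidence, ev$label)
  expect_identical(rep$evidence, label_evidence(rep$bf10))
})

test_that("fixture suite writes six deterministic synthetic cohorts", {
  dir1 <- tempfile("fix")
  paths <- make_fixture_suite(dir1, n = 25, seed = 301)
  expect_length(paths, 6)
  expect_true(all(grepl("^synthetic_", basename(paths))))
  for (p in paths) {
    expect_equal(nrow(utils::read.csv(p)), 50)  # 25 participants x 2
  }
  # refusal without force, byte-identical regeneration with force
  expect_error(make_fixture_suite(dir1, n = 25, seed = 301), "force")
  dir2 <- tempfile("fix")
  paths2 <- make_fixture_suite(dir2, n = 25, seed = 301)
  for (i in seq_along(paths)) {
    expect_identical(readLines(paths[i]), readLines(paths2[i]))
  }
  # pooled baseline SDs near their presets (sampling error at n = 25/limb)
  presets <- cohort_presets()
  for (p in paths) {
    ds <- read_trial_csv(p, scale = "raw")
    name <- sub("^synthetic_(.*)\\.csv$", "\\1", basename(p))
    expect_lt(abs(pooled_baseline_sd(ds) / presets[[name]]$pre_sd - 1), 0.45)
  }
})

test_that("reports serialize to CSV and JSON", {
  ds <- draw_raw_cohort(cohort_presets()$elbow_flexor_55, n = 15, seed = 401)
  rep <- run_trial_analysis(list(ef = ds), quiet = TRUE)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_trial_report(rep, csv, js)
  expect_equal(utils::read.csv(csv)$bf10, rep$bf10, tolerance = 1e-9)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$estimate, rep$estimate, tolerance = 1e-9)
})

test_that("the CLI verbs drive the same pipeline", {
  out <- tempfile(fileext = ".csv")
  expect_message(
    withinbayes_cli(c("simulate", "--n", "8", "--seed", "5", "--out", out)),
    "simulate")
  ds <- read_trial_csv(out, scale = "standardized")
  expect_equal(ds, draw_prior_predictive(n = 8, seed = 5),
               ignore_attr = TRUE)

  fixdir <- tempfile("cli_fix")
  expect_message(
    withinbayes_cli(c("fixtures", "--dir", fixdir, "--n", "6",
                      "--seed", "7")),
    "6 file")
  prefix <- tempfile("rep")
  msgs <- capture_messages(capture.output(withinbayes_cli(c(
    "analyze", "--input", paste(dir(fixdir, full.names = TRUE)[1:2],
                                collapse = ","),
    "--out-prefix", prefix))))
  expect_true(any(grepl("analyze", msgs)))
  expect_true(file.exists(paste0(prefix, ".csv")))
  expect_true(any(grepl("prior rescaled", msgs)))

  expect_output(
    suppressMessages(withinbayes_cli(c("design", "precision", "--n", "6,10",
                                       "--sims", "10", "--seed", "3"))),
    "mean_cri_length")
})

test_that("YAML configuration populates priors and presets", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "generative:",
    "  ate_mean: 0.1",
    "  ate_sd: 0.2",
    "fitting:",
    "  sd: 0.5",
    "presets:",
    "  - outcome_name: biceps",
    "    pre_mean: 30",
    "    pre_sd: 5",
    "    unit: mm"
  ), cfg)
  conf <- read_priors_config(cfg)
  expect_equal(conf$generative$ate_mean, 0.1)
  expect_equal(conf$generative$typical_improvement_mean, 0.44)
  expect_equal(conf$fitting$sd, 0.5)
  expect_named(conf$presets, "biceps")
  expect_equal(conf$presets$biceps$pre_sd, 5)
})
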