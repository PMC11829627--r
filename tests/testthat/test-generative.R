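# closed-form moments of the generative model used as Monte-Carlo oracles:
# conditional on (theta, delta) a paired difference is
#   d_i = delta + (b_{i,1} - b_{i,0}) + (eta_{i,1} - eta_{i,0})
# so var(d_i) = 2 * (sigma_b^2 + sigma_eta^2) with the default per-limb
# response and change-level error, and 2 * (2 * sigma_eps^2) under the
# shared-response / pre-post-error variant.

test_that("no-noise degenerate draws propagate the fixed effects exactly", {
  pr <- generative_priors(typical_improvement_mean = 0.44,
                          typical_improvement_sd = 0,
                          ate_mean = 0.30, ate_sd = 0,
                          heterogeneous_response_sd = 0,
                          measurement_error_sd = 0)
  ds <- draw_prior_predictive(pr, n = 5, seed = 1)
  expect_equal(unname(paired_differences(ds)), rep(0.30, 5))
  expect_equal(ds$change[ds$condition == 0], rep(0.44, 5))
  expect_equal(ds$change[ds$condition == 1], rep(0.74, 5))
})

test_that("paired-difference variance matches the closed form under both structures", {
  pr <- generative_priors()
  reps <- 2000
  for (cfg in list(list(measurement = "change", rpc = TRUE,
                        v = 2 * (0.15^2 + 0.20^2)),
                   list(measurement = "pre_post", rpc = FALSE,
                        v = 2 * (2 * 0.20^2)))) {
    set.seed(99)
    v_hat <- replicate(reps, {
      ds <- draw_prior_predictive(pr, n = 20, measurement = cfg$measurement,
                                  response_per_condition = cfg$rpc)
      var(paired_differences(ds))
    })
    # SE of the mean sample variance: sd of a chi-square_{19}-scaled variance
    se <- sqrt(2 / 19) * cfg$v / sqrt(reps)
    expect_lt(abs(mean(v_hat) - cfg$v), 4 * se)
  }
})

test_that("dataset-level ATE draws follow their prior; null draws are zero", {
  set.seed(7)
  deltas <- replicate(2000, attr(draw_prior_predictive(n = 2), "realized")$delta)
  expect_lt(abs(mean(deltas) - 0.30), 4 * 0.27 / sqrt(2000))
  expect_lt(abs(sd(deltas) - 0.27), 0.03)

  set.seed(8)
  dbars <- replicate(400, {
    mean(paired_differences(draw_prior_predictive(n = 10, null_effect = TRUE)))
  })
  # null differences have mean 0 and per-dataset mean SD sqrt(0.125/10)
  expect_lt(abs(mean(dbars)), 4 * sqrt(0.125 / 10) / sqrt(400))
})

test_that("between-condition covariance reflects shared components", {
  pr <- generative_priors()
  pool <- function(rpc) {
    set.seed(123)
    do.call(rbind, lapply(1:1200, function(i) {
      ds <- draw_prior_predictive(pr, n = 5, response_per_condition = rpc)
      cbind(ds$change[ds$condition == 0], ds$change[ds$condition == 1])
    }))
  }
  # shared response: cov = theta-var + b-var; per-limb response: theta-var only
  x <- pool(FALSE)
  expect_lt(abs(cov(x[, 1], x[, 2]) - (0.40^2 + 0.15^2)), 0.02)
  x <- pool(TRUE)
  expect_lt(abs(cov(x[, 1], x[, 2]) - 0.40^2), 0.02)
  # and with shared response the b_i term cancels exactly in differences:
  # paired-difference variance drops to 2 * sigma_eta^2
  set.seed(5)
  v_hat <- mean(replicate(1000, {
    var(paired_differences(draw_prior_predictive(pr, n = 20,
                                                 response_per_condition = FALSE)))
  }))
  expect_lt(abs(v_hat - 2 * 0.20^2), 4 * sqrt(2 / 19) * 0.08 / sqrt(1000))
})

test_that("seeded draws are bit-reproducible and inputs are validated", {
  a <- draw_prior_predictive(n = 12, seed = 77)
  b <- draw_prior_predictive(n = 12, seed = 77)
  expect_identical(a, b)
  expect_error(draw_prior_predictive(n = 1), "invalid design")
  expect_error(generative_priors(ate_sd = -0.1), "must be >= 0")
})

test_that("raw cohorts match their preset baseline and change scaling", {
  preset <- cohort_preset("elbow_flexor_55", 39.6, 8.6, unit = "mm")
  ds <- draw_raw_cohort(preset, n = 1000, seed = 21)
  expect_lt(abs(mean(ds$pre) - 39.6), 3 * 8.6 / sqrt(2000))
  expect_equal(ds$post - ds$pre, ds$change)

  # change-score SD scales as pre_sd times the standardized model SD
  set.seed(22)
  ch0 <- unlist(lapply(1:400, function(i) {
    ds <- draw_raw_cohort(preset, n = 10)
    ds$change[ds$condition == 0]
  }))
  sd_model <- sqrt(0.40^2 + 0.15^2 + 0.20^2)  # theta + b + eta, condition 0
  expect_lt(abs(sd(ch0) - 8.6 * sd_model), 0.05 * 8.6 * sd_model)
})

test_that("no-noise raw cohorts shift post by exactly the typical improvement", {
  pr <- generative_priors(typical_improvement_mean = 0.44,
                          typical_improvement_sd = 0, ate_mean = 0,
                          ate_sd = 0, heterogeneous_response_sd = 0,
                          measurement_error_sd = 0)
  ds <- draw_raw_cohort(cohort_preset("mt", 40, 8.6), pr, n = 8, seed = 3)
  expect_equal(ds$post, ds$pre + 0.44 * 8.6)
})

test_that("requested pre/post correlation is achieved or rejected", {
  preset <- cohort_preset("mt", 39.6, 8.6, pre_post_correlation = 0.98)
  ds <- draw_raw_cohort(preset, n = 4000, seed = 31)
  for (cond in 0:1) {
    sub <- ds[ds$condition == cond, ]
    expect_lt(abs(cor(sub$pre, sub$post) - 0.98), 0.01)
  }
  # with the default variances the attainable range is about [0.968, 1]
  bad <- cohort_preset("mt", 39.6, 8.6, pre_post_correlation = 0.9)
  expect_error(draw_raw_cohort(bad, n = 50, seed = 1), "not attainable")
  expect_error(cohort_preset("mt", 39.6, 8.6, pre_post_correlation = 1.2),
               "\\[-1, 1\\]")
})

test_that("standardization divides by the pooled baseline SD and round-trips", {
  df <- data.frame(participant_id = rep(sprintf("P%d", 1:4), each = 2),
                   condition = rep(0:1, 4),
                   pre = c(30, 31, 40, 41, 50, 51, 35, 36))
  df$post <- df$pre + 4.3
  df$change <- 4.3
  ds <- trial_dataset(df, scale = "raw", unit_label = "mm")
  sd_pooled <- pooled_baseline_sd(ds)
  std <- standardize_changes(ds)
  expect_equal(unique(std$change), 4.3 / sd_pooled)
  expect_identical(attr(std, "scale"), "standardized")
  expect_equal(attr(std, "standardization")$sd_pooled, sd_pooled)

  # idempotence contract
  expect_error(standardize_changes(std), "already standardized")
  expect_identical(standardize_changes(std, if_standardized = "identity"),
                   std)

  # round trip: standardized raw cohort recovers the generative difference
  # variance 2*(sigma_b^2 + sigma_eta^2) = 0.125
  set.seed(41)
  v_hat <- mean(replicate(400, {
    raw <- draw_raw_cohort(cohort_preset("mt", 39.6, 8.6), n = 25)
    var(paired_differences(standardize_changes(raw)))
  }))
  expect_lt(abs(v_hat - 0.125), 0.01)
})

test_that("degenerate baseline scale cannot be standardized", {
  df <- data.frame(participant_id = rep(c("a", "b", "c"), each = 2),
                   condition = rep(0:1, 3), pre = 10, post = 11, change = 1)
  ds <- trial_dataset(df, scale = "raw")
  expect_error(standardize_changes(ds), "degenerate")
})
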