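test_that("cohort generation is deterministic under a fixed seed", {
  spec <- cohort_spec(100, 0.5, seed = 1)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  mk <- marker_spec(1, 0, detection_miss_rate = 0.05)
  co <- generate_cohort(spec)
  expect_identical(generate_marker_scores(co, mk, seed = 3),
                   generate_marker_scores(co, mk, seed = 3))
  # different seed gives different draws
  expect_false(identical(generate_cohort(spec),
                         generate_cohort(cohort_spec(100, 0.5, seed = 2))))
})

test_that("cohort spec validation rejects bad configurations", {
  expect_error(cohort_spec(0, 0.5), "n_subjects")
  expect_error(cohort_spec(10, 0), "prevalence")
  expect_error(cohort_spec(10, 1), "prevalence")
  expect_error(
    cohort_spec(10, 0.5, covariates = list(
      covariate_spec("age", "normal", list(mean = 60, sd = 5)),
      covariate_spec("age", "normal", list(mean = 60, sd = 5)))),
    "unique")
  expect_error(covariate_spec("x", "normal", list(mean = 0, sd = -1)),
               "invalid")
  expect_error(covariate_spec("x", "gamma", list(shape = 2)), "missing")
})

test_that("outcome prevalence converges to the specified value", {
  co <- generate_cohort(cohort_spec(10000, 0.5, seed = 7))
  expect_equal(nrow(co), 10000)
  # binomial SD = sqrt(0.25/10000) = 0.005
  expect_lt(abs(mean(co$outcome) - 0.5), 3 * 0.005)
})

test_that("closed-form binormal AUC matches the normal-CDF identity", {
  expect_equal(closed_form_auc(marker_spec(0, 0)), 0.5)
  expect_equal(closed_form_auc(marker_spec(1, 0)), pnorm(1 / sqrt(2)),
               tolerance = 1e-12)
  expect_gt(closed_form_auc(marker_spec(50, 0)), 1 - 1e-12)
})

test_that("generated marker recovers the latent AUC under both links", {
  for (link in c("clamp", "logistic")) {
    mk <- marker_spec(1, 0, link = link)
    co <- make_scored_cohort(2000, 0.5, seed = 11)
    co <- generate_marker_scores(co, mk, seed = 12)
    expect_lt(abs(auc(co$marker_score, co$outcome) - 0.760), 0.03)
  }
  # uninformative marker
  mk0 <- marker_spec(0, 0)
  co <- generate_marker_scores(generate_cohort(cohort_spec(4000, 0.5,
                                                           seed = 13)),
                               mk0, seed = 14)
  expect_lt(abs(auc(co$marker_score, co$outcome) - 0.5), 0.03)
  expect_true(all(co$marker_score >= 0 & co$marker_score <= 1))
})

test_that("detection misses leave the expected fraction unscored", {
  mk <- marker_spec(1, 0, detection_miss_rate = 0.05)
  co <- generate_marker_scores(generate_cohort(cohort_spec(1000, 0.5,
                                                           seed = 21)),
                               mk, seed = 22)
  n_miss <- sum(is.na(co$marker_score))
  expect_lt(abs(n_miss - 50), 3 * sqrt(1000 * 0.05 * 0.95))
  expect_error(marker_spec(1, 0, detection_miss_rate = 1), "miss_rate")
  expect_error(marker_spec(1, 0, sigma_case = 0), "positive")
})

test_that("missingness injection respects rate, mechanism and schema", {
  co <- generate_cohort(cohort_spec(200, 0.5, seed = 31))
  expect_identical(inject_missingness(co, "years_quit", 0), co)
  m1 <- inject_missingness(co, "years_quit", 0.35, "MCAR", seed = 5)
  expect_lt(abs(sum(is.na(m1$years_quit)) - 70),
            3 * sqrt(200 * 0.35 * 0.65))
  expect_identical(m1, inject_missingness(co, "years_quit", 0.35, "MCAR",
                                          seed = 5))
  expect_error(inject_missingness(co, "no_such_field", 0.1), "unknown field")
  expect_error(inject_missingness(co, "years_quit", 0.2, "MAR"),
               "conditioning covariate")

  # MAR: missingness probability increases with the conditioning covariate
  big <- generate_cohort(cohort_spec(5000, 0.5, seed = 32))
  m2 <- inject_missingness(big, "years_quit", 0.3, "MAR", on = "age",
                           seed = 6)
  mis <- is.na(m2$years_quit)
  expect_gt(mean(big$age[mis]), mean(big$age[!mis]))
})

test_that("cohort CSV round-trips values, missingness and column order", {
  co <- make_scored_cohort(60, 0.4, seed = 41, miss_rate = 0.1)
  co <- inject_missingness(co, "years_quit", 0.25, seed = 42)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_identical(names(back),
                   c("id", "outcome", "marker_score",
                     sort(setdiff(names(co), c("id", "outcome",
                                               "marker_score")))))
  for (nm in names(co)) expect_equal(back[[nm]], co[[nm]])

  bad <- co
  bad$outcome[3] <- 2L
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_cohort_csv(path), "outcome")
})
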