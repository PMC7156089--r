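test_that("binned LR is the ratio of within-class bin frequencies", {
  # 30% of events and 10% of nonevents in the first bin, no zero cells
  scores <- c(rep(0.1, 30), rep(0.3, 70), rep(0.1, 10), rep(0.3, 90))
  labels <- c(rep(1, 100), rep(0, 100))
  m <- estimate_lr_binned(scores, labels)
  expect_equal(lr_at(m, 0.1), 3.0)
  expect_equal(lr_at(m, 0.3), 70 / 90, tolerance = 1e-12)

  # continuity correction only on zero-cell bins: (5.5/51)/(0.5/51) = 11
  scores <- c(rep(0.9, 5), rep(0.1, 45), rep(0.1, 50))
  labels <- c(rep(1, 50), rep(0, 50))
  m <- estimate_lr_binned(scores, labels)
  expect_equal(lr_at(m, 0.9), 11.0)

  expect_error(estimate_lr_binned(runif(10), rep(1, 10)), "both events")
  expect_error(estimate_lr_binned(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("binned LR approaches 1 everywhere for an uninformative marker", {
  set.seed(77)
  scores <- runif(6000)
  labels <- rbinom(6000, 1, 0.5)
  m <- estimate_lr_binned(scores, labels)
  expect_true(all(abs(m$lr - 1) < 0.2))
})

test_that("binormal LR follows the fitted normal density ratio", {
  m <- manual_binormal_lr(mu_case = 1, mu_control = 0)
  # equal sigmas: log-LR at latent z is z - 1/2
  expect_equal(lr_at(m, plogis(0.5)), 1, tolerance = 1e-9)
  expect_equal(lr_at(m, plogis(1.5)), exp(1), tolerance = 1e-9)
  # identical class distributions give LR = 1 everywhere
  m0 <- manual_binormal_lr(0, 0)
  expect_equal(lr_at(m0, c(0.1, 0.5, 0.9)), rep(1, 3))
  # monotone in the score for equal sigmas, mu_case > mu_control
  g <- lr_at(m, seq(0.01, 0.99, by = 0.01))
  expect_true(all(diff(g) > 0))

  expect_error(estimate_lr_binormal(c(0.2, 0.2, 0.8, 0.8), c(1, 1, 0, 0)),
               "zero within-class variance")
  expect_error(estimate_lr_binormal(c(0.2, 0.8), c(1, 0)), "two subjects")
})

test_that("binormal estimation recovers generating parameters at n = 2000", {
  mk <- marker_spec(1, 0, link = "logistic")
  co <- generate_marker_scores(
    generate_cohort(cohort_spec(2000, 0.5, seed = 55)), mk, seed = 56)
  m <- estimate_lr_binormal(co$marker_score, co$outcome)
  n1 <- sum(co$outcome); n0 <- sum(1 - co$outcome)
  se_mu <- sqrt(1 / n1 + 1 / n0)
  expect_lt(abs((m$mu_case - m$mu_control) - 1), 3 * se_mu)
  expect_lt(abs(m$sigma_case - 1), 3 / sqrt(2 * n1))
  expect_lt(abs(m$sigma_control - 1), 3 / sqrt(2 * n0))
})

test_that("lr_at respects the bin conventions", {
  m <- manual_binned_lr(seq(0, 1, 0.2), c(1, 2, 3, 4, 5))
  expect_equal(lr_at(m, 0.2), 2)       # interior edge goes right
  expect_equal(lr_at(m, 1.0), 5)       # last bin closed
  expect_equal(lr_at(m, 0), 1)
  expect_error(lr_at(m, 1.2), "\\[0, 1\\]")
})

test_that("posterior probability implements the odds update", {
  expect_equal(posterior_probability(0.5, 1), 0.5)
  expect_equal(posterior_probability(0.2, 4), 0.5)
  expect_equal(posterior_probability(0.9, 1 / 9), 0.5)
  expect_error(posterior_probability(0.5, 0), "positive")
  expect_error(posterior_probability(0.5, Inf), "positive")
  expect_error(posterior_probability(1.4, 1), "\\[0, 1\\]")

  # identity at lr = 1 over a grid (up to the clamp epsilon)
  p <- seq(0.001, 0.999, length.out = 1000)
  expect_equal(posterior_probability(p, 1), p, tolerance = 1e-9)

  # strictly increasing in both arguments
  expect_true(all(diff(posterior_probability(p, 2.5)) > 0))
  lrs <- seq(0.1, 10, length.out = 200)
  expect_true(all(diff(posterior_probability(0.3, lrs)) > 0))
})

test_that("sequential updates compose multiplicatively", {
  set.seed(99)
  p <- runif(200)
  lr1 <- exp(rnorm(200)); lr2 <- exp(rnorm(200))
  once <- posterior_probability(p, lr1 * lr2)
  twice <- posterior_probability(posterior_probability(p, lr1), lr2)
  expect_equal(twice, once, tolerance = 1e-9)
})

test_that("update_cohort applies the per-subject posterior", {
  co <- data.frame(id = letters[1:4], outcome = c(0L, 1L, 0L, 1L),
                   marker_score = c(0.2, 0.8, 0.2, 0.8),
                   prior = c(0.1, 0.1, 0.4, 0.4))
  m <- manual_binned_lr(c(0, 0.5, 1), c(0.5, 2.0))
  out <- update_cohort(co, "prior", m)
  expect_equal(out$posterior, c(1 / 19, 2 / 11, 1 / 4, 4 / 7),
               tolerance = 1e-12)

  # LR identically 1 reproduces the prior
  one <- manual_binned_lr(c(0, 1), 1)
  expect_equal(update_cohort(co, "prior", one)$posterior, co$prior,
               tolerance = 1e-5)

  co$prior[2] <- NA
  expect_error(update_cohort(co, "prior", m), "b")
})

test_that("label-permuted LR estimation adds no discrimination", {
  co <- make_scored_cohort(2000, 0.4, seed = 61)
  prior <- risk_probability(mayo_example(), co)
  set.seed(62)
  perm <- sample(co$outcome)
  for (est in list(estimate_lr_binned, estimate_lr_binormal)) {
    m <- est(co$marker_score, perm)
    post <- posterior_probability(prior, lr_at(m, co$marker_score))
    expect_lt(abs(auc(post, co$outcome) - auc(prior, co$outcome)), 0.05)
  }
})

test_that("LR models serialize to JSON and back", {
  co <- make_scored_cohort(300, 0.4, seed = 63)
  for (est in list(estimate_lr_binned, estimate_lr_binormal)) {
    m <- est(co$marker_score, co$outcome)
    path <- tempfile(fileext = ".json")
    write_lr_json(m, path)
    back <- read_lr_json(path)
    s <- seq(0, 1, by = 0.05)
    expect_equal(lr_at(back, s), lr_at(m, s), tolerance = 1e-12)
  }
})

test_that("cross-fit posteriors stay close to full-sample posteriors", {
  co <- make_scored_cohort(1000, 0.4, seed = 64)
  prior <- risk_probability(mayo_example(), co)
  post_cf <- posterior_crossfit(prior, co$marker_score, co$outcome,
                                method = "binned", seed = 65)
  expect_true(all(post_cf > 0 & post_cf < 1))
  m <- estimate_lr_binned(co$marker_score, co$outcome)
  post_in <- posterior_probability(prior, lr_at(m, co$marker_score))
  expect_lt(abs(auc(post_cf, co$outcome) - auc(post_in, co$outcome)), 0.05)
})
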