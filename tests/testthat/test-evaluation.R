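test_that("auc matches hand-enumerated pair statistics", {
  expect_equal(auc(c(0.9, 0.4, 0.1, 0.4, 0.3), c(1, 1, 0, 0, 0)), 5.5 / 6)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)       # separated
  expect_equal(auc(rep(0.3, 10), rbinom(10, 1, 0.5) * 0 + c(rep(1, 5), rep(0, 5))),
               0.5)                                         # all ties
  expect_error(auc(runif(5), rep(1, 5)), "both events")
})

test_that("auc equals the brute-force pairwise oracle, including ties", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(5:100, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    expect_equal(auc(scores, labels), brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auc agrees with an independent library implementation", {
  set.seed(110)
  scores <- c(runif(150), sample(seq(0, 1, 0.1), 50, replace = TRUE))
  labels <- c(1, 0, rbinom(198, 1, 0.4))
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("auc is invariant under strictly monotone score transforms", {
  set.seed(102)
  scores <- runif(300)
  labels <- c(1, 0, rbinom(298, 1, 0.3))
  a <- auc(scores, labels)
  expect_equal(auc(qlogis(scores), labels), a)
  expect_equal(auc(scores^3, labels), a)
  expect_equal(auc(-1 / (scores + 1), labels), a)
})

test_that("roc curve has proper endpoints and trapezoidal area", {
  set.seed(103)
  scores <- sample(seq(0, 1, by = 0.05), 400, replace = TRUE)
  labels <- c(1, 0, rbinom(398, 1, 0.35))
  rc <- roc_curve(scores, labels)
  expect_equal(rc$sensitivity[1], 0)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$sensitivity[nrow(rc)], 1)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_true(all(diff(rc$sensitivity) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_equal(attr(rc, "auc"), auc(scores, labels), tolerance = 1e-12)

  # scores equal to labels: the three canonical points
  rc2 <- roc_curve(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(rc2$fpr, c(0, 0, 1))
  expect_equal(rc2$sensitivity, c(0, 1, 1))

  # null marker at n = 1000: AUC within 3 SE of 0.5
  set.seed(104)
  s <- runif(1000); l <- rbinom(1000, 1, 0.5)
  n1 <- sum(l); n0 <- 1000 - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc(s, l) - 0.5), 3 * se)
})

test_that("idi is the difference of mean risk gains with valid inference", {
  # posterior equal to prior
  p <- runif(50); l <- c(1, 0, rbinom(48, 1, 0.5))
  r0 <- idi(p, p, l)
  expect_identical(r0$estimate, 0)
  expect_identical(r0$p_value, 1)

  # worked example: events gain +0.2, nonevents -0.1 -> estimate 0.3
  prior <- c(0.3, 0.3, 0.5, 0.5)
  post <- c(0.5, 0.5, 0.4, 0.4)
  labels <- c(1, 1, 0, 0)
  expect_warning(r <- idi(prior, post, labels), "degenerate variance")
  expect_equal(r$estimate, 0.3)

  # antisymmetry under label swap
  set.seed(105)
  pr <- runif(200); po <- plogis(qlogis(pr) + rnorm(200))
  lb <- c(1, 0, rbinom(198, 1, 0.4))
  expect_equal(idi(pr, po, 1 - lb)$estimate, -idi(pr, po, lb)$estimate)

  # asymptotic vs bootstrap agree roughly on a real instance
  ra <- idi(pr, po, lb)
  rb <- idi(pr, po, lb, method = "bootstrap", B = 2000, seed = 9)
  expect_equal(ra$estimate, rb$estimate)
  expect_lt(abs(ra$standard_error - rb$standard_error),
            0.5 * ra$standard_error)
  expect_true(ra$ci_low <= ra$estimate && ra$estimate <= ra$ci_high)
})

test_that("percent reclassified follows the off-diagonal share", {
  expect_equal(percent_reclassified(c(36, 12, 0, 2, 0), 1), 28L)
  expect_equal(percent_reclassified(c(2, 2, 6, 6, 14), 3), 80L)
  expect_identical(percent_reclassified(c(0, 0, 0, 0, 0), 5), NA_integer_)
  expect_error(percent_reclassified(c(-1, 2), 1), "nonnegative")
})

test_that("reclassification table bins, counts and percents are exact", {
  # posterior equal to prior: diagonal matrices, 0% in nonempty rows
  p <- c(0.05, 0.25, 0.45, 0.65, 0.85, 0.1)
  l <- c(1, 0, 1, 0, 1, 0)
  tab <- reclassification_table(p, p, l)
  expect_true(all(tab$events[upper.tri(tab$events)] == 0))
  expect_true(all(tab$events[lower.tri(tab$events)] == 0))
  expect_true(all(tab$pct_events %in% c(0L, NA)))
  expect_true(all(tab$pct_nonevents %in% c(0L, NA)))
  expect_equal(sum(tab$events), sum(l == 1))
  expect_equal(sum(tab$nonevents), sum(l == 0))

  # edge convention: a prior of exactly 0.2 sits in [0.2, 0.4)
  tab2 <- reclassification_table(c(0.2, 0.5), c(0.2, 0.5), c(1, 0))
  expect_equal(unname(tab2$events[2, 2]), 1)
  expect_equal(rownames(tab2$events)[2], "[0.2,0.4)")

  expect_error(reclassification_table(c(0.5, 1.2), c(0.5, 0.5), c(1, 0)),
               "\\[0, 1\\]")
})

test_that("category NRI nets upward moves of events against nonevents", {
  p <- c(0.05, 0.25, 0.45, 0.65, 0.85, 0.1)
  l <- c(1, 0, 1, 0, 1, 0)
  expect_equal(category_nri(reclassification_table(p, p, l)), 0)

  # all events up one bin, all nonevents down one: maximum NRI of 2
  pe <- rep(0.3, 10); pn <- rep(0.3, 10)
  tab <- reclassification_table(c(pe, pn), c(pe + 0.2, pn - 0.2),
                                c(rep(1, 10), rep(0, 10)))
  expect_equal(category_nri(tab), 2)

  # hand-counted 2x2 example
  ev <- matrix(c(1, 0, 3, 6), 2)
  ne <- matrix(c(6, 3, 0, 1), 2)
  expect_equal(category_nri(reclass_from_counts(ev, ne)), 0.6)
})

test_that("reclassification tables export in the published layout", {
  co <- make_scored_cohort(300, 0.4, seed = 71)
  prior <- risk_probability(mayo_example(), co)
  m <- estimate_lr_binned(co$marker_score, co$outcome)
  post <- posterior_probability(prior, lr_at(m, co$marker_score))
  tab <- reclassification_table(prior, post, co$outcome)
  path <- tempfile(fileext = ".csv")
  write_reclass_csv(tab, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 10)
  expect_equal(sum(back[back$group == "events", 3:7]), sum(co$outcome))
  expect_equal(sum(back[back$group == "nonevents", 3:7]),
               sum(1 - co$outcome))
  expect_equal(names(back)[ncol(back)], "pct_reclassified")
})
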