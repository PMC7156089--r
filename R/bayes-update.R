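#' Estimate a binned marker likelihood ratio
#'
#' Partitions \[0, 1\] into bins and estimates, per bin, the ratio of the
#' marker's frequency among events to its frequency among nonevents:
#' \deqn{LR_b = \frac{(e_b + c)/(E + 2c)}{(n_b + c)/(N + 2c)}}
#' with a continuity constant c = 0.5 applied only to bins where either
#' class count is zero.
#'
#' @param scores Marker scores in \[0, 1\].
#' @param labels Binary outcome (1 = event); both classes required.
#' @param bin_edges Strictly increasing edges spanning \[0, 1\]; default
#'   five equal-width bins.
#' @param smooth Continuity constant c (default 0.5).
#' @return An `lr_model` (method `"binned"`).
#' @export
estimate_lr_binned <- function(scores, labels,
                               bin_edges = seq(0, 1, by = 0.2),
                               smooth = 0.5) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("marker scores must be in [0, 1] with no missing values",
         call. = FALSE)
  }
  if (is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 1) {
    stop("`bin_edges` must increase strictly from 0 to 1", call. = FALSE)
  }
  nb <- length(bin_edges) - 1L
  bin <- score_bin(scores, bin_edges)
  e_b <- tabulate(bin[labels == 1L], nbins = nb)
  n_b <- tabulate(bin[labels == 0L], nbins = nb)
  E <- sum(e_b); N <- sum(n_b)
  zero <- e_b == 0L | n_b == 0L
  c_b <- ifelse(zero, smooth, 0)
  lr <- ((e_b + c_b) / (E + 2 * c_b)) / ((n_b + c_b) / (N + 2 * c_b))
  structure(list(method = "binned", bin_edges = bin_edges, lr = lr,
                 event_counts = e_b, nonevent_counts = n_b,
                 smooth = smooth),
            class = "lr_model")
}

# Left-closed right-open bins, last bin closed; interior edges belong to the
# bin on their right.
score_bin <- function(scores, bin_edges) {
  findInterval(scores, bin_edges, rightmost.closed = TRUE)
}

#' Estimate a binormal marker likelihood ratio
#'
#' Logit-transforms the scores and fits a normal density per outcome class
#' (sample mean and SD); the likelihood ratio at score y is the ratio of
#' fitted densities at logit(y).
#'
#' @inheritParams estimate_lr_binned
#' @param eps Scores are clamped to \[eps, 1 - eps\] before the logit.
#' @return An `lr_model` (method `"binormal"`).
#' @export
estimate_lr_binormal <- function(scores, labels, eps = 1e-6) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("marker scores must be in [0, 1] with no missing values",
         call. = FALSE)
  }
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("binormal LR needs at least two subjects per class", call. = FALSE)
  }
  z <- qlogis(pmin(1 - eps, pmax(eps, scores)))
  z1 <- z[labels == 1L]; z0 <- z[labels == 0L]
  s1 <- sd(z1); s0 <- sd(z0)
  if (s1 == 0 || s0 == 0) {
    stop("zero within-class variance: binormal LR is undefined",
         call. = FALSE)
  }
  structure(list(method = "binormal",
                 mu_case = mean(z1), sigma_case = s1,
                 mu_control = mean(z0), sigma_control = s0,
                 eps = eps),
            class = "lr_model")
}

#' Evaluate a likelihood-ratio model at marker scores
#'
#' Binned models return the containing bin's LR (bins left-closed
#' right-open, last bin closed); binormal models return the fitted normal
#' density ratio at the logit-transformed score.
#'
#' @param model An `lr_model`.
#' @param score Scores in \[0, 1\].
#' @return Positive likelihood ratios.
#' @export
lr_at <- function(model, score) {
  stopifnot(inherits(model, "lr_model"))
  if (anyNA(score) || any(score < 0 | score > 1)) {
    stop("scores must be in [0, 1] with no missing values", call. = FALSE)
  }
  if (model$method == "binned") {
    return(model$lr[score_bin(score, model$bin_edges)])
  }
  z <- qlogis(pmin(1 - model$eps, pmax(model$eps, score)))
  exp(dnorm(z, model$mu_case, model$sigma_case, log = TRUE) -
        dnorm(z, model$mu_control, model$sigma_control, log = TRUE))
}

#' Posterior probability via Bayes' rule
#'
#' Posterior odds = likelihood ratio x prior odds; the prior is clamped to
#' \[eps, 1 - eps\] before the odds transform so calculators emitting
#' exactly 0 or 1 do not break the update.
#'
#' @param prior Prior probabilities in \[0, 1\].
#' @param lr Positive finite likelihood ratios (recycled if scalar).
#' @param eps Clamp constant (default 1e-6).
#' @return Posterior probabilities in (0, 1).
#' @export
posterior_probability <- function(prior, lr, eps = 1e-6) {
  if (anyNA(prior) || any(prior < 0 | prior > 1)) {
    stop("`prior` must be probabilities in [0, 1]", call. = FALSE)
  }
  if (anyNA(lr) || any(!is.finite(lr)) || any(lr <= 0)) {
    stop("`lr` must be positive and finite", call. = FALSE)
  }
  p <- pmin(1 - eps, pmax(eps, prior))
  odds <- lr * p / (1 - p)
  odds / (1 + odds)
}

#' Update a cohort's prior risks with a marker likelihood ratio
#'
#' @param cohort Cohort data frame with the prior column and `marker_score`.
#' @param prior_col Name of the prior-probability column.
#' @param lr_model An `lr_model`.
#' @param posterior_col Name of the posterior column to add.
#' @return Cohort with the posterior column appended.
#' @export
update_cohort <- function(cohort, prior_col, lr_model,
                          posterior_col = "posterior") {
  if (!prior_col %in% names(cohort)) {
    stop(sprintf("cohort has no '%s' column", prior_col), call. = FALSE)
  }
  bad <- is.na(cohort[[prior_col]]) | is.na(cohort$marker_score)
  if (any(bad)) {
    ids <- if (!is.null(cohort$id)) cohort$id[bad] else which(bad)
    stop("missing prior or marker for subject(s): ",
         paste(head(ids, 10), collapse = ", "), call. = FALSE)
  }
  lr <- lr_at(lr_model, cohort$marker_score)
  cohort[[posterior_col]] <- posterior_probability(cohort[[prior_col]], lr)
  cohort
}

#' Cross-fit posterior probabilities
#'
#' Estimates the likelihood ratio on held-out folds so each subject's update
#' never uses their own outcome, avoiding the in-sample optimism of
#' estimating the LR on the cohort being updated.
#'
#' @param prior Prior probabilities.
#' @param scores Marker scores in \[0, 1\].
#' @param labels Binary outcomes.
#' @param method `"binned"` or `"binormal"`.
#' @param nfolds Number of folds (default 2).
#' @param seed Integer seed for the fold split (stratified by outcome).
#' @param ... Passed to the LR estimator.
#' @return Posterior probabilities.
#' @export
posterior_crossfit <- function(prior, scores, labels,
                               method = c("binned", "binormal"),
                               nfolds = 2L, seed = 1L, ...) {
  method <- match.arg(method)
  labels <- check_binary_labels(labels)
  n <- length(labels)
  stopifnot(length(prior) == n, length(scores) == n, nfolds >= 2L)
  set.seed(derive_seed(seed, "crossfit"))
  fold <- integer(n)
  for (cls in c(0L, 1L)) {   # stratified so every fold sees both classes
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  est <- switch(method, binned = estimate_lr_binned,
                binormal = estimate_lr_binormal)
  post <- numeric(n)
  for (k in seq_len(nfolds)) {
    hold <- fold == k
    m <- est(scores[!hold], labels[!hold], ...)
    post[hold] <- posterior_probability(prior[hold],
                                        lr_at(m, scores[hold]))
  }
  post
}

#' Serialize / read a likelihood-ratio model as JSON
#'
#' @param model An `lr_model`.
#' @param path File path.
#' @return `write_lr_json()` returns `path` invisibly; `read_lr_json()`
#'   returns the `lr_model`.
#' @export
write_lr_json <- function(model, path) {
  stopifnot(inherits(model, "lr_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lr_json
#' @export
read_lr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "lr_model")
}

#' @export
print.lr_model <- function(x, ...) {
  if (x$method == "binned") {
    cat("<lr_model> binned\n")
    lab <- bin_labels(x$bin_edges)
    for (i in seq_along(x$lr)) {
      cat(sprintf("  %-10s LR = %8.4f  (events %d / nonevents %d)\n",
                  lab[i], x$lr[i], x$event_counts[i], x$nonevent_counts[i]))
    }
  } else {
    cat(sprintf(
      "<lr_model> binormal (logit scale)\n  cases    N(%.3f, %.3f)\n  controls N(%.3f, %.3f)\n",
      x$mu_case, x$sigma_case, x$mu_control, x$sigma_control))
  }
  invisible(x)
}
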