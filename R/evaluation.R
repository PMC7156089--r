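#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen event outscores a randomly chosen
#' nonevent, with ties credited 0.5; identical to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores Numeric scores (any scale; only the ordering matters).
#' @param labels Binary outcome (1 = event); both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores)) stop("`scores` must not contain NA", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (descending), plus the
#' (0,0) endpoint.  The trapezoidal area equals [auc()] to numerical
#' precision.
#'
#' @inheritParams auc
#' @return Object of class `roc_curve`: data frame with `threshold`,
#'   `sensitivity`, `fpr` (1 - specificity), and attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  tp <- cumsum(labels[ord] == 1L)
  fp <- cumsum(labels[ord] == 0L)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tied block
  sens <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  area <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  out <- data.frame(threshold = c(Inf, s[last]),
                    sensitivity = sens, fpr = fpr)
  structure(out, auc = area, class = c("roc_curve", "data.frame"))
}

#' Integrated discrimination improvement
#'
#' IDI = (mean risk gain among events) - (mean risk gain among nonevents),
#' where the gain is updated minus initial predicted risk.  The default
#' asymptotic standard error treats the per-subject gains as two independent
#' samples; a seeded within-class bootstrap is available.
#'
#' @param prior Initial-model predicted risks.
#' @param posterior Updated-model predicted risks.
#' @param labels Binary outcome (1 = event).
#' @param method `"asymptotic"` or `"bootstrap"`.
#' @param B Bootstrap replicates (default 2000).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `idi_result`: list with `estimate`,
#'   `standard_error`, `ci_low`, `ci_high`, `p_value`, `method`.
#' @export
idi <- function(prior, posterior, labels, method = c("asymptotic", "bootstrap"),
                B = 2000L, seed = 1L, conf_level = 0.95) {
  method <- match.arg(method)
  labels <- check_binary_labels(labels)
  stopifnot(length(prior) == length(labels),
            length(posterior) == length(labels))
  d <- posterior - prior
  d1 <- d[labels == 1L]; d0 <- d[labels == 0L]
  est <- mean(d1) - mean(d0)
  z_crit <- qnorm(1 - (1 - conf_level) / 2)
  if (method == "asymptotic") {
    v1 <- if (length(d1) > 1L) var(d1) else 0
    v0 <- if (length(d0) > 1L) var(d0) else 0
    se <- sqrt(v1 / length(d1) + v0 / length(d0))
    if (se == 0) {
      if (est == 0) {
        return(structure(list(estimate = 0, standard_error = 0,
                              ci_low = 0, ci_high = 0, p_value = 1,
                              method = "asymptotic"),
                         class = "idi_result"))
      }
      warning("degenerate variance; falling back to bootstrap IDI inference")
      return(idi(prior, posterior, labels, method = "bootstrap",
                 B = B, seed = seed, conf_level = conf_level))
    }
    z <- est / se
    return(structure(list(estimate = est, standard_error = se,
                          ci_low = est - z_crit * se,
                          ci_high = est + z_crit * se,
                          p_value = 2 * pnorm(-abs(z)),
                          method = "asymptotic"),
                     class = "idi_result"))
  }
  set.seed(derive_seed(seed, "idi-boot"))
  boot <- replicate(B, {
    mean(sample(d1, replace = TRUE)) - mean(sample(d0, replace = TRUE))
  })
  se <- sd(boot)
  alpha <- 1 - conf_level
  ci <- quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  structure(list(estimate = est, standard_error = se,
                 ci_low = ci[1], ci_high = ci[2],
                 p_value = min(1, p), method = "bootstrap"),
            class = "idi_result")
}

#' @export
print.idi_result <- function(x, ...) {
  cat(sprintf("IDI = %.4f (SE %.4f, 95%% CI %.4f to %.4f, p = %.4g; %s)\n",
              x$estimate, x$standard_error, x$ci_low, x$ci_high,
              x$p_value, x$method))
  invisible(x)
}

bin_labels <- function(bin_edges) {
  k <- length(bin_edges) - 1L
  close <- c(rep(")", k - 1L), "]")
  sprintf("[%s,%s%s", format(bin_edges[-(k + 1L)], trim = TRUE),
          format(bin_edges[-1L], trim = TRUE), close)
}

#' Percent reclassified in one row of a reclassification table
#'
#' 100 x (off-diagonal count / row total), rounded to the nearest integer
#' (ties to even, as `round()`); `NA` for an empty row.
#'
#' @param row_counts Nonnegative counts across updated-model categories.
#' @param diagonal_index 1-based index of the unchanged (diagonal) category.
#' @return Integer percent or `NA`.
#' @export
percent_reclassified <- function(row_counts, diagonal_index) {
  if (anyNA(row_counts) || any(row_counts < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  stopifnot(diagonal_index >= 1L, diagonal_index <= length(row_counts))
  s <- sum(row_counts)
  if (s == 0) return(NA_integer_)
  as.integer(round(100 * (s - row_counts[diagonal_index]) / s))
}

#' Reclassification table
#'
#' Cross-tabulates initial-model against updated-model risk categories,
#' separately for events and nonevents, with percent reclassified per
#' initial category.  Categories are left-closed right-open with the last
#' bin closed; the default edges are the conventional five bands
#' \[0,0.2), \[0.2,0.4), \[0.4,0.6), \[0.6,0.8), \[0.8,1\].
#'
#' @inheritParams idi
#' @param bin_edges Strictly increasing category edges spanning \[0, 1\].
#' @return Object of class `reclass_table`: list with `events`,
#'   `nonevents` (count matrices), `pct_events`, `pct_nonevents`
#'   (integer percents per initial category, `NA` for empty rows) and
#'   `bin_edges`.
#' @export
reclassification_table <- function(prior, posterior, labels,
                                   bin_edges = seq(0, 1, by = 0.2)) {
  labels <- check_binary_labels(labels)
  stopifnot(length(prior) == length(labels),
            length(posterior) == length(labels))
  if (anyNA(prior) || anyNA(posterior) ||
      any(prior < 0 | prior > 1 | posterior < 0 | posterior > 1)) {
    stop("risks must be probabilities in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(bin_edges, strictly = TRUE) ||
      bin_edges[1] != 0 || bin_edges[length(bin_edges)] != 1) {
    stop("`bin_edges` must increase strictly from 0 to 1", call. = FALSE)
  }
  k <- length(bin_edges) - 1L
  lab <- bin_labels(bin_edges)
  b_init <- factor(score_bin(prior, bin_edges), levels = seq_len(k))
  b_upd <- factor(score_bin(posterior, bin_edges), levels = seq_len(k))
  mk <- function(keep) {
    m <- table(initial = b_init[keep], updated = b_upd[keep])
    m <- matrix(as.integer(m), k, k, dimnames = list(initial = lab,
                                                     updated = lab))
    m
  }
  ev <- mk(labels == 1L)
  ne <- mk(labels == 0L)
  pct <- function(m) vapply(seq_len(k), function(i) {
    percent_reclassified(m[i, ], i)
  }, integer(1))
  structure(list(events = ev, nonevents = ne,
                 pct_events = pct(ev), pct_nonevents = pct(ne),
                 bin_edges = bin_edges),
            class = "reclass_table")
}

#' @export
print.reclass_table <- function(x, ...) {
  show <- function(m, pct, title) {
    cat(sprintf("%s (n = %d)\n", title, sum(m)))
    df <- as.data.frame.matrix(m)
    df[["% reclassified"]] <- ifelse(is.na(pct), "NA", pct)
    print(df)
    cat("\n")
  }
  show(x$nonevents, x$pct_nonevents, "Nonevents")
  show(x$events, x$pct_events, "Events")
  invisible(x)
}

#' Write a reclassification table as CSV
#'
#' Layout mirrors the usual published form: one block per outcome group,
#' initial categories as rows, updated categories as columns, percent
#' reclassified as the last column.
#'
#' @param x A `reclass_table`.
#' @param path File path.
#' @export
write_reclass_csv <- function(x, path) {
  stopifnot(inherits(x, "reclass_table"))
  block <- function(m, pct, group) {
    data.frame(group = group, initial = rownames(m),
               as.data.frame.matrix(m, optional = TRUE),
               pct_reclassified = pct, check.names = FALSE)
  }
  out <- rbind(block(x$nonevents, x$pct_nonevents, "nonevents"),
               block(x$events, x$pct_events, "events"))
  write.csv(out, path, row.names = FALSE, na = "NA",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a reclassification table from count matrices
#'
#' Wraps already-tabulated event and nonevent count matrices (e.g. rows
#' transcribed from a published table) as a `reclass_table`, recomputing the
#' percent-reclassified columns from the counts.
#'
#' @param events,nonevents Square count matrices (initial categories as
#'   rows, updated as columns).
#' @param bin_edges Category edges; defaults to equal-width bins matching
#'   the matrix dimension.
#' @return A `reclass_table`.
#' @export
reclass_from_counts <- function(events, nonevents,
                                bin_edges = seq(0, 1,
                                                length.out = nrow(events) + 1)) {
  events <- as.matrix(events); nonevents <- as.matrix(nonevents)
  if (nrow(events) != ncol(events) || !all(dim(events) == dim(nonevents))) {
    stop("count matrices must be square and of equal dimension",
         call. = FALSE)
  }
  if (anyNA(events) || anyNA(nonevents) ||
      any(events < 0) || any(nonevents < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  k <- nrow(events)
  lab <- bin_labels(bin_edges)
  dimnames(events) <- dimnames(nonevents) <- list(initial = lab,
                                                  updated = lab)
  pct <- function(m) vapply(seq_len(k), function(i) {
    percent_reclassified(m[i, ], i)
  }, integer(1))
  structure(list(events = events, nonevents = nonevents,
                 pct_events = pct(events), pct_nonevents = pct(nonevents),
                 bin_edges = bin_edges),
            class = "reclass_table")
}

#' Category net reclassification index
#'
#' NRI = \[P(up | event) - P(down | event)\] -
#' \[P(up | nonevent) - P(down | nonevent)\], where up/down means the
#' updated category lies above/below the initial one.
#'
#' @param table A `reclass_table`.
#' @return NRI in \[-2, 2\].
#' @export
category_nri <- function(table) {
  stopifnot(inherits(table, "reclass_table"))
  net_up <- function(m) {
    tot <- sum(m)
    if (tot == 0) stop("empty outcome group in reclassification table",
                       call. = FALSE)
    (sum(m[upper.tri(m)]) - sum(m[lower.tri(m)])) / tot
  }
  net_up(table$events) - net_up(table$nonevents)
}
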