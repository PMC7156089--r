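# Brute-force Mann-Whitney AUC: enumerate all event/nonevent pairs,
# crediting 1 for a win and 0.5 for a tie.  Independent of the package's
# rank-based implementation.
brute_force_auc <- function(scores, labels) {
  ev <- scores[labels == 1]
  ne <- scores[labels == 0]
  total <- 0
  for (e in ev) total <- total + sum(e > ne) + 0.5 * sum(e == ne)
  total / (length(ev) * length(ne))
}

# Mayo-style example risk model used across tests.
mayo_example <- function() {
  risk_model_template(
    "mayo", intercept = -6.8272,
    coefficients = c(age = 0.0391, smoker_current = 0.7917,
                     prior_cancer = 1.3388, nodule_diameter_mm = 0.1274,
                     spiculation = 1.0407, upper_lobe = 0.7838))
}

# Directly-specified LR models for worked examples and null-calibration
# checks (pre-specified mapping, independent of any data).
manual_binned_lr <- function(bin_edges, lr) {
  structure(list(method = "binned", bin_edges = bin_edges, lr = lr,
                 event_counts = rep(NA_integer_, length(lr)),
                 nonevent_counts = rep(NA_integer_, length(lr)),
                 smooth = 0.5),
            class = "lr_model")
}

manual_binormal_lr <- function(mu_case, mu_control, sigma_case = 1,
                               sigma_control = 1) {
  structure(list(method = "binormal", mu_case = mu_case,
                 sigma_case = sigma_case, mu_control = mu_control,
                 sigma_control = sigma_control, eps = 1e-6),
            class = "lr_model")
}

# Published reclassification tables (counts and printed percent-reclassified
# cells) shipped as a plain-text fixture; returns a list of count matrices
# plus the printed percents.
published_tables <- function() {
  path <- system.file("extdata", "published_reclassification_tables.csv",
                      package = "incrval")
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (tb in unique(df$table)) {
    for (gp in unique(df$group)) {
      sub <- df[df$table == tb & df$group == gp, ]
      sub <- sub[order(sub$initial_bin), ]
      out[[paste0("t", tb, "_", gp)]] <- list(
        counts = as.matrix(sub[, c("c1", "c2", "c3", "c4", "c5")]),
        pct_printed = sub$pct_printed)
    }
  }
  out
}

# Small informative synthetic cohort with marker scores attached.
make_scored_cohort <- function(n = 400, prevalence = 0.4, mu_diff = 1,
                               seed = 42, miss_rate = 0) {
  co <- generate_cohort(cohort_spec(n, prevalence, seed = seed))
  generate_marker_scores(co, marker_spec(mu_case = mu_diff, mu_control = 0,
                                         detection_miss_rate = miss_rate),
                         seed = seed + 1)
}
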