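#' Assemble a study configuration
#'
#' Describes one end-to-end incremental-value study: where the cohort comes
#' from (synthetic spec or CSV), which prior risk model(s) to evaluate, how
#' the marker likelihood ratio is estimated, the risk-category edges, and
#' whether multiple imputation is applied to missing covariates.
#'
#' @param cohort Either `list(source = "synthetic", n_subjects, prevalence,
#'   marker = list(...), missingness = list(...))` (marker args as in
#'   [marker_spec()]; optional missingness args as in
#'   [inject_missingness()]), or `list(source = "csv", path, regions)`
#'   (`regions` optional: per-scan detection CSV reduced via
#'   [assign_marker_scores()]).
#' @param models A [risk_model_spec()], a list of them, or a path readable
#'   by [load_model_spec()].
#' @param lr List: `method` (`"binned"` or `"binormal"`), optional
#'   `bin_edges`, `crossfit` (logical, default `FALSE`: the LR is estimated
#'   on the cohort being updated), `nfolds`.
#' @param bin_edges Risk-category edges for reclassification (default the
#'   five conventional bands).
#' @param mi List: `enabled` (default `FALSE`), `m` (default 5),
#'   `iterations` (default 10).
#' @param seed Global seed; every stage derives a substream from it.
#' @param out_dir Output directory; when non-`NULL`, [run_study()] persists
#'   all intermediates there.
#' @return A `study_config` list.
#' @export
study_config <- function(cohort, models, lr = list(method = "binned"),
                         bin_edges = seq(0, 1, by = 0.2),
                         mi = list(enabled = FALSE), seed = 1L,
                         out_dir = NULL) {
  stopifnot(is.list(cohort), !is.null(cohort$source))
  if (!cohort$source %in% c("synthetic", "csv")) {
    stop("cohort$source must be 'synthetic' or 'csv'", call. = FALSE)
  }
  lr$method <- match.arg(lr$method %||% "binned", c("binned", "binormal"))
  lr$crossfit <- isTRUE(lr$crossfit)
  lr$nfolds <- lr$nfolds %||% 2L
  mi$enabled <- isTRUE(mi$enabled)
  mi$m <- mi$m %||% 5L
  mi$iterations <- mi$iterations %||% 10L
  structure(list(cohort = cohort, models = models, lr = lr,
                 bin_edges = bin_edges, mi = mi, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

#' Load a study configuration from YAML
#'
#' @param path YAML file with the fields of [study_config()]; `models` may
#'   be a path (resolved relative to the config file).
#' @return A `study_config`.
#' @export
load_study_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.character(doc$models) &&
      !file.exists(doc$models)) {
    candidate <- file.path(dirname(path), doc$models)
    if (file.exists(candidate)) doc$models <- candidate
  }
  study_config(cohort = doc$cohort, models = doc$models,
               lr = doc$lr %||% list(method = "binned"),
               bin_edges = unlist(doc$bin_edges) %||% seq(0, 1, by = 0.2),
               mi = doc$mi %||% list(enabled = FALSE),
               seed = doc$seed %||% 1L,
               out_dir = doc$out_dir)
}

resolve_models <- function(models) {
  if (is.character(models)) models <- load_model_spec(models)
  if (inherits(models, "risk_model_spec")) models <- list(models)
  names(models) <- vapply(models, `[[`, character(1), "name")
  models
}

build_cohort <- function(config) {
  cc <- config$cohort
  if (cc$source == "csv") {
    cohort <- read_cohort_csv(cc$path)
    if (!is.null(cc$regions)) {
      cohort <- assign_marker_scores(cohort, read_region_csv(cc$regions))
    }
    if (is.null(cohort$marker_score)) {
      stop("cohort CSV has no marker_score column and no regions file given",
           call. = FALSE)
    }
    return(cohort)
  }
  spec <- cohort_spec(n_subjects = cc$n_subjects,
                      prevalence = cc$prevalence,
                      covariates = cc$covariates %||% default_covariate_specs(),
                      seed = derive_seed(config$seed, "cohort-stage"))
  cohort <- generate_cohort(spec)
  mk <- cc$marker
  if (is.null(mk)) stop("synthetic cohort config needs a `marker` block",
                        call. = FALSE)
  mspec <- marker_spec(mu_case = mk$mu_case, mu_control = mk$mu_control,
                       sigma_case = mk$sigma_case %||% 1,
                       sigma_control = mk$sigma_control %||% 1,
                       link = mk$link %||% "clamp",
                       detection_miss_rate = mk$detection_miss_rate %||% 0)
  cohort <- generate_marker_scores(cohort, mspec,
                                   seed = derive_seed(config$seed,
                                                      "marker-stage"))
  ms <- cc$missingness
  if (!is.null(ms)) {
    cohort <- inject_missingness(cohort, field = ms$field, rate = ms$rate,
                                 mechanism = ms$mechanism %||% "MCAR",
                                 on = ms$on,
                                 seed = derive_seed(config$seed,
                                                    "missing-stage"))
  }
  cohort
}

estimate_lr <- function(config, scores, labels) {
  if (config$lr$method == "binned") {
    estimate_lr_binned(scores, labels,
                       bin_edges = unlist(config$lr$bin_edges) %||%
                         seq(0, 1, by = 0.2))
  } else {
    estimate_lr_binormal(scores, labels)
  }
}

posterior_for <- function(config, prior, scores, labels, lr_model) {
  if (config$lr$crossfit) {
    posterior_crossfit(prior, scores, labels,
                       method = config$lr$method,
                       nfolds = config$lr$nfolds,
                       seed = derive_seed(config$seed, "crossfit-stage"))
  } else {
    posterior_probability(prior, lr_at(lr_model, scores))
  }
}

evaluate_model <- function(config, cohort, prior, posterior) {
  labels <- cohort$outcome
  tab <- reclassification_table(prior, posterior, labels,
                                bin_edges = config$bin_edges)
  list(auc_prior = auc(prior, labels),
       auc_posterior = auc(posterior, labels),
       idi = idi(prior, posterior, labels,
                 seed = derive_seed(config$seed, "idi-stage")),
       reclassification = tab,
       nri = category_nri(tab))
}

#' Run an incremental-value study end to end
#'
#' Stages: build or read the cohort; reduce region detections to one marker
#' score per subject; exclude unscored subjects; evaluate prior risk per
#' model; estimate the marker likelihood ratio; update priors by Bayes'
#' rule; compute AUCs, IDI, the reclassification table and the category
#' NRI; and, when multiple imputation is enabled and covariates are
#' missing, repeat the prior/update/IDI stage on each completed dataset and
#' pool the IDI with Rubin's rules.  All intermediates are persisted when
#' `config$out_dir` is set.  Identical config + seed gives an identical
#' report.
#'
#' @param config A [study_config()].
#' @return A `study_report`: list with `n_total`, `n_excluded`,
#'   `n_analyzed`, `auc_marker`, `lr_model`, per-model results (`models`),
#'   MI results (`mi`, when run) and `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  models <- resolve_models(config$models)
  cohort <- build_cohort(config)
  n_total <- nrow(cohort)

  excl <- exclude_unscored(cohort)
  cohort <- excl$cohort
  log_stage("exclude_unscored", n_in = n_total, n_out = nrow(cohort),
            n_excluded = excl$n_excluded)
  if (nrow(cohort) == 0L) stop("no subjects remain after exclusion",
                               call. = FALSE)

  labels <- cohort$outcome
  scores <- cohort$marker_score
  lr_model <- estimate_lr(config, scores, labels)

  priors <- lapply(models, risk_probability, cohort = cohort)
  prior_missing <- Reduce(`|`, lapply(priors, is.na))
  mi_result <- NULL
  results <- list()

  if (any(prior_missing) && config$mi$enabled) {
    completed <- impute_chained(cohort, m = config$mi$m,
                                iterations = config$mi$iterations,
                                seed = derive_seed(config$seed, "mi-stage"))
    log_stage("impute_chained", n_in = nrow(cohort),
              m = config$mi$m, n_missing = sum(prior_missing))
    mi_result <- list(m = config$mi$m, models = list())
    for (nm in names(models)) {
      per_imp <- lapply(completed, function(comp) {
        prior <- risk_probability(models[[nm]], comp)
        post <- posterior_for(config, prior, scores, labels, lr_model)
        list(prior = prior, posterior = post,
             idi = idi(prior, post, labels,
                       seed = derive_seed(config$seed, "idi-stage")),
             auc_prior = auc(prior, labels),
             auc_posterior = auc(post, labels))
      })
      pooled <- rubins_pool(
        vapply(per_imp, function(x) x$idi$estimate, numeric(1)),
        vapply(per_imp, function(x) x$idi$standard_error^2, numeric(1))
      )
      # headline tables/AUCs from the first completed dataset, as one
      # representative imputation
      first <- per_imp[[1L]]
      results[[nm]] <- evaluate_model(config, cohort, first$prior,
                                      first$posterior)
      mi_result$models[[nm]] <- list(
        pooled_idi = pooled,
        mean_auc_prior = mean(vapply(per_imp, `[[`, numeric(1),
                                     "auc_prior")),
        mean_auc_posterior = mean(vapply(per_imp, `[[`, numeric(1),
                                         "auc_posterior"))
      )
      priors[[nm]] <- first$prior
      attr(results[[nm]], "posterior") <- first$posterior
    }
  } else {
    if (any(prior_missing)) {
      message(sprintf(
        "excluding %d subject(s) with missing risk-model covariates (MI disabled)",
        sum(prior_missing)))
      cohort <- cohort[!prior_missing, , drop = FALSE]
      labels <- cohort$outcome
      scores <- cohort$marker_score
      lr_model <- estimate_lr(config, scores, labels)
      priors <- lapply(models, risk_probability, cohort = cohort)
    }
    for (nm in names(models)) {
      post <- posterior_for(config, priors[[nm]], scores, labels, lr_model)
      results[[nm]] <- evaluate_model(config, cohort, priors[[nm]], post)
      attr(results[[nm]], "posterior") <- post
    }
  }

  scored <- cohort
  for (nm in names(models)) {
    scored[[paste0("prior_", nm)]] <- priors[[nm]]
    scored[[paste0("posterior_", nm)]] <- attr(results[[nm]], "posterior")
  }

  report <- structure(list(
    n_total = n_total,
    n_excluded = excl$n_excluded,
    excluded_ids = excl$excluded_ids,
    n_analyzed = nrow(cohort),
    auc_marker = auc(scores, labels),
    lr_model = lr_model,
    models = results,
    mi = mi_result,
    scored_cohort = scored,
    provenance = list(seed = config$seed,
                      config_hash = content_hash(strip_config(config)),
                      package_version = as.character(
                        utils::packageVersion("incrval")))
  ), class = "study_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# out_dir must not affect the provenance hash
strip_config <- function(config) {
  config$out_dir <- NULL
  unclass(config)
}

log_stage <- function(stage, ...) {
  kv <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), unlist(kv), sep = "=", collapse = " ")))
}

#' Persist a study report and its intermediates
#'
#' Writes the scored cohort (priors and posteriors per model) as CSV, the
#' LR model as JSON, one reclassification-table CSV and one ROC-points CSV
#' per model, and the full report as JSON.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(report$scored_cohort, file.path(dir, "cohort_scored.csv"))
  write_lr_json(report$lr_model, file.path(dir, "lr_model.json"))
  for (nm in names(report$models)) {
    res <- report$models[[nm]]
    write_reclass_csv(res$reclassification,
                      file.path(dir, sprintf("reclassification_%s.csv", nm)))
    lab <- report$scored_cohort$outcome
    roc <- rbind(
      cbind(model = "prior",
            as.data.frame(roc_curve(report$scored_cohort[[paste0("prior_", nm)]], lab))),
      cbind(model = "marker",
            as.data.frame(roc_curve(report$scored_cohort$marker_score, lab))),
      cbind(model = "posterior",
            as.data.frame(roc_curve(report$scored_cohort[[paste0("posterior_", nm)]], lab)))
    )
    write.csv(roc, file.path(dir, sprintf("roc_points_%s.csv", nm)),
              row.names = FALSE, fileEncoding = "UTF-8")
  }
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

report_to_list <- function(report) {
  model_list <- lapply(report$models, function(res) {
    list(auc_prior = res$auc_prior,
         auc_posterior = res$auc_posterior,
         idi = unclass(res$idi),
         nri = res$nri,
         reclassification = list(
           bin_edges = res$reclassification$bin_edges,
           events = apply(res$reclassification$events, 1, as.list),
           nonevents = apply(res$reclassification$nonevents, 1, as.list),
           pct_events = as.list(res$reclassification$pct_events),
           pct_nonevents = as.list(res$reclassification$pct_nonevents)))
  })
  mi_list <- if (!is.null(report$mi)) {
    list(m = report$mi$m,
         models = lapply(report$mi$models, function(x) {
           list(pooled_idi = unclass(x$pooled_idi),
                mean_auc_prior = x$mean_auc_prior,
                mean_auc_posterior = x$mean_auc_posterior)
         }))
  }
  list(n_total = report$n_total,
       n_excluded = report$n_excluded,
       n_analyzed = report$n_analyzed,
       auc_marker = report$auc_marker,
       lr_model = unclass(report$lr_model),
       models = model_list,
       mi = mi_list,
       provenance = report$provenance)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects analyzed (%d excluded of %d)\n",
              x$n_analyzed, x$n_excluded, x$n_total))
  cat(sprintf("  AUC (marker alone): %.3f\n", x$auc_marker))
  for (nm in names(x$models)) {
    res <- x$models[[nm]]
    cat(sprintf("  model '%s': AUC prior %.3f -> posterior %.3f; NRI %.3f\n",
                nm, res$auc_prior, res$auc_posterior, res$nri))
    cat("    ")
    print(res$idi)
  }
  if (!is.null(x$mi)) {
    for (nm in names(x$mi$models)) {
      cat(sprintf("  MI (m = %d), model '%s': pooled ", x$mi$m, nm))
      print(x$mi$models[[nm]]$pooled_idi)
    }
  }
  invisible(x)
}
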