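#' Specify one synthetic covariate
#'
#' Describes the marginal distribution of a single covariate in a synthetic
#' cohort, optionally shifted in the malignant (case) class so that clinical
#' risk models built on the covariate carry real signal.
#'
#' @param name Covariate name (unique within a cohort spec).
#' @param dist Distribution family: `"normal"`, `"lognormal"`, `"gamma"`,
#'   `"bernoulli"` or `"poisson"`.
#' @param params Named list of family parameters: `mean`/`sd` (normal),
#'   `meanlog`/`sdlog` (lognormal), `shape`/`scale` (gamma), `p` (bernoulli),
#'   `lambda` (poisson).
#' @param case_shift Additive shift applied in the case class: to the mean
#'   (normal), `meanlog` (lognormal), the drawn value (gamma), `p`
#'   (bernoulli, clamped to \[0,1\]) or `lambda` (poisson).
#' @param lower,upper Optional truncation bounds; draws are clamped.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(name, dist = c("normal", "lognormal", "gamma",
                                          "bernoulli", "poisson"),
                           params = list(), case_shift = 0,
                           lower = -Inf, upper = Inf) {
  dist <- match.arg(dist)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("covariate `name` must be a nonempty string", call. = FALSE)
  }
  need <- switch(dist,
    normal    = c("mean", "sd"),
    lognormal = c("meanlog", "sdlog"),
    gamma     = c("shape", "scale"),
    bernoulli = "p",
    poisson   = "lambda"
  )
  missing_par <- setdiff(need, names(params))
  if (length(missing_par)) {
    stop(sprintf("covariate '%s': missing %s parameter(s): %s",
                 name, dist, paste(missing_par, collapse = ", ")),
         call. = FALSE)
  }
  bad <- switch(dist,
    normal    = params$sd <= 0,
    lognormal = params$sdlog <= 0,
    gamma     = params$shape <= 0 || params$scale <= 0,
    bernoulli = params$p < 0 || params$p > 1,
    poisson   = params$lambda < 0
  )
  if (isTRUE(bad)) {
    stop(sprintf("covariate '%s': invalid %s parameters", name, dist),
         call. = FALSE)
  }
  structure(list(name = name, dist = dist, params = params,
                 case_shift = case_shift, lower = lower, upper = upper),
            class = "covariate_spec")
}

#' Default covariate set for a lung-nodule style cohort
#'
#' Marginals chosen to look like a nodule-evaluation population: age in
#' years, smoking history, pack-years, years since quitting, prior cancer,
#' nodule diameter in millimetres (log-normal, clamped to 3-30 mm),
#' spiculation, upper-lobe location, and the extra covariates a
#' McWilliams-style calculator asks for (sex, family history, emphysema,
#' part-solid type, nodule count).  Cases are shifted modestly on age,
#' diameter, spiculation and prior-cancer so covariate-based priors are
#' informative.
#'
#' @return List of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  list(
    covariate_spec("age", "normal", list(mean = 62, sd = 8),
                   case_shift = 3, lower = 35, upper = 90),
    covariate_spec("sex", "bernoulli", list(p = 0.5)),
    covariate_spec("smoker_current", "bernoulli", list(p = 0.45),
                   case_shift = 0.10),
    covariate_spec("pack_years", "gamma", list(shape = 2, scale = 18),
                   case_shift = 8, lower = 0, upper = 200),
    covariate_spec("years_quit", "gamma", list(shape = 1.5, scale = 8),
                   lower = 0, upper = 50),
    covariate_spec("prior_cancer", "bernoulli", list(p = 0.08),
                   case_shift = 0.08),
    covariate_spec("nodule_diameter_mm", "lognormal",
                   list(meanlog = log(9), sdlog = 0.40),
                   case_shift = 0.30, lower = 3, upper = 30),
    covariate_spec("spiculation", "bernoulli", list(p = 0.20),
                   case_shift = 0.22),
    covariate_spec("upper_lobe", "bernoulli", list(p = 0.50),
                   case_shift = 0.10),
    covariate_spec("family_history", "bernoulli", list(p = 0.15)),
    covariate_spec("emphysema", "bernoulli", list(p = 0.30),
                   case_shift = 0.08),
    covariate_spec("part_solid", "bernoulli", list(p = 0.20)),
    covariate_spec("nodule_count", "poisson", list(lambda = 0.8),
                   lower = 0)
  )
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param prevalence Outcome (malignancy) prevalence, strictly in (0, 1).
#' @param covariates List of [covariate_spec()] objects with unique names;
#'   defaults to [default_covariate_specs()].
#' @param seed Integer seed; all generation stages derive substream seeds
#'   from it deterministically.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects, prevalence,
                        covariates = default_covariate_specs(),
                        seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      is.na(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must be strictly between 0 and 1", call. = FALSE)
  }
  nm <- vapply(covariates, function(cv) cv$name, character(1))
  if (anyDuplicated(nm)) {
    stop("covariate names must be unique: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 prevalence = prevalence,
                 covariates = covariates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_covariate <- function(cv, outcome) {
  n <- length(outcome)
  shift <- ifelse(outcome == 1L, cv$case_shift, 0)
  p <- cv$params
  x <- switch(cv$dist,
    normal    = rnorm(n, p$mean + shift, p$sd),
    lognormal = rlnorm(n, p$meanlog + shift, p$sdlog),
    gamma     = rgamma(n, shape = p$shape, scale = p$scale) + shift,
    bernoulli = rbinom(n, 1L, pmin(1, pmax(0, p$p + shift))),
    poisson   = rpois(n, pmax(0, p$lambda + shift))
  )
  pmin(cv$upper, pmax(cv$lower, x))
}

#' Generate a synthetic cohort
#'
#' Draws a binary malignancy outcome at the specified prevalence and the
#' covariates per their marginal specs (with optional case shifts).
#' Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with columns `id`, `outcome` and one column per
#'   covariate.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_subjects
  set.seed(derive_seed(spec$seed, "cohort"))
  outcome <- rbinom(n, 1L, spec$prevalence)
  cov_cols <- lapply(spec$covariates, draw_covariate, outcome = outcome)
  names(cov_cols) <- vapply(spec$covariates, `[[`, character(1), "name")
  out <- data.frame(id = sprintf("S%05d", seq_len(n)),
                    outcome = outcome,
                    cov_cols,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Specify a binormal marker model
#'
#' The marker is drawn from a latent normal in each outcome class and mapped
#' monotonically into \[0, 1\] so it behaves like a probability score (as an
#' image classifier would emit).  A fraction of subjects can be left without
#' a score, emulating scans in which no suspicious region is detected.
#'
#' @param mu_case,mu_control Latent-scale means for events / nonevents.
#' @param sigma_case,sigma_control Latent-scale SDs (> 0).
#' @param link Monotone latent-to-\[0,1\] map: `"clamp"` (affine rescale of
#'   the +/- 3 SD latent range onto (0.01, 0.99), then hard clamp) or
#'   `"logistic"` (logistic squash centred between the class means).
#' @param detection_miss_rate Probability in \[0, 1) that a subject receives
#'   no marker score at all.
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(mu_case, mu_control,
                        sigma_case = 1, sigma_control = 1,
                        link = c("clamp", "logistic"),
                        detection_miss_rate = 0) {
  link <- match.arg(link)
  if (sigma_case <= 0 || sigma_control <= 0) {
    stop("marker sigmas must be positive", call. = FALSE)
  }
  if (detection_miss_rate < 0 || detection_miss_rate >= 1) {
    stop("`detection_miss_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(list(mu_case = mu_case, mu_control = mu_control,
                 sigma_case = sigma_case, sigma_control = sigma_control,
                 link = link, detection_miss_rate = detection_miss_rate),
            class = "marker_spec")
}

apply_link <- function(latent, spec) {
  if (spec$link == "logistic") {
    return(plogis(latent - (spec$mu_case + spec$mu_control) / 2))
  }
  smax <- max(spec$sigma_case, spec$sigma_control)
  lo <- min(spec$mu_case, spec$mu_control) - 3 * smax
  hi <- max(spec$mu_case, spec$mu_control) + 3 * smax
  pmin(0.99, pmax(0.01, 0.01 + 0.98 * (latent - lo) / (hi - lo)))
}

#' Attach binormal marker scores to a cohort
#'
#' @param cohort Cohort data frame with an `outcome` column.
#' @param spec A [marker_spec()].
#' @param seed Integer seed.
#' @return The cohort with a `marker_score` column; missed-detection
#'   subjects get `NA`.
#' @export
generate_marker_scores <- function(cohort, spec, seed = 1L) {
  stopifnot(inherits(spec, "marker_spec"))
  if (is.null(cohort$outcome)) {
    stop("cohort outcomes must be assigned before marker generation",
         call. = FALSE)
  }
  n <- nrow(cohort)
  set.seed(derive_seed(seed, "marker"))
  mu <- ifelse(cohort$outcome == 1L, spec$mu_case, spec$mu_control)
  sg <- ifelse(cohort$outcome == 1L, spec$sigma_case, spec$sigma_control)
  latent <- rnorm(n, mu, sg)
  score <- apply_link(latent, spec)
  if (spec$detection_miss_rate > 0) {
    score[runif(n) < spec$detection_miss_rate] <- NA_real_
  }
  cohort$marker_score <- score
  cohort
}

#' Closed-form AUC of a binormal marker
#'
#' For a strictly monotone link the AUC of the observed score equals the AUC
#' of the latent marker,
#' \eqn{\Phi\!\left((\mu_1-\mu_0)/\sqrt{\sigma_1^2+\sigma_0^2}\right)}.
#' Used as the oracle for parameter-recovery tests.
#'
#' @param spec A [marker_spec()].
#' @return True AUC in \[0, 1\].
#' @export
closed_form_auc <- function(spec) {
  stopifnot(inherits(spec, "marker_spec"))
  pnorm((spec$mu_case - spec$mu_control) /
          sqrt(spec$sigma_case^2 + spec$sigma_control^2))
}

#' Inject missingness into one covariate
#'
#' Blanks a covariate in a random subset of subjects, either completely at
#' random (MCAR) or at random given a conditioning covariate (MAR: the
#' missingness probability increases monotonically with the conditioning
#' covariate's rank, averaging `rate`).
#'
#' @param cohort Cohort data frame.
#' @param field Covariate to blank.
#' @param rate Expected missingness fraction in \[0, 1).
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param on Conditioning covariate name (required for `"MAR"`).
#' @param seed Integer seed.
#' @return Cohort with `NA` in the blanked cells.
#' @export
inject_missingness <- function(cohort, field, rate,
                               mechanism = c("MCAR", "MAR"),
                               on = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!field %in% names(cohort)) {
    stop(sprintf("unknown field '%s' in cohort", field), call. = FALSE)
  }
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(cohort)
  n <- nrow(cohort)
  set.seed(derive_seed(seed, paste0("miss:", field)))
  if (mechanism == "MCAR") {
    p <- rep(rate, n)
  } else {
    if (is.null(on) || !on %in% names(cohort)) {
      stop("MAR mechanism requires a conditioning covariate via `on`",
           call. = FALSE)
    }
    # probabilities proportional to rank of the conditioning covariate,
    # rescaled to average `rate` and capped at 1
    r <- rank(cohort[[on]], ties.method = "average")
    p <- pmin(1, rate * 2 * r / (n + 1))
  }
  cohort[[field]][runif(n) < p] <- NA
  cohort
}

covariate_columns <- function(cohort) {
  setdiff(names(cohort), c("id", "outcome", "marker_score"))
}

#' Write / read a cohort as CSV
#'
#' Columns are `id`, `outcome`, `marker_score` (if present), then covariates
#' in alphabetical order; missing values are empty cells.  The round trip is
#' lossless for values and missingness.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  covs <- sort(covariate_columns(cohort))
  lead <- intersect(c("id", "outcome", "marker_score"), names(cohort))
  write.csv(cohort[, c(lead, covs), drop = FALSE], path,
            row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                 check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("id", "outcome") %in% names(df))) {
    stop("cohort CSV must have 'id' and 'outcome' columns", call. = FALSE)
  }
  if (anyNA(df$outcome) || !all(df$outcome %in% c(0, 1))) {
    bad <- which(anyNA(df$outcome) | !df$outcome %in% c(0, 1))
    stop(sprintf("invalid outcome value at data row(s) %s: must be 0/1",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  df$id <- as.character(df$id)
  df$outcome <- as.integer(df$outcome)
  df
}
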