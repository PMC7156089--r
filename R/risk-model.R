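#' Specify one term of a logistic risk model
#'
#' @param covariate Covariate name.
#' @param coefficient Log-odds coefficient.
#' @param transform Covariate transform: `"identity"`, `"log"` (natural log,
#'   positive input required), `"scale"` (divide by constant `param`), or
#'   `"indicator"` (1 if the value is nonzero, or equals `param` when given).
#' @param param Transform parameter (`"scale"` divisor or `"indicator"`
#'   level); ignored otherwise.
#' @return A `term_spec` list.
#' @export
term_spec <- function(covariate, coefficient,
                      transform = c("identity", "log", "scale", "indicator"),
                      param = NULL) {
  transform <- match.arg(transform)
  if (!is.character(covariate) || length(covariate) != 1L || !nzchar(covariate)) {
    stop("`covariate` must be a nonempty string", call. = FALSE)
  }
  if (!is.numeric(coefficient) || length(coefficient) != 1L || is.na(coefficient)) {
    stop(sprintf("term '%s': missing or non-numeric coefficient", covariate),
         call. = FALSE)
  }
  if (transform == "scale" &&
      (is.null(param) || !is.numeric(param) || param == 0)) {
    stop(sprintf("term '%s': 'scale' transform needs a nonzero `param`",
                 covariate), call. = FALSE)
  }
  structure(list(covariate = covariate, transform = transform,
                 param = param, coefficient = coefficient),
            class = "term_spec")
}

#' Specify a logistic prior-risk model
#'
#' Houses a published-style malignancy risk calculator as intercept plus
#' transformed covariate terms on the log-odds scale; the predicted risk is
#' the inverse logit of the linear predictor.
#'
#' @param name Model name (nonempty).
#' @param intercept Intercept on the log-odds scale.
#' @param terms List of [term_spec()] objects; duplicate covariates are an
#'   error.
#' @return A `risk_model_spec`; `required_covariates` is the set of term
#'   covariates.
#' @export
risk_model_spec <- function(name, intercept, terms = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("model `name` must be a nonempty string", call. = FALSE)
  }
  if (!is.numeric(intercept) || length(intercept) != 1L || is.na(intercept)) {
    stop("`intercept` must be a single number", call. = FALSE)
  }
  terms <- lapply(terms, function(tm) {
    if (inherits(tm, "term_spec")) tm else do.call(term_spec, tm)
  })
  covs <- vapply(terms, `[[`, character(1), "covariate")
  if (anyDuplicated(covs)) {
    stop("duplicate covariate in terms: ",
         paste(unique(covs[duplicated(covs)]), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, intercept = intercept, terms = terms,
                 required_covariates = covs),
            class = "risk_model_spec")
}

apply_transform <- function(tm, x) {
  switch(tm$transform,
    identity = x,
    log = {
      bad <- !is.na(x) & x <= 0
      if (any(bad)) {
        stop(sprintf("natural-log transform of non-positive value in '%s'",
                     tm$covariate), call. = FALSE)
      }
      log(x)
    },
    scale = x / tm$param,
    indicator = {
      if (is.null(tm$param)) as.numeric(x != 0) else as.numeric(x == tm$param)
    }
  )
}

#' Linear predictor of a risk model
#'
#' Evaluates intercept + sum of coefficient x transform(covariate) for each
#' subject.  Subjects missing any required covariate get `NA` (flagged for
#' downstream imputation or exclusion rather than an error); their ids are
#' attached as attribute `"missing_subjects"`.
#'
#' @param spec A [risk_model_spec()].
#' @param cohort Cohort data frame (one row per subject).
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(spec, cohort) {
  stopifnot(inherits(spec, "risk_model_spec"))
  absent <- setdiff(spec$required_covariates, names(cohort))
  if (length(absent)) {
    stop(sprintf("model '%s': cohort lacks required covariate(s): %s",
                 spec$name, paste(absent, collapse = ", ")), call. = FALSE)
  }
  lp <- rep(spec$intercept, nrow(cohort))
  for (tm in spec$terms) {
    lp <- lp + tm$coefficient * apply_transform(tm, cohort[[tm$covariate]])
  }
  if (anyNA(lp) && !is.null(cohort$id)) {
    attr(lp, "missing_subjects") <- cohort$id[is.na(lp)]
  }
  lp
}

#' Prior risk probability from a risk model
#'
#' Inverse-logit of [linear_predictor()]; numerically stable over the full
#' double range (uses `plogis`).
#'
#' @inheritParams linear_predictor
#' @return Probabilities in (0, 1), `NA` where required covariates are
#'   missing.
#' @export
risk_probability <- function(spec, cohort) {
  lp <- linear_predictor(spec, cohort)
  p <- plogis(as.numeric(lp))
  attr(p, "missing_subjects") <- attr(lp, "missing_subjects")
  p
}

# Covariate templates of the cited calculator families.  Coefficients are
# deliberately NOT shipped here: they are configuration the user supplies
# (see load_model_spec()), these templates only fix the covariate sets and
# transforms.
risk_model_templates <- function() {
  list(
    gould = list(
      list(covariate = "nodule_diameter_mm", transform = "log"),
      list(covariate = "age", transform = "identity"),
      list(covariate = "smoker_current", transform = "identity"),
      list(covariate = "years_quit", transform = "scale", param = 10)
    ),
    mayo = list(
      list(covariate = "age", transform = "identity"),
      list(covariate = "smoker_current", transform = "identity"),
      list(covariate = "prior_cancer", transform = "identity"),
      list(covariate = "nodule_diameter_mm", transform = "identity"),
      list(covariate = "spiculation", transform = "identity"),
      list(covariate = "upper_lobe", transform = "identity")
    ),
    mcwilliams = list(
      list(covariate = "age", transform = "identity"),
      list(covariate = "sex", transform = "identity"),
      list(covariate = "family_history", transform = "identity"),
      list(covariate = "emphysema", transform = "identity"),
      list(covariate = "nodule_diameter_mm", transform = "log"),
      list(covariate = "part_solid", transform = "identity"),
      list(covariate = "upper_lobe", transform = "identity"),
      list(covariate = "nodule_count", transform = "identity"),
      list(covariate = "spiculation", transform = "identity")
    )
  )
}

#' Build a risk model from a named covariate template
#'
#' Templates `"gould"`, `"mayo"` and `"mcwilliams"` declare the covariate
#' sets and transforms of the corresponding calculator families; the
#' coefficients (and intercept) must be supplied by the user, typically from
#' a config file, and verified against the original publications.
#'
#' @param template One of `"gould"`, `"mayo"`, `"mcwilliams"`.
#' @param intercept Intercept on the log-odds scale.
#' @param coefficients Named numeric vector/list, one entry per template
#'   covariate; a missing entry is an error.
#' @param name Model name (defaults to the template name).
#' @return A [risk_model_spec()].
#' @export
risk_model_template <- function(template = c("gould", "mayo", "mcwilliams"),
                                intercept, coefficients, name = template) {
  template <- match.arg(template)
  skel <- risk_model_templates()[[template]]
  coefficients <- as.list(coefficients)
  terms <- lapply(skel, function(tm) {
    cf <- coefficients[[tm$covariate]]
    if (is.null(cf)) {
      stop(sprintf("template '%s': missing coefficient for covariate '%s'",
                   template, tm$covariate), call. = FALSE)
    }
    term_spec(tm$covariate, cf, tm$transform, tm$param)
  })
  risk_model_spec(name = name[[1]], intercept = intercept, terms = terms)
}

term_to_list <- function(tm) {
  out <- list(covariate = tm$covariate, transform = tm$transform,
              coefficient = tm$coefficient)
  if (!is.null(tm$param)) out$param <- tm$param
  out
}

#' Load / save risk model specs from YAML or JSON
#'
#' The document is either one model or a list of models.  Each model has
#' keys `name`, `intercept`, and either `terms` (list of
#' `{covariate, transform, param, coefficient}`) or `template` +
#' `coefficients` (see [risk_model_template()]).
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` vs
#'   `.json`).
#' @return `load_model_spec()`: a [risk_model_spec()] or named list of them.
#' @export
load_model_spec <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  parse_one <- function(m) {
    if (is.null(m$name) && is.null(m$template)) {
      stop("model document needs a 'name' or 'template' key", call. = FALSE)
    }
    if (!is.null(m$template)) {
      if (is.null(m$intercept)) {
        stop(sprintf("model '%s': missing intercept",
                     m$name %||% m$template), call. = FALSE)
      }
      return(risk_model_template(m$template, intercept = m$intercept,
                                 coefficients = m$coefficients %||% list(),
                                 name = m$name %||% m$template))
    }
    if (is.null(m$intercept)) {
      stop(sprintf("model '%s': missing intercept", m$name), call. = FALSE)
    }
    risk_model_spec(m$name, m$intercept, m$terms %||% list())
  }
  if (!is.null(doc$name) || !is.null(doc$template) ||
      !is.null(doc$intercept)) {
    return(parse_one(doc))
  }
  specs <- lapply(doc, parse_one)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' @rdname load_model_spec
#' @param spec A [risk_model_spec()] or list of them.
#' @export
write_model_spec <- function(spec, path) {
  to_list <- function(s) list(name = s$name, intercept = s$intercept,
                              terms = lapply(s$terms, term_to_list))
  doc <- if (inherits(spec, "risk_model_spec")) to_list(spec) else
    unname(lapply(spec, to_list))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @export
print.risk_model_spec <- function(x, ...) {
  cat(sprintf("<risk_model_spec> %s\n  intercept: %g\n", x$name, x$intercept))
  for (tm in x$terms) {
    cat(sprintf("  %+.4f * %s(%s%s)\n", tm$coefficient, tm$transform,
                tm$covariate,
                if (!is.null(tm$param)) paste0(", ", tm$param) else ""))
  }
  invisible(x)
}
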