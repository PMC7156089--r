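#' Reduce one subject's region detections to a marker score
#'
#' A detection model emits zero or more suspicious regions per CT scan, each
#' with a malignancy probability; the subject-level marker is the maximum
#' across detected regions.  A scan with no detections yields no score.
#'
#' @param probabilities Numeric vector of per-region malignancy
#'   probabilities for one subject (possibly empty).
#' @return The maximum probability, or `NA` for an empty input.
#' @export
subject_marker_score <- function(probabilities) {
  if (length(probabilities) == 0L) return(NA_real_)
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1)) {
    stop("region malignancy probabilities must be in [0, 1]", call. = FALSE)
  }
  max(probabilities)
}

#' Read a region-detection table
#'
#' @param path CSV with columns `subject_id`, `region_id`,
#'   `malignancy_probability`.
#' @return Data frame of detections.
#' @export
read_region_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_id", "region_id", "malignancy_probability")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop("region CSV lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df$malignancy_probability) ||
      any(df$malignancy_probability < 0 | df$malignancy_probability > 1)) {
    stop("region malignancy probabilities must be in [0, 1]", call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Attach region-derived marker scores to a cohort
#'
#' Applies [subject_marker_score()] per subject; subjects with no detected
#' regions get `NA`.  The region id achieving the maximum (first seen on
#' ties) is recorded in attribute `"argmax_region"` for audit.
#'
#' @param cohort Cohort data frame with an `id` column.
#' @param regions Region data frame as from [read_region_csv()].
#' @return Cohort with a `marker_score` column.
#' @export
assign_marker_scores <- function(cohort, regions) {
  if (anyNA(regions$malignancy_probability) ||
      any(regions$malignancy_probability < 0 |
          regions$malignancy_probability > 1)) {
    stop("region malignancy probabilities must be in [0, 1]", call. = FALSE)
  }
  by_subj <- split(regions, regions$subject_id)
  score <- rep(NA_real_, nrow(cohort))
  argmax <- rep(NA_character_, nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rg <- by_subj[[cohort$id[i]]]
    if (!is.null(rg) && nrow(rg) > 0L) {
      k <- which.max(rg$malignancy_probability)  # first-seen wins on ties
      score[i] <- rg$malignancy_probability[k]
      argmax[i] <- as.character(rg$region_id[k])
    }
  }
  cohort$marker_score <- score
  attr(cohort, "argmax_region") <- stats::setNames(argmax, cohort$id)
  cohort
}

#' Exclude subjects without a marker score
#'
#' Mirrors the analysis rule of removing scans for which the image model
#' predicted no suspicious region.  Alternatively, absent scores can be
#' replaced by a floor value for sensitivity analyses.
#'
#' @param cohort Cohort data frame with a `marker_score` column.
#' @param floor_score Optional probability: instead of excluding, absent
#'   scores are set to this value.
#' @return List with `cohort` (retained subjects), `n_excluded`, and
#'   `excluded_ids`.
#' @export
exclude_unscored <- function(cohort, floor_score = NULL) {
  if (is.null(cohort$marker_score)) {
    stop("cohort has no `marker_score` column", call. = FALSE)
  }
  absent <- is.na(cohort$marker_score)
  if (!is.null(floor_score)) {
    stopifnot(is_prob(floor_score))
    cohort$marker_score[absent] <- floor_score
    return(list(cohort = cohort, n_excluded = 0L,
                excluded_ids = character(0)))
  }
  excluded_ids <- if (!is.null(cohort$id)) cohort$id[absent] else
    as.character(which(absent))
  if (any(absent)) {
    message(sprintf("excluding %d subject(s) with no marker score: %s",
                    sum(absent),
                    paste(head(excluded_ids, 10), collapse = ", ")))
  }
  out <- cohort[!absent, , drop = FALSE]
  rownames(out) <- NULL
  list(cohort = out, n_excluded = sum(absent), excluded_ids = excluded_ids)
}
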