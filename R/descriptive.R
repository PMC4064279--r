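#' Count injuries by surveillance classification
#'
#' Tallies an injury log under the two-tier surveillance definitions:
#' every injury reported to a show therapist is a medical-attention
#' injury, and those causing at least one missed performance are
#' additionally time-loss (TL-1) injuries -- so the TL-1 count can never
#' exceed the medical-attention count. Records flagged as personal
#' (non-work) health conditions via a logical `personal_health` column are
#' excluded from both counts and reported separately.
#'
#' @param log Injury-log data frame with column `missed_performances`
#'   (and/or a `classification` column with values `"medical_attention"` /
#'   `"tl1"`; when both are present a `"tl1"` record with zero missed
#'   performances is a validation error).
#' @return A tibble with rows `medical_attention` and `tl1` and column
#'   `n`; the number of excluded personal-health records is attached as
#'   attribute `n_excluded`.
#' @examples
#' log <- tibble::tibble(missed_performances = c(0, 0, 2, 0, 1, 0, 0, 0, 5))
#' classify_injuries(log)
#' @export
classify_injuries <- function(log) {
  stopifnot(is.data.frame(log))
  if (!any(c("missed_performances", "classification") %in% names(log))) {
    abort("injury log needs a `missed_performances` or `classification` column")
  }
  n_excluded <- 0L
  if ("personal_health" %in% names(log)) {
    n_excluded <- sum(log$personal_health, na.rm = TRUE)
    log <- log[!(log$personal_health %in% TRUE), , drop = FALSE]
  }
  if ("missed_performances" %in% names(log)) {
    if (any(!is.finite(log$missed_performances) |
              log$missed_performances < 0)) {
      abort("`missed_performances` must be non-negative counts")
    }
    tl1 <- log$missed_performances >= 1
    if ("classification" %in% names(log)) {
      bad <- which(log$classification == "tl1" & !tl1)
      if (length(bad) > 0) {
        abort(sprintf(paste0(
          "record(s) %s are classified tl1 but missed no performances"),
          paste(bad, collapse = ", ")))
      }
    }
  } else {
    tl1 <- log$classification == "tl1"
  }
  out <- tibble::tibble(
    classification = c("medical_attention", "tl1"),
    n = c(nrow(log), sum(tl1))
  )
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Injury incidence rate per 1000 artist-performances
#'
#' @param n_injuries Number of injuries (vectorised).
#' @param n_exposures Number of artist-performances (> 0); an injury count
#'   above the exposure count is rejected.
#' @param classification Optional label(s) carried into the output.
#' @return A tibble with `n_injuries`, `n_exposures` and `rate_per_1000`
#'   (injuries per 1000 artist-performances, reported to one decimal,
#'   half-up -- the surveillance reporting convention).
#' @examples
#' injury_rate(c(9, 3), 2660, c("medical_attention", "tl1"))
#' @export
injury_rate <- function(n_injuries, n_exposures, classification = NULL) {
  if (any(!is.finite(n_exposures) | n_exposures <= 0)) {
    abort("`n_exposures` must be positive")
  }
  if (any(!is.finite(n_injuries) | n_injuries < 0)) {
    abort("`n_injuries` must be non-negative")
  }
  if (any(n_injuries > n_exposures)) {
    abort("`n_injuries` cannot exceed `n_exposures`")
  }
  out <- tibble::tibble(
    n_injuries = n_injuries,
    n_exposures = n_exposures,
    rate_per_1000 = round_half_up(n_injuries / n_exposures * 1000, 1)
  )
  if (!is.null(classification)) {
    out <- dplyr::mutate(out, classification = classification, .before = 1)
  }
  out
}

#' Recruitment rate as a percentage
#'
#' @param consented Number of participants recruited.
#' @param approached Number approached (> 0, >= `consented`).
#' @return Percentage recruited, one decimal, half-up; vectorised.
#' @examples
#' recruitment_rate(37, 82)  # 45.1
#' recruitment_rate(36, 82)  # 43.9
#' @export
recruitment_rate <- function(consented, approached) {
  if (any(!is.finite(approached) | approached <= 0)) {
    abort("`approached` must be positive")
  }
  if (any(!is.finite(consented) | consented < 0)) {
    abort("`consented` must be non-negative")
  }
  if (any(consented > approached)) {
    abort("`consented` cannot exceed `approached`")
  }
  round_half_up(100 * consented / approached, 1)
}

#' Incidence-rate report for an injury log
#'
#' Convenience wrapper combining [classify_injuries()] and
#' [injury_rate()]: classification counts with their rates per 1000
#' artist-performances.
#'
#' @param log Injury-log data frame (see [classify_injuries()]).
#' @param n_exposures Total artist-performances over the surveillance
#'   window.
#' @return A tibble with one row per classification: `classification`,
#'   `n_injuries`, `n_exposures`, `rate_per_1000`.
#' @examples
#' log <- tibble::tibble(missed_performances = c(0, 0, 2, 0, 1, 0, 0, 0, 5))
#' injury_rate_table(log, 2660)
#' @export
injury_rate_table <- function(log, n_exposures) {
  counts <- classify_injuries(log)
  injury_rate(counts$n, n_exposures, counts$classification)
}
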