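#' Artist-performances needed to accrue a number of cases
#'
#' The number of artist-performances that must occur equals the required
#' number of cases divided by the injury rate per 1000 artist-exposures:
#' `cases / (rate_per_1000 / 1000)`. Returned unrounded.
#'
#' @param cases Required number of cases (injuries); vectorised.
#' @param rate_per_1000 Injury rate per 1000 artist-performances (> 0).
#' @return Numeric vector of artist-performances.
#' @examples
#' performances_required(828, 10)   # 82800
#' performances_required(1301, 10)  # 130100
#' @export
performances_required <- function(cases, rate_per_1000) {
  if (any(!is.finite(cases) | cases < 0)) {
    abort("`cases` must be non-negative")
  }
  if (any(!is.finite(rate_per_1000) | rate_per_1000 <= 0)) {
    abort("`rate_per_1000` must be positive")
  }
  cases / (rate_per_1000 / 1000)
}

#' Months of follow-up for a roster to accumulate the performances
#'
#' Converts a number of artist-performances into calendar months for a
#' fixed roster performing year-round:
#' `months = performances / (n_artists * performances_per_artist_year) * 12`.
#'
#' @param performances Artist-performances to accumulate (>= 0);
#'   vectorised.
#' @param n_artists Roster size (>= 1).
#' @param performances_per_artist_year Average performances per artist per
#'   year (> 0); the planning default elsewhere in the package is 470, the
#'   schedule of a nightly-show company.
#' @return Numeric vector of months (unrounded).
#' @examples
#' months_required(performances_required(1301, 1.5), 210, 470)
#' @export
months_required <- function(performances, n_artists,
                            performances_per_artist_year) {
  if (any(!is.finite(performances) | performances < 0)) {
    abort("`performances` must be non-negative")
  }
  n_artists <- check_count(n_artists, "n_artists", min = 1)
  performances_per_artist_year <-
    check_positive(performances_per_artist_year,
                   "performances_per_artist_year")
  performances / (n_artists * performances_per_artist_year) * 12
}

#' Full study-duration plan for a required case count
#'
#' Chains the two planning conversions -- cases to artist-performances to
#' months for a roster -- and reports both the raw and the
#' nearest-integer (half-up) months.
#'
#' @param required_cases Required cases; vectorised.
#' @param injury_rate_per_1000 Expected injury rate per 1000
#'   artist-performances.
#' @param n_artists Roster size (default 210: 35 artists per show on six
#'   shows, the planning recruitment scenario).
#' @param performances_per_artist_year Average performances per artist per
#'   year (default 470).
#' @return A tibble with one row per case count: `required_cases`,
#'   `injury_rate_per_1000`, `artist_performances`, `n_artists`,
#'   `performances_per_artist_year`, `months`, `months_rounded`.
#' @examples
#' plan_study(c(828, 1301), injury_rate_per_1000 = 1.5)
#' @export
plan_study <- function(required_cases, injury_rate_per_1000,
                       n_artists = 210, performances_per_artist_year = 470) {
  perf <- performances_required(required_cases, injury_rate_per_1000)
  months <- months_required(perf, n_artists, performances_per_artist_year)
  tibble::tibble(
    required_cases = required_cases,
    injury_rate_per_1000 = injury_rate_per_1000,
    artist_performances = perf,
    n_artists = as.integer(n_artists),
    performances_per_artist_year = performances_per_artist_year,
    months = months,
    months_rounded = as.integer(round_half_up(months))
  )
}

#' Plan study duration over a grid of matched-design scenarios
#'
#' For each scenario row, computes the required cases from the correlated
#' matched case-control method ([required_cases()]) and converts them to
#' artist-performances and months of follow-up. The canonical sweep
#' crosses the minimal important difference (`psi` 1.25 and 1.5) with the
#' expected injury rate (time-loss ~1.5/1000 vs medical attention
#' ~10/1000) over the per-variable exposure correlations.
#'
#' @param scenarios Data frame with columns `psi`, `rate_per_1000` and
#'   `phi` (optionally `variable` labels); one row per scenario. An empty
#'   frame returns an empty plan.
#' @param n_artists,performances_per_artist_year Roster assumptions, as in
#'   [plan_study()].
#' @param p0,m,alpha,power Remaining matched-design parameters, as in
#'   [matched_design()].
#' @return A tibble with the scenario columns, `required_cases`,
#'   `achieved_power`, `artist_performances`, `months` and
#'   `months_rounded`.
#' @examples
#' plan_scenarios(tibble::tibble(psi = 1.5, rate_per_1000 = 1.5,
#'                               phi = c(0.16, 0.58)))
#' @export
plan_scenarios <- function(scenarios, n_artists = 210,
                           performances_per_artist_year = 470, p0 = 0.3,
                           m = 10, alpha = 0.05, power = 0.8) {
  stopifnot(is.data.frame(scenarios))
  needed <- c("psi", "rate_per_1000", "phi")
  missing_cols <- setdiff(needed, names(scenarios))
  if (length(missing_cols) > 0) {
    abort(paste0("scenarios lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(scenarios) == 0) {
    return(tibble::tibble(
      psi = numeric(), rate_per_1000 = numeric(), phi = numeric(),
      required_cases = integer(), achieved_power = numeric(),
      artist_performances = numeric(), n_artists = integer(),
      months = numeric(), months_rounded = integer()
    ))
  }
  purrr::map_dfr(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, , drop = FALSE]
    rc <- required_cases(matched_design(
      p0 = p0, psi = row$psi, m = m, phi = row$phi, alpha = alpha,
      power = power
    ))
    plan <- plan_study(rc$required_cases, row$rate_per_1000, n_artists,
                       performances_per_artist_year)
    out <- tibble::tibble(
      psi = row$psi, rate_per_1000 = row$rate_per_1000, phi = row$phi,
      required_cases = rc$required_cases,
      achieved_power = rc$achieved_power,
      artist_performances = plan$artist_performances,
      n_artists = plan$n_artists,
      months = plan$months,
      months_rounded = plan$months_rounded
    )
    if ("variable" %in% names(row)) {
      out <- dplyr::mutate(out, variable = row$variable, .before = 1)
    }
    out
  })
}
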