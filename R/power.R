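#' Describe one prospective daily-measurement power scenario
#'
#' A trial design is one cell of the power exploration for the prospective
#' cohort: roster size, follow-up days, baseline injury rate, minimal
#' important difference (as a rate ratio per 2-category state change),
#' day-to-day ICC of the driving state, significance level and analysis
#' engine. Several designs row-bound together form a grid for
#' [power_grid()].
#'
#' @param n_artists Number of artists followed (>= 2).
#' @param n_days Number of observation days (>= 2); one performance per
#'   artist-day.
#' @param baseline_rate_per_1000 Baseline injury rate per 1000
#'   artist-exposures.
#' @param mid_rate_ratio Minimal important difference: injury rate ratio
#'   per 2-category state increase (1 = null).
#' @param icc Intraclass correlation of the daily state (default 0.35, the
#'   mid-range overall-feeling value of the pilot panel).
#' @param alpha Two-sided significance level.
#' @param engine Analysis engine, `"marginal"` (GEE) or `"mixed"`.
#' @return A one-row tibble of the validated design.
#' @examples
#' trial_design(180, 100)
#' @export
trial_design <- function(n_artists, n_days, baseline_rate_per_1000 = 1.6,
                         mid_rate_ratio = 1.25, icc = 0.35, alpha = 0.05,
                         engine = c("marginal", "mixed")) {
  engine <- match.arg(engine)
  tibble::tibble(
    n_artists = check_count(n_artists, "n_artists", min = 2),
    n_days = check_count(n_days, "n_days", min = 2),
    baseline_rate_per_1000 = check_positive(baseline_rate_per_1000,
                                            "baseline_rate_per_1000"),
    mid_rate_ratio = check_positive(mid_rate_ratio, "mid_rate_ratio"),
    icc = check_fraction(icc, "icc", 0, 1, open_hi = TRUE),
    alpha = check_fraction(alpha, "alpha", 0, 1, open_lo = TRUE,
                           open_hi = TRUE),
    engine = engine
  )
}

#' Monte-Carlo power of a prospective daily-measurement design
#'
#' Repeats the full pipeline -- generate a correlated daily-state panel,
#' generate per-performance injuries under the design's rate ratio, fit
#' the chosen injury model -- and counts two-sided Wald rejections of the
#' state coefficient at the design's `alpha`. Replicates whose fit does not
#' converge (most commonly "no events" at rare-event settings) are excluded
#' from the denominator and reported in `n_failed_fits`; a result with more
#' than 20% failed fits carries `unreliable = TRUE`.
#'
#' @param design One-row design tibble from [trial_design()].
#' @param reps Number of Monte-Carlo replicates; fewer than 100 triggers a
#'   warning as the result is not reportable.
#' @param seed Integer seed; each replicate uses a derived sub-seed, so
#'   results are reproducible and replicates independent.
#' @param missing_prob Per-cell missingness injected into the simulated
#'   panels (default the generator's 4% item-nonresponse condition).
#' @param ... Passed on to [fit_injury_model()] (e.g. `working`,
#'   `mixed_type`, `nAGQ`).
#' @return A one-row tibble (class `injury_power_grid`) with the design
#'   columns plus `reps`, `rejections`, `n_failed_fits`, `power`,
#'   `mc_stderr` and `unreliable`.
#' @examples
#' d <- trial_design(40, 30, baseline_rate_per_1000 = 30,
#'                   mid_rate_ratio = 2)
#' estimate_power(d, reps = 100, seed = 1)
#' @export
estimate_power <- function(design, reps = 500, seed = 1L,
                           missing_prob = 0.04, ...) {
  stopifnot(is.data.frame(design), nrow(design) == 1)
  reps <- check_count(reps, "reps", min = 1)
  if (reps < 100) {
    warn(sprintf("reps = %d is below 100; power estimate is not reportable",
                 reps))
  }
  rejected <- logical(reps)
  failed <- 0L
  for (r in seq_len(reps)) {
    fit <- power_replicate(design, derive_seed(seed, "power", r),
                           missing_prob, ...)
    if (!isTRUE(fit$converged)) {
      failed <- failed + 1L
      rejected[r] <- NA
    } else {
      rejected[r] <- fit$p_value < design$alpha
    }
  }
  denom <- reps - failed
  power <- if (denom > 0) sum(rejected, na.rm = TRUE) / denom else NA_real_
  out <- dplyr::mutate(
    design,
    reps = reps,
    rejections = sum(rejected, na.rm = TRUE),
    n_failed_fits = failed,
    power = power,
    mc_stderr = if (denom > 0) sqrt(power * (1 - power) / denom) else NA_real_,
    unreliable = failed > 0.2 * reps
  )
  if (out$unreliable) {
    warn(sprintf("%d of %d fits failed; power estimate flagged unreliable",
                 failed, reps))
  }
  class(out) <- c("injury_power_grid", class(tibble::tibble()))
  out
}

power_replicate <- function(design, rep_seed, missing_prob, ...) {
  cfg <- generator_config(
    n_participants = design$n_artists, n_days = design$n_days,
    variables = "state", icc = design$icc,
    baseline_rate_per_1000 = design$baseline_rate_per_1000,
    rate_ratio_per_2cat = design$mid_rate_ratio,
    missing_prob = missing_prob, seed = rep_seed
  )
  panel <- simulate_state_panel(cfg)
  injuries <- simulate_injuries(panel, "state", cfg)
  fit <- fit_injury_model(panel, injuries, "state", engine = design$engine,
                          ...)
  list(converged = fit$converged, p_value = fit$p_value)
}

#' Power over a grid of prospective designs
#'
#' Maps [estimate_power()] over a tibble of designs (one per row, as built
#' by [trial_design()] and `dplyr::bind_rows()` or `tidyr::expand_grid()`),
#' with a distinct derived seed per cell. An empty grid returns an empty
#' tibble.
#'
#' @param designs Tibble of designs, one row per scenario.
#' @param reps Replicates per cell.
#' @param seed Root seed; cell `i` uses a seed derived from `(seed, i)`.
#' @param ... Passed to [estimate_power()].
#' @return A tibble of class `injury_power_grid`, one row per design, in
#'   input order; see [autoplot.injury_power_grid()] for display.
#' @examples
#' grid <- dplyr::bind_rows(
#'   trial_design(30, 20, baseline_rate_per_1000 = 40, mid_rate_ratio = 2),
#'   trial_design(60, 20, baseline_rate_per_1000 = 40, mid_rate_ratio = 2)
#' )
#' power_grid(grid, reps = 100, seed = 1)
#' @export
power_grid <- function(designs, reps = 500, seed = 1L, ...) {
  stopifnot(is.data.frame(designs))
  if (nrow(designs) == 0) {
    out <- tibble::tibble(
      n_artists = integer(), n_days = integer(),
      baseline_rate_per_1000 = numeric(), mid_rate_ratio = numeric(),
      icc = numeric(), alpha = numeric(), engine = character(),
      reps = integer(), rejections = integer(), n_failed_fits = integer(),
      power = numeric(), mc_stderr = numeric(), unreliable = logical()
    )
    class(out) <- c("injury_power_grid", class(tibble::tibble()))
    return(out)
  }
  out <- purrr::map_dfr(seq_len(nrow(designs)), function(i) {
    estimate_power(designs[i, , drop = FALSE], reps = reps,
                   seed = derive_seed(seed, "grid", i), ...)
  })
  class(out) <- c("injury_power_grid", class(tibble::tibble()))
  out
}
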