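#' Configuration of the synthetic daily-state panel generator
#'
#' Bundles and validates every parameter of the synthetic cohort: roster
#' size, follow-up length, the daily ordinal state variables with their
#' target intraclass correlations, the ordinal scale, the injury process,
#' and the root seed. The defaults emulate the pilot artist cohort: 37
#' artists followed for about 70 nightly performances, the nine daily state
#' items with their estimated ICCs (see [daily_state_iccs()]), a baseline
#' time-loss (TL-1) injury rate of 1.6 per 1000 artist-exposures, a minimal
#' important difference of a 25% rate increase per 2-category state change,
#' and roughly 4% item nonresponse (the pilot observed 68/1297 and 42/1297
#' missed items on its two flagged questions).
#'
#' @param n_participants Number of participants (artists) in the panel.
#' @param n_days Number of follow-up days; one performance (exposure) per
#'   participant-day.
#' @param variables Character vector of daily state variable names.
#' @param icc Intraclass correlation targets in `[0, 1)`, recycled or named
#'   by variable: the share of latent state variance attributable to stable
#'   between-participant differences.
#' @param n_categories Number of ordinal response categories (default 7,
#'   the 7-point Likert daily items).
#' @param baseline_rate_per_1000 Baseline injury rate per 1000
#'   participant-performances (default 1.6, the company TL-1 rate).
#' @param rate_ratio_per_2cat Multiplicative change in injury rate per
#'   2-category increase in the state (default 1.25, the 25% minimal
#'   important difference). `1` means no effect.
#' @param missing_prob Probability that any one recorded state value is
#'   missing, independently per cell (missing completely at random).
#' @param tl1_prob Probability that a generated injury causes at least one
#'   missed performance, i.e. is time-loss (TL-1) as well as medical
#'   attention (default 1/3, the pilot's 3 of 9).
#' @param seed Root integer seed; identical configurations and seeds yield
#'   bit-identical panels and injury logs.
#' @return A validated list of class `generator_config`.
#' @seealso [simulate_state_panel()], [simulate_injuries()]
#' @examples
#' cfg <- generator_config(n_participants = 10, n_days = 14, seed = 1)
#' cfg$icc[["confidence"]]
#' @export
generator_config <- function(n_participants = 37,
                             n_days = 70,
                             variables = daily_state_iccs()$variable,
                             icc = daily_state_iccs()$icc,
                             n_categories = 7,
                             baseline_rate_per_1000 = 1.6,
                             rate_ratio_per_2cat = 1.25,
                             missing_prob = 0.04,
                             tl1_prob = 1 / 3,
                             seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants", min = 1)
  n_days <- check_count(n_days, "n_days", min = 1)
  if (!is.character(variables) || length(variables) < 1 ||
      anyDuplicated(variables)) {
    abort("`variables` must be distinct variable names")
  }
  if (!is.numeric(icc)) abort("`icc` must be numeric")
  if (!is.null(names(icc))) {
    if (!all(variables %in% names(icc))) {
      abort("`icc` names must cover every entry of `variables`")
    }
    icc <- icc[variables]
  } else if (length(icc) == 1) {
    icc <- rep(icc, length(variables))
    names(icc) <- variables
  } else if (length(icc) == length(variables)) {
    names(icc) <- variables
  } else {
    abort("`icc` must have length 1 or length(variables), or be named")
  }
  for (v in variables) {
    if (!is.finite(icc[[v]]) || icc[[v]] < 0 || icc[[v]] >= 1) {
      abort(sprintf("`icc` for variable '%s' must lie in [0, 1) (got %s)",
                    v, format(icc[[v]])))
    }
  }
  n_categories <- check_count(n_categories, "n_categories", min = 2)
  if (length(baseline_rate_per_1000) != 1 ||
      !is.finite(baseline_rate_per_1000) || baseline_rate_per_1000 < 0) {
    abort("`baseline_rate_per_1000` must be a single non-negative rate")
  }
  rate_ratio_per_2cat <- check_positive(rate_ratio_per_2cat,
                                        "rate_ratio_per_2cat")
  missing_prob <- check_fraction(missing_prob, "missing_prob")
  tl1_prob <- check_fraction(tl1_prob, "tl1_prob")
  if (length(seed) != 1 || !is.finite(seed) || seed != floor(seed)) {
    abort("`seed` must be a single integer")
  }
  structure(
    list(
      n_participants = n_participants, n_days = n_days,
      variables = variables, icc = icc, n_categories = n_categories,
      baseline_rate_per_1000 = as.numeric(baseline_rate_per_1000),
      rate_ratio_per_2cat = rate_ratio_per_2cat,
      missing_prob = missing_prob, tl1_prob = tl1_prob,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d participants x %d days, %d variables (%d-point scale)\n",
    x$n_participants, x$n_days, length(x$variables), x$n_categories
  ))
  cat(sprintf(
    "  baseline %.3g/1000, rate ratio %.3g per 2 categories, %.1f%% missing, seed %d\n",
    x$baseline_rate_per_1000, x$rate_ratio_per_2cat, 100 * x$missing_prob,
    x$seed
  ))
  invisible(x)
}

participant_ids <- function(n) {
  sprintf("P%0*d", max(2L, nchar(n)), seq_len(n))
}

#' Simulate a panel of daily ordinal psychological states
#'
#' Draws, for each participant and variable, a latent Gaussian series
#' `z = b_participant + e_day` with `Var(b) = icc` and `Var(e) = 1 - icc`,
#' giving exchangeable (compound-symmetry) day-to-day correlation equal to
#' the target ICC. The latent values are discretised into the ordinal scale
#' through the equiprobable standard-normal cutpoints
#' `qnorm(k / n_categories)`, so the marginal distribution over categories
#' is uniform and discretisation preserves rank. Missingness is then
#' injected completely at random at `missing_prob` per cell; the latent
#' value is retained so that attenuation of ICC estimates by
#' discretisation can be quantified.
#'
#' @param config A [generator_config()].
#' @return A long-format tibble (one row per participant, day and variable)
#'   with columns `participant_id`, `day_index` (0-based), `variable`,
#'   `value` (integer category in `1:n_categories`, `NA` when missing) and
#'   `latent` (the underlying continuous draw).
#' @examples
#' cfg <- generator_config(n_participants = 5, n_days = 10, seed = 42)
#' panel <- simulate_state_panel(cfg)
#' dplyr::count(panel, variable)
#' @export
simulate_state_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_p <- config$n_participants
  n_d <- config$n_days
  k <- config$n_categories
  cuts <- qnorm(seq_len(k - 1) / k)
  ids <- participant_ids(n_p)
  withr::with_seed(derive_seed(config$seed, "states"), {
    pieces <- lapply(config$variables, function(v) {
      icc <- config$icc[[v]]
      b <- rnorm(n_p, 0, sqrt(icc))
      z <- rep(b, each = n_d) + rnorm(n_p * n_d, 0, sqrt(1 - icc))
      value <- findInterval(z, cuts) + 1L
      if (config$missing_prob > 0) {
        value[stats::runif(n_p * n_d) < config$missing_prob] <- NA_integer_
      }
      tibble::tibble(
        participant_id = rep(ids, each = n_d),
        day_index = rep(seq_len(n_d) - 1L, times = n_p),
        variable = v,
        value = value,
        latent = z
      )
    })
  })
  dplyr::bind_rows(pieces)
}

#' Simulate per-performance injuries driven by a daily state
#'
#' Treats every participant-day of the panel as one performance (one
#' artist-exposure) and draws an independent Bernoulli injury with
#' probability
#' `min(1, baseline_rate_per_1000 / 1000 * rate_ratio_per_2cat^((s - mid)/2))`,
#' where `s` is that day's state value and `mid` the scale midpoint.
#' Centering at the midpoint keeps the marginal injury rate at the baseline
#' when the effect is null (and approximately so otherwise, since the
#' discretised states are symmetric about the midpoint). Days whose state
#' value is missing are exposed at the baseline rate. Each injury receives
#' medical attention; with probability `tl1_prob` it additionally causes at
#' least one missed performance and is classified time-loss (`"tl1"`).
#'
#' @param panel A state panel from [simulate_state_panel()] (or read with
#'   [read_panel_csv()]).
#' @param variable Name of the state variable driving the injury hazard.
#' @param config The [generator_config()] holding the injury parameters and
#'   seed (the injury draw uses its own seed stream, so states and injuries
#'   are independently reproducible).
#' @return An injury-log tibble with columns `participant_id`, `day_index`,
#'   `classification` (`"medical_attention"` or `"tl1"`; time-loss injuries
#'   are a subset of medical-attention injuries) and `missed_performances`
#'   (`>= 1` iff time-loss).
#' @examples
#' cfg <- generator_config(n_participants = 20, n_days = 30,
#'                         baseline_rate_per_1000 = 50, seed = 7)
#' panel <- simulate_state_panel(cfg)
#' simulate_injuries(panel, "confidence", cfg)
#' @export
simulate_injuries <- function(panel, variable, config) {
  stopifnot(inherits(config, "generator_config"))
  if (!variable %in% unique(panel$variable)) {
    abort(sprintf("variable '%s' is not present in the panel", variable))
  }
  days <- dplyr::filter(panel, .data$variable == !!variable)
  mid <- (1 + config$n_categories) / 2
  s <- ifelse(is.na(days$value), mid, as.numeric(days$value))
  p <- config$baseline_rate_per_1000 / 1000 *
    config$rate_ratio_per_2cat^((s - mid) / 2)
  n_clipped <- sum(p > 1)
  if (n_clipped > 0) {
    warn(sprintf(
      "injury probability clipped at 1 for %d participant-day(s)", n_clipped
    ))
    p <- pmin(p, 1)
  }
  withr::with_seed(derive_seed(config$seed, "injuries"), {
    hit <- rbinom(length(p), 1L, p) == 1L
    log <- tibble::tibble(
      participant_id = days$participant_id[hit],
      day_index = days$day_index[hit]
    )
    tl1 <- rbinom(nrow(log), 1L, config$tl1_prob) == 1L
    log$classification <- ifelse(tl1, "tl1", "medical_attention")
    log$missed_performances <- ifelse(tl1, 1L + rpois(nrow(log), 1), 0L)
  })
  log
}
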