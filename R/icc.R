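#' Intraclass correlation of daily state variables
#'
#' Estimates, for each requested variable, the one-way random-effects
#' intraclass correlation ICC(1) of the daily values within participants:
#'
#' \deqn{\widehat{ICC} = \frac{MS_B - MS_W}{MS_B + (k_0 - 1) MS_W}}
#'
#' where \eqn{MS_B} and \eqn{MS_W} are the between- and within-participant
#' mean squares of the one-way ANOVA and \eqn{k_0} the effective group size
#' for unbalanced designs, \eqn{k_0 = (N - \sum_i k_i^2 / N) / (n - 1)}
#' (equal to the common group size on balanced panels). Ordinal values are
#' treated as numeric scores; missing values are dropped per variable, so
#' panels with item nonresponse are handled as unbalanced designs.
#'
#' Participants whose values never vary (the pilot cohort contained three
#' such artists) push \eqn{MS_W} towards zero; when the within-participant
#' mean square is exactly zero the estimate is reported as 1 with
#' `degenerate = TRUE` (or `NA` if the between mean square is also zero).
#' Negative ANOVA estimates are reported as computed and flagged, because
#' they are legitimate inputs to downstream power calculations; set
#' `truncate = TRUE` to clamp them at zero.
#'
#' @param panel Long-format state panel with columns `participant_id`,
#'   `day_index`, `variable`, `value`.
#' @param variables Variables to estimate; default all in the panel.
#' @param use_latent Use the continuous `latent` column (when present, as in
#'   generator output) instead of the ordinal `value`; useful to separate
#'   discretisation attenuation from sampling error.
#' @param truncate Clamp negative estimates at zero.
#' @return A tibble with one row per variable: `variable`, `icc`,
#'   `n_participants`, `mean_days_per_participant`, `k0`, `ms_between`,
#'   `ms_within`, `degenerate`, `negative`.
#' @examples
#' cfg <- generator_config(n_participants = 40, n_days = 30, seed = 3)
#' panel <- simulate_state_panel(cfg)
#' estimate_icc(panel, c("confidence", "ill_past_24h"))
#' @export
estimate_icc <- function(panel, variables = NULL, use_latent = FALSE,
                         truncate = FALSE) {
  required <- c("participant_id", "variable",
                if (use_latent) "latent" else "value")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  variables <- variables %||% unique(panel$variable)
  unknown <- setdiff(variables, unique(panel$variable))
  if (length(unknown) > 0) {
    abort(paste0("variable(s) not in panel: ", paste(unknown, collapse = ", ")))
  }
  purrr::map_dfr(variables, function(v) {
    rows <- panel[panel$variable == v, ]
    y <- if (use_latent) rows$latent else as.numeric(rows$value)
    keep <- !is.na(y)
    y <- y[keep]
    g <- factor(rows$participant_id[keep])
    ki <- tabulate(g)
    usable <- sum(ki >= 2)
    if (usable < 2) {
      abort(
        sprintf(paste0(
          "variable '%s': need at least 2 participants with at least 2 ",
          "non-missing days (found %d)"), v, usable),
        class = "injurydesign_insufficient_data"
      )
    }
    anova_icc(y, g, v, truncate)
  })
}

# One-way ANOVA ICC(1) with the unbalanced-design effective group size.
anova_icc <- function(y, g, variable, truncate = FALSE) {
  ki <- tabulate(g)
  keep_groups <- ki > 0
  ki <- ki[keep_groups]
  n <- length(ki)
  N <- sum(ki)
  sums <- rowsum(y, g)[keep_groups]
  ssq <- rowsum(y^2, g)[keep_groups]
  grand <- sum(sums) / N
  ssb <- sum(sums^2 / ki) - N * grand^2
  ssw <- sum(ssq) - sum(sums^2 / ki)
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  k0 <- (N - sum(ki^2) / N) / (n - 1)
  if (msw <= .Machine$double.eps * max(1, msb)) {
    icc <- if (msb > 0) 1 else NA_real_
    degenerate <- TRUE
  } else {
    icc <- (msb - msw) / (msb + (k0 - 1) * msw)
    degenerate <- FALSE
  }
  negative <- isTRUE(icc < 0)
  if (truncate && negative) icc <- 0
  tibble::tibble(
    variable = variable, icc = icc, n_participants = n,
    mean_days_per_participant = N / n, k0 = k0,
    ms_between = msb, ms_within = msw,
    degenerate = degenerate, negative = negative
  )
}
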