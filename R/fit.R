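#' Fit an injury model relating a daily state to per-performance injury
#'
#' Builds the per-participant-day analysis table (binary injury indicator
#' against that day's state value, days with a missing state dropped) and
#' fits one of two engines:
#'
#' * `engine = "marginal"`: binomial-logit marginal regression estimated by
#'   generalized estimating equations, clustered by participant with an
#'   exchangeable (default) or independence working correlation and robust
#'   sandwich standard errors. This mirrors the population-averaged
#'   analysis planned for daily-measurement injury cohorts.
#' * `engine = "mixed"`: binomial-logit mixed model with a participant
#'   random intercept fitted with \pkg{lme4} (default `nAGQ = 0`, the fast
#'   adaptive-Gauss-Hermite-free approximation, adequate for Wald screening
#'   of a single slope in simulation loops; set `nAGQ = 1` for the Laplace
#'   fit). `mixed_type = "linear"` instead fits a linear-probability mixed
#'   model (`lmer` on the 0/1 outcome), kept as a literal-minded variant.
#'
#' The reported test is the two-sided Wald test of the state coefficient
#' (robust z for the marginal engine, model-based z otherwise). Replicates
#' with no injuries, non-convergence, or separation return
#' `converged = FALSE` with a reason, and are excluded from power
#' denominators by [estimate_power()].
#'
#' @param panel State panel (long format, as from [simulate_state_panel()]).
#' @param injuries Injury log (as from [simulate_injuries()]).
#' @param variable State variable to use as the exposure.
#' @param engine `"marginal"` (GEE) or `"mixed"` (random intercept).
#' @param working Working correlation for the marginal engine.
#' @param mixed_type `"logit"` or `"linear"` for the mixed engine.
#' @param nAGQ Integration setting passed to [lme4::glmer()].
#' @return An object of class `injury_fit`; use [generics::tidy()] and
#'   [generics::glance()] to extract coefficient and fit-level summaries.
#' @examples
#' cfg <- generator_config(n_participants = 30, n_days = 40,
#'                         baseline_rate_per_1000 = 30, seed = 11)
#' panel <- simulate_state_panel(cfg)
#' inj <- simulate_injuries(panel, "anxiety", cfg)
#' fit <- fit_injury_model(panel, inj, "anxiety")
#' tidy(fit)
#' glance(fit)
#' @export
fit_injury_model <- function(panel, injuries, variable,
                             engine = c("marginal", "mixed"),
                             working = c("exchangeable", "independence"),
                             mixed_type = c("logit", "linear"),
                             nAGQ = 0L) {
  engine <- match.arg(engine)
  working <- match.arg(working)
  mixed_type <- match.arg(mixed_type)
  if (!variable %in% unique(panel$variable)) {
    abort(sprintf("variable '%s' is not present in the panel", variable))
  }
  rows <- panel[panel$variable == variable & !is.na(panel$value), ]
  key <- paste(rows$participant_id, rows$day_index)
  inj_key <- unique(paste(injuries$participant_id, injuries$day_index))
  y <- as.integer(key %in% inj_key)
  x <- as.numeric(rows$value)
  cluster <- rows$participant_id
  base <- list(
    engine = engine, variable = variable, n_obs = length(y),
    n_events = sum(y), n_participants = length(unique(cluster)),
    working = if (engine == "marginal") working else NA_character_,
    mixed_type = if (engine == "mixed") mixed_type else NA_character_
  )
  res <- if (engine == "marginal") {
    fit_marginal_engine(y, x, cluster, working)
  } else {
    fit_mixed_engine(y, x, cluster, mixed_type, nAGQ)
  }
  structure(c(base, res), class = "injury_fit")
}

fit_marginal_engine <- function(y, x, cluster, working) {
  f <- gee_binomial_logit(y, x, cluster, corstr = working)
  if (!isTRUE(f$converged)) {
    return(list(converged = FALSE, reason = f$reason,
                coefficient = NA_real_, std_error = NA_real_,
                naive_se = NA_real_, intercept = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                alpha_working = NA_real_))
  }
  z <- f$coefficients[["state"]] / f$robust_se[["state"]]
  list(
    converged = TRUE, reason = NA_character_,
    coefficient = f$coefficients[["state"]],
    std_error = f$robust_se[["state"]],
    naive_se = f$naive_se[["state"]],
    intercept = f$coefficients[["(Intercept)"]],
    statistic = z, p_value = 2 * pnorm(-abs(z)),
    alpha_working = f$alpha
  )
}

fit_mixed_engine <- function(y, x, cluster, mixed_type, nAGQ) {
  if (sum(y) == 0) {
    return(list(converged = FALSE, reason = "no events",
                coefficient = NA_real_, std_error = NA_real_,
                naive_se = NA_real_, intercept = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                alpha_working = NA_real_))
  }
  dat <- data.frame(y = y, state = x, pid = cluster)
  fit <- tryCatch(
    if (mixed_type == "logit") {
      suppressMessages(suppressWarnings(lme4::glmer(
        y ~ state + (1 | pid), data = dat, family = binomial,
        nAGQ = nAGQ, control = lme4::glmerControl(calc.derivs = FALSE)
      )))
    } else {
      suppressMessages(suppressWarnings(lme4::lmer(
        y ~ state + (1 | pid), data = dat,
        control = lme4::lmerControl(calc.derivs = FALSE)
      )))
    },
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(converged = FALSE, reason = "mixed model failed",
                coefficient = NA_real_, std_error = NA_real_,
                naive_se = NA_real_, intercept = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                alpha_working = NA_real_))
  }
  co <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  if (abs(co[["state"]]) > 30 || !is.finite(se[["state"]])) {
    return(list(converged = FALSE, reason = "separation",
                coefficient = NA_real_, std_error = NA_real_,
                naive_se = NA_real_, intercept = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                alpha_working = NA_real_))
  }
  z <- co[["state"]] / se[["state"]]
  list(
    converged = TRUE, reason = NA_character_,
    coefficient = co[["state"]], std_error = se[["state"]],
    naive_se = se[["state"]], intercept = co[["(Intercept)"]],
    statistic = z, p_value = 2 * pnorm(-abs(z)),
    alpha_working = NA_real_
  )
}

#' @export
print.injury_fit <- function(x, ...) {
  cat(sprintf("<injury_fit> engine=%s variable=%s (%d obs, %d events)\n",
              x$engine, x$variable, x$n_obs, x$n_events))
  if (isTRUE(x$converged)) {
    cat(sprintf("  state: %.4f (se %.4f), z = %.2f, p = %.3g\n",
                x$coefficient, x$std_error, x$statistic, x$p_value))
  } else {
    cat(sprintf("  not converged: %s\n", x$reason))
  }
  invisible(x)
}

#' Tidy an injury model fit
#'
#' @param x An `injury_fit` from [fit_injury_model()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`estimate` on the
#'   log-odds scale; `std.error` is the robust standard error for the
#'   marginal engine).
#' @exportS3Method generics::tidy
tidy.injury_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble::tibble(
      term = c("(Intercept)", "state"), estimate = NA_real_,
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    ))
  }
  tibble::tibble(
    term = c("(Intercept)", "state"),
    estimate = c(x$intercept, x$coefficient),
    std.error = c(NA_real_, x$std_error),
    statistic = c(NA_real_, x$statistic),
    p.value = c(NA_real_, x$p_value)
  )
}

#' Fit-level summary of an injury model
#'
#' @param x An `injury_fit` from [fit_injury_model()].
#' @param ... Unused.
#' @return A one-row tibble with engine, convergence, working-correlation
#'   and sample-size information.
#' @exportS3Method generics::glance
glance.injury_fit <- function(x, ...) {
  tibble::tibble(
    engine = x$engine, variable = x$variable, converged = isTRUE(x$converged),
    reason = x$reason, n_obs = x$n_obs, n_events = x$n_events,
    n_participants = x$n_participants, alpha_working = x$alpha_working
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
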