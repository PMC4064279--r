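#' Specify a correlated m:1 matched case-control design
#'
#' Parameters of the sample-size problem for an m:1 matched case-control
#' study with correlated dichotomous exposure -- the design used to plan a
#' prospective nested case-crossover study, where every matched set is one
#' injured artist (exposure at the injury performance) plus `m` referent
#' observations of the same artist, so the within-set exposure correlation
#' `phi` is the day-to-day intraclass correlation of the dichotomised
#' state.
#'
#' Internally the method is the classic correlated matched case-control
#' calculation (the PS/Dupont lineage, the standard tool taking exactly
#' this parameter set). With `p1 = psi p0 / (1 + p0 (psi - 1))` the case
#' exposure probability, the `m` control observations are conditionally
#' independent given the case's exposure, exposed with probability
#' `p0 + phi sqrt(p1 q1 p0 q0) / p1` (case exposed) or
#' `p0 - phi sqrt(p1 q1 p0 q0) / q1` (case unexposed). Parameter
#' combinations for which these conditional probabilities leave `[0, 1]`
#' are rejected as invalid designs.
#'
#' @param p0 Exposure probability among controls, in (0, 1).
#' @param psi Exposure odds ratio (the minimal important difference on the
#'   odds scale), > 0.
#' @param m Controls per case, >= 1.
#' @param phi Exposure correlation between matched observations, in [0, 1).
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @param continuity_correction Apply a 0.5 continuity correction to the
#'   normal approximation. Off by default: the uncorrected approximation is
#'   the one that reproduces the reference sample sizes of this method
#'   lineage (see the methods vignette).
#' @return A validated list of class `matched_design`.
#' @examples
#' d <- matched_design(phi = 0.16)
#' required_cases(d)
#' @export
matched_design <- function(p0 = 0.3, psi = 1.25, m = 10, phi = 0,
                           alpha = 0.05, power = 0.8,
                           continuity_correction = FALSE) {
  p0 <- check_fraction(p0, "p0", 0, 1, open_lo = TRUE, open_hi = TRUE)
  psi <- check_positive(psi, "psi")
  m <- check_count(m, "m", min = 1)
  phi <- check_fraction(phi, "phi", 0, 1, open_hi = TRUE)
  alpha <- check_fraction(alpha, "alpha", 0, 1, open_lo = TRUE,
                          open_hi = TRUE)
  power <- check_fraction(power, "power", 0, 1, open_lo = TRUE,
                          open_hi = TRUE)
  p1 <- psi * p0 / (1 + p0 * (psi - 1))
  s <- sqrt(p1 * (1 - p1) * p0 * (1 - p0))
  p0_case_exposed <- p0 + phi * s / p1
  p0_case_unexposed <- p0 - phi * s / (1 - p1)
  if (p0_case_exposed > 1 || p0_case_unexposed < 0) {
    abort(sprintf(paste0(
      "invalid design: (p0 = %.3g, psi = %.3g, phi = %.3g) implies a ",
      "control exposure probability outside [0, 1]"), p0, psi, phi))
  }
  structure(
    list(p0 = p0, psi = psi, m = m, phi = phi, alpha = alpha, power = power,
         continuity_correction = continuity_correction, p1 = p1,
         p0_case_exposed = p0_case_exposed,
         p0_case_unexposed = p0_case_unexposed),
    class = "matched_design"
  )
}

#' @export
print.matched_design <- function(x, ...) {
  cat(sprintf(
    "<matched_design> %d:1 matching, p0 = %.3g, psi = %.3g, phi = %.3g\n",
    x$m, x$p0, x$psi, x$phi))
  cat(sprintf("  alpha = %.3g (two-sided), target power = %.3g%s\n",
              x$alpha, x$power,
              if (x$continuity_correction) ", continuity-corrected" else ""))
  invisible(x)
}

# Distribution of the number exposed per matched set (t = 0..m+1) together
# with the conditional-logistic probability that the exposed one is the
# case, pi(t) = psi t / (psi t + m + 1 - t), and the moments of the
# per-set conditional score u = y - t/(m+1) used by the normal
# approximation.
matched_components <- function(design) {
  m <- design$m
  M <- m + 1
  j <- 0:m
  pt <- numeric(M + 1)
  add1 <- design$p1 * dbinom(j, m, design$p0_case_exposed)
  add0 <- (1 - design$p1) * dbinom(j, m, design$p0_case_unexposed)
  pt[(j + 1) + 1] <- pt[(j + 1) + 1] + add1  # case exposed: t = j + 1
  pt[j + 1] <- pt[j + 1] + add0              # case unexposed: t = j
  t <- 0:M
  pi_t <- ifelse(t == 0, 0, design$psi * t / (design$psi * t + M - t))
  mu0 <- t / M
  e_score <- sum(pt * (pi_t - mu0))
  e_score2 <- sum(pt * (pi_t * (1 - mu0)^2 + (1 - pi_t) * mu0^2))
  list(
    t = t, pt = pt, pi_t = pi_t, mu0 = mu0,
    e_score = e_score,
    var_alt = e_score2 - e_score^2,
    var_null = sum(pt * mu0 * (1 - mu0))
  )
}

#' Achieved power of a matched design for a given number of cases
#'
#' Normal approximation to the power of the conditional score test for the
#' matched case-control design: sets with `t` of the `m + 1` members
#' exposed contribute the statistic `y - t/(m+1)` (`y` = case exposed),
#' whose null conditional mean and variance follow from within-set
#' exchangeability; the alternative tilts the case's exposure odds by
#' `psi`, giving `P(y = 1 | t) = psi t / (psi t + m + 1 - t)`; the
#' distribution of `t` follows from the correlated exposure model of
#' [matched_design()]. Power is the probability that the standardised sum
#' over `n_cases` sets exceeds the two-sided critical value.
#'
#' @param design A [matched_design()].
#' @param n_cases Number of cases (matched sets), >= 1; vectorised.
#' @return Achieved power, a numeric vector along `n_cases`, monotone
#'   non-decreasing in `n_cases`.
#' @examples
#' d <- matched_design(phi = 0.16)
#' power_given_cases(d, c(400, 828, 1200))
#' @export
power_given_cases <- function(design, n_cases) {
  stopifnot(inherits(design, "matched_design"))
  if (any(!is.finite(n_cases) | n_cases < 1)) {
    abort("`n_cases` must contain numbers >= 1")
  }
  comp <- matched_components(design)
  z <- qnorm(1 - design$alpha / 2)
  cc <- if (design$continuity_correction) 0.5 else 0
  vapply(n_cases, function(n) {
    sd_alt <- sqrt(n * comp$var_alt)
    crit <- z * sqrt(n * comp$var_null)
    pnorm((n * comp$e_score - crit - cc) / sd_alt) +
      pnorm((-n * comp$e_score - crit - cc) / sd_alt)
  }, numeric(1))
}

#' Required number of cases for a matched case-control design
#'
#' Smallest integer number of cases (injured participants / matched sets)
#' whose achieved power under [power_given_cases()] reaches the design's
#' target. The achieved power at that integer is reported alongside.
#'
#' @param design A [matched_design()].
#' @param max_cases Upper search bound; exceeding it raises an explicit
#'   error rather than silently truncating.
#' @return A one-row tibble with the design parameters, `required_cases`
#'   and `achieved_power`.
#' @examples
#' required_cases(matched_design(phi = 0.58))
#' @export
required_cases <- function(design, max_cases = 1e7) {
  stopifnot(inherits(design, "matched_design"))
  f <- function(n) power_given_cases(design, n) - design$power
  hi <- 16
  while (f(hi) < 0 && hi < max_cases) hi <- hi * 2
  if (f(hi) < 0) {
    abort(sprintf(
      "target power %.3g unreachable within %g cases (psi too close to 1?)",
      design$power, max_cases))
  }
  n <- if (f(1) >= 0) 1 else uniroot(f, c(1, hi), tol = 1e-9)$root
  n <- ceiling(n - 1e-9)
  while (power_given_cases(design, n) < design$power) n <- n + 1
  tibble::tibble(
    p0 = design$p0, psi = design$psi, m = design$m, phi = design$phi,
    alpha = design$alpha, target_power = design$power,
    required_cases = as.integer(n),
    achieved_power = power_given_cases(design, n)
  )
}

#' Required cases across a list of exposure correlations
#'
#' Evaluates [required_cases()] for several within-person exposure
#' correlations at once -- typically the per-variable daily-state ICCs --
#' producing the familiar variable / ICC / sample-size planning table.
#'
#' @param phi Numeric vector of exposure correlations, or a data frame
#'   with columns `variable` and `icc` (e.g. [daily_state_iccs()]).
#' @param ... Remaining design parameters passed to [matched_design()].
#' @return A tibble of class `matched_size_table`: one row per `phi` with
#'   `variable` (when supplied), `phi`, `required_cases`,
#'   `achieved_power`.
#' @examples
#' required_cases_table(daily_state_iccs())
#' @export
required_cases_table <- function(phi = daily_state_iccs(), ...) {
  if (is.data.frame(phi)) {
    stopifnot(all(c("variable", "icc") %in% names(phi)))
    labels <- phi$variable
    phis <- phi$icc
  } else {
    labels <- NULL
    phis <- phi
  }
  out <- purrr::map_dfr(phis, function(ph) {
    required_cases(matched_design(phi = ph, ...))
  })
  if (!is.null(labels)) {
    out <- dplyr::mutate(out, variable = labels, .before = 1)
  }
  class(out) <- c("matched_size_table", class(tibble::tibble()))
  out
}

#' Monte-Carlo check of the matched-design power approximation
#'
#' Simulates the matched-set model directly and applies the conditional
#' score test per replicate study: each set draws its total number of
#' exposed members `t` from the correlated set-total distribution, the
#' case occasion is the exposed one with probability
#' `psi t / (psi t + m + 1 - t)`, and the study-level statistic
#' `sum(y - t/(m+1)) / sqrt(sum(t (m+1-t)) / (m+1)^2)` is compared to the
#' two-sided normal critical value. At `phi = 0` this is exactly
#' equivalent to drawing every member's exposure independently (case with
#' probability `p1`, controls `p0`). The simulation shares the analytic
#' formula's probability model but not its normal approximation, so it
#' serves as an independent check of the latter.
#'
#' @param design A [matched_design()].
#' @param n_cases Matched sets per replicate study.
#' @param n_sim Number of replicate studies.
#' @param seed Integer seed.
#' @return A one-row tibble with `power` (rejection fraction), `n_sim` and
#'   the Monte-Carlo standard error.
#' @examples
#' d <- matched_design(phi = 0.16)
#' simulate_matched_power(d, n_cases = 828, n_sim = 2000, seed = 1)
#' @export
simulate_matched_power <- function(design, n_cases, n_sim = 10000,
                                   seed = 1L) {
  stopifnot(inherits(design, "matched_design"))
  n_cases <- check_count(n_cases, "n_cases", min = 1)
  n_sim <- check_count(n_sim, "n_sim", min = 1)
  comp <- matched_components(design)
  M <- design$m + 1
  zcrit <- qnorm(1 - design$alpha / 2)
  total <- n_sim * n_cases
  withr::with_seed(derive_seed(seed, "matched"), {
    t <- sample(comp$t, total, replace = TRUE, prob = comp$pt)
    y <- rbinom(total, 1L, comp$pi_t[t + 1])
    rep_id <- rep(seq_len(n_sim), each = n_cases)
    s_sum <- rowsum(y - t / M, rep_id)
    v_sum <- rowsum(t * (M - t), rep_id) / M^2
    reject <- v_sum > 0 & abs(s_sum) / sqrt(pmax(v_sum, 1e-300)) > zcrit
  })
  p <- mean(reject)
  tibble::tibble(
    power = p, n_sim = n_sim,
    mc_stderr = sqrt(p * (1 - p) / n_sim)
  )
}

#' @exportS3Method generics::tidy
tidy.matched_design <- function(x, ...) {
  tibble::tibble(
    parameter = c("p0", "psi", "m", "phi", "alpha", "target_power",
                  "p1", "p0_case_exposed", "p0_case_unexposed"),
    value = c(x$p0, x$psi, x$m, x$phi, x$alpha, x$power, x$p1,
              x$p0_case_exposed, x$p0_case_unexposed)
  )
}

#' @exportS3Method generics::glance
glance.matched_design <- function(x, ...) {
  tibble::tibble(
    p0 = x$p0, psi = x$psi, m = x$m, phi = x$phi, alpha = x$alpha,
    target_power = x$power, p1 = x$p1,
    continuity_correction = x$continuity_correction
  )
}
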