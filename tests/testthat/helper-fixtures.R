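# Shared fixtures: everything is generated in code at test time.

# A small complete panel with known group structure, built by hand (no RNG):
# participant means 2, 4, 6 with within-participant wiggle c(-1, 0, 0, 1).
toy_panel <- function() {
  wiggle <- c(-1L, 0L, 0L, 1L)
  tibble::tibble(
    participant_id = rep(c("A", "B", "C"), each = 4),
    day_index = rep(0:3, times = 3),
    variable = "mood",
    value = rep(c(2L, 4L, 6L), each = 4) + rep(wiggle, times = 3)
  )
}

# Panel whose participants are internally constant but mutually different.
constant_within_panel <- function() {
  tibble::tibble(
    participant_id = rep(c("A", "B", "C", "D"), each = 5),
    day_index = rep(0:4, times = 4),
    variable = "mood",
    value = rep(c(1L, 3L, 5L, 7L), each = 5)
  )
}

# Moderate event-rate generator config for fast model-fitting tests.
fast_fit_config <- function(seed = 1, ...) {
  generator_config(
    n_participants = 50, n_days = 40, variables = "state", icc = 0.35,
    baseline_rate_per_1000 = 25, rate_ratio_per_2cat = 1.6,
    missing_prob = 0, seed = seed, ...
  )
}

# Independent brute-force one-way ANOVA sums of squares (the textbook
# route through stats::aov), used as the oracle for the ICC estimator.
aov_icc_oracle <- function(values, groups) {
  fit <- stats::aov(values ~ factor(groups))
  ms <- summary(fit)[[1]][["Mean Sq"]]
  k <- length(values) / length(unique(groups))  # balanced designs only
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

# Member-level matched-set simulation: case exposure Bernoulli(p1),
# control exposures independent Bernoulli(p0). Valid as an oracle for the
# analytic power exactly at phi = 0, where the conditional-logistic
# P(case | t) coincides with this sampling model.
member_level_matched_power <- function(design, n_cases, n_sim, seed) {
  stopifnot(design$phi == 0)
  M <- design$m + 1
  withr::with_seed(seed, {
    total <- n_sim * n_cases
    y <- stats::rbinom(total, 1L, design$p1)
    k <- stats::rbinom(total, design$m, design$p0)
    t <- y + k
    rep_id <- rep(seq_len(n_sim), each = n_cases)
    s_sum <- rowsum(y - t / M, rep_id)
    v_sum <- rowsum(t * (M - t), rep_id) / M^2
    mean(v_sum > 0 &
           abs(s_sum) / sqrt(pmax(v_sum, 1e-300)) > qnorm(0.975))
  })
}
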