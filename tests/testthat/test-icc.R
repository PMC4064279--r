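test_that("constant-within, varying-between panels give ICC 1 with a flag", {
  est <- estimate_icc(constant_within_panel())
  expect_equal(est$icc, 1)
  expect_true(est$degenerate)
  # all values identical everywhere: no variance to apportion at all
  flat <- constant_within_panel()
  flat$value <- 4L
  est_flat <- estimate_icc(flat)
  expect_true(is.na(est_flat$icc))
  expect_true(est_flat$degenerate)
})

test_that("i.i.d. values ignoring participants give ICC near zero", {
  set.seed(40)
  panel <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:80), each = 50),
    day_index = rep(0:49, times = 80),
    variable = "s",
    value = sample(1:7, 4000, replace = TRUE)
  )
  est <- estimate_icc(panel)
  expect_lt(abs(est$icc), 0.03)
  expect_false(est$degenerate)
})

test_that("balanced panels equal the classical ICC(1) aov oracle", {
  set.seed(41)
  for (rep in 1:3) {
    n_p <- sample(5:12, 1)
    n_d <- sample(4:9, 1)
    panel <- tibble::tibble(
      participant_id = rep(sprintf("P%02d", seq_len(n_p)), each = n_d),
      day_index = rep(seq_len(n_d) - 1L, times = n_p),
      variable = "s",
      value = sample(1:7, n_p * n_d, replace = TRUE) +
        rep(sample(0:3, n_p, replace = TRUE), each = n_d)
    )
    est <- estimate_icc(panel)
    oracle <- aov_icc_oracle(as.numeric(panel$value), panel$participant_id)
    expect_equal(est$icc, oracle, tolerance = 1e-10)
    expect_equal(est$k0, n_d)  # balanced effective group size
  }
})

test_that("unbalanced panels use the effective group size k0", {
  set.seed(42)
  ki <- c(3, 5, 8, 12, 20)
  panel <- tibble::tibble(
    participant_id = rep(sprintf("P%d", seq_along(ki)), times = ki),
    day_index = unlist(lapply(ki, seq_len)) - 1L,
    variable = "s",
    value = rpois(sum(ki), 4) + rep(c(0, 1, 2, 0, 3), times = ki)
  )
  est <- estimate_icc(panel)
  N <- sum(ki)
  expect_equal(est$k0, (N - sum(ki^2) / N) / (length(ki) - 1))
  expect_equal(est$mean_days_per_participant, mean(ki))
  # oracle recomputation from scratch via aov mean squares + k0
  fit <- stats::aov(as.numeric(value) ~ factor(participant_id), data = panel)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  expect_equal(est$icc, (ms[1] - ms[2]) / (ms[1] + (est$k0 - 1) * ms[2]),
               tolerance = 1e-10)
})

test_that("the estimator is invariant to affine rescaling of scores", {
  panel <- toy_panel()
  a <- estimate_icc(panel)$icc
  panel$value <- 3 + 2 * panel$value
  b <- estimate_icc(panel)$icc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("missing values make the design unbalanced but still estimable", {
  cfg <- generator_config(n_participants = 60, n_days = 40,
                          variables = "s", icc = 0.4, missing_prob = 0.1,
                          seed = 12)
  panel <- simulate_state_panel(cfg)
  est <- estimate_icc(panel)
  expect_lt(est$mean_days_per_participant, 40)
  expect_lt(abs(est$icc - 0.4), 0.12)
})

test_that("insufficient panels raise a typed error", {
  tiny <- tibble::tibble(
    participant_id = c("A", "A", "B"), day_index = c(0L, 1L, 0L),
    variable = "s", value = c(1L, 2L, 3L)
  )
  expect_error(estimate_icc(tiny), class = "injurydesign_insufficient_data")
  expect_error(estimate_icc(toy_panel(), "absent"), "absent")
})

test_that("negative estimates are reported, flagged, and truncatable", {
  # fewer distinct group means than chance predicts => negative ICC
  panel <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = 4),
    day_index = rep(0:3, 2),
    variable = "s",
    value = c(1L, 7L, 1L, 7L, 7L, 1L, 7L, 1L)
  )
  est <- estimate_icc(panel)
  expect_lt(est$icc, 0)
  expect_true(est$negative)
  expect_equal(estimate_icc(panel, truncate = TRUE)$icc, 0)
})

test_that("ordinal scores attenuate the latent ICC by discretisation", {
  cfg <- generator_config(n_participants = 210, n_days = 100,
                          variables = "s", icc = 0.58, missing_prob = 0,
                          seed = 9)
  panel <- simulate_state_panel(cfg)
  latent <- estimate_icc(panel, use_latent = TRUE)$icc
  ordinal <- estimate_icc(panel)$icc
  expect_lt(abs(latent - 0.58), 0.05)   # estimator round-trip
  # equiprobable 7-category discretisation attenuates correlations by
  # the squared score-latent correlation, lambda^2 ~ 0.918; the ordinal
  # estimate sits below the latent one but above the attenuation floor
  expect_lt(ordinal, latent)
  expect_gt(ordinal, 0.85 * 0.58)
})
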