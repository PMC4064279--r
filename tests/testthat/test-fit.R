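test_that("independence working correlation reduces to ordinary logistic", {
  cfg <- fast_fit_config(seed = 61)
  panel <- simulate_state_panel(cfg)
  inj <- simulate_injuries(panel, "state", cfg)
  fit <- fit_injury_model(panel, inj, "state", working = "independence")
  td <- tidy(fit)
  # oracle: plain glm on the same analysis table
  key <- paste(panel$participant_id, panel$day_index)
  y <- as.integer(key %in% paste(inj$participant_id, inj$day_index))
  g <- stats::glm(y ~ value, family = binomial,
                  data = transform(panel, y = y))
  expect_equal(td$estimate[td$term == "state"],
               unname(coef(g)["value"]), tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "(Intercept)"],
               unname(coef(g)["(Intercept)"]), tolerance = 1e-8)
  expect_equal(fit$naive_se, unname(summary(g)$coefficients["value", 2]),
               tolerance = 1e-4)
})

test_that("robust errors match the independent clustered-sandwich oracle", {
  skip_if_not_installed("sandwich")
  cfg <- fast_fit_config(seed = 62)
  panel <- simulate_state_panel(cfg)
  inj <- simulate_injuries(panel, "state", cfg)
  fit <- fit_injury_model(panel, inj, "state", working = "independence")
  key <- paste(panel$participant_id, panel$day_index)
  dat <- transform(
    panel,
    y = as.integer(key %in% paste(inj$participant_id, inj$day_index))
  )
  g <- stats::glm(y ~ value, family = binomial, data = dat)
  vc <- sandwich::vcovCL(g, cluster = dat$participant_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(fit$std_error, sqrt(vc["value", "value"]), tolerance = 1e-4)
})

test_that("exchangeable fits are deterministic and close to glm when icc = 0", {
  cfg <- generator_config(n_participants = 80, n_days = 40,
                          variables = "state", icc = 0,
                          baseline_rate_per_1000 = 25,
                          rate_ratio_per_2cat = 1.6, missing_prob = 0,
                          seed = 63)
  panel <- simulate_state_panel(cfg)
  inj <- simulate_injuries(panel, "state", cfg)
  f1 <- fit_injury_model(panel, inj, "state", working = "exchangeable")
  f2 <- fit_injury_model(panel, inj, "state", working = "exchangeable")
  expect_identical(tidy(f1), tidy(f2))  # fixed input, fixed output
  expect_lt(abs(f1$alpha_working), 0.01)
  key <- paste(panel$participant_id, panel$day_index)
  y <- as.integer(key %in% paste(inj$participant_id, inj$day_index))
  g <- stats::glm(y ~ value, family = binomial,
                  data = transform(panel, y = y))
  # with an estimated (near-zero) working alpha the fit is close to,
  # but not identical with, ordinary logistic regression
  expect_lt(abs(f1$coefficient - unname(coef(g)["value"])), 0.01)
})

test_that("pathological replicates are flagged rather than fitted", {
  cfg <- fast_fit_config(seed = 64)
  panel <- simulate_state_panel(cfg)
  none <- tibble::tibble(participant_id = character(),
                         day_index = integer())
  f <- fit_injury_model(panel, none, "state")
  expect_false(f$converged)
  expect_equal(f$reason, "no events")
  fm <- fit_injury_model(panel, none, "state", engine = "mixed")
  expect_false(fm$converged)
  expect_equal(fm$reason, "no events")
  expect_error(fit_injury_model(panel, none, "absent"), "absent")
  expect_true(all(is.na(tidy(f)$estimate)))
})

test_that("mixed engines (logit and linear) return usable Wald tests", {
  cfg <- fast_fit_config(seed = 65)
  panel <- simulate_state_panel(cfg)
  inj <- simulate_injuries(panel, "state", cfg)
  fx <- fit_injury_model(panel, inj, "state", engine = "mixed")
  expect_true(fx$converged)
  expect_true(is.finite(fx$statistic))
  expect_gt(fx$coefficient, 0)  # generator effect is positive
  fl <- fit_injury_model(panel, inj, "state", engine = "mixed",
                         mixed_type = "linear")
  expect_true(fl$converged)
  expect_true(is.finite(fl$p_value))
  g <- glance(fx)
  expect_equal(g$engine, "mixed")
  expect_equal(g$n_events, nrow(dplyr::distinct(
    inj, participant_id, day_index)))
})

test_that("marginal and mixed engines agree on strong effects", {
  cfg <- generator_config(n_participants = 60, n_days = 50,
                          variables = "state", icc = 0.35,
                          baseline_rate_per_1000 = 40,
                          rate_ratio_per_2cat = 2.5, missing_prob = 0,
                          seed = 66)
  panel <- simulate_state_panel(cfg)
  inj <- simulate_injuries(panel, "state", cfg)
  fm <- fit_injury_model(panel, inj, "state")
  fx <- fit_injury_model(panel, inj, "state", engine = "mixed")
  # same target (log rate ratio per category ~ log(2.5)/2 = 0.46)
  expect_lt(abs(fm$coefficient - log(2.5) / 2), 0.2)
  expect_lt(abs(fm$coefficient - fx$coefficient), 0.1)
})
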