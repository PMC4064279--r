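test_that("generator config validates its fields by name", {
  expect_error(generator_config(n_participants = 0), "n_participants")
  expect_error(generator_config(n_categories = 1), "n_categories")
  expect_error(generator_config(icc = 1), "icc")
  expect_error(generator_config(icc = -0.1), "icc")
  expect_error(generator_config(variables = "x", icc = c(a = 0.2)), "icc")
  expect_error(generator_config(missing_prob = 1.5), "missing_prob")
  expect_error(generator_config(rate_ratio_per_2cat = 0), "rate_ratio")
  cfg <- generator_config(variables = c("a", "b"), icc = 0.3)
  expect_equal(unname(cfg$icc), c(0.3, 0.3))
})

test_that("identical config and seed give bit-identical panels and logs", {
  cfg <- generator_config(n_participants = 12, n_days = 20,
                          baseline_rate_per_1000 = 40, seed = 99)
  p1 <- simulate_state_panel(cfg)
  p2 <- simulate_state_panel(cfg)
  expect_identical(p1, p2)
  i1 <- simulate_injuries(p1, "confidence", cfg)
  i2 <- simulate_injuries(p2, "confidence", cfg)
  expect_identical(i1, i2)
  # a different seed changes the draw
  cfg2 <- generator_config(n_participants = 12, n_days = 20,
                           baseline_rate_per_1000 = 40, seed = 100)
  expect_false(identical(simulate_state_panel(cfg2), p1))
})

test_that("panels are complete, in range, and rank-preservingly discretised", {
  cfg <- generator_config(n_participants = 15, n_days = 25, seed = 4,
                          missing_prob = 0.05)
  panel <- simulate_state_panel(cfg)
  expect_equal(nrow(panel), 15 * 25 * 9)
  expect_equal(
    anyDuplicated(panel[c("participant_id", "day_index", "variable")]), 0L)
  ok <- is.na(panel$value) | (panel$value >= 1 & panel$value <= 7)
  expect_true(all(ok))
  expect_true(anyNA(panel$value))  # missingness was injected
  # same latent ordering => same or increasing category, within a variable
  one <- panel[panel$variable == "anxiety" & !is.na(panel$value), ]
  ord <- order(one$latent)
  expect_true(all(diff(one$value[ord]) >= 0))
})

test_that("ICC limiting cases behave as designed", {
  # icc = 0: days are exchangeable across participants
  cfg0 <- generator_config(n_participants = 150, n_days = 60,
                           variables = "s", icc = 0, missing_prob = 0,
                           seed = 21)
  est0 <- estimate_icc(simulate_state_panel(cfg0), use_latent = TRUE)
  expect_lt(abs(est0$icc), 0.03)
  # icc = 0.99: participants nearly constant, spread between them
  cfg99 <- generator_config(n_participants = 40, n_days = 50,
                            variables = "s", icc = 0.99, missing_prob = 0,
                            seed = 22)
  p99 <- simulate_state_panel(cfg99)
  within_var <- tapply(p99$latent, p99$participant_id, var)
  expect_lt(mean(within_var), 0.02)
  expect_gt(var(tapply(p99$latent, p99$participant_id, mean)), 0.5)
})

test_that("generated latent series recover a mid-range target ICC", {
  cfg <- generator_config(n_participants = 210, n_days = 100,
                          variables = "s", icc = 0.35, missing_prob = 0,
                          seed = 7)
  est <- estimate_icc(simulate_state_panel(cfg), use_latent = TRUE)
  expect_lt(abs(est$icc - 0.35), 0.05)
})

test_that("latent day-to-day correlation is compound-symmetric", {
  cfg <- generator_config(n_participants = 1500, n_days = 4,
                          variables = "s", icc = 0.4, missing_prob = 0,
                          seed = 31)
  panel <- simulate_state_panel(cfg)
  wide <- matrix(panel$latent, nrow = 1500, ncol = 4, byrow = TRUE)
  cm <- cor(wide)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off - 0.4) < 0.06))
})

test_that("null-effect injury counts match the binomial expectation", {
  cfg <- generator_config(n_participants = 1000, n_days = 100,
                          variables = "s", icc = 0.35,
                          baseline_rate_per_1000 = 1.6,
                          rate_ratio_per_2cat = 1, missing_prob = 0,
                          seed = 11)
  panel <- simulate_state_panel(cfg)
  inj <- simulate_injuries(panel, "s", cfg)
  expected <- 100000 * 1.6 / 1000
  sd3 <- 3 * sqrt(expected * (1 - 1.6 / 1000))
  expect_lt(abs(nrow(inj) - expected), sd3)
})

test_that("degenerate injury settings behave", {
  cfg <- generator_config(n_participants = 10, n_days = 10,
                          variables = "s", icc = 0.2,
                          baseline_rate_per_1000 = 0, seed = 3)
  panel <- simulate_state_panel(cfg)
  expect_equal(nrow(simulate_injuries(panel, "s", cfg)), 0L)
  expect_error(simulate_injuries(panel, "nope", cfg), "nope")
  # probabilities beyond 1 are clipped with a warning that counts cells
  cfg_hot <- generator_config(n_participants = 10, n_days = 10,
                              variables = "s", icc = 0.2,
                              baseline_rate_per_1000 = 900,
                              rate_ratio_per_2cat = 4, missing_prob = 0,
                              seed = 3)
  p_hot <- simulate_state_panel(cfg_hot)
  expect_warning(simulate_injuries(p_hot, "s", cfg_hot), "clipped")
})

test_that("injury frequency is monotone in the rate ratio above the null", {
  counts <- vapply(c(1, 1.5, 2.5), function(rr) {
    cfg <- generator_config(n_participants = 200, n_days = 60,
                            variables = "s", icc = 0.35,
                            baseline_rate_per_1000 = 20,
                            rate_ratio_per_2cat = rr, missing_prob = 0,
                            seed = 17)
    panel <- simulate_state_panel(cfg)
    nrow(simulate_injuries(panel, "s", cfg))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("time-loss injuries are a subset of medical-attention injuries", {
  cfg <- generator_config(n_participants = 100, n_days = 50,
                          variables = "s", icc = 0.3,
                          baseline_rate_per_1000 = 60, seed = 5)
  panel <- simulate_state_panel(cfg)
  inj <- simulate_injuries(panel, "s", cfg)
  expect_gt(nrow(inj), 0)
  expect_true(all(inj$classification %in% c("medical_attention", "tl1")))
  expect_true(all(inj$missed_performances[inj$classification == "tl1"] >= 1))
  expect_true(all(inj$missed_performances[
    inj$classification == "medical_attention"] == 0))
  counts <- classify_injuries(inj)
  expect_lte(counts$n[counts$classification == "tl1"],
             counts$n[counts$classification == "medical_attention"])
  # injuries fall on exposure days
  expect_true(all(inj$day_index >= 0 & inj$day_index < 50))
})
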