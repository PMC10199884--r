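test_that("generation is deterministic given config and seed", {
  cfg <- small_cfg(n_population = 1500L)
  b1 <- simulate_cohort(cfg, seed = 11)
  b2 <- simulate_cohort(cfg, seed = 11)
  expect_identical(b1$insurees, b2$insurees)
  expect_identical(b1$assessments, b2$assessments)
  expect_identical(b1$claims, b2$claims)
  b3 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(b1$claims, b3$claims))
})

test_that("population covariates converge to configured marginals", {
  cfg <- generator_config(n_population = 20000L, uptake_rate = 0.009,
                          seed = 5L)
  set.seed(cfg$seed)
  pop <- generate_population(cfg)
  # user share within 3 binomial SE of the uptake rate
  se <- sqrt(0.009 * 0.991 / 20000)
  expect_lt(abs(mean(pop$arm == "user") - 0.009), 3 * se)
  expect_lt(abs(mean(pop$sex == "female") - 0.532),
            3 * sqrt(0.532 * 0.468 / 20000))
  # truncation at 18 shifts the normal mean up by sd*phi(a)/(1-Phi(a))
  a <- (17.5 - 48.4) / 14
  mu_trunc <- 48.4 + 14 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(pop$age) - mu_trunc), 3 * 14 / sqrt(20000))
  expect_true(all(pop$age >= 18))
  expect_lt(abs(mean(pop$ses == "missing") - 0.011),
            3 * sqrt(0.011 * 0.989 / 20000))
  expect_lt(abs(mean(pop$history_premalignancy) - 0.047),
            3 * sqrt(0.047 * 0.953 / 20000))
})

test_that("an empty population yields empty downstream tables", {
  cfg <- small_cfg(n_population = 0L)
  b <- simulate_cohort(cfg, seed = 1)
  expect_equal(nrow(b$insurees), 0L)
  expect_equal(nrow(b$assessments), 0L)
  expect_equal(nrow(b$claims), 0L)
})

test_that("assessment records obey structural invariants", {
  cfg <- small_cfg(n_population = 3000L, uptake_rate = 0.3)
  set.seed(3)
  pop <- generate_population(cfg)
  a <- generate_assessments(pop, cfg)
  # failed photos never carry a teledermatologist rating
  expect_true(all(a[cnn_result == "failed", telederm_result == "none"]))
  expect_true(all(a[cnn_result != "failed", telederm_result != "none"]))
  # every included user has at least one successful assessment
  ok <- a[, any(cnn_result != "failed"), by = person_id]
  expect_true(all(ok$V1))
  expect_setequal(unique(a$person_id), pop[arm == "user", person_id])
  # indices are 1..n within user, and per-outcome counts sum to the total
  expect_true(all(a[, identical(assessment_index, seq_len(.N)),
                    by = person_id]$V1))
  expect_equal(sum(table(a$cnn_result)), nrow(a))
})

test_that("CNN outcome frequencies match config for homogeneous users", {
  cfg <- small_cfg(n_population = 4000L, uptake_rate = 0.5,
                   risk_icc = Inf)
  set.seed(7)
  pop <- generate_population(cfg)
  a <- generate_assessments(pop, cfg)
  n <- nrow(a)
  for (pr in list(c("high", 0.235), c("failed", 0.048))) {
    p0 <- as.numeric(pr[2])
    expect_lt(abs(mean(a$cnn_result == pr[1]) - p0),
              3 * sqrt(p0 * (1 - p0) / n))
  }
  # teledermatologist override rates, conditional on CNN outcome
  up <- a[cnn_result == "low", mean(telederm_result == "high")]
  dn <- a[cnn_result == "high", mean(telederm_result == "low")]
  expect_lt(abs(up - 0.028), 3 * sqrt(0.028 * 0.972 / sum(a$cnn_result == "low")))
  expect_lt(abs(dn - 0.338), 3 * sqrt(0.338 * 0.662 / sum(a$cnn_result == "high")))
})

test_that("with default heterogeneity ~37% of users ever get a high-risk flag", {
  cfg <- small_cfg(n_population = 8000L, uptake_rate = 0.5)
  set.seed(21)
  pop <- generate_population(cfg)
  a <- generate_assessments(pop, cfg)
  risky <- a[, any(combined_risk(cnn_result, telederm_result) == "high",
                   na.rm = TRUE), by = person_id]
  share <- mean(risky$V1)
  n_u <- nrow(risky)
  expect_lt(abs(share - 0.371), 4 * sqrt(0.371 * 0.629 / n_u))
})

test_that("zero override probabilities make combined risk equal CNN risk", {
  cfg <- small_cfg(n_population = 1000L, uptake_rate = 0.5,
                   upgrade_prob = 0, downgrade_prob = 0)
  set.seed(2)
  pop <- generate_population(cfg)
  a <- generate_assessments(pop, cfg)
  ok <- a[cnn_result != "failed"]
  expect_identical(combined_risk(ok$cnn_result, ok$telederm_result),
                   ok$cnn_result)
})

test_that("an always-failing CNN raises after bounded retries", {
  cfg <- small_cfg(n_population = 30L, uptake_rate = 0.5,
                   cnn_probs = c(low = 0, low_symptoms = 0, high = 0,
                                 failed = 1))
  set.seed(1)
  pop <- generate_population(cfg)
  expect_error(generate_assessments(pop, cfg),
               class = "dermclaims_config_error")
})

test_that("zero claim probabilities give an empty claims table", {
  zero <- setNames(rep(0, 5), claim_categories())
  cfg <- small_cfg(
    n_population = 500L,
    claim_probs = list(control = zero, user_high = zero, user_low = zero),
    gp_rates = list(user = c(gp_biopsy_excision = 0, gp_teledermatology = 0),
                    control = c(gp_biopsy_excision = 0,
                                gp_teledermatology = 0)))
  b <- simulate_cohort(cfg, seed = 4)
  expect_equal(nrow(b$claims), 0L)
})

test_that("claims carry valid costs, settings and converge to config rates", {
  cfg <- generator_config(n_population = 30000L, uptake_rate = 0.3,
                          seed = 9L)
  b <- simulate_cohort(cfg)
  cl <- b$claims
  expect_true(all(cl$cost >= 0))
  expect_identical(cl$cost, round(cl$cost, 2))
  expect_true(all(cl[intervention %in% c("gp_biopsy_excision",
                                         "gp_teledermatology"),
                     setting == "primary"]))
  expect_true(all(cl[intervention %in% c("mohs", "hospital_excision_benign",
                                         "hospital_excision_premalignant"),
                     setting == "secondary"]))
  # person-level nevus proportions close to the configured ones
  persons <- b$insurees[, .(person_id, arm = fifelse(arm == "user", "user",
                                                     "control"))]
  tb <- build_contingency(persons, cl, "nevus")
  p_user <- tb$a / (tb$a + tb$b)
  p_ctrl <- tb$c / (tb$c + tb$d)
  expect_lt(abs(p_user - 0.0448), 4 * sqrt(0.0448 * 0.9552 / (tb$a + tb$b)))
  expect_lt(abs(p_ctrl - 0.0117), 4 * sqrt(0.0117 * 0.9883 / (tb$c + tb$d)))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(uptake_rate = 1.2),
               class = "dermclaims_config_error")
  expect_error(generator_config(cnn_probs = c(low = 0.5, low_symptoms = 0.2,
                                              high = 0.2, failed = 0.2)),
               class = "dermclaims_config_error")
  bad_cost <- default_cost_means()
  bad_cost$user[["nevus"]] <- -5
  expect_error(generator_config(cost_mean = bad_cost),
               class = "dermclaims_config_error")
})
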