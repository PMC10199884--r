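test_that("contingency tables deduplicate at person level", {
  persons <- fixed_persons(2, 3)
  cl <- claims_table(c("U000001", "U000001", "C000002"),
                     c("nevus", "nevus", "nevus"))
  tb <- build_contingency(persons, cl, "nevus")
  expect_equal(unclass(tb)[c("a", "b", "c", "d")],
               list(a = 1L, b = 1L, c = 1L, d = 2L))
  # no claims at all
  tb0 <- build_contingency(persons, claims_table(character(0), character(0)),
                           "nevus")
  expect_equal(c(tb0$a, tb0$c), c(0L, 0L))
  expect_equal(c(tb0$b, tb0$d), c(2L, 3L))
  # primary-care claims are not diagnosis-group claims
  gp <- claims_table("U000001", "nevus", intervention = "gp_biopsy_excision",
                     setting = "primary")
  tb1 <- build_contingency(persons, gp, "nevus")
  expect_equal(tb1$a, 0L)
  expect_error(build_contingency(persons, cl, "warts"),
               class = "dermclaims_domain_error")
})

test_that("combined outcomes pool categories before deduplication", {
  persons <- fixed_persons(2, 2)
  cl <- claims_table(c("U000001", "U000001"), c("nevus", "benign_tumor"))
  tb <- build_contingency(persons, cl, c("nevus", "benign_tumor"))
  expect_equal(tb$a, 1L)
})

test_that("odds ratios and Woolf intervals reproduce published examples", {
  # premalignant lesions, person counts users 391/18,960 vs controls 896/56,880
  or1 <- odds_ratio(contingency(391, 18960 - 391, 896, 56880 - 896))
  expect_equal(round(or1$odds_ratio, 2), 1.32)
  expect_lt(abs(or1$ci_low - 1.16), 0.02)
  expect_lt(abs(or1$ci_high - 1.49), 0.02)
  # nevi
  or2 <- odds_ratio(contingency(850, 18960 - 850, 667, 56880 - 667))
  expect_equal(round(or2$odds_ratio, 2), 3.96)
  # symmetric table
  expect_equal(odds_ratio(contingency(5, 5, 5, 5))$odds_ratio, 1.0)
})

test_that("odds-ratio exposure swap gives reciprocal estimates", {
  set.seed(42)
  for (i in 1:25) {
    cells <- as.list(rpois(4, 20) + 1)
    names(cells) <- c("a", "b", "c", "d")
    o1 <- odds_ratio(cells)$odds_ratio
    o2 <- odds_ratio(list(a = cells$c, b = cells$d, c = cells$a,
                          d = cells$b))$odds_ratio
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
  }
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  or <- odds_ratio(contingency(0, 10, 5, 5))
  expect_true(or$haldane)
  expect_true(is.finite(or$odds_ratio) && is.finite(or$ci_low))
  expect_false(odds_ratio(contingency(1, 10, 5, 5))$haldane)
})

test_that("Fisher p matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact_p(contingency(5, 5, 5, 5)), 1.0)
  set.seed(7)
  for (i in 1:60) {
    cells <- rpois(4, 5)
    p_impl <- fisher_exact_p(contingency(cells[1], cells[2], cells[3],
                                         cells[4]))
    p_enum <- fisher_enum_p(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_impl, p_enum, tolerance = 1e-10)
  }
  expect_lt(fisher_exact_p(contingency(391, 18569, 896, 55984)), 0.001)
})

test_that("two-proportion z-test matches an independent formula oracle", {
  # identical proportions
  r <- two_proportion_z(10, 100, 20, 200)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  # study-scale example is overwhelmingly significant
  expect_lt(two_proportion_z(1424, 18960, 1913, 56880)$p_value, 0.001)
  # random inputs vs direct formula and vs prop.test's chi-square
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    x1 <- rbinom(1, n1, 0.3); x2 <- rbinom(1, n2, 0.4)
    r <- two_proportion_z(x1, n1, x2, n2)
    pp <- (x1 + x2) / (n1 + n2)
    z_ref <- (x1 / n1 - x2 / n2) /
      sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(r$z, z_ref, tolerance = 1e-12)
    if (x1 > 0 && x2 > 0 && x1 < n1 && x2 < n2) {
      chi <- suppressWarnings(
        prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$statistic)
      expect_equal(r$z^2, unname(chi), tolerance = 1e-9)
    }
  }
  # degenerate pooled proportion
  d <- two_proportion_z(0, 10, 0, 10)
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  expect_error(two_proportion_z(1, 0, 1, 10),
               class = "dermclaims_domain_error")
})

test_that("claims per 1000 persons reproduce the published rates", {
  expect_equal(claims_per_1000(1424, 18960)$rate_rounded, 75.11)
  expect_equal(claims_per_1000(1913, 56880)$rate_rounded, 33.63)
  expect_equal(round(claims_per_1000(1424, 18960)$rate -
                       claims_per_1000(1913, 56880)$rate, 2), 41.47)
  expect_equal(claims_per_1000(0, 1000)$rate, 0)
  expect_error(claims_per_1000(5, 0), class = "dermclaims_domain_error")
})

test_that("BH adjustment equals the quadratic-time reference", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(3)
  for (i in 1:30) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_reference(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "dermclaims_domain_error")
})

test_that("users split by risk feedback per the CNN-or-teledermatologist rule", {
  a <- data.table(
    person_id = c("U1", "U1", "U2", "U2", "U3", "U4", "U4"),
    assessment_index = c(1L, 2L, 1L, 2L, 1L, 1L, 2L),
    cnn_result = c("low", "high", "low", "failed", "failed", "low", "low"),
    symptoms = NA,
    telederm_result = c("low", "low", "low", "none", "none", "high", "low"))
  expect_warning(s <- subgroup_split(c("U1", "U2", "U3", "U4"), a),
                 "excluded")
  expect_setequal(s$high_risk, c("U1", "U4"))  # U4 high via upgrade
  expect_equal(s$low_risk, "U2")               # failed photos ignored
  expect_equal(s$excluded, "U3")
})

test_that("subgroup and history cohorts preserve matched sets", {
  users <- data.table(person_id = c("U1", "U2"), age = c(40L, 50L),
                      sex = "male", ses = "low", region = "R01",
                      history_premalignancy = c(TRUE, FALSE),
                      n_comorbidities = 0L, arm = "user")
  pool <- data.table(person_id = sprintf("C%d", 1:8),
                     age = rep(c(40L, 50L), each = 4), sex = "male",
                     ses = "low", region = "R01",
                     history_premalignancy = rep(c(TRUE, FALSE), each = 4),
                     n_comorbidities = 0L, arm = "control-pool")
  m <- match_cohort(users, pool, ratio = 3, seed = 1)
  sub <- subcohort(m, "U1")
  expect_equal(sum(sub$arm == "user"), 1L)
  expect_equal(sum(sub$arm == "control"), 3L)
  expect_setequal(sub[arm == "control", person_id],
                  m$matches[user_id == "U1", control_id])
  hist <- history_subgroup(rbind(users, pool), m)
  expect_setequal(hist[arm == "user", person_id], "U1")
  # no positive-history users -> empty subcohort
  users2 <- copy(users)[, history_premalignancy := FALSE]
  m2 <- match_cohort(users2, pool, ratio = 3, seed = 1)
  expect_equal(nrow(history_subgroup(rbind(users2, pool), m2)[arm == "user"]),
               0L)
})

test_that("association tables carry a BH family and rounded estimates", {
  set.seed(5)
  persons <- fixed_persons(400, 1200)
  pick <- function(n, arm_ids) sample(arm_ids, n)
  cl <- rbind(
    claims_table(pick(60, persons[arm == "user", person_id]), "nevus"),
    claims_table(pick(40, persons[arm == "control", person_id]), "nevus"),
    claims_table(pick(20, persons[arm == "user", person_id]), "malignant"),
    claims_table(pick(50, persons[arm == "control", person_id]), "malignant"))
  tab <- association_table(persons, cl)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$p_adjusted >= tab$p_fisher))
  expect_identical(tab$odds_ratio, round(tab$odds_ratio, 2))
  # zero-claim categories fall back to the corrected estimate without error
  expect_true(all(is.finite(tab$odds_ratio)))
})
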