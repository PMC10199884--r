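library(data.table)

# small, densely matchable synthetic scenario for module tests
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_population = 5000L, uptake_rate = 0.1, n_regions = 4L),
    list(...))
  do.call(generator_config, args)
}

# persons table with fixed arm sizes (bypasses population simulation when
# only the claims model is under test)
fixed_persons <- function(n_users, n_controls) {
  data.table(
    person_id = c(sprintf("U%06d", seq_len(n_users)),
                  sprintf("C%06d", seq_len(n_controls))),
    arm = rep(c("user", "control"), c(n_users, n_controls)))
}

# same, but labelled as generator input (control-pool arm)
fixed_population <- function(n_users, n_controls) {
  p <- fixed_persons(n_users, n_controls)
  p[arm == "control", arm := "control-pool"]
  p
}

empty_assessments <- function() {
  data.table(person_id = character(0), assessment_index = integer(0),
             cnn_result = character(0), symptoms = logical(0),
             telederm_result = character(0))
}

claims_table <- function(person_id, category,
                         intervention = "none",
                         setting = "secondary",
                         cost = 100) {
  data.table(person_id = person_id, category = category,
             intervention = intervention, setting = setting,
             year = 2019L, cost = cost)
}

contingency <- function(a, b, c, d) {
  structure(list(a = a, b = b, c = c, d = d), class = "contingency")
}

# independent oracle: two-sided Fisher p by exhaustive enumeration over
# all tables with the observed margins (hypergeometric)
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; cs <- a + c; n <- a + b + c + d
  as <- max(0, cs - (n - r1)):min(r1, cs)
  probs <- dhyper(as, r1, n - r1, cs)
  p_obs <- dhyper(a, r1, n - r1, cs)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent oracle: quadratic-time Benjamini-Hochberg step-up
bh_reference <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    ri <- sum(p <= p[i]) # rank with ties
    min(1, min(vapply(seq_len(m), function(j) {
      rj <- sum(p <= p[j])
      if (p[j] >= p[i]) m * p[j] / rj else Inf
    }, numeric(1))))
  }, numeric(1))
}

# independent oracle: Welch two-sample t-test from first principles
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# tier-aware match-key equality check used by the exactness oracle
keys_equal <- function(u, ctrl, tier, breaks = c(18L, seq(30L, 80L, 10L)),
                       cap = 5L) {
  same <- as.character(assign_age_band(u$age, breaks)) ==
    as.character(assign_age_band(ctrl$age, breaks)) &&
    u$sex == ctrl$sex && u$ses == ctrl$ses &&
    u$history_premalignancy == ctrl$history_premalignancy &&
    min(u$n_comorbidities, cap) == min(ctrl$n_comorbidities, cap)
  if (tier == "full") same && u$region == ctrl$region else same
}
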