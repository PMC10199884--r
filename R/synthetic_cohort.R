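#' @import data.table
#' @importFrom stats rbinom rnbinom rpois rbeta rlnorm rnorm dnbinom
#'   fisher.test p.adjust pnorm qnorm t.test setNames uniroot
NULL

# zero-truncated negative binomial draws with a given *truncated* mean.
# For size = 1 (geometric) the untruncated mean is trunc_mean - 1 exactly;
# otherwise solved numerically once per call.
rztnb <- function(n, trunc_mean, size) {
  if (n == 0L) return(integer(0))
  if (size == 1) {
    mu <- trunc_mean - 1
  } else {
    f <- function(m) m / (1 - (size / (size + m))^size) - trunc_mean
    mu <- uniroot(f, c(1e-6, trunc_mean * 10))$root
  }
  # inverse-CDF conditioned on X >= 1, vectorised
  u <- stats::runif(n)
  p0 <- dnbinom(0, size = size, mu = mu)
  stats::qnbinom(p0 + u * (1 - p0), size = size, mu = mu)
}

#' Generate a synthetic insured population
#'
#' Draws `n_population` insurees with demographics and matching
#' covariates (age, sex, SES, residential area, (pre)malignancy history,
#' comorbidity proxy count) and assigns each to the app-user arm with
#' probability `uptake_rate`. Control-pool covariates follow the same
#' distributions unless `covariate_shift` is nonzero, so exact matches
#' exist by construction.
#'
#' @param config A [generator_config()].
#' @return A `data.table` with one row per insuree: `person_id`, `age`,
#'   `sex`, `ses`, `region`, `history_premalignancy`, `n_comorbidities`,
#'   `arm` (`"user"` or `"control-pool"`).
#' @export
generate_population <- function(config) {
  validate_config(config)
  n <- config$n_population
  if (n == 0L) {
    return(data.table(person_id = character(0), age = integer(0),
                      sex = character(0), ses = character(0),
                      region = character(0),
                      history_premalignancy = logical(0),
                      n_comorbidities = integer(0), arm = character(0)))
  }
  age <- round(rnorm(n, config$age_mean, config$age_sd))
  while (any(bad <- age < 18)) # truncate at adult ages by re-draw
    age[bad] <- round(rnorm(sum(bad), config$age_mean, config$age_sd))
  sex <- ifelse(rbinom(n, 1L, config$sex_female) == 1L, "female", "male")
  ses <- ifelse(rbinom(n, 1L, config$ses_missing) == 1L, "missing",
                sample(names(config$ses_probs), n, replace = TRUE,
                       prob = config$ses_probs))
  # region sizes decay smoothly so some keys are scarce
  w <- 1 / sqrt(seq_len(config$n_regions))
  region <- sample(sprintf("R%02d", seq_len(config$n_regions)), n,
                   replace = TRUE, prob = w / sum(w))
  pop <- data.table(
    person_id = sprintf("P%07d", seq_len(n)),
    age = as.integer(age),
    sex = sex, ses = ses, region = region,
    history_premalignancy = rbinom(n, 1L, config$history_prev) == 1L,
    n_comorbidities = as.integer(rnbinom(n, size = config$comorb_size,
                                         mu = config$comorb_mu)),
    arm = ifelse(rbinom(n, 1L, config$uptake_rate) == 1L,
                 "user", "control-pool"))
  if (config$covariate_shift != 0) {
    ctrl <- pop$arm == "control-pool"
    pop[ctrl, age := pmax(18L, as.integer(age + config$covariate_shift))]
  }
  pop[]
}

#' Generate app assessment records for users
#'
#' Each user performs a zero-truncated negative-binomial number of photo
#' assessments. Per photo, the CNN returns low risk (with or without
#' reported symptoms), high risk, or fails the quality check. A
#' teledermatologist panel reviews every non-failed photo and may upgrade
#' a CNN-low photo to high risk or downgrade a CNN-high photo to low
#' risk; failed photos get no teledermatologist rating. Per-user CNN
#' high-risk propensity is beta-distributed (precision `risk_icc`),
#' modelling repeated photography of the same lesion. Users whose photos
#' all failed are re-drawn (study inclusion requires at least one
#' successful assessment); after 100 attempts a degenerate configuration
#' raises an error.
#'
#' @param population Output of [generate_population()] (or any table with
#'   `person_id` and `arm`); only `arm == "user"` rows get assessments.
#' @param config A [generator_config()].
#' @return A `data.table`: `person_id`, `assessment_index`, `cnn_result`
#'   (`low`/`high`/`failed`), `symptoms` (logical, `NA` unless CNN-low),
#'   `telederm_result` (`low`/`high`/`none`).
#' @export
generate_assessments <- function(population, config) {
  validate_config(config)
  users <- population[arm == "user", person_id]
  nu <- length(users)
  if (nu == 0L) {
    return(data.table(person_id = character(0), assessment_index = integer(0),
                      cnn_result = character(0), symptoms = logical(0),
                      telederm_result = character(0)))
  }
  p <- config$cnn_probs
  p_high_max <- 1 - p[["failed"]]
  draw <- function(ids) {
    k <- rztnb(length(ids), config$assess_mean, config$assess_size)
    m <- if (p_high_max > 0) p[["high"]] / p_high_max else 0
    if (is.finite(config$risk_icc) && m > 0 && m < 1) {
      hprop <- p_high_max * rbeta(length(ids), m * config$risk_icc,
                                  (1 - m) * config$risk_icc)
    } else {
      hprop <- rep(p[["high"]], length(ids))
    }
    idx <- rep(seq_along(ids), k)
    n_tot <- length(idx)
    u <- stats::runif(n_tot)
    ph <- hprop[idx]
    cnn <- ifelse(u < ph, "high",
                  ifelse(u < ph + p[["failed"]], "failed", "low"))
    sympt <- rep(NA, n_tot)
    low <- cnn == "low"
    sympt[low] <- stats::runif(sum(low)) <
      p[["low_symptoms"]] / (p[["low"]] + p[["low_symptoms"]])
    td <- rep("none", n_tot)
    td[low] <- ifelse(stats::runif(sum(low)) < config$upgrade_prob,
                      "high", "low")
    hi <- cnn == "high"
    td[hi] <- ifelse(stats::runif(sum(hi)) < config$downgrade_prob,
                     "low", "high")
    data.table(person_id = rep(ids, k),
               assessment_index = sequence(k),
               cnn_result = cnn, symptoms = as.logical(sympt),
               telederm_result = td)
  }
  out <- draw(users)
  for (attempt in seq_len(100L)) {
    ok <- out[, .(ok = any(cnn_result != "failed")), by = person_id]
    bad <- ok[ok == FALSE, person_id]
    if (length(bad) == 0L) break
    out <- rbind(out[!person_id %in% bad], draw(bad))
  }
  if (out[, .(ok = any(cnn_result != "failed")), by = person_id][, any(!ok)])
    config_error(paste("could not give every user a successful assessment;",
                       "is the failure probability ~1?"))
  setkey(out, person_id, assessment_index)
  out[]
}

#' Combined risk of an assessment
#'
#' An assessment is high risk when either the CNN or the
#' teledermatologist assigned high risk; low risk when neither did;
#' `NA` for failed photos (which have no rating).
#'
#' @param cnn_result,telederm_result Vectors as in the assessment table.
#' @return Character vector `"high"`/`"low"`/`NA`.
#' @export
combined_risk <- function(cnn_result, telederm_result) {
  ifelse(cnn_result == "failed", NA_character_,
         ifelse(cnn_result == "high" | telederm_result == "high",
                "high", "low"))
}

# person-level stratum used by the claims model: control, or user split by
# whether any assessment was (combined) high risk
person_strata <- function(population, assessments) {
  risky <- assessments[
    , .(high = any(combined_risk(cnn_result, telederm_result) == "high",
                   na.rm = TRUE)), by = person_id]
  strat <- population[, .(person_id, arm)]
  strat <- merge(strat, risky, by = "person_id", all.x = TRUE)
  strat[, stratum := fifelse(arm != "user", "control",
                             fifelse(!is.na(high) & high,
                                     "user_high", "user_low"))]
  strat[, .(person_id, arm, stratum)]
}

rlnorm_mean <- function(n, mean, sdlog) {
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate healthcare claims
#'
#' Person-level claim incidence per diagnosis category is Bernoulli with
#' probabilities conditioned on arm and, for users, on ever having had a
#' high-risk assessment. Claimants receive 1 + Poisson additional claims
#' in the category; per-claim costs are log-normal with category- and
#' arm-specific means, truncated at zero by construction and rounded to
#' cents. Secondary (dermatologist) claims may carry an intervention
#' label (Mohs surgery, hospital excision); primary-care intervention
#' claims (GP biopsy/excision, GP teledermatology) are generated as an
#' additional Poisson stream per person.
#'
#' @param population Insuree table (needs `person_id`, `arm`).
#' @param assessments Assessment table for users (used to split users
#'   into high-/low-risk strata).
#' @param config A [generator_config()].
#' @return A `data.table`: `person_id`, `category`, `intervention`,
#'   `setting`, `year`, `cost`.
#' @export
generate_claims <- function(population, assessments, config) {
  validate_config(config)
  if (nrow(population) == 0L) {
    return(data.table(person_id = character(0), category = character(0),
                      intervention = character(0), setting = character(0),
                      year = integer(0), cost = numeric(0)))
  }
  strat <- person_strata(population, assessments)
  out <- vector("list", 0L)
  for (cat in claim_categories()) {
    p <- vapply(c(control = "control", user_high = "user_high",
                  user_low = "user_low"),
                function(s) config$claim_probs[[s]][[cat]], numeric(1))
    has <- rbinom(nrow(strat), 1L, p[strat$stratum]) == 1L
    claimants <- strat[has]
    if (nrow(claimants) == 0L) next
    k <- 1L + rpois(nrow(claimants), config$extra_claims_mean[[cat]])
    idx <- rep(seq_len(nrow(claimants)), k)
    arm_of <- fifelse(claimants$arm[idx] == "user", "user", "control")
    cost <- round(rlnorm_mean(length(idx),
                              ifelse(arm_of == "user",
                                     config$cost_mean$user[[cat]],
                                     config$cost_mean$control[[cat]]),
                              config$cost_sdlog), 2)
    cl <- data.table(person_id = claimants$person_id[idx],
                     category = cat,
                     intervention = "none",
                     setting = "secondary",
                     year = config$year,
                     cost = cost,
                     .arm = arm_of)
    out[[length(out) + 1L]] <- cl
  }
  claims <- if (length(out)) rbindlist(out) else
    data.table(person_id = character(0), category = character(0),
               intervention = character(0), setting = character(0),
               year = integer(0), cost = numeric(0), .arm = character(0))
  # intervention labels on eligible secondary claims
  if (nrow(claims) > 0L) {
    u <- stats::runif(nrow(claims))
    for (arm in c("user", "control")) {
      ip <- config$intervention_probs[[arm]]
      is_arm <- claims$.arm == arm
      mal <- is_arm & claims$category == "malignant"
      claims[mal & u < ip[["mohs"]], intervention := "mohs"]
      claims[mal & u >= ip[["mohs"]] &
               u < ip[["mohs"]] + ip[["hospital_excision_premalignant"]],
             intervention := "hospital_excision_premalignant"]
      pre <- is_arm & claims$category == "premalignant"
      claims[pre & u < ip[["hospital_excision_premalignant"]],
             intervention := "hospital_excision_premalignant"]
      ben <- is_arm & claims$category %in% c("nevus", "benign_tumor")
      claims[ben & u < ip[["hospital_excision_benign"]],
             intervention := "hospital_excision_benign"]
    }
  }
  claims[, .arm := NULL]
  # primary-care intervention stream
  gp <- vector("list", 0L)
  for (arm_nm in c("user", "control")) {
    ids <- if (arm_nm == "user") strat[arm == "user", person_id] else
      strat[arm != "user", person_id]
    for (iv in primary_interventions()) {
      rate <- config$gp_rates[[arm_nm]][[iv]]
      k <- rpois(length(ids), rate)
      if (sum(k) == 0L) next
      pid <- rep(ids, k)
      cat_mix <- if (iv == "gp_biopsy_excision")
        c(nevus = 0.4, premalignant = 0.2, malignant = 0.2,
          benign_tumor = 0.1, unrelated_dermatology = 0.1)
      else c(unrelated_dermatology = 0.5, nevus = 0.3, premalignant = 0.1,
             malignant = 0.05, benign_tumor = 0.05)
      gp[[length(gp) + 1L]] <- data.table(
        person_id = pid,
        category = sample(names(cat_mix), length(pid), replace = TRUE,
                          prob = cat_mix),
        intervention = iv,
        setting = "primary",
        year = config$year,
        cost = round(rlnorm_mean(length(pid), config$gp_cost_mean[[iv]],
                                 config$cost_sdlog), 2))
    }
  }
  claims <- rbindlist(c(list(claims), gp), use.names = TRUE)
  setkey(claims, person_id)
  claims[]
}

#' Simulate a full synthetic data bundle
#'
#' Runs population, assessment and claims generation under a single seed.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return List with `insurees`, `assessments`, `claims` data.tables and
#'   the `config` used (seed updated).
#' @export
simulate_cohort <- function(config = generator_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  insurees <- generate_population(config)
  assessments <- generate_assessments(insurees, config)
  claims <- generate_claims(insurees, assessments, config)
  list(insurees = insurees, assessments = assessments, claims = claims,
       config = config)
}
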