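#' Diagnosis categories used throughout the pipeline
#'
#' Dermatological claims are analysed in five diagnosis groups:
#' premalignant skin lesions (e.g. actinic keratosis), malignant skin
#' lesions (melanoma, keratinocytic carcinoma), nevi, benign skin tumors,
#' and dermatological claims unrelated to skin-lesion triage (the
#' internal-validity control, e.g. varicose veins).
#'
#' @return Character vector of the five category codes.
#' @export
claim_categories <- function() {
  c("premalignant", "malignant", "nevus", "benign_tumor",
    "unrelated_dermatology")
}

#' Intervention codes carried on claims
#'
#' Primary-care interventions (GP biopsy/excision, GP teledermatology
#' consultation) always have `setting = "primary"`; Mohs surgery and
#' hospital excisions always have `setting = "secondary"`. Ordinary
#' dermatologist claims carry `"none"`.
#'
#' @return Character vector of intervention codes, `"none"` first.
#' @export
intervention_codes <- function() {
  c("none", "gp_biopsy_excision", "gp_teledermatology", "mohs",
    "hospital_excision_benign", "hospital_excision_premalignant")
}

primary_interventions <- function() {
  c("gp_biopsy_excision", "gp_teledermatology")
}

#' Configuration for the synthetic cohort generator
#'
#' Builds (and validates) the parameter set controlling the synthetic
#' insured population, app-usage logs and claims. Defaults emulate the
#' study conditions: an insured population with roughly 0.9% app uptake,
#' per-photo CNN outcome frequencies of 58.5% low risk / 13.2% low risk
#' with symptoms / 23.5% high risk / 4.8% failed, a 2.8% teledermatologist
#' upgrade rate on CNN-low photos and a 33.8% downgrade rate on CNN-high
#' photos, person-level claim probabilities per diagnosis category by arm
#' and risk subgroup, and log-normal per-claim costs whose means are
#' anchored to the per-person annual cost levels of the two arms.
#'
#' Assessment counts per user follow a zero-truncated negative binomial
#' (default geometric, truncated mean 64128/18960). Per-user CNN high-risk
#' propensity is beta-distributed (mean 0.235, precision `risk_icc`),
#' which induces the within-user correlation of outcomes needed for the
#' share of users with at least one high-risk assessment to sit near 37%
#' rather than the ~50% implied by independent photos.
#'
#' @param n_population Number of insurees to simulate.
#' @param uptake_rate Probability an insuree is an app user.
#' @param seed Integer seed recorded in the manifest; all generator
#'   randomness derives from it.
#' @param assess_mean Truncated mean of assessments per user.
#' @param assess_size Negative-binomial size (dispersion) of the
#'   assessment-count distribution; 1 = geometric.
#' @param cnn_probs Named probabilities for per-photo CNN outcomes
#'   `low`, `low_symptoms`, `high`, `failed`; must sum to 1.
#' @param upgrade_prob Probability a teledermatologist upgrades a CNN-low
#'   photo to high risk.
#' @param downgrade_prob Probability a teledermatologist downgrades a
#'   CNN-high photo to low risk.
#' @param risk_icc Precision of the per-user beta distribution of CNN
#'   high-risk propensity; `Inf` gives homogeneous users.
#' @param claim_probs List with elements `control`, `user_high`,
#'   `user_low`: named per-category probabilities that a person has at
#'   least one claim in the category.
#' @param extra_claims_mean Named per-category Poisson mean of additional
#'   claims per claimant (claims per claimant = 1 + Poisson).
#' @param cost_mean List with `user` and `control` named vectors of mean
#'   cost per claim (euros) by category.
#' @param cost_sdlog Log-scale SD of the log-normal per-claim cost.
#' @param gp_rates List with `user`/`control` named vectors of expected
#'   primary-care intervention claims per person per year.
#' @param gp_cost_mean Named mean euro cost of primary-care claims.
#' @param intervention_probs List with `user`/`control` named vectors
#'   `mohs`, `hospital_excision_premalignant`, `hospital_excision_benign`:
#'   probabilities that a secondary claim of the eligible category carries
#'   that intervention.
#' @param sex_female Probability of female sex.
#' @param age_mean,age_sd Age distribution (normal truncated at 18).
#' @param ses_probs Named probabilities of low/middle/high SES among
#'   persons with known SES.
#' @param ses_missing Probability SES is missing.
#' @param n_regions Number of residential area codes.
#' @param history_prev Prevalence of a positive (pre)malignancy history.
#' @param comorb_mu,comorb_size Negative-binomial parameters of the
#'   comorbidity proxy count (unique drug classes).
#' @param covariate_shift Years added to control-pool ages (0 = identical
#'   covariate distributions, so exact matches exist; nonzero exercises
#'   matching-failure paths).
#' @param year Calendar year stamped on claims.
#'
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_population = 200000L,
                             uptake_rate = 0.009,
                             seed = 1L,
                             assess_mean = 64128 / 18960,
                             assess_size = 1,
                             cnn_probs = c(low = 0.585, low_symptoms = 0.132,
                                           high = 0.235, failed = 0.048),
                             upgrade_prob = 0.028,
                             downgrade_prob = 0.338,
                             risk_icc = 0.4844,
                             claim_probs = default_claim_probs(),
                             extra_claims_mean = c(premalignant = 0.3,
                                                   malignant = 0,
                                                   nevus = 0.3,
                                                   benign_tumor = 0.3,
                                                   unrelated_dermatology = 0.3),
                             cost_mean = default_cost_means(),
                             cost_sdlog = 0.5,
                             gp_rates = list(
                               user = c(gp_biopsy_excision = 1424 / 18960,
                                        gp_teledermatology = 99 / 18960),
                               control = c(gp_biopsy_excision = 1913 / 56880,
                                           gp_teledermatology = 131 / 56880)),
                             gp_cost_mean = c(gp_biopsy_excision = 60,
                                              gp_teledermatology = 50),
                             intervention_probs = list(
                               user = c(mohs = 0.0479,
                                        hospital_excision_premalignant = 0.516,
                                        hospital_excision_benign = 0.2555),
                               control = c(mohs = 0.0532,
                                           hospital_excision_premalignant = 0.383,
                                           hospital_excision_benign = 0.2244)),
                             sex_female = 0.532,
                             age_mean = 48.4,
                             age_sd = 14.0,
                             ses_probs = c(low = 0.230, middle = 0.426,
                                           high = 0.332) / 0.988,
                             ses_missing = 0.011,
                             n_regions = 60L,
                             history_prev = 0.047,
                             comorb_mu = 0.4,
                             comorb_size = 0.3,
                             covariate_shift = 0,
                             year = 2019L) {
  cfg <- list(
    n_population = as.integer(n_population), uptake_rate = uptake_rate,
    seed = as.integer(seed), assess_mean = assess_mean,
    assess_size = assess_size, cnn_probs = cnn_probs,
    upgrade_prob = upgrade_prob, downgrade_prob = downgrade_prob,
    risk_icc = risk_icc, claim_probs = claim_probs,
    extra_claims_mean = extra_claims_mean, cost_mean = cost_mean,
    cost_sdlog = cost_sdlog, gp_rates = gp_rates,
    gp_cost_mean = gp_cost_mean, intervention_probs = intervention_probs,
    sex_female = sex_female, age_mean = age_mean, age_sd = age_sd,
    ses_probs = ses_probs, ses_missing = ses_missing,
    n_regions = as.integer(n_regions), history_prev = history_prev,
    comorb_mu = comorb_mu, comorb_size = comorb_size,
    covariate_shift = covariate_shift, year = as.integer(year))
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

#' Default person-level claim probabilities
#'
#' Per-category probabilities that a person has at least one claim,
#' stratified by arm and, for users, by whether they ever received a
#' high-risk assessment. Values are the person-count proportions of the
#' study's claims tables; the nevus / benign-tumor split within the
#' high/low user strata uses the overall user split (850:267).
#'
#' @return List with named vectors `control`, `user_high`, `user_low`.
#' @export
default_claim_probs <- function() {
  nev_frac <- 850 / 1117       # nevus share of nevi+benign claimants, users
  list(
    control = c(premalignant = 896 / 56880,
                malignant = 1785 / 56880,
                nevus = 667 / 56880,
                benign_tumor = 279 / 56880,
                unrelated_dermatology = 2800 / 56880),
    user_high = c(premalignant = 208 / 7041,
                  malignant = 442 / 7041,
                  nevus = 695 / 7041 * nev_frac,
                  benign_tumor = 695 / 7041 * (1 - nev_frac),
                  unrelated_dermatology = 425 / 7041),
    user_low = c(premalignant = 183 / 11919,
                 malignant = 331 / 11919,
                 nevus = 419 / 11919 * nev_frac,
                 benign_tumor = 419 / 11919 * (1 - nev_frac),
                 unrelated_dermatology = 576 / 11919))
}

#' Default mean cost per claim by category and arm
#'
#' Malignant means are the study's printed per-claim costs; the other
#' categories (not printed per claim) are set so that, combined with the
#' default claim probabilities and claims-per-claimant, the per-person
#' annual cost means of the two arms land near the reported levels
#' (about 65 vs 43 euros).
#'
#' @return List with named vectors `user` and `control` (euros).
#' @export
default_cost_means <- function() {
  list(
    user = c(premalignant = 210, malignant = 613.36, nevus = 185,
             benign_tumor = 150, unrelated_dermatology = 290),
    control = c(premalignant = 210, malignant = 520.05, nevus = 185,
                benign_tumor = 150, unrelated_dermatology = 290))
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("dermclaims_config_error", "error")))
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    config_error(sprintf("%s must be probabilities in [0, 1]", what))
}

validate_config <- function(cfg) {
  cats <- claim_categories()
  check_prob(cfg$uptake_rate, "uptake_rate")
  check_prob(cfg$cnn_probs, "cnn_probs")
  if (abs(sum(cfg$cnn_probs) - 1) > 1e-12)
    config_error("cnn_probs must sum to 1")
  if (!setequal(names(cfg$cnn_probs),
                c("low", "low_symptoms", "high", "failed")))
    config_error("cnn_probs must be named low, low_symptoms, high, failed")
  check_prob(c(cfg$upgrade_prob, cfg$downgrade_prob, cfg$ses_missing,
               cfg$history_prev, cfg$sex_female), "outcome probabilities")
  check_prob(cfg$ses_probs, "ses_probs")
  if (abs(sum(cfg$ses_probs) - 1) > 1e-12)
    config_error("ses_probs must sum to 1")
  for (arm in names(cfg$claim_probs)) {
    p <- cfg$claim_probs[[arm]]
    if (!setequal(names(p), cats))
      config_error(sprintf("claim_probs$%s must cover all categories", arm))
    check_prob(p, sprintf("claim_probs$%s", arm))
  }
  if (!setequal(names(cfg$claim_probs), c("control", "user_high", "user_low")))
    config_error("claim_probs needs elements control, user_high, user_low")
  for (arm in c("user", "control")) {
    m <- cfg$cost_mean[[arm]]
    if (!setequal(names(m), cats) || any(m < 0) || any(!is.finite(m)))
      config_error(sprintf("cost_mean$%s must be nonnegative per category", arm))
    check_prob(cfg$intervention_probs[[arm]],
               sprintf("intervention_probs$%s", arm))
    if (any(cfg$gp_rates[[arm]] < 0))
      config_error("gp_rates must be nonnegative")
  }
  if (any(cfg$extra_claims_mean < 0))
    config_error("extra_claims_mean must be nonnegative")
  if (cfg$assess_mean <= 1 || cfg$assess_size <= 0)
    config_error("assessment count needs truncated mean > 1 and size > 0")
  if (cfg$n_population < 0) config_error("n_population must be nonnegative")
  if (cfg$risk_icc <= 0) config_error("risk_icc must be positive")
  invisible(cfg)
}
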