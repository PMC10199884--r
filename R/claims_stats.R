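#' @importFrom utils head
NULL

domain_error <- function(msg) {
  stop(errorCondition(msg, class = c("dermclaims_domain_error", "error")))
}

#' Person-level 2x2 contingency table for one claim category
#'
#' Cross-classifies analyzed persons (exposure = app use) against the
#' presence of at least one claim in `category`. Multiple claims by the
#' same person count once (person-level deduplication).
#'
#' Diagnosis-group analyses cover dermatologist claims, so only
#' secondary/tertiary-care claims are counted by default; primary-care
#' intervention claims are analysed separately via
#' [intervention_rates()].
#'
#' @param persons `data.table` with `person_id`, `arm`
#'   (`"user"`/`"control"`), e.g. from [analysis_set()].
#' @param claims Claims table (`person_id`, `category`, ...).
#' @param category One of [claim_categories()], or a character vector of
#'   categories treated as a combined outcome (e.g. nevi + benign tumors).
#' @param setting_filter Care settings counted (default `"secondary"`;
#'   use `"all"` for every claim).
#' @return Object of class `"contingency"`: named list `a` (users with
#'   claim), `b` (users without), `c` (controls with), `d` (controls
#'   without).
#' @export
build_contingency <- function(persons, claims, category,
                              setting_filter = "secondary") {
  if (!all(category %in% claim_categories()))
    domain_error(sprintf("unknown claim category: %s",
                         paste(setdiff(category, claim_categories()),
                               collapse = ", ")))
  if (!identical(setting_filter, "all"))
    claims <- claims[setting %in% setting_filter]
  claimants <- unique(claims[category, on = "category", nomatch = NULL,
                             person_id])
  has <- persons$person_id %in% claimants
  user <- persons$arm == "user"
  out <- list(a = sum(user & has), b = sum(user & !has),
              c = sum(!user & has), d = sum(!user & !has))
  class(out) <- "contingency"
  out
}

#' Sample odds ratio with Woolf confidence interval
#'
#' Point estimate is the cross-product ratio (a*d)/(b*c). The 95% CI
#' uses the normal approximation on the log odds ratio
#' exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is
#' zero, the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied to both estimate and CI and flagged.
#'
#' @param tab A [build_contingency()] result (or list with a, b, c, d).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `odds_ratio`, `ci_low`, `ci_high`, `haldane` (logical
#'   flag for the zero-cell correction).
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  cells <- as.numeric(c(tab$a, tab$b, tab$c, tab$d))
  if (any(cells < 0) || any(!is.finite(cells)))
    domain_error("contingency cells must be finite and nonnegative")
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       haldane = haldane)
}

#' Fisher's exact test, two-sided p-value
#'
#' Two-sided p-value of Fisher's Exact Test for Count Data on the 2x2
#' person-level table: the sum of hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one.
#'
#' @param tab A [build_contingency()] result.
#' @return Numeric p-value in \[0, 1\].
#' @export
fisher_exact_p <- function(tab) {
  m <- matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE)
  fisher.test(m)$p.value
}

#' Two-proportion z-test (pooled variance)
#'
#' Compares two independent binomial proportions x1/n1 vs x2/n2 with the
#' pooled-variance normal approximation, by default without continuity
#' correction. When the pooled proportion is 0 or 1 the variance is
#' degenerate; z = 0 and p = 1 are returned with a flag.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param correct Apply Yates-style continuity correction.
#' @return List: `z`, `p_value`, `degenerate`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) domain_error("group sizes must be positive")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  if (v == 0)
    return(list(z = 0, p_value = 1, degenerate = TRUE))
  num <- p1 - p2
  if (correct) {
    cc <- min(abs(num), (1 / n1 + 1 / n2) / 2)
    num <- sign(num) * (abs(num) - cc)
  }
  z <- num / sqrt(v)
  list(z = z, p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Claims per 1000 persons
#'
#' @param claims Number of claims (count).
#' @param persons Number of persons at risk (must be positive).
#' @return List: `claims`, `persons`, `rate` (claims per 1000 persons),
#'   `rate_rounded` (2 decimals, round-half-even, as reported).
#' @export
claims_per_1000 <- function(claims, persons) {
  if (persons <= 0) domain_error("persons must be positive")
  rate <- 1000 * claims / persons
  list(claims = claims, persons = persons, rate = rate,
       rate_rounded = round(rate, 2))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (same order), monotone, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    domain_error("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Split users by app risk feedback
#'
#' Users with at least one high-risk assessment (CNN or teledermatologist
#' assigned high risk) form the high-risk subgroup; users whose non-failed
#' assessments were all low risk form the low-risk subgroup. Users with
#' only failed assessments violate the inclusion rule and are dropped
#' with a warning.
#'
#' @param users Character vector of user person ids (the analyzed users).
#' @param assessments Assessment table.
#' @return List: `high_risk`, `low_risk` (character id vectors),
#'   `excluded` (ids with only failed assessments).
#' @export
subgroup_split <- function(users, assessments) {
  a <- assessments[person_id %in% users]
  a[, risk := combined_risk(cnn_result, telederm_result)]
  per <- a[, .(any_high = any(risk == "high", na.rm = TRUE),
               any_ok = any(!is.na(risk))), by = person_id]
  missing_ids <- setdiff(users, per$person_id)
  excluded <- c(per[any_ok == FALSE, person_id], missing_ids)
  if (length(excluded) > 0L)
    warning(sprintf("%d user(s) without a successful assessment excluded",
                    length(excluded)))
  list(high_risk = per[any_ok & any_high, person_id],
       low_risk = per[any_ok & !any_high, person_id],
       excluded = excluded)
}

#' Restrict a matched cohort to users with given ids
#'
#' Keeps the selected users and exactly their matched controls, so
#' subgroup analyses run the same association operations on a preserved
#' matched structure.
#'
#' @param cohort A [match_cohort()] result.
#' @param user_ids Users to keep.
#' @return `data.table` with `person_id`, `arm` for the subcohort.
#' @export
subcohort <- function(cohort, user_ids) {
  keep <- cohort$users[tier != "unmatched" & user_id %in% user_ids, user_id]
  rbind(data.table(person_id = keep, arm = "user"),
        data.table(person_id = cohort$matches[user_id %in% keep, control_id],
                   arm = "control"))
}

#' Users with a positive (pre)malignancy history plus their controls
#'
#' @param insurees Insuree table with `history_premalignancy`.
#' @param cohort A [match_cohort()] result.
#' @return `data.table` with `person_id`, `arm` for the history subcohort.
#' @export
history_subgroup <- function(insurees, cohort) {
  pos <- as.data.table(insurees)[history_premalignancy == TRUE, person_id]
  subcohort(cohort, pos)
}

#' Person-level association table across claim categories
#'
#' For each outcome (by default the five categories, optionally combined
#' outcomes given as list entries with multiple categories), builds the
#' person-level 2x2 table and reports claimant proportions per arm, the
#' odds ratio with 95% CI, Fisher exact p, two-proportion z p, and
#' BH-adjusted p-values (one family per call).
#'
#' @param persons Analyzed persons (`person_id`, `arm`).
#' @param claims Claims table.
#' @param outcomes Named list of category vectors; default one outcome
#'   per category.
#' @return `data.table`, one row per outcome.
#' @export
association_table <- function(persons, claims,
                              outcomes = as.list(setNames(
                                claim_categories(), claim_categories()))) {
  rows <- lapply(names(outcomes), function(nm) {
    tb <- build_contingency(persons, claims, outcomes[[nm]])
    or <- odds_ratio(tb)
    zt <- two_proportion_z(tb$a, tb$a + tb$b, tb$c, tb$c + tb$d)
    data.table(outcome = nm, a = tb$a, b = tb$b, c = tb$c, d = tb$d,
               pct_users = round(100 * tb$a / (tb$a + tb$b), 2),
               pct_controls = round(100 * tb$c / (tb$c + tb$d), 2),
               odds_ratio = round(or$odds_ratio, 2),
               ci_low = round(or$ci_low, 2),
               ci_high = round(or$ci_high, 2),
               p_fisher = fisher_exact_p(tb),
               p_zprop = zt$p_value)
  })
  out <- rbindlist(rows)
  out[, p_adjusted := bh_adjust(p_fisher)]
  out[]
}

#' Intervention claim volumes per 1000 persons
#'
#' Mirrors the diagnostic/therapeutic intervention comparison: per
#' intervention type, claim counts by arm, claims per 1000 persons,
#' the user-minus-control rate difference, and the two-proportion z
#' p-value on person denominators, BH-adjusted as one family.
#'
#' @param persons Analyzed persons (`person_id`, `arm`).
#' @param claims Claims table.
#' @return `data.table`, one row per intervention type.
#' @export
intervention_rates <- function(persons, claims) {
  n_u <- sum(persons$arm == "user")
  n_c <- sum(persons$arm == "control")
  cl <- merge(claims, persons, by = "person_id")
  ivs <- setdiff(intervention_codes(), "none")
  rows <- lapply(ivs, function(iv) {
    x_u <- nrow(cl[intervention == iv & arm == "user"])
    x_c <- nrow(cl[intervention == iv & arm == "control"])
    r_u <- claims_per_1000(x_u, n_u)
    r_c <- claims_per_1000(x_c, n_c)
    zt <- two_proportion_z(x_u, n_u, x_c, n_c)
    data.table(intervention = iv,
               setting = if (iv %in% primary_interventions()) "primary"
                         else "secondary",
               claims_users = x_u, claims_controls = x_c,
               rate_users = r_u$rate_rounded,
               rate_controls = r_c$rate_rounded,
               delta = round(r_u$rate - r_c$rate, 2),
               p_zprop = zt$p_value)
  })
  out <- rbindlist(rows)
  out[, p_adjusted := bh_adjust(p_zprop)]
  out[]
}
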