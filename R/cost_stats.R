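per_person_costs <- function(claims, persons, category = "all",
                             setting_filter = "secondary") {
  cl <- claims
  if (!identical(setting_filter, "all"))
    cl <- cl[setting %in% setting_filter]
  if (!identical(category, "all")) {
    if (!all(category %in% claim_categories()))
      domain_error("unknown claim category")
    cl <- cl[category, on = "category", nomatch = NULL]
  }
  tot <- cl[, .(cost = sum(cost)), by = person_id]
  x <- merge(persons, tot, by = "person_id", all.x = TRUE)
  x[is.na(cost), cost := 0]
  x
}

#' Annual dermatological cost per person, by arm
#'
#' Mean annual cost per person in each arm (persons without claims
#' contribute zero), their difference (users minus controls) with a
#' Welch two-sided t-test and confidence interval. Matching the study's
#' costing scope, only secondary/tertiary (dermatologist) claims are
#' costed by default.
#'
#' @param claims Claims table.
#' @param persons Analyzed persons (`person_id`, `arm`); both arms must
#'   be non-empty.
#' @param category `"all"` or a vector of [claim_categories()].
#' @param setting_filter `"secondary"` (default), `"primary"`, or
#'   `"all"`.
#' @param var_equal Use the pooled-variance Student t-test instead of
#'   Welch.
#' @param conf_level Confidence level for the difference.
#' @return List: `category`, `mean_users`, `mean_controls`, `delta`,
#'   `delta_ci` (length-2), `p_value`, `n_users`, `n_controls`.
#' @export
annual_cost_per_person <- function(claims, persons, category = "all",
                                   setting_filter = "secondary",
                                   var_equal = FALSE, conf_level = 0.95) {
  if (!all(c("user", "control") %in% persons$arm))
    domain_error("both arms must be non-empty")
  x <- per_person_costs(claims, persons, category, setting_filter)
  cu <- x[arm == "user", cost]
  cc <- x[arm == "control", cost]
  if (stats::sd(cu) == 0 && stats::sd(cc) == 0) {
    d <- mean(cu) - mean(cc)
    tt <- list(p.value = if (d == 0) 1 else 0, conf.int = c(d, d))
  } else {
    tt <- t.test(cu, cc, var.equal = var_equal, conf.level = conf_level)
  }
  list(category = paste(category, collapse = "+"),
       mean_users = mean(cu), mean_controls = mean(cc),
       delta = mean(cu) - mean(cc),
       delta_ci = as.numeric(tt$conf.int),
       p_value = tt$p.value,
       n_users = length(cu), n_controls = length(cc))
}

#' Mean cost per claim by arm for one category
#'
#' Claim-level (not person-level) arithmetic mean cost, with a Welch
#' t-test comparing arms. Arms without claims in the category are
#' reported as absent (`NA`).
#'
#' @inheritParams annual_cost_per_person
#' @param category A vector of [claim_categories()].
#' @return List: `category`, `mean_users`, `mean_controls`,
#'   `n_claims_users`, `n_claims_controls`, `p_value` (`NA` unless both
#'   arms have >= 2 claims).
#' @export
mean_cost_per_claim <- function(claims, persons, category,
                                setting_filter = "secondary",
                                var_equal = FALSE) {
  if (!all(category %in% claim_categories()))
    domain_error("unknown claim category")
  cl <- merge(claims, persons, by = "person_id")
  if (!identical(setting_filter, "all"))
    cl <- cl[setting %in% setting_filter]
  cl <- cl[category, on = "category", nomatch = NULL]
  cu <- cl[arm == "user", cost]
  cc <- cl[arm == "control", cost]
  p <- if (length(cu) >= 2 && length(cc) >= 2 &&
           (stats::sd(cu) > 0 || stats::sd(cc) > 0))
    t.test(cu, cc, var.equal = var_equal)$p.value else NA_real_
  list(category = paste(category, collapse = "+"),
       mean_users = if (length(cu)) mean(cu) else NA_real_,
       mean_controls = if (length(cc)) mean(cc) else NA_real_,
       n_claims_users = length(cu), n_claims_controls = length(cc),
       p_value = p)
}

#' Cost summary across categories
#'
#' Per-category and overall per-person mean annual costs by arm with the
#' user-minus-control difference, Welch test and CI, plus per-claim mean
#' costs. P-values for the per-person comparisons are BH-adjusted as one
#' family.
#'
#' @inheritParams annual_cost_per_person
#' @return `data.table`, one row per category plus an `"all"` row.
#' @export
cost_summary <- function(claims, persons, setting_filter = "secondary",
                         var_equal = FALSE) {
  cats <- c(as.list(claim_categories()), list("all"))
  rows <- lapply(cats, function(cat) {
    pp <- annual_cost_per_person(claims, persons, cat, setting_filter,
                                 var_equal)
    pc <- if (identical(cat, "all"))
      list(mean_users = NA_real_, mean_controls = NA_real_,
           p_value = NA_real_)
    else mean_cost_per_claim(claims, persons, cat, setting_filter,
                             var_equal)
    data.table(category = pp$category,
               mean_per_person_users = round(pp$mean_users, 2),
               mean_per_person_controls = round(pp$mean_controls, 2),
               delta = round(pp$delta, 2),
               delta_ci_low = round(pp$delta_ci[1], 2),
               delta_ci_high = round(pp$delta_ci[2], 2),
               p_value = pp$p_value,
               mean_per_claim_users = round(pc$mean_users, 2),
               mean_per_claim_controls = round(pc$mean_controls, 2),
               p_value_per_claim = pc$p_value)
  })
  out <- rbindlist(rows)
  out[, p_adjusted := bh_adjust(p_value)]
  out[]
}
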