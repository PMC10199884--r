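#' Incremental cost-effectiveness ratio
#'
#' ICER = (cost of intervention - cost of standard of care) /
#' (effectiveness of intervention - effectiveness of standard of care),
#' here euros per additionally detected (pre)malignancy, where detected
#' (pre)malignancies are proxied by unique persons with a claim for a
#' premalignant or malignant skin lesion. Costs and effectiveness must
#' be on a consistent scale (both totals or both per person).
#'
#' @param cost_intervention,cost_standard Costs (euros).
#' @param eff_intervention,eff_standard Effectiveness (detected
#'   (pre)malignancies).
#' @return List: `icer` (euros per additional detection; `NA` when the
#'   incremental effectiveness is zero), `undefined` flag, `dominant`
#'   flag (negative ICER: cheaper and more effective, or costlier and
#'   less effective).
#' @export
icer <- function(cost_intervention, cost_standard,
                 eff_intervention, eff_standard) {
  d_eff <- eff_intervention - eff_standard
  d_cost <- cost_intervention - cost_standard
  if (d_eff == 0)
    return(list(icer = NA_real_, undefined = TRUE, dominant = FALSE))
  val <- d_cost / d_eff
  list(icer = val, undefined = FALSE, dominant = val < 0)
}

#' Observed per-user increments from cohort data
#'
#' Computes, from an analyzed cohort and its claims, the ingredients of
#' the cost-effectiveness calibration: per-user incremental
#' (pre)malignancy claimants and benign/nevus claimants (user-arm minus
#' control-arm person-level proportions) and the corresponding
#' incremental per-person annual costs.
#'
#' @param persons Analyzed persons (`person_id`, `arm`).
#' @param claims Claims table.
#' @param setting_filter Costing scope, as in [annual_cost_per_person()].
#' @return List: `d_detect` (incremental (pre)malignancy claimants per
#'   user), `d_benign` (incremental nevus/benign-tumor claimants per
#'   user), `d_cost_malignant`, `d_cost_benign` (incremental per-person
#'   euros).
#' @export
observed_increments <- function(persons, claims,
                                setting_filter = "secondary") {
  prop <- function(cats) {
    tb <- build_contingency(persons, claims, cats)
    tb$a / (tb$a + tb$b) - tb$c / (tb$c + tb$d)
  }
  dc <- function(cats)
    annual_cost_per_person(claims, persons, cats, setting_filter)$delta
  mal <- c("premalignant", "malignant")
  ben <- c("nevus", "benign_tumor")
  list(d_detect = prop(mal), d_benign = prop(ben),
       d_cost_malignant = dc(mal), d_cost_benign = dc(ben))
}

#' Calibrate the detection-cascade cost-effectiveness model
#'
#' The model writes the per-user incremental detections as
#' `v * pi * alpha * sens` and the incremental benign/nevus claimants as
#' `v * (1 - pi) * alpha * (1 - spec)`, where `v` is lesion volume, `pi`
#' the (pre)malignant prevalence among photographed lesions and `alpha`
#' adherence; the products `v*pi*alpha` and `v*(1-pi)*alpha` are
#' identified from the observed increments at the calibration accuracy
#' (`sens0`, `spec0`). Unit costs per incremental claimant come from the
#' observed incremental per-person costs.
#'
#' @param increments An [observed_increments()] result (or list with the
#'   same fields, e.g. from printed aggregates).
#' @param sens0,spec0 Calibration sensitivity and specificity (the
#'   app's published accuracy, about 0.87 and 0.70).
#' @param app_cost Annual app cost per user (euros); never published, so
#'   a required modelling input.
#' @return List of class `"cea_params"`: `vpa` (= v*pi*alpha), `vqa`
#'   (= v*(1-pi)*alpha), `c_m`, `c_b` (euros per incremental claimant),
#'   `app_cost`, `sens0`, `spec0`, and the observed-data ICERs
#'   `icer_full_observed`, `icer_benign_observed`.
#' @export
calibrate_cea <- function(increments, sens0 = 0.87, spec0 = 0.70,
                          app_cost = 16.26) {
  if (increments$d_detect <= 0 || increments$d_benign <= 0)
    stop(errorCondition(
      "calibration needs positive incremental detections and benign claims",
      class = c("dermclaims_calibration_error", "error")))
  if (sens0 <= 0 || sens0 > 1 || spec0 < 0 || spec0 >= 1)
    config_error("sens0 must be in (0,1] and spec0 in [0,1)")
  if (app_cost < 0) config_error("app_cost must be nonnegative")
  par <- list(vpa = increments$d_detect / sens0,
              vqa = increments$d_benign / (1 - spec0),
              c_m = increments$d_cost_malignant / increments$d_detect,
              c_b = increments$d_cost_benign / increments$d_benign,
              app_cost = app_cost, sens0 = sens0, spec0 = spec0)
  par$icer_full_observed <-
    (app_cost + increments$d_cost_benign + increments$d_cost_malignant) /
    increments$d_detect
  par$icer_benign_observed <-
    (app_cost + increments$d_cost_benign) / increments$d_detect
  class(par) <- "cea_params"
  par
}

#' ICER surface over sensitivity and specificity
#'
#' Evaluates, per grid point, the per-user incremental detections
#' `dNm = vpa * sens` and benign claimants `dNb = vqa * (1 - spec)`, and
#' the arm-difference ICERs: the full ICER
#' `(app_cost + dNb*c_b + dNm*c_m) / dNm` (all incremental
#' dermatological costs, including treatment of the additionally
#' detected (pre)malignancies) and the benign-only ICER
#' `(app_cost + dNb*c_b) / dNm`. Grid points with `sens = 0` have no
#' incremental detections; their ICERs are infinite and flagged, not
#' errors.
#'
#' @param params A [calibrate_cea()] result.
#' @param sens,spec Grid vectors of sensitivity and specificity
#'   (defaults 0.50 to 1.00 in steps of 0.05).
#' @return `data.table` in long format: `sens`, `spec`, `d_detect`,
#'   `d_benign`, `icer_full`, `icer_benign_only`, `finite`.
#' @export
icer_surface <- function(params, sens = seq(0.50, 1.00, by = 0.05),
                         spec = seq(0.50, 1.00, by = 0.05)) {
  stopifnot(inherits(params, "cea_params"))
  grid <- CJ(sens = sens, spec = spec)
  grid[, d_detect := params$vpa * sens]
  grid[, d_benign := params$vqa * (1 - spec)]
  grid[, icer_full := (params$app_cost + d_benign * params$c_b +
                         d_detect * params$c_m) / d_detect]
  grid[, icer_benign_only := (params$app_cost + d_benign * params$c_b) /
         d_detect]
  grid[, finite := is.finite(icer_full) & is.finite(icer_benign_only)]
  grid[]
}
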