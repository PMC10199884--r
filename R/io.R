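insuree_cols <- c("person_id", "age", "sex", "ses", "region",
                  "history_premalignancy", "n_comorbidities", "arm")
assessment_cols <- c("person_id", "assessment_index", "cnn_result",
                     "symptoms", "telederm_result")
claim_cols <- c("person_id", "category", "intervention", "setting",
                "year", "cost")

parse_error <- function(file, row, col, msg) {
  stop(errorCondition(
    sprintf("%s: row %s, column '%s': %s", file, row, col, msg),
    class = c("dermclaims_parse_error", "error")))
}

check_enum <- function(x, allowed, file, col) {
  bad <- which(!x %in% allowed)
  if (length(bad) > 0L)
    parse_error(file, bad[1], col,
                sprintf("value '%s' not one of {%s}", x[bad[1]],
                        paste(allowed, collapse = ", ")))
}

#' Write the synthetic data bundle to CSV
#'
#' Writes `insurees.csv`, `assessments.csv`, `claims.csv` and a
#' `manifest.json` recording the seed and a configuration hash. Euro
#' costs are written as fixed two-decimal strings so write/read
#' round-trips are exact.
#'
#' @param bundle A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- copy(bundle$claims)
  cl[, cost := sprintf("%.2f", cost)]
  paths <- file.path(dir, c("insurees.csv", "assessments.csv",
                            "claims.csv", "manifest.json"))
  fwrite(bundle$insurees, paths[1])
  fwrite(bundle$assessments, paths[2])
  fwrite(cl, paths[3])
  jsonlite::write_json(
    list(seed = bundle$config$seed,
         config_hash = rlang::hash(unclass(bundle$config)),
         n_insurees = nrow(bundle$insurees),
         n_assessments = nrow(bundle$assessments),
         n_claims = nrow(bundle$claims)),
    paths[4], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read and validate the three input tables
#'
#' Reads `insurees.csv`, `assessments.csv`, `claims.csv` from `dir`,
#' checking the documented schema: required columns, enum membership
#' (sex, SES, arm, CNN and teledermatologist results, claim category,
#' intervention, setting), ages >= 18 and nonnegative costs. Violations
#' raise a parse error naming file, row and column.
#'
#' @param dir Directory containing the three CSV files.
#' @return List with `insurees`, `assessments`, `claims` data.tables.
#' @export
read_cohort_tables <- function(dir) {
  read_one <- function(file, cols) {
    path <- file.path(dir, file)
    if (!file.exists(path))
      stop(errorCondition(sprintf("missing input table: %s", path),
                          class = c("dermclaims_parse_error", "error")))
    x <- fread(path, colClasses = list(character = "person_id"))
    missing <- setdiff(cols, names(x))
    if (length(missing) > 0L)
      parse_error(file, "header", missing[1], "required column absent")
    x
  }
  ins <- read_one("insurees.csv", insuree_cols)
  if (nrow(ins) > 0L) {
    check_enum(ins$sex, c("male", "female"), "insurees.csv", "sex")
    check_enum(ins$ses, c("low", "middle", "high", "missing"),
               "insurees.csv", "ses")
    check_enum(ins$arm, c("user", "control-pool"), "insurees.csv", "arm")
    bad <- which(ins$age < 18)
    if (length(bad) > 0L)
      parse_error("insurees.csv", bad[1], "age", "age below 18")
  }
  ass <- read_one("assessments.csv", assessment_cols)
  if (nrow(ass) > 0L) {
    check_enum(ass$cnn_result, c("low", "high", "failed"),
               "assessments.csv", "cnn_result")
    check_enum(ass$telederm_result, c("low", "high", "none"),
               "assessments.csv", "telederm_result")
    bad <- which(ass$cnn_result == "failed" & ass$telederm_result != "none")
    if (length(bad) > 0L)
      parse_error("assessments.csv", bad[1], "telederm_result",
                  "failed photos cannot carry a teledermatologist rating")
  }
  cl <- read_one("claims.csv", claim_cols)
  if (nrow(cl) > 0L) {
    check_enum(cl$category, claim_categories(), "claims.csv", "category")
    check_enum(cl$intervention, intervention_codes(), "claims.csv",
               "intervention")
    check_enum(cl$setting, c("primary", "secondary"), "claims.csv",
               "setting")
    cl[, cost := as.numeric(cost)]
    bad <- which(!is.finite(cl$cost) | cl$cost < 0)
    if (length(bad) > 0L)
      parse_error("claims.csv", bad[1], "cost",
                  "costs must be finite and nonnegative")
    bad <- which(cl$intervention %in% primary_interventions() &
                   cl$setting != "primary")
    if (length(bad) > 0L)
      parse_error("claims.csv", bad[1], "setting",
                  "GP interventions must be primary care")
    bad <- which(cl$intervention %in%
                   c("mohs", "hospital_excision_benign",
                     "hospital_excision_premalignant") &
                   cl$setting != "secondary")
    if (length(bad) > 0L)
      parse_error("claims.csv", bad[1], "setting",
                  "hospital interventions must be secondary care")
  } else {
    cl[, cost := as.numeric(cost)]
  }
  list(insurees = ins, assessments = ass, claims = cl)
}

#' Published aggregate inputs of the reference cohort
#'
#' Loads the transcribed published aggregate tables of the evaluated
#' cohort (person-level claimant counts overall and by risk subgroup,
#' intervention claim volumes, assessment marginals, cost aggregates and
#' the calibration accuracy) shipped as plain-text inputs under
#' `extdata/`. These printed aggregates are inputs to the exact
#' recomputation checks and to the cost-effectiveness calibration.
#'
#' @return List with `person_counts`, `claim_volumes` data.tables and
#'   `aggregates` (named numeric vector).
#' @export
study_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "dermclaims",
                                  mustWork = TRUE)
  agg <- fread(path("study_aggregates.csv"))
  list(person_counts = fread(path("study_person_counts.csv")),
       claim_volumes = fread(path("study_claim_volumes.csv")),
       aggregates = setNames(agg$value, agg$item))
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, match, claims association analyses (overall, risk
#' subgroups, history subgroup), intervention rates, cost summaries and
#' the cost-effectiveness model, optionally writing all result tables
#' and a manifest to `out_dir`. Deterministic given `seed`.
#'
#' @param config A [generator_config()] for the synthetic stage.
#' @param seed Integer master seed (overrides `config$seed`).
#' @param ratio Matching ratio.
#' @param app_cost,sens0,spec0 Cost-effectiveness inputs, see
#'   [calibrate_cea()].
#' @param out_dir Optional output directory for CSV tables and manifest.
#' @return List bundle with all stage outputs.
#' @export
run_pipeline <- function(config = generator_config(), seed = NULL,
                         ratio = 3L, app_cost = 16.26, sens0 = 0.87,
                         spec0 = 0.70, out_dir = NULL) {
  sim <- simulate_cohort(config, seed)
  cohort <- match_cohort(sim$insurees[arm == "user"],
                         sim$insurees[arm == "control-pool"],
                         ratio = ratio, seed = sim$config$seed + 1L)
  persons <- analysis_set(cohort)
  report <- matching_report(cohort, sim$insurees)

  assoc_overall <- association_table(persons, sim$claims)
  split <- subgroup_split(persons[arm == "user", person_id],
                          sim$assessments)
  sub_out <- c(as.list(setNames(claim_categories(), claim_categories())),
               list(nevi_benign = c("nevus", "benign_tumor")))
  assoc_high <- association_table(subcohort(cohort, split$high_risk),
                                  sim$claims, sub_out)
  assoc_low <- association_table(subcohort(cohort, split$low_risk),
                                 sim$claims, sub_out)
  hist_set <- history_subgroup(sim$insurees, cohort)
  assoc_history <- if (sum(hist_set$arm == "user") > 0L &&
                         sum(hist_set$arm == "control") > 0L)
    association_table(hist_set, sim$claims) else NULL
  rates <- intervention_rates(persons, sim$claims)
  costs <- cost_summary(sim$claims, persons)
  inc <- observed_increments(persons, sim$claims)
  cea <- calibrate_cea(inc, sens0 = sens0, spec0 = spec0,
                       app_cost = app_cost)
  surface <- icer_surface(cea)

  bundle <- list(sim = sim, cohort = cohort, persons = persons,
                 matching = report, assoc_overall = assoc_overall,
                 subgroups = split, assoc_high = assoc_high,
                 assoc_low = assoc_low, assoc_history = assoc_history,
                 rates = rates, costs = costs, increments = inc,
                 cea = cea, surface = surface)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_tables(sim, out_dir)
    fwrite(cohort$matches, file.path(out_dir, "matched_cohort.csv"))
    fwrite(report$tiers, file.path(out_dir, "matching_tiers.csv"))
    fwrite(report$balance, file.path(out_dir, "matching_balance.csv"))
    fwrite(assoc_overall, file.path(out_dir, "associations.csv"))
    fwrite(assoc_high, file.path(out_dir, "associations_high_risk.csv"))
    fwrite(assoc_low, file.path(out_dir, "associations_low_risk.csv"))
    if (!is.null(assoc_history))
      fwrite(assoc_history, file.path(out_dir, "associations_history.csv"))
    fwrite(rates, file.path(out_dir, "intervention_rates.csv"))
    fwrite(costs, file.path(out_dir, "costs.csv"))
    fwrite(surface, file.path(out_dir, "icer_surface.csv"))
    jsonlite::write_json(
      list(seed = sim$config$seed,
           config_hash = rlang::hash(unclass(sim$config)),
           stages = list(
             simulate = list(insurees = nrow(sim$insurees),
                             assessments = nrow(sim$assessments),
                             claims = nrow(sim$claims)),
             match = as.list(setNames(report$tiers$n, report$tiers$tier)),
             analyze = list(users = sum(persons$arm == "user"),
                            controls = sum(persons$arm == "control")),
             cea = list(icer_observed = cea$icer_full_observed))),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
  }
  invisible(bundle)
}
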