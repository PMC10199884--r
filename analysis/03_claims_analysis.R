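#!/usr/bin/env Rscript
# Stage 3: person-level claims association analyses: odds ratios per
# diagnosis category overall, by app risk feedback subgroup, and in the
# positive-history subgroup; plus intervention claim volumes per 1000
# persons.

suppressMessages({library(dermclaims); library(data.table)})
seed <- 2019L

d <- read_cohort_tables("results/data")
cohort <- match_cohort(d$insurees[arm == "user"],
                       d$insurees[arm == "control-pool"],
                       ratio = 3, seed = seed + 1L)
persons <- analysis_set(cohort)

assoc <- association_table(persons, d$claims)
fwrite(assoc, "results/associations.csv")
cat("overall person-level associations (app users vs matched controls):\n")
print(assoc[, .(outcome, pct_users, pct_controls, odds_ratio, ci_low,
                ci_high, p_adjusted)])

split <- subgroup_split(persons[arm == "user", person_id], d$assessments)
outs <- c(as.list(setNames(claim_categories(), claim_categories())),
          list(nevi_benign = c("nevus", "benign_tumor")))
assoc_high <- association_table(subcohort(cohort, split$high_risk),
                                d$claims, outs)
assoc_low <- association_table(subcohort(cohort, split$low_risk),
                               d$claims, outs)
fwrite(assoc_high, "results/associations_high_risk.csv")
fwrite(assoc_low, "results/associations_low_risk.csv")
cat(sprintf("\n%.1f%% of users had at least one high-risk assessment\n",
            100 * length(split$high_risk) /
              (length(split$high_risk) + length(split$low_risk))))
cat(sprintf("nevi+benign OR: %.2f (high-risk users), %.2f (low-risk users)\n",
            assoc_high[outcome == "nevi_benign", odds_ratio],
            assoc_low[outcome == "nevi_benign", odds_ratio]))

hist_set <- history_subgroup(d$insurees, cohort)
assoc_hist <- association_table(hist_set, d$claims)
fwrite(assoc_hist, "results/associations_history.csv")

rates <- intervention_rates(persons, d$claims)
fwrite(rates, "results/intervention_rates.csv")
cat("\nintervention claims per 1000 persons:\n")
print(rates[, .(intervention, rate_users, rate_controls, delta)])
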