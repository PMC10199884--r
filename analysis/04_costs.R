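#!/usr/bin/env Rscript
# Stage 4: annual dermatological costs per person and per claim, by
# diagnosis category and arm (secondary/tertiary claims, matching the
# costing scope of the claims analyses).

suppressMessages({library(dermclaims); library(data.table)})
seed <- 2019L

d <- read_cohort_tables("results/data")
cohort <- match_cohort(d$insurees[arm == "user"],
                       d$insurees[arm == "control-pool"],
                       ratio = 3, seed = seed + 1L)
persons <- analysis_set(cohort)

costs <- cost_summary(d$claims, persons)
fwrite(costs, "results/costs.csv")
print(costs[, .(category, mean_per_person_users, mean_per_person_controls,
                delta, p_adjusted)])
all_row <- costs[category == "all"]
cat(sprintf("\nannual cost per person: users EUR %.2f vs controls EUR %.2f (delta %.2f, 95%% CI %.2f-%.2f)\n",
            all_row$mean_per_person_users, all_row$mean_per_person_controls,
            all_row$delta, all_row$delta_ci_low, all_row$delta_ci_high))
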