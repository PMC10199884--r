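#!/usr/bin/env Rscript
# Stage 5: short-term cost-effectiveness. Calibrates the detection
# cascade at the app's published accuracy (sens 0.87, spec 0.70) on the
# observed arm-level increments and evaluates the ICER over the
# sensitivity x specificity grid.

suppressMessages({library(dermclaims); library(data.table)})
seed <- 2019L

d <- read_cohort_tables("results/data")
cohort <- match_cohort(d$insurees[arm == "user"],
                       d$insurees[arm == "control-pool"],
                       ratio = 3, seed = seed + 1L)
persons <- analysis_set(cohort)

inc <- observed_increments(persons, d$claims)
par <- calibrate_cea(inc, sens0 = 0.87, spec0 = 0.70, app_cost = 16.26)
surf <- icer_surface(par)
fwrite(surf, "results/icer_surface.csv")

cat(sprintf("incremental detections per user: %.4f; benign claimants: %.4f\n",
            inc$d_detect, inc$d_benign))
cat(sprintf("ICER at calibration accuracy: EUR %.0f per additional (pre)malignancy detected\n",
            par$icer_full_observed))
cat(sprintf("  benign-costs-only ICER:     EUR %.0f\n",
            par$icer_benign_observed))
cat(sprintf("ICER at perfect accuracy:     EUR %.0f (full), EUR %.0f (benign only)\n",
            surf[sens == 1 & spec == 1, icer_full],
            surf[sens == 1 & spec == 1, icer_benign_only]))
cat(sprintf("ICER range over the grid:     EUR %.0f - %.0f\n",
            surf[, min(icer_benign_only)], surf[, max(icer_full)]))
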