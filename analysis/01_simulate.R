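#!/usr/bin/env Rscript
# Stage 1: generate the synthetic insured population, app-usage logs and
# claims at near-study scale (400,000 insurees, 5% uptake -> ~20,000 app
# users) and write the three input tables plus a manifest.

suppressMessages(library(dermclaims))
seed <- 2019L

cfg <- generator_config(n_population = 400000L, uptake_rate = 0.05,
                        seed = seed)
bundle <- simulate_cohort(cfg)
write_cohort_tables(bundle, "results/data")

cat(sprintf("insurees: %d (%d app users)\n", nrow(bundle$insurees),
            sum(bundle$insurees$arm == "user")))
cat(sprintf("assessments: %d (%.1f%% CNN high risk, %.1f%% failed)\n",
            nrow(bundle$assessments),
            100 * mean(bundle$assessments$cnn_result == "high"),
            100 * mean(bundle$assessments$cnn_result == "failed")))
cat(sprintf("claims: %d\n", nrow(bundle$claims)))
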