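#!/usr/bin/env Rscript
# Predictive validity on the synthetic study: team-wise Spearman
# correlations between SSG and 11-vs-11 player scores per indicator (and
# between the physiological tests and the 11-vs-11 composites), aggregated
# by DerSimonian-Laird random-effects meta-analysis, with Cohen magnitude
# labels. The generator's rho = 0.6 sets the true cross-format
# consistency, so moderate aggregated coefficients are the expected
# picture for the rate indicators.
#
# Run analysis/02 and 03 first (03 writes the pipeline bundle reused here).

suppressMessages(library(ssgvalidity))

study <- read_study("results/synthetic")
res <- run_pipeline(study$events, study$roster, study$games)

cat("SSG scores vs 11-vs-11 scores, aggregated over the four teams:\n")
print(res$validity_indicators, n = 20)

cat("\nPhysiological/motor tests vs 11-vs-11 composites:\n")
print(res$validity_tests, n = 10)

readr::write_csv(res$validity_indicators, "results/validity_indicators.csv")
readr::write_csv(res$validity_tests, "results/validity_tests.csv")
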