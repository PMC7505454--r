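#!/usr/bin/env Rscript
# Score every retained player of the synthetic study: per-bout rates for
# the count indicators, random-intercept logistic posterior scores for the
# binary indicators, success-proxy-derived weights, and the overall
# offensive/defensive composites. Writes the full pipeline report bundle
# under results/pipeline/.
#
# Run analysis/02_simulate_study.R first.

suppressMessages(library(ssgvalidity))

study <- read_study("results/synthetic")
res <- run_pipeline(study$events, study$roster, study$games,
                    out_dir = "results/pipeline")
print(res)

cat("\nDerived indicator weights (aggregated proxy correlations):\n")
print(res$weights[, c("indicator", "side", "weight", "ci_low", "ci_high")])

cat("\nTop five offensive players (11-vs-11 composite):\n")
top <- res$composites$M11[order(-res$composites$M11$offensive), ][1:5, ]
print(top)
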