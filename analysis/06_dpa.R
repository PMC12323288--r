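#!/usr/bin/env Rscript
# Stage 6: divergence point analysis.
#
# Estimates, per group, the onset of sustained target-over-agent-related
# looking in the 750-2500 ms window (first 200-ms run of one-sided
# significant bins) and bootstraps participants (1000 iterations) for
# percentile CIs and a proportion-based test of the group difference.
#
# Input (results/): tensor.csv
# Outputs (results/): divergence.csv, difference.csv

suppressMessages(library(vwpred))

seed <- 1
out_dir <- "results"
tensor <- read_result(file.path(out_dir, "tensor.csv"))

dpa <- bootstrap_divergence(tensor, groups = c("autistic", "nt"),
                            n_boot = 1000, seed = seed * 8 + 6)
print(dpa)
write_results(list(divergence = dpa$per_group,
                   difference = dpa$difference), out_dir)
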