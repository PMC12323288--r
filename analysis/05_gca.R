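#!/usr/bin/env Rscript
# Stage 5: growth-curve analysis of the log-gaze proportion ratio.
#
# Fits linear mixed models of the trial-level log-ratio on orthogonal
# time polynomials, group, and their interactions, with random intercepts
# for participants and trials (NT group as reference). The polynomial
# order is chosen by forward likelihood-ratio tests up to the quintic;
# the selected-order REML fit is reported.
#
# Input (results/): tensor.csv
# Outputs (results/): growth.csv, growth_varcor.csv, order_table.csv

suppressMessages(library(vwpred))

out_dir <- "results"
tensor <- read_result(file.path(out_dir, "tensor.csv"))
series <- log_ratio_series(tensor, "trial")

message("Selecting polynomial order (ML likelihood-ratio tests) ...")
sel <- select_order(series, k_max = 5, ref_group = "nt")
message("Selected order: k = ", sel$k)
print(as.data.frame(sel$table), digits = 4, row.names = FALSE)

fit <- fit_growth_model(series, k = sel$k, ref_group = "nt")
print(fit)
write_results(list(growth = fit$coefficients,
                   growth_varcor = fit$varcor,
                   order_table = sel$table), out_dir)
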