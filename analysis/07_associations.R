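#!/usr/bin/env Rscript
# Stage 7: individual differences and behavioral accuracy.
#
# Correlates the two prediction-efficiency indices with CARS (autistic
# group) and AQ total / subscale scores (both groups; BH-FDR within each
# five-subscale family), and fits the logistic mixed model of per-trial
# accuracy on group.
#
# Input (results/): tensor.csv (indirectly via indices.csv), indices.csv,
#   scores.csv, responses.csv
# Outputs (results/): correlations.csv, accuracy.csv

suppressMessages(library(vwpred))

out_dir <- "results"
indices <- read_result(file.path(out_dir, "indices.csv"))
scores <- read_result(file.path(out_dir, "scores.csv"))
responses <- read_result(file.path(out_dir, "responses.csv"))

cors <- correlation_suite(indices, scores)
message("Correlations with AQ total and CARS:")
main <- cors[cors$measure %in% c("aq_total", "cars_total"), ]
print(as.data.frame(main[, c("group", "index", "measure", "n", "r", "p",
                             "ci_lo", "ci_hi")]),
      digits = 3, row.names = FALSE)

acc <- suppressWarnings(accuracy_model(responses, ref_group = "nt"))
print(acc)

acc_tbl <- if (acc$separation) {
  tibble::tibble(term = "groupautistic", estimate = NA_real_,
                 se = NA_real_, z = NA_real_, p = NA_real_,
                 separation = TRUE)
} else {
  dplyr::mutate(acc$coefficients, separation = FALSE)
}
write_results(list(correlations = cors, accuracy = acc_tbl), out_dir)
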