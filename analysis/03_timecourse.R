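#!/usr/bin/env Rscript
# Stage 3: fixation-proportion curves, log-gaze proportion ratios, and
# per-participant prediction-efficiency indices.
#
# The log-ratio index averages log((target + 0.5) / (unrelated + 0.5))
# over the prediction window (0-1300 ms, bins 0-25); the individual
# divergence point is the start of the first 200-ms run in which a
# participant's target proportion exceeds the agent-related proportion
# after verb onset.
#
# Input (results/): tensor.csv
# Outputs (results/): curves.csv, indices.csv

suppressMessages(library(vwpred))

out_dir <- "results"
tensor <- read_result(file.path(out_dir, "tensor.csv"))

curves <- proportion_curves(tensor)
indices <- participant_indices(tensor)
write_results(list(curves = curves, indices = indices), out_dir)

message("Mean log-ratio index by group:")
print(round(tapply(indices$log_ratio_index, indices$group, mean), 3))
message("Participants without a defined individual divergence point: ",
        sum(is.na(indices$individual_dp_ms)))

# diagnostic curve export (optional plot)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(time_ms, prop, colour = condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lo, ymax = ci_hi,
                                      fill = condition),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group) +
    ggplot2::geom_vline(xintercept = c(750, 1300, 2100), linetype = 3) +
    ggplot2::labs(x = "Time from sentence onset (ms)",
                  y = "Fixation proportion")
  ggplot2::ggsave(file.path(out_dir, "curves.pdf"), p,
                  width = 9, height = 4)
  message("Wrote ", file.path(out_dir, "curves.pdf"))
}
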