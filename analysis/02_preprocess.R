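#!/usr/bin/env Rscript
# Stage 2: raw gaze -> binned fixation tensor.
#
# Runs the I-VT fixation filter (75-ms gap interpolation, binocular
# averaging, 30 deg/s velocity threshold, 75-ms/0.5-degree merging,
# 100-ms minimum duration), assigns fixations to the four 384x384-px
# AOIs, and binary-codes occupancy into 50-ms bins over 0-2500 ms.
#
# Input (results/): gaze.tsv, designs.csv, scores.csv
# Output (results/): tensor.csv (long format)

suppressMessages(library(vwpred))

out_dir <- "results"
gaze <- read_gaze_table(file.path(out_dir, "gaze.tsv"))
designs <- read_result(file.path(out_dir, "designs.csv"))
scores <- read_result(file.path(out_dir, "scores.csv"))

message("Detecting fixations for ",
        length(unique(gaze$participant_id)), " participants ...")
tensor <- preprocess_cohort(
  gaze, designs,
  groups = dplyr::distinct(scores, participant_id, group)
)
write_results(list(tensor = tensor), out_dir)

occ <- colMeans(tensor[c("target", "agent_related", "action_related",
                         "unrelated")])
message("Overall AOI occupancy rates (fraction of bins coded 1):")
print(round(occ, 3))
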