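#!/usr/bin/env Rscript
# Stage 5: image-withdrawal robustness of the in-group < out-group bias gap.
#
# Withdraws one in-group and one out-group face per subject in every possible
# combination (3^4 x 3^4 = 6561), recomputes per-day biases from the retained
# faces, and tests the in/out difference per combination with a two-sided
# Wilcoxon signed-rank test.

suppressPackageStartupMessages(library(socattn))

data_dir <- "results/data"
out <- "results"

trials <- read_trials_csv(file.path(data_dir, "trials_saline.csv"))
bias_face <- distractor_bias_by_face(drifting_time_table(trials))
message("Per-face bias cells: ", nrow(bias_face))

rb <- withdrawal_robustness(bias_face, alpha = 0.05)
print(rb)
message(sprintf("in-group minus out-group bias, mean over combinations: %.1f ms",
                mean(rb$mean_diffs, na.rm = TRUE)))
write_robustness(rb, file.path(out, "withdrawal_robustness.json"))
message("Report written to ", file.path(out, "withdrawal_robustness.json"))
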