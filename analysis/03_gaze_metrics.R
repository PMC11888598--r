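#!/usr/bin/env Rscript
# Stage 3: attention statistics from the trial tables.
#
# Computes drifting times (intact minus scrambled RT per cell), distractor
# biases per subject-day for in-group / out-group faces, and the first-saccade
# capture-probability differences, for each drug condition.

suppressPackageStartupMessages(library(socattn))

data_dir <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (cond in c("saline", "ot")) {
  trials <- read_trials_csv(file.path(data_dir, sprintf("trials_%s.csv", cond)))
  message(toupper(cond), ": ", nrow(trials), " trials, ",
          sum(!trials$valid), " discarded for fixation breaks")

  dt <- drifting_time_table(trials)
  write.csv(dt, file.path(out, sprintf("drifting_times_%s.csv", cond)),
            row.names = FALSE, quote = FALSE)

  bias <- rbind(distractor_bias_table(dt, "in"),
                distractor_bias_table(dt, "out"))
  write.csv(bias, file.path(out, sprintf("distractor_bias_%s.csv", cond)),
            row.names = FALSE, quote = FALSE)
  agg <- aggregate(bias_ms ~ group, bias, function(x) c(mean = mean(x), sd = sd(x)))
  message("  mean bias (ms): ",
          paste(agg$group, sprintf("%.1f +/- %.1f", agg$bias_ms[, "mean"],
                                   agg$bias_ms[, "sd"]), collapse = "; "))

  # capture probabilities, pooled per subject over days
  fs <- do.call(rbind, lapply(unique(trials$subject), function(s) {
    r <- first_saccade_prob_diff(trials, subject = s)
    data.frame(subject = s, p_intact = r$p_intact, p_scrambled = r$p_scrambled,
               diff = r$diff)
  }))
  write.csv(fs, file.path(out, sprintf("first_saccade_%s.csv", cond)),
            row.names = FALSE, quote = FALSE)
  message("  first-saccade capture difference (intact - scrambled): ",
          paste(sprintf("%s %.2f", fs$subject, fs$diff), collapse = ", "))
}
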