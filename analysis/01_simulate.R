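#!/usr/bin/env Rscript
# Stage 1: simulate a complete study at the default conditions.
#
# Writes the colony event log, the per-dimension score matrices, and the
# saline/OT trial tables under results/data/, together with the generative
# ground truth so later stages can be judged against it.

suppressPackageStartupMessages(library(socattn))

seed <- 20260919
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- study_config()
message("Simulating: ", length(cfg$roster), " subjects, ", cfg$n_days,
        " days x ", cfg$sessions_per_day, " sessions (seed ", seed, ")")
bundle <- gen_full_study(cfg, seed)

write_events_csv(bundle$events, file.path(out, "events.csv"))
for (d in SOC_DIMENSIONS) {
  write_score_matrix(bundle$matrices[[d]],
                     file.path(out, sprintf("score_matrix_%s.csv", d)))
}
write_trials_csv(bundle$trials_saline, file.path(out, "trials_saline.csv"))
write_trials_csv(bundle$trials_ot, file.path(out, "trials_ot.csv"))
jsonlite::write_json(
  lapply(bundle$ground_truth, function(v) if (is.null(names(v))) v else as.list(v)),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

message("Event log: ", nrow(bundle$events), " directed interactions")
message("Trials per condition: ", nrow(bundle$trials_saline))
message("Ground-truth omega* = (",
        paste(sprintf("%.2f", cfg$omega_star), collapse = ", "),
        "), coupling a = ", cfg$a, ", b = ", cfg$b,
        ", OT slope multiplier ", cfg$ot_slope_multiplier)
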