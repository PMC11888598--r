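#!/usr/bin/env Rscript
# Stage 4: exhaustive weight grid search linking engagement to attention.
#
# For each condition: SEI weights against in-group and out-group biases
# (most-negative-r objective) and IEI weights against per-face in-group biases
# (most-positive-r objective), on the 0.02 grid. Checks the recovered
# directions against the simulation's ground truth and summarizes the group
# spread with pairwise SEI differences.

suppressPackageStartupMessages(library(socattn))

data_dir <- "results/data"
out <- "results"
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
omega_star <- unlist(truth$omega_star)
cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

events <- read_events_csv(file.path(data_dir, "events.csv"))
roster <- jsonlite::read_json(file.path(data_dir, "score_matrix_aggression.csv.json"),
                              simplifyVector = TRUE)$roster
matrices <- build_score_matrices(events, roster)

for (cond in c("saline", "ot")) {
  trials <- read_trials_csv(file.path(data_dir, sprintf("trials_%s.csv", cond)))
  dt <- drifting_time_table(trials)
  message("\n== ", toupper(cond), " ==")
  for (g in c("in", "out")) {
    bias <- distractor_bias_table(dt, g)
    gs <- grid_search_weights(bias, matrices, "sei", step = 0.02)
    message(sprintf("SEI vs %s-group bias: best r = %.3f at (%.2f, %.2f, %.2f), slope %.2f; cosine to omega* = %.3f",
                    g, gs$best_r, gs$canonical[1], gs$canonical[2],
                    gs$canonical[3], gs$fit$slope,
                    cosine(gs$canonical, omega_star)))
    write_grid_search(gs, file.path(out, sprintf("fit_sei_%s_%s.json", g, cond)),
                      surface_csv = file.path(out, sprintf("surface_sei_%s_%s.csv", g, cond)))
    if (g == "in") {
      pd <- pairwise_index_differences(compute_sei(matrices, gs$canonical))
      message(sprintf("  pairwise SEI differences: %.2f +/- %.2f over %d pairs",
                      pd$mean, pd$sd, pd$n_pairs))
      write.csv(pd$differences, file.path(out, sprintf("sei_pairwise_%s.csv", cond)),
                row.names = FALSE, quote = FALSE)
    }
  }
  bias_face <- distractor_bias_by_face(dt, "in")
  gi <- grid_search_weights(bias_face, matrices, "iei", step = 0.02)
  message(sprintf("IEI vs per-face in-group bias: best r = %.3f at (%.2f, %.2f, %.2f)",
                  gi$best_r, gi$canonical[1], gi$canonical[2], gi$canonical[3]))
  write_grid_search(gi, file.path(out, sprintf("fit_iei_in_%s.json", cond)))
}
message("\nGrid-search reports and r-surfaces written under ", out)
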