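#!/usr/bin/env Rscript
# Stage 2: dichotomous interaction scoring.
#
# Rebuilds the +1/-1 score matrices from the raw event log (independently of
# what stage 1 wrote), summarizes the colony's engagement structure at equal
# weights, and reports the per-dimension dominance picture.

suppressPackageStartupMessages(library(socattn))

data_dir <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

events <- read_events_csv(file.path(data_dir, "events.csv"))
roster <- jsonlite::read_json(file.path(data_dir, "score_matrix_aggression.csv.json"),
                              simplifyVector = TRUE)$roster
message(nrow(events), " events over ", length(roster), " subjects")

matrices <- build_score_matrices(events, roster)
for (d in SOC_DIMENSIONS) {
  message("\n", d, " scores (rows = actor credit):")
  print(unclass(matrices[[d]]))
  stored <- read_score_matrix(file.path(data_dir, sprintf("score_matrix_%s.csv", d)))
  stopifnot(identical(unclass(stored), unclass(matrices[[d]])))
}

# equal-weight engagement indices: the simplest summary of the network
sei <- compute_sei(matrices, c(1, 1, 1))
message("\nSEI at equal weights (sums to ", sum(sei), " by antisymmetry):")
print(sei)
iei <- engagement_index_table(matrices, c(1, 1, 1), "iei")
write.csv(iei, file.path(out, "iei_equal_weights.csv"), row.names = FALSE,
          quote = FALSE)
write.csv(data.frame(subject = names(sei), sei = unname(sei)),
          file.path(out, "sei_equal_weights.csv"), row.names = FALSE,
          quote = FALSE)
message("Wrote SEI/IEI tables at equal weights under ", out)
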