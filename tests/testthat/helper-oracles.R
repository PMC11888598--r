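# Independent oracles and small fixture builders, kept deliberately naive so
# they stay independent of the implementation paths they check.

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# brute-force per-dyad majority scoring: recount events with explicit loops
naive_score_matrix <- function(events, roster, dimension, mode = "count") {
  n <- length(roster)
  S <- matrix(0L, n, n, dimnames = list(roster, roster))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sel_ij <- events$dimension == dimension &
      events$actor == roster[i] & events$recipient == roster[j]
    sel_ji <- events$dimension == dimension &
      events$actor == roster[j] & events$recipient == roster[i]
    a <- if (mode == "count") sum(sel_ij) else sum(events$duration_s[sel_ij])
    b <- if (mode == "count") sum(sel_ji) else sum(events$duration_s[sel_ji])
    # a = initiated by i toward j; grooming credit goes to the receiver
    ci <- if (dimension == "grooming") b else a
    cj <- if (dimension == "grooming") a else b
    S[i, j] <- if (ci > cj) 1L else if (cj > ci) -1L else 0L
  }
  S
}

# random event log over a roster (uniform dyads/dimensions)
rand_event_log <- function(n_events, roster, seed) {
  set.seed(seed)
  if (n_events == 0) {
    return(data.frame(session_id = character(0), time_s = numeric(0),
                      actor = character(0), recipient = character(0),
                      dimension = character(0), duration_s = numeric(0)))
  }
  actor <- sample(roster, n_events, replace = TRUE)
  recipient <- vapply(actor, function(a) sample(setdiff(roster, a), 1), "")
  data.frame(session_id = "s1", time_s = round(runif(n_events, 0, 3600), 1),
             actor = actor, recipient = unname(recipient),
             dimension = sample(SOC_DIMENSIONS, n_events, replace = TRUE),
             duration_s = round(runif(n_events, 0, 60), 1))
}

# random antisymmetric {-1,0,1} score matrices for all three dimensions
rand_score_matrices <- function(roster, seed) {
  set.seed(seed)
  out <- lapply(SOC_DIMENSIONS, function(d) {
    n <- length(roster)
    S <- matrix(0L, n, n, dimnames = list(roster, roster))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      s <- sample(c(-1L, 0L, 1L), 1)
      S[i, j] <- s; S[j, i] <- -s
    }
    structure(S, class = c("score_matrix", "matrix"), dimension = d, mode = "count")
  })
  names(out) <- SOC_DIMENSIONS
  out
}

# trial table with constant RTs per cell, one row per trial
make_cell_trials <- function(cells, subject = "MA", day = 1, n_per_cell = 4) {
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    ce <- cells[k, ]
    data.frame(subject = subject, day = day, drug_condition = "none",
               trial_type = "interference", distractor_id = ce$face,
               distractor_class = ce$class, group = ce$group,
               congruency = ce$congruency,
               rt_ms = rep(ce$rt, ce$n %||% n_per_cell),
               first_sacc_to_distractor = NA, valid = TRUE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive grid search: explicit triple loop over the weight grid, cor() per point
naive_grid_search <- function(bias, matrices, step, objective = "most_negative_r") {
  g <- seq(0, 1, by = step)
  X <- sapply(matrices[c("aggression", "grooming", "proximity")],
              function(S) rowSums(unclass(S)))
  idx_of <- function(w) drop(X %*% w)[as.character(bias$subject)]
  out <- list()
  for (wa in g) for (wg in g) for (wp in g) {
    w <- c(wa, wg, wp)
    if (all(w == 0)) next
    x <- idx_of(w)
    if (var(x) < 1e-12) next
    out[[length(out) + 1]] <- c(w, r = cor(x, bias$bias_ms))
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("omega_a", "omega_g", "omega_p", "r")
  best <- if (objective == "most_negative_r") min(m[, "r"]) else max(m[, "r"])
  list(surface = m, best_r = best)
}

# small study configs used across tests (kept cheap); overrides win
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_days = 4, sessions_per_day = 2, obs_sessions = 4),
                            list(...))
  do.call(study_config, args)
}
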