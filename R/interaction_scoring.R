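#' @importFrom stats rbinom rexp rnorm rpois runif sd var complete.cases
#' @importFrom utils read.csv write.csv combn head
NULL

#' Behavioral dimensions recognized by the scoring framework
#'
#' The three dimensions of dyadic interaction scored in the colony:
#' `"proximity"`, `"grooming"`, `"aggression"`.
#'
#' @export
SOC_DIMENSIONS <- c("proximity", "grooming", "aggression")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a behavioral event log
#'
#' Checks the event table contract: required columns, non-negative times and
#' durations, recognized dimensions, actor != recipient, and (optionally) that
#' all subjects belong to a roster.
#'
#' @param events data.frame with columns `session_id`, `time_s`, `actor`,
#'   `recipient`, `dimension`, `duration_s`.
#' @param roster optional character vector of subject ids; if given, any actor
#'   or recipient outside the roster is an error.
#' @return the events, invisibly, with `dimension` as character.
#' @export
validate_events <- function(events, roster = NULL) {
  req <- c("session_id", "time_s", "actor", "recipient", "dimension", "duration_s")
  miss <- setdiff(req, names(events))
  if (length(miss)) stop("event log missing columns: ", paste(miss, collapse = ", "))
  events$dimension <- as.character(events$dimension)
  events$actor <- as.character(events$actor)
  events$recipient <- as.character(events$recipient)
  if (nrow(events)) {
    bad <- setdiff(unique(events$dimension), SOC_DIMENSIONS)
    if (length(bad)) stop("unknown behavioral dimension(s): ", paste(bad, collapse = ", "))
    if (any(events$actor == events$recipient)) stop("events with actor == recipient are invalid")
    if (any(events$duration_s < 0)) stop("negative event duration")
    if (any(events$time_s < 0)) stop("negative event time")
    if (!is.null(roster)) {
      unk <- setdiff(unique(c(events$actor, events$recipient)), roster)
      if (length(unk)) stop("subject id(s) not in roster: ", paste(unk, collapse = ", "))
    }
  }
  invisible(events)
}

#' Tally directed interactions within one dyad and dimension
#'
#' Aggregates an event log into the two directed totals for an ordered dyad
#' `(i, j)`, either as event counts or as total durations. Events belonging to
#' other dyads or dimensions are ignored.
#'
#' @param events behavioral event log (see [validate_events()]).
#' @param dyad character vector of two subject ids `c(i, j)`.
#' @param dimension one of `"proximity"`, `"grooming"`, `"aggression"`.
#' @param mode `"count"` (default) compares numbers of events; `"duration"`
#'   compares summed durations. Exposed because field practice mixes both
#'   (approach counts vs time spent in aggressive engagement).
#' @param roster optional roster for validation.
#' @return object of class `directed_tally`: list with `dyad`, `dimension`,
#'   `i_to_j`, `j_to_i`, `mode`.
#' @export
tally_interactions <- function(events, dyad, dimension, mode = c("count", "duration"),
                               roster = NULL) {
  mode <- match.arg(mode)
  dimension <- match.arg(dimension, SOC_DIMENSIONS)
  stopifnot(length(dyad) == 2)
  dyad <- as.character(dyad)
  if (dyad[1] == dyad[2]) stop("dyad members must differ")
  events <- validate_events(events, roster)
  if (!is.null(roster)) {
    unk <- setdiff(dyad, roster)
    if (length(unk)) stop("subject id(s) not in roster: ", paste(unk, collapse = ", "))
  }
  sel <- events$dimension == dimension &
    ((events$actor == dyad[1] & events$recipient == dyad[2]) |
       (events$actor == dyad[2] & events$recipient == dyad[1]))
  ev <- events[sel, , drop = FALSE]
  w <- if (mode == "count") rep(1, nrow(ev)) else ev$duration_s
  structure(list(
    dyad = dyad, dimension = dimension,
    i_to_j = sum(w[ev$actor == dyad[1]]),
    j_to_i = sum(w[ev$actor == dyad[2]]),
    mode = mode
  ), class = "directed_tally")
}

#' Dichotomous score for one dyad
#'
#' Applies the +1/-1 scoring convention: within a dyad and dimension, the
#' subject on the "winning" side of the directed comparison scores +1 and the
#' other -1; with no interactions, or a tie, both score 0.
#'
#' Direction semantics differ by dimension:
#' * proximity: +1 to the subject who approaches more (the more frequent actor);
#' * grooming: +1 to the subject who *receives* more grooming (event actor is
#'   the groomer, so credit goes against the actor direction);
#' * aggression: +1 to the subject who initiates more.
#'
#' @param tally a `directed_tally` from [tally_interactions()].
#' @return named integer vector of length 2 (scores for `dyad[1]`, `dyad[2]`),
#'   each in `{-1, 0, 1}`.
#' @export
score_dyad <- function(tally) {
  stopifnot(inherits(tally, "directed_tally"))
  a <- tally$i_to_j   # initiated by i
  b <- tally$j_to_i   # initiated by j
  # credit_i: the quantity that earns i the +1 when strictly larger
  if (tally$dimension == "grooming") {
    credit_i <- b; credit_j <- a        # i receives what j initiates
  } else {
    credit_i <- a; credit_j <- b        # approach / initiated aggression
  }
  s <- if (credit_i > credit_j) c(1L, -1L) else if (credit_j > credit_i) c(-1L, 1L) else c(0L, 0L)
  names(s) <- tally$dyad
  s
}

#' Build an antisymmetric score matrix for one dimension
#'
#' Scores every dyad in the roster over the full event log and assembles the
#' N x N interaction score matrix S with `S[i, j] = -S[j, i]`, entries in
#' `{-1, 0, 1}` and zero diagonal.
#'
#' @inheritParams tally_interactions
#' @param roster character vector of N >= 2 distinct subject ids; fixes row and
#'   column order.
#' @return object of class `score_matrix`: an integer matrix with `dimnames`
#'   equal to the roster and attributes `dimension` and `mode`.
#' @export
build_score_matrix <- function(events, roster, dimension, mode = c("count", "duration")) {
  mode <- match.arg(mode)
  dimension <- match.arg(dimension, SOC_DIMENSIONS)
  roster <- as.character(roster)
  if (length(roster) < 2) stop("roster must contain at least 2 subjects")
  if (anyDuplicated(roster)) stop("roster contains duplicate subject ids")
  validate_events(events, roster)
  n <- length(roster)
  S <- matrix(0L, n, n, dimnames = list(roster, roster))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sc <- score_dyad(tally_interactions(events, roster[c(i, j)], dimension, mode))
      S[i, j] <- sc[[1]]
      S[j, i] <- sc[[2]]
    }
  }
  structure(S, class = c("score_matrix", "matrix"), dimension = dimension, mode = mode)
}

#' Build score matrices for all three dimensions
#'
#' @inheritParams build_score_matrix
#' @param modes named character vector giving the comparator per dimension.
#' @return named list of `score_matrix` objects (`proximity`, `grooming`,
#'   `aggression`).
#' @export
build_score_matrices <- function(events, roster,
                                 modes = c(proximity = "count", grooming = "count",
                                           aggression = "count")) {
  out <- lapply(SOC_DIMENSIONS, function(d) {
    if (nrow(events) && !any(events$dimension == d)) {
      warning("no ", d, " events in the log; its scores are all zero")
    }
    build_score_matrix(events, roster, d, mode = modes[[d]] %||% "count")
  })
  names(out) <- SOC_DIMENSIONS
  out
}

#' Check score-matrix invariants
#'
#' Asserts entries in `{-1,0,1}`, zero diagonal, antisymmetry, and total sum 0.
#' @param S a `score_matrix` (or plain matrix).
#' @return `TRUE` invisibly; error describing the violated invariant otherwise.
#' @export
assert_score_matrix <- function(S) {
  if (!is.matrix(S)) stop("score matrix must be a matrix")
  if (nrow(S) != ncol(S)) stop("score matrix must be square")
  if (!all(S %in% c(-1L, 0L, 1L))) stop("score entries must be in {-1, 0, 1}")
  if (any(diag(S) != 0)) stop("score matrix diagonal must be zero")
  if (any(S + t(S) != 0)) stop("score matrix must be antisymmetric")
  if (sum(S) != 0) stop("score matrix entries must sum to zero")
  invisible(TRUE)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Interaction score matrix (", attr(x, "dimension"), ", mode=", attr(x, "mode"),
      ")\n", sep = "")
  print(unclass(x))
  invisible(x)
}

# ---- external interfaces -----------------------------------------------------

#' Read / write behavioral event logs
#'
#' Events CSV has columns `session_id,time_s,actor,recipient,dimension,duration_s`.
#'
#' @param path file path.
#' @param roster optional roster used for validation on read.
#' @return `read_events_csv`: validated event data.frame.
#' @export
read_events_csv <- function(path, roster = NULL) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  validate_events(ev, roster)
  ev
}

#' @rdname read_events_csv
#' @param events event data.frame to write.
#' @export
write_events_csv <- function(events, path) {
  validate_events(events)
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write score matrices
#'
#' The matrix is written as a labelled CSV plus a JSON sidecar (`<path>.json`)
#' recording the dimension, comparator mode, and roster.
#'
#' @param S a `score_matrix`.
#' @param path CSV file path.
#' @return `read_score_matrix`: the reconstructed `score_matrix`.
#' @export
write_score_matrix <- function(S, path) {
  assert_score_matrix(S)
  write.csv(as.data.frame(unclass(S)), path, row.names = TRUE, quote = FALSE)
  jsonlite::write_json(
    list(dimension = attr(S, "dimension"), mode = attr(S, "mode"),
         roster = rownames(S)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  S <- as.matrix(df)
  storage.mode(S) <- "integer"
  S <- S[meta$roster, meta$roster, drop = FALSE]
  S <- structure(S, class = c("score_matrix", "matrix"),
                 dimension = meta$dimension, mode = meta$mode)
  assert_score_matrix(S)
  S
}
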