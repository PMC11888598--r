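# Weight vectors are always ordered (omega_a, omega_g, omega_p):
# aggression, grooming, proximity.
WEIGHT_NAMES <- c("omega_a", "omega_g", "omega_p")
DIM_ORDER <- c("aggression", "grooming", "proximity")

as_weights <- function(weights) {
  w <- unname(as.numeric(weights))
  if (length(w) != 3 || anyNA(w)) stop("weights must be 3 numeric values (omega_a, omega_g, omega_p)")
  names(w) <- WEIGHT_NAMES
  w
}

check_matrices <- function(matrices) {
  miss <- setdiff(DIM_ORDER, names(matrices))
  if (length(miss)) stop("score matrix missing for dimension(s): ", paste(miss, collapse = ", "))
  rosters <- lapply(matrices[DIM_ORDER], rownames)
  if (!all(vapply(rosters[-1], identical, logical(1), rosters[[1]]))) {
    stop("score matrices must share the same roster order")
  }
  invisible(matrices[DIM_ORDER])
}

# N x 3 matrix of per-subject score row-sums, columns (aggression, grooming, proximity)
score_rowsums <- function(matrices) {
  matrices <- check_matrices(matrices)
  X <- vapply(matrices, function(S) rowSums(unclass(S)), numeric(nrow(matrices[[1]])))
  colnames(X) <- DIM_ORDER
  X
}

# M x 3 matrix of dyadic scores for ordered dyads (actor -> partner)
dyad_scores <- function(matrices) {
  matrices <- check_matrices(matrices)
  roster <- rownames(matrices[[1]])
  n <- length(roster)
  pairs <- expand.grid(partner = seq_len(n), actor = seq_len(n))[, 2:1]
  pairs <- pairs[pairs$actor != pairs$partner, , drop = FALSE]
  X <- vapply(matrices, function(S) unclass(S)[cbind(pairs$actor, pairs$partner)],
              numeric(nrow(pairs)))
  colnames(X) <- DIM_ORDER
  data.frame(actor = roster[pairs$actor], partner = roster[pairs$partner], X,
             row.names = NULL, check.names = FALSE)
}

#' Social engagement index (SEI)
#'
#' `SEI = omega_a * sum_i A_i + omega_g * sum_i G_i + omega_p * sum_i P_i`,
#' the weighted sum of a subject's interaction scores across all partners and
#' the three behavioral dimensions. With antisymmetric score matrices the SEIs
#' sum to zero across the group for any weights.
#'
#' @param matrices named list of `score_matrix` objects (`aggression`,
#'   `grooming`, `proximity`) sharing one roster.
#' @param weights numeric length-3 `(omega_a, omega_g, omega_p)`.
#' @param subject optional subject id; default returns all subjects.
#' @return named numeric vector of SEIs (or a single value when `subject` is
#'   given).
#' @export
compute_sei <- function(matrices, weights, subject = NULL) {
  w <- as_weights(weights)
  X <- score_rowsums(matrices)
  sei <- drop(X %*% w)
  if (!is.null(subject)) {
    if (!subject %in% names(sei)) stop("subject not in roster: ", subject)
    return(sei[[subject]])
  }
  sei
}

#' Individual engagement index (IEI)
#'
#' `IEI_actor(partner) = omega_a * A + omega_g * G + omega_p * P`, the weighted
#' sum of the actor's dyadic scores toward one specific partner. For equal
#' weights, `IEI(i -> j) = -IEI(j -> i)` by antisymmetry.
#'
#' @inheritParams compute_sei
#' @param actor,partner distinct subject ids from the roster.
#' @return a single numeric index.
#' @export
compute_iei <- function(matrices, weights, actor, partner) {
  w <- as_weights(weights)
  matrices <- check_matrices(matrices)
  roster <- rownames(matrices[[1]])
  if (!actor %in% roster) stop("actor not in roster: ", actor)
  if (!partner %in% roster) stop("partner not in roster: ", partner)
  if (actor == partner) stop("actor and partner must differ")
  s <- vapply(matrices, function(S) unclass(S)[actor, partner], numeric(1))
  sum(w * s)
}

#' Engagement index table
#'
#' All SEI values (one per subject) or IEI values (one per ordered dyad) under
#' one weight vector.
#'
#' @inheritParams compute_sei
#' @param kind `"sei"` or `"iei"`.
#' @return data.frame: for SEI, columns `subject`, `index`; for IEI, columns
#'   `actor`, `partner`, `index`.
#' @export
engagement_index_table <- function(matrices, weights, kind = c("sei", "iei")) {
  kind <- match.arg(kind)
  w <- as_weights(weights)
  if (kind == "sei") {
    sei <- compute_sei(matrices, w)
    return(data.frame(subject = names(sei), index = unname(sei)))
  }
  d <- dyad_scores(matrices)
  data.frame(actor = d$actor, partner = d$partner,
             index = as.matrix(d[, DIM_ORDER]) %*% w |> drop())
}

#' Weight grid
#'
#' The full Cartesian grid `{0, step, ..., 1}^3` of weight vectors, excluding
#' the all-zero vector. Degenerate vectors that yield zero index variance for a
#' particular data set are screened later, inside [grid_search_weights()].
#'
#' @param step grid step in (0, 1]; must divide 1 (default 0.02).
#' @return numeric matrix with columns `omega_a`, `omega_g`, `omega_p`.
#' @export
weight_grid <- function(step = 0.02) {
  if (step <= 0 || step > 1) stop("step must be in (0, 1]")
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-9) stop("step must divide 1")
  g <- (0:k) * step
  W <- as.matrix(expand.grid(omega_a = g, omega_g = g, omega_p = g))
  W[rowSums(W) > 0, , drop = FALSE]
}

#' Canonical representative of a tie set
#'
#' Among weight vectors tied on the correlation objective, pick the one with
#' the largest component sum; remaining ties break lexicographically on
#' `(omega_a, omega_g, omega_p)`, descending.
#'
#' @param tie_set matrix or data.frame of weight vectors (columns a, g, p).
#' @return named numeric vector of length 3.
#' @export
canonical_weights <- function(tie_set) {
  W <- as.matrix(tie_set)
  if (!nrow(W)) stop("empty tie set")
  o <- order(rowSums(W), W[, 1], W[, 2], W[, 3], decreasing = TRUE)
  as_weights(W[o[1], ])
}

#' Ordinary least-squares line with Pearson statistics
#'
#' Slope and intercept by OLS, Pearson correlation `r`, and a two-sided p-value
#' from the t distribution with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` with nonzero variance.
#' @return object of class `fit_result`: list (`slope`, `intercept`, `r`, `p`,
#'   `n`).
#' @export
fit_line <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (var(x) == 0) stop("zero variance in x")
  r <- stats::cor(x, y)
  slope <- r * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- max(2 * stats::pt(-abs(tt), df = n - 2), .Machine$double.xmin)
  structure(list(slope = slope, intercept = intercept, r = r, p = p, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("linear fit: slope %.4g, intercept %.4g, r = %.4f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}

# Pearson r between y and every index column, computed from per-unit
# sufficient statistics (units repeat across observations, e.g. one SEI per
# subject observed over many days). Returns a vector of length ncol(Iu).
grouped_pearson <- function(Iu, unit_idx, y) {
  n <- length(y)
  cnt <- tabulate(unit_idx, nbins = nrow(Iu))
  sum_y <- as.numeric(rowsum(y, unit_idx, reorder = TRUE))
  # rowsum drops absent units; rebuild full-length vector
  present <- sort(unique(unit_idx))
  sy_full <- numeric(nrow(Iu)); sy_full[present] <- sum_y
  Sy <- sum(y); Syy <- sum(y^2)
  Sx <- drop(cnt %*% Iu)
  Sxx <- drop(cnt %*% Iu^2)
  Sxy <- drop(sy_full %*% Iu)
  cov_xy <- Sxy - Sx * Sy / n
  var_x <- Sxx - Sx^2 / n
  var_y <- Syy - Sy^2 / n
  r <- cov_xy / sqrt(var_x * var_y)
  list(r = r, var_x = var_x / (n - 1))
}

#' Exhaustive weight grid search against distractor biases
#'
#' Evaluates the Pearson correlation between engagement indices and distractor
#' biases at every weight vector on the grid, and returns the full r surface,
#' the extreme under the stated objective, the set of exact ties, a canonical
#' representative, and the OLS fit at the canonical weights.
#'
#' Bias records pair with indices by subject for SEI, and by directed dyad
#' (subject toward the depicted groupmate) for IEI; for IEI the bias table must
#' carry the depicted face as `partner` or `face_id`. Weight vectors whose
#' index has (numerically) zero variance across the paired observations are
#' excluded from the surface, since r is undefined there.
#'
#' @param bias_records data.frame with `subject`, `day`, `bias_ms` (plus
#'   `partner`/`face_id` for IEI), e.g. from [distractor_bias_table()] or
#'   [distractor_bias_by_face()].
#' @param matrices named list of the three `score_matrix` objects.
#' @param index_kind `"sei"` or `"iei"`.
#' @param objective `"most_negative_r"` or `"most_positive_r"`; defaults follow
#'   the analysis conventions (SEI: most negative; IEI: most positive).
#' @param step grid step (default 0.02).
#' @param tie_tol tolerance for tie membership on r (default 1e-9).
#' @return object of class `grid_search_result`: list with `objective`, `step`,
#'   `r_surface` (data.frame `omega_a`, `omega_g`, `omega_p`, `r`), `best_r`,
#'   `tie_set` (matrix), `canonical`, `fit` ([fit_line()] at the canonical
#'   weights), `n_obs`, `n_units`, `n_screened`.
#' @export
grid_search_weights <- function(bias_records, matrices,
                                index_kind = c("sei", "iei"),
                                objective = NULL, step = 0.02, tie_tol = 1e-9) {
  index_kind <- match.arg(index_kind)
  objective <- objective %||% switch(index_kind, sei = "most_negative_r",
                                     iei = "most_positive_r")
  objective <- match.arg(objective, c("most_negative_r", "most_positive_r"))
  if (!nrow(bias_records)) stop("no bias records")
  y <- bias_records$bias_ms
  if (anyNA(y)) stop("bias records contain NA")

  if (index_kind == "sei") {
    Xu <- score_rowsums(matrices)
    unit_ids <- rownames(Xu)
    key <- as.character(bias_records$subject)
  } else {
    d <- dyad_scores(matrices)
    Xu <- as.matrix(d[, DIM_ORDER])
    unit_ids <- paste(d$actor, d$partner, sep = "->")
    partner <- bias_records$partner %||% bias_records$face_id
    if (is.null(partner)) stop("IEI pairing needs a 'partner' or 'face_id' column in bias_records")
    key <- paste(as.character(bias_records$subject), as.character(partner), sep = "->")
  }
  unit_idx <- match(key, unit_ids)
  if (anyNA(unit_idx)) {
    stop("bias records not joinable to an index unit: ",
         paste(unique(key[is.na(unit_idx)]), collapse = ", "))
  }
  n <- length(y)
  if (n < 3) stop("need at least 3 paired (index, bias) observations")

  W <- weight_grid(step)
  Iu <- Xu %*% t(W)                       # units x grid
  gp <- grouped_pearson(Iu, unit_idx, y)
  ok <- gp$var_x > 1e-12
  if (!any(ok)) stop("degenerate pairing: index variance is zero at every grid point")
  r <- gp$r
  surface <- data.frame(W[ok, , drop = FALSE], r = r[ok])
  best_r <- if (objective == "most_negative_r") min(surface$r) else max(surface$r)
  tie <- abs(surface$r - best_r) <= tie_tol
  tie_set <- as.matrix(surface[tie, WEIGHT_NAMES, drop = FALSE])
  rownames(tie_set) <- NULL
  canonical <- canonical_weights(tie_set)
  fit <- fit_line(drop(Xu %*% canonical)[unit_idx], y)
  structure(list(objective = objective, index_kind = index_kind, step = step,
                 r_surface = surface, best_r = best_r, tie_set = tie_set,
                 canonical = canonical, fit = fit, n_obs = n,
                 n_units = length(unique(unit_idx)), n_screened = sum(!ok)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid search (%s, %s, step %g): best r = %.4f at (%.2f, %.2f, %.2f); %d tie(s), %d grid points (%d screened)\n",
              toupper(x$index_kind), x$objective, x$step, x$best_r,
              x$canonical[1], x$canonical[2], x$canonical[3],
              nrow(x$tie_set), nrow(x$r_surface), x$n_screened))
  print(x$fit)
  invisible(x)
}

#' Write a grid-search report
#'
#' JSON report with objective, best r, tie set, canonical weights, and the fit
#' at the canonical weights; optionally the dense r surface as CSV.
#'
#' @param res a `grid_search_result`.
#' @param path JSON output path.
#' @param surface_csv optional path for the dense surface
#'   (`omega_a,omega_g,omega_p,r,n`).
#' @export
write_grid_search <- function(res, path, surface_csv = NULL) {
  stopifnot(inherits(res, "grid_search_result"))
  jsonlite::write_json(list(
    index_kind = res$index_kind, objective = res$objective, step = res$step,
    best_r = res$best_r,
    tie_set = apply(res$tie_set, 1, as.numeric, simplify = FALSE),
    canonical = as.list(res$canonical),
    fit = unclass(res$fit), n_obs = res$n_obs, n_units = res$n_units,
    n_screened = res$n_screened
  ), path, auto_unbox = TRUE, digits = NA)
  if (!is.null(surface_csv)) {
    out <- res$r_surface
    out$n <- res$n_obs
    write.csv(out, surface_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Pairwise engagement-index differences
#'
#' `|SEI_i - SEI_j|` over all unordered subject pairs (the "hexagon" summary
#' for a four-monkey group: C(4,2) = 6 values), with mean and SD. The average
#' pairwise difference summarizes how strongly general social tendencies
#' spread the group.
#'
#' @param values named numeric vector of indices (e.g. [compute_sei()] output),
#'   length >= 2.
#' @return list (`differences` data.frame `i`, `j`, `diff`; `mean`; `sd`;
#'   `n_pairs`).
#' @export
pairwise_index_differences <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 index values")
  ids <- names(values) %||% as.character(seq_len(n))
  pr <- combn(n, 2)
  d <- abs(values[pr[1, ]] - values[pr[2, ]])
  diffs <- data.frame(i = ids[pr[1, ]], j = ids[pr[2, ]], diff = unname(d))
  list(differences = diffs, mean = mean(d), sd = sd(d), n_pairs = ncol(pr))
}
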