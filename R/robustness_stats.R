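#' Enumerate image-withdrawal combinations
#'
#' For the stimulus-robustness analysis each subject withdraws one in-group and
#' one out-group face image from its distractor set; the full Cartesian
#' enumeration over subjects gives `n_in^S * n_out^S` combinations (e.g.
#' 3^4 x 3^4 = 6561 for four subjects with three faces per side). A side with
#' a single face contributes no choice (withdrawal disabled on that side).
#'
#' @param n_subjects number of subjects S (>= 1).
#' @param n_in,n_out number of in-group / out-group face images per subject
#'   (>= 1).
#' @return data.frame with one row per combination and columns
#'   `in_1..in_S`, `out_1..out_S` holding the index (1-based) of the withdrawn
#'   image; deterministic order.
#' @export
enumerate_withdrawals <- function(n_subjects, n_in, n_out) {
  if (n_subjects < 1 || n_in < 1 || n_out < 1) {
    stop("n_subjects, n_in, n_out must all be positive")
  }
  cols <- c(lapply(seq_len(n_subjects), function(s) seq_len(n_in)),
            lapply(seq_len(n_subjects), function(s) seq_len(n_out)))
  names(cols) <- c(paste0("in_", seq_len(n_subjects)),
                   paste0("out_", seq_len(n_subjects)))
  out <- expand.grid(cols, KEEP.OUT.ATTRS = FALSE)
  stopifnot(nrow(out) == n_in^n_subjects * n_out^n_subjects)
  out
}

#' Two-sided Wilcoxon signed-rank test (fast path)
#'
#' Paired signed-rank test matching [stats::wilcox.test()] conventions: zero
#' differences are dropped, p is exact (via `psignrank`) for `n <= exact_max`
#' untied pairs, and otherwise uses the normal approximation with continuity
#' and tie correction. Implemented directly so the image-withdrawal loop can
#' run thousands of tests cheaply; equivalence with `wilcox.test` is verified
#' in the test suite.
#'
#' @param x,y paired numeric vectors (or `x` already the differences,
#'   `y = NULL`).
#' @param exact_max largest n for which the exact distribution is used
#'   (default 25; ties always force the approximation).
#' @return list (`statistic` = V, `signed_sum` = sum of signed ranks, `p`,
#'   `n` = nonzero pairs, `exact`).
#' @export
signed_rank_test <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, signed_sum = 0, p = 1, n = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signed_sum <- sum(sign(d) * r)
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= exact_max && !ties) {
    p <- if (V > n * (n + 1) / 4) {
      stats::psignrank(V - 1, n, lower.tail = FALSE)
    } else {
      stats::psignrank(V, n)
    }
    p <- min(2 * p, 1)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- V - mu
    z <- z - sign(z) * 0.5                 # continuity correction
    z <- z / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = V, signed_sum = signed_sum, p = p, n = n, exact = exact)
}

#' Image-withdrawal robustness of the in/out bias difference
#'
#' For every combination of one withdrawn in-group and one withdrawn out-group
#' face per subject, recomputes per-day distractor biases from the retained
#' faces, tests in-group vs out-group biases with a two-sided Wilcoxon
#' signed-rank test paired by (subject, day), and reports the fraction of
#' combinations significant at `alpha`. Combinations with fewer than
#' `min_pairs` evaluable subject-day pairs are excluded from the denominator
#' and counted.
#'
#' @param trials trial table, or a precomputed per-face bias table from
#'   [distractor_bias_by_face()].
#' @param alpha significance level (default 0.05).
#' @param min_pairs minimum paired subject-days per combination (default 2).
#' @param exclude_unrewarded passed to [drifting_time_table()] when `trials`
#'   is a trial table.
#' @return object of class `withdrawal_robustness`: list with
#'   `n_combinations`, `n_evaluable`, `n_significant`, `fraction_significant`,
#'   `alpha`, `p_values`, `signed_sums`, `mean_diffs` (per combination,
#'   in-group minus out-group).
#' @export
withdrawal_robustness <- function(trials, alpha = 0.05, min_pairs = 2,
                                  exclude_unrewarded = TRUE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  bias <- if (all(c("face_id", "bias_ms") %in% names(trials)) &&
              !"rt_ms" %in% names(trials)) {
    trials
  } else {
    distractor_bias_by_face(drifting_time_table(trials, exclude_unrewarded))
  }
  bias <- bias[bias$group %in% c("in", "out"), , drop = FALSE]
  subjects <- sort(unique(bias$subject))
  days <- sort(unique(bias$day))
  faces <- lapply(c("in", "out"), function(g) {
    lapply(subjects, function(s) sort(unique(bias$face_id[bias$subject == s & bias$group == g])))
  })
  names(faces) <- c("in", "out")
  n_in <- lengths(faces[["in"]]); n_out <- lengths(faces[["out"]])
  if (length(unique(n_in)) != 1 || length(unique(n_out)) != 1) {
    stop("subjects must share the same number of in-group and out-group faces")
  }
  if (n_in[1] < 1 || n_out[1] < 1) stop("need at least one face per group")

  # bias array [subject, day, face-slot] per group; NA for missing cells
  build_arr <- function(g) {
    arr <- array(NA_real_, c(length(subjects), length(days), max(lengths(faces[[g]]))))
    bg <- bias[bias$group == g, , drop = FALSE]
    si <- match(bg$subject, subjects)
    di <- match(bg$day, days)
    fi <- mapply(function(s, f) match(f, faces[[g]][[s]]), si, bg$face_id)
    arr[cbind(si, di, fi)] <- bg$bias_ms
    arr
  }
  arr_in <- build_arr("in"); arr_out <- build_arr("out")
  combos <- enumerate_withdrawals(length(subjects), n_in[1], n_out[1])
  S <- length(subjects); D <- length(days)

  mean_retained <- function(arr, withdrawn) {
    # per subject-day mean over the retained faces (all but the withdrawn slot)
    out <- matrix(NA_real_, S, D)
    for (s in seq_len(S)) {
      keep <- setdiff(seq_len(dim(arr)[3]), withdrawn[s])
      v <- arr[s, , keep, drop = FALSE]
      out[s, ] <- rowMeans(matrix(v, nrow = D), na.rm = TRUE)
    }
    out[is.nan(out)] <- NA
    out
  }

  nC <- nrow(combos)
  p <- rep(NA_real_, nC); ss <- rep(NA_real_, nC); md <- rep(NA_real_, nC)
  in_cols <- as.matrix(combos[, seq_len(S), drop = FALSE])
  out_cols <- as.matrix(combos[, S + seq_len(S), drop = FALSE])
  for (k in seq_len(nC)) {
    bi <- mean_retained(arr_in, in_cols[k, ])
    bo <- mean_retained(arr_out, out_cols[k, ])
    d <- as.numeric(bi - bo)
    d <- d[!is.na(d)]
    if (length(d) < min_pairs) next
    res <- signed_rank_test(d)
    p[k] <- res$p; ss[k] <- res$signed_sum; md[k] <- mean(d)
  }
  evaluable <- !is.na(p)
  # alpha = 1 counts every evaluable combination (p can equal 1 exactly)
  n_sig <- if (alpha >= 1) sum(evaluable) else sum(p[evaluable] < alpha)
  structure(list(
    n_combinations = nC, n_evaluable = sum(evaluable), n_significant = n_sig,
    fraction_significant = if (any(evaluable)) n_sig / sum(evaluable) else NA_real_,
    alpha = alpha, p_values = p, signed_sums = ss, mean_diffs = md,
    subjects = subjects, n_in = n_in[1], n_out = n_out[1]
  ), class = "withdrawal_robustness")
}

#' @export
print.withdrawal_robustness <- function(x, ...) {
  cat(sprintf("image-withdrawal robustness: %d/%d evaluable combinations significant at alpha=%g (%.2f%%); %d unevaluable\n",
              x$n_significant, x$n_evaluable, x$alpha,
              100 * x$fraction_significant, x$n_combinations - x$n_evaluable))
  invisible(x)
}

#' Write a withdrawal-robustness report
#'
#' JSON summary plus a CSV of per-combination p-values.
#'
#' @param res a `withdrawal_robustness` object.
#' @param path JSON output path.
#' @param p_values_csv path for the p-value CSV (default `<path>_pvalues.csv`).
#' @export
write_robustness <- function(res, path,
                             p_values_csv = sub("\\.json$", "_pvalues.csv", path)) {
  stopifnot(inherits(res, "withdrawal_robustness"))
  write.csv(data.frame(combination = seq_along(res$p_values), p = res$p_values,
                       signed_rank_sum = res$signed_sums,
                       mean_in_minus_out = res$mean_diffs),
            p_values_csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    n_combinations = res$n_combinations, n_evaluable = res$n_evaluable,
    n_significant = res$n_significant,
    fraction_significant = res$fraction_significant, alpha = res$alpha,
    p_values_path = basename(p_values_csv)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Saline vs oxytocin condition contrast
#'
#' Paired two-tailed t test on distractor biases matched by (subject, day
#' pair), plus per-dimension weight change ratios
#' `(omega_OT - omega_saline) / omega_saline` and the slope pair when the two
#' conditions' grid-search fits are supplied.
#'
#' @param bias_saline,bias_ot bias tables (`subject`, `day`, `bias_ms`) for the
#'   two conditions; rows are paired on (subject, day).
#' @param fit_saline,fit_ot optional fits per condition: either
#'   `grid_search_result` objects (slopes at each condition's canonical
#'   weights, plus weight change ratios) or plain [fit_line()] results
#'   (slopes only, e.g. both computed at a common weight vector so the ratio
#'   is scale-free).
#' @return object of class `condition_contrast`: list with `n`, `mean_diff`
#'   (OT minus saline, ms), `t`, `p`, `change_ratios` (NA where the saline
#'   weight is 0), `slopes`, `slope_ratio`.
#' @export
condition_contrast <- function(bias_saline, bias_ot, fit_saline = NULL, fit_ot = NULL) {
  key_s <- paste(bias_saline$subject, bias_saline$day)
  key_o <- paste(bias_ot$subject, bias_ot$day)
  if (length(key_s) != length(key_o) || !setequal(key_s, key_o)) {
    stop("saline and OT bias records are not pairable by (subject, day)")
  }
  x <- bias_saline$bias_ms[order(key_s)]
  y <- bias_ot$bias_ms[order(key_o)]
  d <- y - x
  n <- length(d)
  if (n < 2) stop("need at least 2 paired records")
  if (sd(d) == 0) {
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    ht <- stats::t.test(y, x, paired = TRUE)
    tt <- unname(ht$statistic); p <- ht$p.value
  }
  ratios <- slopes <- slope_ratio <- NULL
  if (!is.null(fit_saline) && !is.null(fit_ot)) {
    ws <- fit_saline$canonical; wo <- fit_ot$canonical
    if (!is.null(ws) && !is.null(wo)) {
      ratios <- ifelse(ws == 0, NA_real_, (wo - ws) / ws)
      names(ratios) <- names(ws)
    }
    slope_of <- function(f) if (inherits(f, "grid_search_result")) f$fit$slope else f$slope
    slopes <- c(saline = slope_of(fit_saline), ot = slope_of(fit_ot))
    slope_ratio <- if (slopes[["saline"]] != 0) slopes[["ot"]] / slopes[["saline"]] else NA_real_
  }
  structure(list(metric = "distractor_bias", n = n, mean_diff = mean(d),
                 t = tt, p = p, change_ratios = ratios, slopes = slopes,
                 slope_ratio = slope_ratio),
            class = "condition_contrast")
}

#' @export
print.condition_contrast <- function(x, ...) {
  cat(sprintf("condition contrast (OT - saline): mean diff %.2f ms, paired t = %.3g, p = %.3g, n = %d\n",
              x$mean_diff, x$t, x$p, x$n))
  if (!is.null(x$slopes)) {
    cat(sprintf("  slopes: saline %.2f, OT %.2f (ratio %.2f)\n",
                x$slopes[["saline"]], x$slopes[["ot"]], x$slope_ratio))
  }
  if (!is.null(x$change_ratios)) {
    cat("  weight change ratios:",
        paste(names(x$change_ratios), sprintf("%.2f", x$change_ratios),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
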