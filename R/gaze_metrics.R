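#' @import data.table
NULL

#' Construct an eye-position trace
#'
#' A 1 kHz (by default) two-dimensional eye-position recording for one trial,
#' together with the trial's event timestamps. Time is milliseconds from the
#' start of the trace (fixation onset).
#'
#' @param x,y position series in degrees, equal length.
#' @param sample_rate sampling rate in Hz.
#' @param events named list of trial events, in ms / deg:
#'   `fixation_on`, `distractor_on` (absent for visuomotor trials),
#'   `target_move`, `target_x`, and optionally `distractor_x`.
#' @return object of class `eye_trace`.
#' @export
eye_trace <- function(x, y = NULL, sample_rate = 1000, events = list()) {
  if (is.null(y)) y <- numeric(length(x))
  if (length(x) != length(y)) stop("x and y series must have equal length")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(
    x = as.numeric(x), y = as.numeric(y),
    sample_rate = sample_rate,
    t_ms = (seq_along(x) - 1) * 1000 / sample_rate,
    events = events
  ), class = "eye_trace")
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("eye_trace: %d samples @ %g Hz (%.0f ms)\n",
              length(x$x), x$sample_rate, max(x$t_ms)))
  if (length(x$events)) {
    ev <- x$events
    cat("  events:", paste(names(ev), unlist(ev), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Eye velocity and acceleration
#'
#' Differentiates the position series and low-pass filters the result at
#' `cutoff_hz` (first-order Butterworth applied forwards and backwards, so the
#' velocity estimate is zero-phase), emulating an analog differentiator that
#' rejects signal above 25 Hz. Acceleration is the first difference of the
#' filtered speed times the sample rate. All series are padded to the input
#' length.
#'
#' @param trace an [eye_trace()].
#' @param cutoff_hz low-pass cutoff for the velocity signal (default 25).
#' @param filter_order Butterworth order (default 1; a second-order variant can
#'   be selected here).
#' @return list with `vx`, `vy` (deg/s), `speed` (deg/s, radial), `accel`
#'   (deg/s^2, derivative of speed), and `t_ms`.
#' @export
compute_velocity <- function(trace, cutoff_hz = 25, filter_order = 1) {
  stopifnot(inherits(trace, "eye_trace"))
  n <- length(trace$x)
  if (n < 24) stop("trace too short for velocity filtering (need >= 24 samples)")
  fs <- trace$sample_rate
  bf <- signal::butter(filter_order, cutoff_hz / (fs / 2), type = "low")
  filt_diff <- function(p) {
    v <- diff(p) * fs
    v <- c(v, v[length(v)])
    as.numeric(signal::filtfilt(bf, v))
  }
  vx <- filt_diff(trace$x)
  vy <- filt_diff(trace$y)
  speed <- sqrt(vx^2 + vy^2)
  a <- diff(speed) * fs
  a <- c(a, a[length(a)])
  list(vx = vx, vy = vy, speed = speed, accel = a, t_ms = trace$t_ms)
}

#' Detect saccades by joint velocity and acceleration thresholds
#'
#' Within each epoch where radial eye speed stays at or above `v_thresh`, the
#' saccade onset is the first sample that also satisfies
#' `|acceleration| >= a_thresh`; epochs with no such sample are discarded as
#' drift. The offset is the first subsequent sample with speed below
#' `v_thresh`. Events are non-overlapping and time ordered.
#'
#' @param trace an [eye_trace()].
#' @param v_thresh velocity threshold, deg/s (default 50).
#' @param a_thresh acceleration threshold, deg/s^2 (default 500).
#' @param kin optional precomputed output of [compute_velocity()].
#' @return data.frame with zero or more rows: `onset_ms`, `offset_ms`,
#'   `peak_velocity`, `direction` (sign of the horizontal displacement).
#' @export
detect_saccades <- function(trace, v_thresh = 50, a_thresh = 500, kin = NULL) {
  stopifnot(inherits(trace, "eye_trace"))
  if (is.null(kin)) kin <- compute_velocity(trace)
  above <- kin$speed >= v_thresh
  out <- list()
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  n <- length(kin$speed)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    ok <- idx[abs(kin$accel[idx]) >= a_thresh]
    if (!length(ok)) next
    onset <- ok[1]
    offset <- min(ends[k] + 1, n)
    out[[length(out) + 1]] <- data.frame(
      onset_ms = kin$t_ms[onset],
      offset_ms = kin$t_ms[offset],
      peak_velocity = max(kin$speed[idx]),
      direction = sign(trace$x[offset] - trace$x[onset])
    )
  }
  if (!length(out)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      peak_velocity = numeric(0), direction = numeric(0)))
  }
  do.call(rbind, out)
}

#' Fixation-interval trial validation
#'
#' A trial is discarded when any saccade onset falls in the 500 ms interval
#' preceding the distractor onset (half-open: `[ref - 500, ref)`); visuomotor
#' trials, which have no distractor, use the target relocation as reference.
#'
#' @param trace an [eye_trace()] carrying `distractor_on` or `target_move`.
#' @param saccades output of [detect_saccades()].
#' @param window_ms length of the protected fixation interval (default 500).
#' @return `TRUE` if the trial is valid.
#' @export
validate_trial <- function(trace, saccades, window_ms = 500) {
  ev <- trace$events
  ref <- ev$distractor_on %||% ev$target_move
  if (is.null(ref)) stop("trace events must include distractor_on or target_move")
  !any(saccades$onset_ms >= ref - window_ms & saccades$onset_ms < ref)
}

#' Saccadic response time to the target
#'
#' The response time is the onset, measured from target relocation, of the
#' first saccade whose endpoint lands within the target window. If the first
#' saccade after the distractor is instead directed at the distractor (an
#' attentional capture), the trial's RT is taken from the eventual
#' target-acquiring saccade and the capture flag is set.
#'
#' @param trace an [eye_trace()] with `target_move`, `target_x`, and (for
#'   interference trials) `distractor_on`, `distractor_x`.
#' @param saccades output of [detect_saccades()].
#' @param window_deg half-width of the acceptance window around the target /
#'   distractor location (default 2, matching the fixation window size).
#' @param deadline_ms reward deadline; RTs above it are flagged unrewarded
#'   (default 300).
#' @return list with `rt_ms`, `first_sacc_to_distractor` (NA when no distractor
#'   on the trial), `rewarded`.
#' @export
response_time <- function(trace, saccades, window_deg = 2, deadline_ms = 300) {
  ev <- trace$events
  if (is.null(ev$target_move) || is.null(ev$target_x)) {
    stop("trace events must include target_move and target_x")
  }
  ref <- ev$distractor_on %||% ev$target_move
  cand <- saccades[saccades$onset_ms >= ref, , drop = FALSE]
  if (!nrow(cand)) stop("no-response: no saccade after the go event")
  end_x <- vapply(cand$offset_ms, function(t) {
    i <- min(length(trace$x), round(t * trace$sample_rate / 1000) + 1)
    trace$x[i]
  }, numeric(1))
  to_target <- abs(end_x - ev$target_x) <= window_deg
  first_to_distr <- NA
  if (!is.null(ev$distractor_x)) {
    first_to_distr <- abs(end_x[1] - ev$distractor_x) <= window_deg
  }
  hit <- which(to_target & cand$onset_ms >= ev$target_move)
  if (!length(hit)) stop("no-response: no saccade reached the target window")
  rt <- cand$onset_ms[hit[1]] - ev$target_move
  list(rt_ms = rt, first_sacc_to_distractor = first_to_distr,
       rewarded = rt <= deadline_ms)
}

# ---- trial-table metrics -----------------------------------------------------

required_trial_cols <- c("subject", "day", "drug_condition", "trial_type",
                         "distractor_id", "distractor_class", "group",
                         "congruency", "rt_ms", "first_sacc_to_distractor", "valid")

#' Validate a trial table
#'
#' @param trials data.frame with the columns listed in the package README
#'   (`subject`, `day`, `drug_condition`, `trial_type`, `distractor_id`,
#'   `distractor_class`, `group`, `congruency`, `rt_ms`,
#'   `first_sacc_to_distractor`, `valid`).
#' @return the trials, invisibly.
#' @export
validate_trials <- function(trials) {
  miss <- setdiff(required_trial_cols, names(trials))
  if (length(miss)) stop("trial table missing columns: ", paste(miss, collapse = ", "))
  vm <- trials$trial_type == "visuomotor"
  if (any(vm & trials$distractor_class != "none")) {
    stop("visuomotor trials must have distractor_class = 'none'")
  }
  if (any(vm & trials$congruency != "none")) {
    stop("visuomotor trials must have congruency = 'none'")
  }
  if (any(trials$valid & !is.na(trials$rt_ms) & trials$rt_ms <= 0)) {
    stop("valid completed trials must have rt_ms > 0")
  }
  invisible(trials)
}

# usable interference trials for RT statistics
usable_interference <- function(trials, exclude_unrewarded = TRUE, deadline_ms = 300) {
  tr <- trials[trials$valid & trials$trial_type == "interference" & !is.na(trials$rt_ms), ,
               drop = FALSE]
  if (exclude_unrewarded) tr <- tr[tr$rt_ms <= deadline_ms, , drop = FALSE]
  tr
}

#' Drifting time for one analysis cell
#'
#' Drifting time is the mean response time with an intact-face distractor minus
#' the mean response time with the matched scrambled image, within one
#' (subject, day, face, congruency) cell: `DT = RTf - RTs`.
#'
#' @param trials trial table (see [validate_trials()]).
#' @param subject,day,face_id,congruency cell selectors.
#' @param exclude_unrewarded drop trials slower than the reward deadline before
#'   averaging (default TRUE; the alternative retains them).
#' @param deadline_ms reward deadline in ms.
#' @return list (`subject`, `day`, `face_id`, `congruency`, `dt_ms`,
#'   `n_intact`, `n_scrambled`).
#' @export
drifting_time <- function(trials, subject, day, face_id, congruency,
                          exclude_unrewarded = TRUE, deadline_ms = 300) {
  validate_trials(trials)
  tr <- usable_interference(trials, exclude_unrewarded, deadline_ms)
  tr <- tr[tr$subject == subject & tr$day == day & tr$distractor_id == face_id &
             tr$congruency == congruency, , drop = FALSE]
  rt_f <- tr$rt_ms[tr$distractor_class == "intact"]
  rt_s <- tr$rt_ms[tr$distractor_class == "scrambled"]
  if (!length(rt_f) || !length(rt_s)) {
    stop(sprintf("insufficient data for cell (subject=%s, day=%s, face=%s, %s): %d intact, %d scrambled trials",
                 subject, day, face_id, congruency, length(rt_f), length(rt_s)))
  }
  list(subject = subject, day = day, face_id = face_id, congruency = congruency,
       dt_ms = mean(rt_f) - mean(rt_s), n_intact = length(rt_f),
       n_scrambled = length(rt_s))
}

#' Drifting times for every populated cell
#'
#' Vectorized companion of [drifting_time()]: computes `DT = RTf - RTs` for all
#' (subject, day, face, congruency) cells that contain at least one usable
#' intact and one usable scrambled trial.
#'
#' @inheritParams drifting_time
#' @return data.frame with columns `subject`, `day`, `face_id`, `group`,
#'   `congruency`, `dt_ms`, `n_intact`, `n_scrambled`.
#' @export
drifting_time_table <- function(trials, exclude_unrewarded = TRUE, deadline_ms = 300) {
  validate_trials(trials)
  tr <- usable_interference(trials, exclude_unrewarded, deadline_ms)
  if (!nrow(tr)) stop("no usable interference trials")
  dt <- data.table::as.data.table(tr)
  cell <- dt[, .(m = mean(rt_ms), n = .N),
             by = .(subject, day, face_id = distractor_id, group, congruency,
                    distractor_class)]
  wide <- data.table::dcast(cell, subject + day + face_id + group + congruency ~
                              distractor_class, value.var = c("m", "n"))
  for (col in c("m_intact", "m_scrambled", "n_intact", "n_scrambled")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide <- wide[!is.na(m_intact) & !is.na(m_scrambled)]
  out <- wide[, .(subject, day, face_id, group, congruency,
                  dt_ms = m_intact - m_scrambled,
                  n_intact = as.integer(n_intact), n_scrambled = as.integer(n_scrambled))]
  data.table::setDF(out)
  out[order(out$subject, out$day, out$face_id, out$congruency), , drop = FALSE]
}

#' Distractor bias for one subject-day
#'
#' `DistractorBias = DT_incongruent - DT_congruent`, averaging drifting times
#' within each congruency over the faces in the requested group.
#'
#' @param dt_records data.frame from [drifting_time_table()].
#' @param subject,day selectors.
#' @param group `"in"`, `"out"`, or `"all"`.
#' @return list (`subject`, `day`, `group`, `bias_ms`, `n_incon`, `n_con`).
#' @export
distractor_bias <- function(dt_records, subject, day, group = "all") {
  sel <- dt_records$subject == subject & dt_records$day == day
  if (group != "all") sel <- sel & dt_records$group == group
  d <- dt_records[sel, , drop = FALSE]
  inc <- d$dt_ms[d$congruency == "incongruent"]
  con <- d$dt_ms[d$congruency == "congruent"]
  if (!length(inc) || !length(con)) {
    stop(sprintf("insufficient data for bias cell (subject=%s, day=%s, group=%s): %d incongruent, %d congruent DTs",
                 subject, day, group, length(inc), length(con)))
  }
  list(subject = subject, day = day, group = group,
       bias_ms = mean(inc) - mean(con), n_incon = length(inc), n_con = length(con))
}

#' Distractor biases for all subject-days
#'
#' @inheritParams distractor_bias
#' @param on_missing what to do with subject-days lacking either congruency
#'   cell: `"drop"` (default) or `"error"`.
#' @return data.frame with `subject`, `day`, `group`, `bias_ms`.
#' @export
distractor_bias_table <- function(dt_records, group = "all",
                                  on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  keep <- if (group == "all") rep(TRUE, nrow(dt_records)) else dt_records$group == group
  d <- data.table::as.data.table(dt_records[keep, , drop = FALSE])
  if (!nrow(d)) stop("no drifting-time records for group ", group)
  b <- d[, .(
    bias_ms = mean(dt_ms[congruency == "incongruent"]) -
      mean(dt_ms[congruency == "congruent"]),
    n_incon = sum(congruency == "incongruent"),
    n_con = sum(congruency == "congruent")
  ), by = .(subject, day)]
  bad <- b[is.na(bias_ms)]
  if (nrow(bad) && on_missing == "error") {
    stop("missing congruency cell for subject-day(s): ",
         paste(paste(bad$subject, bad$day, sep = "/"), collapse = ", "))
  }
  b <- b[!is.na(bias_ms)]
  out <- data.frame(subject = b$subject, day = b$day, group = group,
                    bias_ms = b$bias_ms)
  out[order(out$subject, out$day), , drop = FALSE]
}

#' Distractor bias per depicted face
#'
#' Per (subject, day, face) bias, used to pair biases with dyadic engagement
#' indices (the depicted groupmate is the partner) and by the image-withdrawal
#' robustness analysis.
#'
#' @inheritParams distractor_bias
#' @return data.frame with `subject`, `day`, `face_id`, `group`, `bias_ms`.
#' @export
distractor_bias_by_face <- function(dt_records, group = "all") {
  keep <- if (group == "all") rep(TRUE, nrow(dt_records)) else dt_records$group == group
  d <- data.table::as.data.table(dt_records[keep, , drop = FALSE])
  b <- d[, .(
    group = group[1],
    bias_ms = mean(dt_ms[congruency == "incongruent"]) -
      mean(dt_ms[congruency == "congruent"])
  ), by = .(subject, day, face_id)]
  b <- b[!is.na(bias_ms)]
  out <- data.frame(subject = b$subject, day = b$day, face_id = b$face_id,
                    group = b$group, bias_ms = b$bias_ms)
  out[order(out$subject, out$day, out$face_id), , drop = FALSE]
}

#' First-saccade capture probability difference
#'
#' In incongruent trials, the probability that the first saccade is directed at
#' the distractor, contrasted between intact faces and scrambled images:
#' `P(capture | intact) - P(capture | scrambled)`.
#'
#' @param trials trial table.
#' @param subject,day optional selectors (NULL pools over them).
#' @param group `"in"`, `"out"`, or `"all"`.
#' @return list (`p_intact`, `p_scrambled`, `diff`, `n_intact`, `n_scrambled`).
#' @export
first_saccade_prob_diff <- function(trials, subject = NULL, day = NULL, group = "all") {
  validate_trials(trials)
  tr <- trials[trials$valid & trials$trial_type == "interference" &
                 trials$congruency == "incongruent" &
                 !is.na(trials$first_sacc_to_distractor), , drop = FALSE]
  if (!is.null(subject)) tr <- tr[tr$subject == subject, , drop = FALSE]
  if (!is.null(day)) tr <- tr[tr$day == day, , drop = FALSE]
  if (group != "all") tr <- tr[tr$group == group, , drop = FALSE]
  fi <- tr$first_sacc_to_distractor[tr$distractor_class == "intact"]
  fs <- tr$first_sacc_to_distractor[tr$distractor_class == "scrambled"]
  if (!length(fi) || !length(fs)) {
    stop("insufficient data: need incongruent trials of both distractor classes")
  }
  p_i <- mean(fi); p_s <- mean(fs)
  list(p_intact = p_i, p_scrambled = p_s, diff = p_i - p_s,
       n_intact = length(fi), n_scrambled = length(fs))
}

# ---- trial / trace IO --------------------------------------------------------

#' Read / write trial tables
#'
#' Trials CSV columns: `subject,day,drug_condition,trial_type,distractor_id,`
#' `distractor_class,group,congruency,rt_ms,first_sacc_to_distractor,valid`.
#'
#' @param path file path.
#' @return `read_trials_csv`: validated trial data.frame.
#' @export
read_trials_csv <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  tr$first_sacc_to_distractor <- as.logical(tr$first_sacc_to_distractor)
  tr$valid <- as.logical(tr$valid)
  validate_trials(tr)
  tr
}

#' @rdname read_trials_csv
#' @param trials trial data.frame to write.
#' @export
write_trials_csv <- function(trials, path) {
  validate_trials(trials)
  write.csv(trials[required_trial_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write eye traces
#'
#' Trace CSV columns `t_ms,x_deg,y_deg`; event timestamps live in a JSON
#' sidecar (`<path>.json`).
#'
#' @param trace an [eye_trace()].
#' @param path CSV file path.
#' @return `read_eye_trace`: the reconstructed `eye_trace`.
#' @export
write_eye_trace <- function(trace, path) {
  stopifnot(inherits(trace, "eye_trace"))
  write.csv(data.frame(t_ms = trace$t_ms, x_deg = trace$x, y_deg = trace$y),
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(sample_rate = trace$sample_rate), trace$events),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eye_trace
#' @export
read_eye_trace <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sr <- meta$sample_rate
  meta$sample_rate <- NULL
  eye_trace(df$x_deg, df$y_deg, sample_rate = sr, events = meta)
}
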