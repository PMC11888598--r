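# run code with a local RNG state so generators are deterministic by seed and
# leave the caller's RNG untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Synthetic study configuration
#'
#' Parameters of the generative model used to emulate the study: a four-monkey
#' colony with dominance orders per behavioral dimension, a 12-day visual
#' orienting experiment (50-trial sessions: 48 interference + 2 visuomotor),
#' and distractor biases linearly coupled to the engagement index under
#' ground-truth weights. Defaults are the study conditions; see the methods
#' vignette for how each was chosen.
#'
#' @param roster subject ids (default 4 monkeys).
#' @param out_group out-group face ids (default 3).
#' @param n_days experimental days (default 12).
#' @param sessions_per_day 50-trial sessions per day (default 15).
#' @param n_interference,n_visuomotor trials per session (48 + 2, i.e. 96%/4%).
#' @param hierarchy named list of dominance orders (highest first) per
#'   dimension; the orders are chosen so the three score row-sum vectors are
#'   linearly independent.
#' @param rate_high,rate_low directed interaction rates (events/hour) for the
#'   dominant and subordinate direction of a dyad.
#' @param obs_sessions,session_hours number and length (h) of colony
#'   observation sessions.
#' @param omega_star ground-truth weights `(omega_a, omega_g, omega_p)`.
#' @param a,b intercept (ms) and slope (ms per index unit) coupling the
#'   per-subject face-interference effect to the engagement index.
#' @param coupling_index which engagement index drives the face effect:
#'   `"sei"` (default; one effect per subject, all faces) or `"iei"` (effect
#'   per depicted in-group partner, `a + b * IEI(subject -> partner)`;
#'   out-group faces get the intercept `a` alone).
#' @param group_effect multiplicative in/out-group scaling of the face effect.
#' @param bias_noise_frac SD of the day-level face-effect jitter, as a fraction
#'   of the SD of the signal component `b * SEI` across subjects.
#' @param base_rt mean RT (ms) for scrambled distractors per congruency.
#' @param rt_noise_sd trial-level RT noise SD (ms).
#' @param vm_rt mean RT (ms) in visuomotor trials.
#' @param capture_prob probability that the first saccade goes to the
#'   distractor in incongruent trials, per distractor class.
#' @param fixation_break_rate fraction of trials discarded for fixation breaks.
#' @param saccade_amplitude target saccade amplitude (deg).
#' @param distractor_ecc distractor eccentricity (deg).
#' @param saccade_duration_ms saccade duration; NULL uses the main-sequence
#'   rule `21 + 2.2 * amplitude`.
#' @param fix_noise_sd fixation positional noise SD (deg).
#' @param ot_slope_multiplier,ot_weight_multipliers oxytocin condition effects:
#'   multiplicative changes to the coupling slope and to the generative weights
#'   `(a, g, p)`.
#' @return object of class `study_config` (a validated list).
#' @export
study_config <- function(roster = c("MA", "MK", "ML", "MC"),
                         out_group = c("MO1", "MO2", "MO3"),
                         n_days = 12,
                         sessions_per_day = 15,
                         n_interference = 48,
                         n_visuomotor = 2,
                         hierarchy = list(
                           aggression = c("MC", "ML", "MK", "MA"),
                           grooming = c("MK", "MC", "MA", "ML"),
                           proximity = c("MA", "MC", "MK", "ML")),
                         rate_high = 6, rate_low = 2,
                         obs_sessions = 20, session_hours = 2,
                         omega_star = c(omega_a = 0.5, omega_g = 0.25, omega_p = 1.0),
                         a = 55, b = -26,
                         coupling_index = c("sei", "iei"),
                         group_effect = c("in" = 0.8, "out" = 1.2),
                         bias_noise_frac = 0.1,
                         base_rt = c(congruent = 143, incongruent = 214),
                         rt_noise_sd = 40,
                         vm_rt = 150,
                         capture_prob = c(intact = 0.4, scrambled = 0.15),
                         fixation_break_rate = 0.02,
                         saccade_amplitude = 14,
                         distractor_ecc = 18,
                         saccade_duration_ms = NULL,
                         fix_noise_sd = 0.02,
                         ot_slope_multiplier = 2.3,
                         ot_weight_multipliers = c(omega_a = 2, omega_g = 0.5, omega_p = 1)) {
  cfg <- as.list(environment())
  cfg$coupling_index <- match.arg(coupling_index)
  if (length(cfg$roster) < 2) stop("roster must have at least 2 subjects")
  if (anyDuplicated(c(cfg$roster, cfg$out_group))) stop("duplicate subject/face ids")
  for (d in SOC_DIMENSIONS) {
    if (!setequal(cfg$hierarchy[[d]], cfg$roster)) {
      stop("hierarchy for ", d, " must be a permutation of the roster")
    }
  }
  if (cfg$rate_high < 0 || cfg$rate_low < 0) stop("interaction rates must be >= 0")
  if (cfg$n_interference + cfg$n_visuomotor <= 0) stop("empty sessions")
  if (any(cfg$capture_prob < 0 | cfg$capture_prob > 1)) stop("capture_prob must be in [0,1]")
  if (cfg$fixation_break_rate < 0 || cfg$fixation_break_rate > 1) {
    stop("fixation_break_rate must be in [0,1]")
  }
  cfg$omega_star <- as_weights(cfg$omega_star)
  cfg$ot_weight_multipliers <- as_weights(cfg$ot_weight_multipliers)
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("study_config: %d subjects, %d out-group faces, %d days x %d sessions x %d trials\n",
              length(x$roster), length(x$out_group), x$n_days, x$sessions_per_day,
              x$n_interference + x$n_visuomotor))
  cat(sprintf("  omega* = (%.2f, %.2f, %.2f), a = %g, b = %g, OT slope x%g\n",
              x$omega_star[1], x$omega_star[2], x$omega_star[3], x$a, x$b,
              x$ot_slope_multiplier))
  invisible(x)
}

# directed event rate for actor -> recipient in a dimension, under the
# configured dominance order. Credit semantics: proximity/aggression credit the
# actor (approacher / initiator); grooming credits the recipient (groomee), so
# the groomer->groomee direction is frequent when the recipient outranks the
# actor.
dyad_rate <- function(cfg, dimension, actor, recipient) {
  h <- cfg$hierarchy[[dimension]]
  actor_high <- match(actor, h) < match(recipient, h)
  credit_actor <- if (dimension == "grooming") !actor_high else actor_high
  if (credit_actor) cfg$rate_high else cfg$rate_low
}

#' Generate a colony interaction event log
#'
#' Poisson event counts per directed dyad, dimension, and observation session,
#' with uniform timestamps within sessions and exponential durations.
#' Deterministic given the seed.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return behavioral event data.frame (see [validate_events()]).
#' @export
gen_interaction_events <- function(config, seed = 1) {
  stopifnot(inherits(config, "study_config"))
  with_seed(seed, {
    roster <- config$roster
    rows <- list()
    for (s in seq_len(config$obs_sessions)) {
      sid <- sprintf("obs%03d", s)
      for (dim_ in SOC_DIMENSIONS) {
        for (i in roster) for (j in roster) {
          if (i == j) next
          lam <- dyad_rate(config, dim_, i, j) * config$session_hours
          k <- rpois(1, lam)
          if (!k) next
          rows[[length(rows) + 1]] <- data.frame(
            session_id = sid,
            time_s = round(sort(runif(k, 0, config$session_hours * 3600)), 1),
            actor = i, recipient = j, dimension = dim_,
            duration_s = round(rexp(k, rate = 1 / 20), 1)
          )
        }
      }
    }
    ev <- if (length(rows)) do.call(rbind, rows) else data.frame(
      session_id = character(0), time_s = numeric(0), actor = character(0),
      recipient = character(0), dimension = character(0), duration_s = numeric(0))
    validate_events(ev, roster)
    ev
  })
}

# generative face-effect signal (ms) per (subject, depicted face):
# a + b * Index, with condition multipliers applied for OT. Under SEI coupling
# the effect is constant across faces; under IEI coupling it follows
# IEI(subject -> partner) for in-group faces and is the bare intercept for
# out-group faces.
study_signal <- function(config, matrices, condition = "none") {
  w <- config$omega_star
  b <- config$b
  if (condition == "OT") {
    w <- w * config$ot_weight_multipliers[WEIGHT_NAMES]
    b <- b * config$ot_slope_multiplier
  }
  roster <- config$roster
  faces <- c(roster, config$out_group)
  sig <- matrix(config$a, length(roster), length(faces),
                dimnames = list(roster, faces))
  sei <- compute_sei(matrices, w)
  if (config$coupling_index == "sei") {
    sig[] <- config$a + b * sei[roster]
  } else {
    for (s in roster) for (p in setdiff(roster, s)) {
      sig[s, p] <- config$a + b * compute_iei(matrices, w, s, p)
    }
  }
  list(signal = sig, sei = sei, b = b, w = w)
}

#' Generate a trial table for the visual orienting task
#'
#' Per trial, RT = base(congruency) +/- face effect / 2 + Gaussian noise,
#' where the face effect applies to intact-face trials only (faster congruent,
#' slower incongruent), its magnitude for subject s on day d is
#' `a + b * Index(s; omega*) + eps_day` scaled by the in/out group effect, and
#' eps_day is day-level jitter. By construction the downstream drifting-time /
#' distractor-bias pipeline recovers a bias linear in the engagement index.
#' Capture flags are drawn from the configured class-specific probabilities.
#'
#' @param config a [study_config()].
#' @param matrices score matrices (e.g. from the generated event log).
#' @param seed integer seed.
#' @param condition `"none"`, `"saline"`, or `"OT"` (OT applies the configured
#'   slope/weight multipliers).
#' @return trial data.frame (see [validate_trials()]) with attribute `truth`
#'   (per-subject signal, SEI, effective slope and weights).
#' @export
gen_trial_set <- function(config, matrices, seed = 1, condition = "none") {
  stopifnot(inherits(config, "study_config"))
  condition <- match.arg(condition, c("none", "saline", "OT"))
  sig <- study_signal(config, matrices, condition)
  roster <- config$roster
  with_seed(seed, {
    # day-level jitter scaled to the spread of the coupled signal component
    sd_day <- config$bias_noise_frac * if (config$coupling_index == "sei") {
      stats::sd(sig$b * sig$sei)
    } else {
      cp <- (sig$signal - config$a)[, roster]
      stats::sd(cp[row(cp) != col(cp)])
    }
    if (!is.finite(sd_day)) sd_day <- 0
    n_int <- config$n_interference * config$sessions_per_day
    n_vm <- config$n_visuomotor * config$sessions_per_day
    faces_in <- lapply(roster, function(s) setdiff(roster, s))
    names(faces_in) <- roster
    out <- vector("list", length(roster) * config$n_days)
    k <- 0
    for (s in roster) {
      stim <- data.frame(
        face = c(faces_in[[s]], config$out_group),
        group = rep(c("in", "out"), c(length(faces_in[[s]]), length(config$out_group))))
      for (d in seq_len(config$n_days)) {
        eps_day <- rnorm(1, 0, sd_day)
        pick <- sample.int(nrow(stim), n_int, replace = TRUE)
        cls <- sample(c("intact", "scrambled"), n_int, replace = TRUE)
        cong <- sample(c("congruent", "incongruent"), n_int, replace = TRUE)
        g <- stim$group[pick]
        eff <- sig$signal[s, stim$face[pick]] + eps_day
        shift <- ifelse(cls == "intact",
                        ifelse(cong == "congruent", -0.5, 0.5) *
                          eff * config$group_effect[g],
                        0)
        rt <- config$base_rt[cong] + shift + rnorm(n_int, 0, config$rt_noise_sd)
        capt <- ifelse(cong == "incongruent",
                       rbinom(n_int, 1, config$capture_prob[cls]) == 1, NA)
        int_df <- data.frame(
          subject = s, day = d, drug_condition = condition,
          trial_type = "interference",
          distractor_id = stim$face[pick], distractor_class = cls,
          group = g, congruency = cong,
          rt_ms = pmax(round(rt, 2), 1),
          first_sacc_to_distractor = capt,
          valid = runif(n_int) >= config$fixation_break_rate)
        vm_df <- data.frame(
          subject = s, day = d, drug_condition = condition,
          trial_type = "visuomotor",
          distractor_id = NA_character_, distractor_class = "none",
          group = "none", congruency = "none",
          rt_ms = pmax(round(config$vm_rt + rnorm(n_vm, 0, config$rt_noise_sd), 2), 1),
          first_sacc_to_distractor = NA,
          valid = runif(n_vm) >= config$fixation_break_rate)
        k <- k + 1
        out[[k]] <- rbind(int_df, vm_df)
      }
    }
    trials <- do.call(rbind, out)
    rownames(trials) <- NULL
    validate_trials(trials)
    attr(trials, "truth") <- list(condition = condition, signal = sig$signal,
                                  sei = sig$sei, b = sig$b, w = sig$w,
                                  sd_day = sd_day)
    trials
  })
}

# minimum-jerk displacement profile on [0, 1]
minjerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

#' Generate a single-saccade eye trace
#'
#' Fixation with Gaussian positional noise plus a horizontal minimum-jerk
#' saccade of the given amplitude; duration follows a main-sequence-like rule
#' (`21 + 2.2 * amplitude` ms) unless given, so peak velocity scales with
#' amplitude.
#'
#' @param onset_ms generative saccade onset (movement start), ms.
#' @param amplitude saccade amplitude, deg (signed).
#' @param total_ms trace length, ms.
#' @param duration_ms saccade duration; NULL for the main-sequence rule.
#' @param start_x starting horizontal position, deg.
#' @param fix_noise_sd positional noise SD, deg (0 for a noiseless trace).
#' @param sample_rate Hz.
#' @param seed integer seed (ignored when `fix_noise_sd = 0`).
#' @param events optional event list to attach.
#' @return an [eye_trace()]; attribute `truth` holds the generative onset and
#'   duration.
#' @export
gen_saccade_trace <- function(onset_ms, amplitude, total_ms = 600,
                              duration_ms = NULL, start_x = 0,
                              fix_noise_sd = 0.02, sample_rate = 1000,
                              seed = 1, events = list()) {
  if (is.null(duration_ms)) duration_ms <- 21 + 2.2 * abs(amplitude)
  n <- round(total_ms * sample_rate / 1000) + 1
  t <- (seq_len(n) - 1) * 1000 / sample_rate
  u <- pmin(pmax((t - onset_ms) / duration_ms, 0), 1)
  x <- start_x + amplitude * minjerk(u)
  if (fix_noise_sd > 0) {
    x <- with_seed(seed, x + rnorm(n, 0, fix_noise_sd))
    y <- with_seed(seed + 1, rnorm(n, 0, fix_noise_sd))
  } else {
    y <- numeric(n)
  }
  tr <- eye_trace(x, y, sample_rate = sample_rate, events = events)
  attr(tr, "truth") <- list(onset_ms = onset_ms, duration_ms = duration_ms,
                            amplitude = amplitude)
  tr
}

#' Generate an eye trace for one trial
#'
#' Builds the trial timeline (800-1200 ms central fixation, 100 ms distractor
#' flash, target relocation 50 ms after distractor onset) and synthesizes a
#' 1 kHz trace whose target-acquiring saccade onset matches the trial's RT;
#' when the capture flag is set and the RT allows it, an earlier capture
#' saccade toward the distractor (and a corrective saccade back) precedes it.
#'
#' @param trial single-row trial record (needs `rt_ms`, `congruency`,
#'   `first_sacc_to_distractor`, `trial_type`).
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return an [eye_trace()] with populated `events` and attribute `truth`.
#' @export
gen_eye_trace <- function(trial, config, seed = 1) {
  stopifnot(inherits(config, "study_config"))
  if (is.na(trial$rt_ms) || trial$rt_ms <= 0) stop("trial RT inconsistent with timeline")
  with_seed(seed, {
    fix_dur <- round(runif(1, 800, 1200))
    vm <- trial$trial_type == "visuomotor"
    distractor_on <- if (vm) NULL else fix_dur
    target_move <- if (vm) fix_dur else fix_dur + 50
    side <- sample(c(-1, 1), 1)
    target_x <- side * config$saccade_amplitude
    distractor_x <- if (vm) NULL else {
      if (trial$congruency == "congruent") side * config$distractor_ecc else -side * config$distractor_ecc
    }
    rt <- trial$rt_ms
    sacc_dur <- config$saccade_duration_ms %||% (21 + 2.2 * config$saccade_amplitude)
    onset <- target_move + rt
    capture <- isTRUE(trial$first_sacc_to_distractor) && !vm && rt > 140
    total <- onset + sacc_dur + 100
    n <- round(total) + 1
    t <- seq_len(n) - 1
    x <- numeric(n)
    add_movement <- function(x, t0, from, to, dur) {
      u <- pmin(pmax((t - t0) / dur, 0), 1)
      x + (to - from) * minjerk(u)
    }
    if (capture) {
      c_on <- target_move + rt - 110
      c_dur <- 21 + 2.2 * config$distractor_ecc
      x <- add_movement(x, c_on, 0, distractor_x, c_dur)
      x <- add_movement(x, onset, distractor_x, target_x, 21 + 2.2 * abs(target_x - distractor_x))
    } else {
      x <- add_movement(x, onset, 0, target_x, sacc_dur)
    }
    x <- x + rnorm(n, 0, config$fix_noise_sd)
    y <- rnorm(n, 0, config$fix_noise_sd)
    ev <- list(fixation_on = 0, target_move = target_move, target_x = target_x)
    if (!vm) {
      ev$distractor_on <- distractor_on
      ev$distractor_x <- distractor_x
    }
    tr <- eye_trace(x, y, sample_rate = 1000, events = ev)
    attr(tr, "truth") <- list(onset_ms = onset,
                              capture_onset_ms = if (capture) target_move + rt - 110 else NULL,
                              rt_ms = rt)
    tr
  })
}

#' Generate a complete synthetic study
#'
#' End-to-end bundle: colony event log, the three score matrices built from
#' it, a baseline trial table, and (optionally) paired saline/OT trial tables
#' with the configured condition effects. Ground truth (`omega*`, `a`, `b`,
#' condition multipliers, seed) is stored alongside so recovery is measurable.
#'
#' @param config a [study_config()].
#' @param seed integer seed (sub-generators use offsets of it).
#' @param conditions if TRUE (default) also generate saline and OT trial
#'   tables.
#' @return object of class `study_bundle`: list (`events`, `matrices`,
#'   `trials`, `trials_saline`, `trials_ot`, `ground_truth`, `config`).
#' @export
gen_full_study <- function(config = study_config(), seed = 1, conditions = TRUE) {
  stopifnot(inherits(config, "study_config"))
  events <- gen_interaction_events(config, seed)
  matrices <- build_score_matrices(events, config$roster)
  trials <- gen_trial_set(config, matrices, seed + 1, condition = "none")
  trials_saline <- trials_ot <- NULL
  if (conditions) {
    trials_saline <- gen_trial_set(config, matrices, seed + 2, condition = "saline")
    trials_ot <- gen_trial_set(config, matrices, seed + 3, condition = "OT")
  }
  structure(list(
    events = events, matrices = matrices, trials = trials,
    trials_saline = trials_saline, trials_ot = trials_ot,
    ground_truth = list(omega_star = config$omega_star, a = config$a, b = config$b,
                        ot_slope_multiplier = config$ot_slope_multiplier,
                        ot_weight_multipliers = config$ot_weight_multipliers,
                        group_effect = config$group_effect, seed = seed),
    config = config
  ), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("study_bundle: %d events, %d baseline trials%s (seed %d)\n",
              nrow(x$events), nrow(x$trials),
              if (!is.null(x$trials_saline)) " + saline/OT conditions" else "",
              x$ground_truth$seed))
  invisible(x)
}
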