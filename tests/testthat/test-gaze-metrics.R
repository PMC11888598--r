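test_that("velocity estimation recovers constant, ramp, and saccadic profiles", {
  # constant position: essentially zero velocity
  tr <- eye_trace(rep(3, 500))
  kin <- compute_velocity(tr)
  expect_true(all(abs(kin$speed) < 1))

  # linear ramp, 10 deg over 1 s: steady-state velocity ~ 10 deg/s
  tr <- eye_trace(seq(0, 10, length.out = 1001))
  kin <- compute_velocity(tr)
  expect_equal(mean(kin$vx[200:800]), 10, tolerance = 0.01)

  # 14-deg, 40-ms minimum-jerk saccade: detected peak velocity within 10% of
  # the analytic velocity profile pushed through the same filter numerically
  dur <- 0.040; A <- 14; fs <- 1000
  tr <- gen_saccade_trace(200, A, total_ms = 500, duration_ms = 40, fix_noise_sd = 0)
  kin <- compute_velocity(tr)
  t <- (0:499) / fs
  u <- pmin(pmax((t - 0.2) / dur, 0), 1)
  v_analytic <- A / dur * (30 * u^2 - 60 * u^3 + 30 * u^4)
  bf <- signal::butter(1, 25 / (fs / 2), type = "low")
  v_filtered <- signal::filtfilt(bf, v_analytic)
  expect_equal(max(kin$speed), max(v_filtered), tolerance = 0.1)

  expect_error(compute_velocity(eye_trace(rep(0, 10))), "too short")
})

test_that("saccade detection finds true events and nothing in fixation noise", {
  # flat noise trace (sigma = 0.05 deg): no detections
  set.seed(1)
  tr <- gen_saccade_trace(1e9, 0, total_ms = 600, fix_noise_sd = 0.05, seed = 11)
  expect_equal(nrow(detect_saccades(tr)), 0)

  # single saccade with generative onset 150 ms: onset recovered to ~ms
  tr1 <- gen_saccade_trace(150, 12, total_ms = 500, fix_noise_sd = 0.02, seed = 3)
  s1 <- detect_saccades(tr1)
  expect_equal(nrow(s1), 1)
  expect_lt(abs(s1$onset_ms - 150), 2 + 3)  # threshold-crossing latency + jitter
  expect_equal(s1$direction, 1)

  # two saccades 300 ms apart: two ordered events
  t <- 0:799
  mj <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5
  x <- 10 * mj(pmin(pmax((t - 150) / 43, 0), 1)) -
    10 * mj(pmin(pmax((t - 450) / 43, 0), 1))
  s2 <- detect_saccades(eye_trace(x))
  expect_equal(nrow(s2), 2)
  expect_lt(s2$onset_ms[1], s2$onset_ms[2])
  expect_equal(s2$direction, c(1, -1))
  expect_true(all(s2$onset_ms < s2$offset_ms))
  expect_true(all(s2$peak_velocity >= 50))
})

test_that("fixation-interval validation uses a half-open 500 ms window", {
  tr <- eye_trace(rep(0, 100), events = list(distractor_on = 1000, target_move = 1050))
  sacc <- function(onset) data.frame(onset_ms = onset, offset_ms = onset + 40,
                                     peak_velocity = 300, direction = 1)
  expect_false(validate_trial(tr, sacc(900)))    # inside the window
  expect_false(validate_trial(tr, sacc(500)))    # boundary: window start included
  expect_true(validate_trial(tr, sacc(1000)))    # at distractor onset: excluded
  expect_true(validate_trial(tr, sacc(499)))     # before the window
  expect_true(validate_trial(tr, sacc(0)[0, ]))  # no saccades at all
  # visuomotor trials reference the target relocation
  trv <- eye_trace(rep(0, 100), events = list(target_move = 800))
  expect_false(validate_trial(trv, sacc(700)))
  expect_error(validate_trial(eye_trace(rep(0, 100)), sacc(1)), "events")
})

test_that("response times come from the first target-acquiring saccade", {
  cfg <- study_config()
  trial <- data.frame(subject = "MA", day = 1, drug_condition = "none",
                      trial_type = "interference", distractor_id = "MK",
                      distractor_class = "intact", group = "in",
                      congruency = "incongruent", rt_ms = 180,
                      first_sacc_to_distractor = FALSE, valid = TRUE)
  tr <- gen_eye_trace(trial, cfg, seed = 5)
  rt <- response_time(tr, detect_saccades(tr))
  expect_equal(rt$rt_ms, 180, tolerance = 0.02)
  expect_false(rt$first_sacc_to_distractor)
  expect_true(rt$rewarded)

  # capture trial: first saccade to the distractor, RT from the corrective one
  trial$first_sacc_to_distractor <- TRUE
  trial$rt_ms <- 260
  tr2 <- gen_eye_trace(trial, cfg, seed = 6)
  rt2 <- response_time(tr2, detect_saccades(tr2))
  expect_true(rt2$first_sacc_to_distractor)
  expect_equal(rt2$rt_ms, 260, tolerance = 0.03)

  # a >300 ms response is flagged unrewarded
  trial$first_sacc_to_distractor <- FALSE
  trial$rt_ms <- 320
  tr3 <- gen_eye_trace(trial, cfg, seed = 7)
  expect_false(response_time(tr3, detect_saccades(tr3))$rewarded)

  # no saccade at all: no-response error
  trf <- eye_trace(rep(0, 1500), events = list(distractor_on = 900,
                                               target_move = 950, target_x = 14))
  expect_error(response_time(trf, detect_saccades(trf)), "no-response")
})

test_that("drifting time reproduces the worked example-day arithmetic", {
  cells <- data.frame(face = "F1", group = "in",
                      class = rep(c("intact", "scrambled"), 2),
                      congruency = rep(c("congruent", "incongruent"), each = 2),
                      rt = c(125.25, 142.80, 228.19, 213.97), n = 4)
  tr <- make_cell_trials(cells)
  dcon <- drifting_time(tr, "MA", 1, "F1", "congruent")
  dinc <- drifting_time(tr, "MA", 1, "F1", "incongruent")
  expect_equal(dcon$dt_ms, -17.55)
  expect_equal(dinc$dt_ms, 14.22)

  # identical RT distributions in both classes: DT = 0
  cells0 <- data.frame(face = "F1", group = "in",
                       class = c("intact", "scrambled"),
                       congruency = "congruent", rt = 150, n = 6)
  expect_equal(drifting_time(make_cell_trials(cells0), "MA", 1, "F1",
                             "congruent")$dt_ms, 0)

  # empty cell errors, naming the cell
  expect_error(drifting_time(tr, "MA", 1, "F9", "congruent"), "F9")
  # the vectorized table agrees with the per-cell op
  dt <- drifting_time_table(tr)
  expect_equal(nrow(dt), 2)
  expect_equal(dt$dt_ms[dt$congruency == "congruent"], -17.55)
  expect_equal(dt$dt_ms[dt$congruency == "incongruent"], 14.22)
})

test_that("drifting time is invariant to constant RT shifts", {
  for (seed in 1:100) {
    set.seed(seed)
    rts <- round(runif(4, 100, 250), 2)
    cells <- data.frame(face = "F1", group = "in",
                        class = rep(c("intact", "scrambled"), 2),
                        congruency = rep(c("congruent", "incongruent"), each = 2),
                        rt = rts, n = 3)
    shift <- runif(1, -40, 40)
    cells2 <- cells; cells2$rt <- cells2$rt + shift
    d1 <- drifting_time_table(make_cell_trials(cells), exclude_unrewarded = FALSE)
    d2 <- drifting_time_table(make_cell_trials(cells2), exclude_unrewarded = FALSE)
    expect_equal(d2$dt_ms, d1$dt_ms)
  }
})

test_that("distractor bias is DT(incongruent) - DT(congruent) and flips under congruency swap", {
  cells <- data.frame(face = "F1", group = "in",
                      class = rep(c("intact", "scrambled"), 2),
                      congruency = rep(c("congruent", "incongruent"), each = 2),
                      rt = c(125.25, 142.80, 228.19, 213.97), n = 4)
  dt <- drifting_time_table(make_cell_trials(cells))
  b <- distractor_bias(dt, "MA", 1, "in")
  expect_equal(b$bias_ms, 31.77)
  expect_equal(distractor_bias_table(dt, "in")$bias_ms, 31.77)

  # all-zero drifting times: zero bias
  dt0 <- dt; dt0$dt_ms <- 0
  expect_equal(distractor_bias(dt0, "MA", 1, "in")$bias_ms, 0)

  # swapping congruency labels negates the bias (property over random tables)
  for (seed in 1:100) {
    set.seed(seed)
    dtr <- data.frame(subject = "MA", day = rep(1:3, each = 4),
                      face_id = rep(c("F1", "F2"), 6), group = "in",
                      congruency = rep(c("congruent", "incongruent"), 6),
                      dt_ms = rnorm(12, 0, 20))
    swapped <- dtr
    swapped$congruency <- ifelse(dtr$congruency == "congruent",
                                 "incongruent", "congruent")
    b1 <- distractor_bias_table(dtr, "in")
    b2 <- distractor_bias_table(swapped, "in")
    expect_equal(b2$bias_ms, -b1$bias_ms)
  }

  # missing congruency cell errors
  expect_error(distractor_bias(dt[dt$congruency == "congruent", ], "MA", 1, "in"),
               "insufficient")
})

test_that("first-saccade probability differences are simple proportion contrasts", {
  mk <- function(class, n_hit, n_tot) {
    data.frame(subject = "MA", day = 1, drug_condition = "none",
               trial_type = "interference", distractor_id = "F1",
               distractor_class = class, group = "in", congruency = "incongruent",
               rt_ms = 150,
               first_sacc_to_distractor = rep(c(TRUE, FALSE), c(n_hit, n_tot - n_hit)),
               valid = TRUE)
  }
  tr <- rbind(mk("intact", 30, 100), mk("scrambled", 10, 100))
  res <- first_saccade_prob_diff(tr)
  expect_equal(res$diff, 0.2)
  expect_equal(res$p_intact, 0.3)
  expect_true(res$p_intact >= 0 && res$p_intact <= 1)

  # identical behavior in both classes: difference 0
  tr0 <- rbind(mk("intact", 12, 50), mk("scrambled", 12, 50))
  expect_equal(first_saccade_prob_diff(tr0)$diff, 0)

  # no incongruent trials: error
  trc <- tr; trc$congruency <- "congruent"
  expect_error(first_saccade_prob_diff(trc), "insufficient")
})

test_that("trial tables and eye traces round-trip through CSV", {
  cfg <- tiny_config()
  st <- gen_full_study(cfg, 2, conditions = FALSE)
  f <- tempfile(fileext = ".csv")
  write_trials_csv(st$trials, f)
  back <- read_trials_csv(f)
  expect_equal(back$rt_ms, st$trials$rt_ms)
  expect_equal(back$subject, st$trials$subject)
  expect_equal(back$valid, st$trials$valid)

  tr <- gen_saccade_trace(150, 10, total_ms = 300, fix_noise_sd = 0.02, seed = 4,
                          events = list(distractor_on = 80, target_move = 130,
                                        target_x = 10))
  f2 <- tempfile(fileext = ".csv")
  write_eye_trace(tr, f2)
  tr2 <- read_eye_trace(f2)
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$sample_rate, tr$sample_rate)
  expect_equal(tr2$events$target_move, 130)
})
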