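test_that("blink-free input passes through blink removal unchanged", {
  g <- make_gaze(600)
  out <- remove_blinks(g)
  expect_false(any(out$blink))
  expect_equal(out$pupil_left_mm, g$pupil_left_mm)
  expect_equal(nrow(blink_intervals(out)), 0)
})

test_that("a zeroed span in a constant pupil interpolates back exactly", {
  g <- make_gaze(600, pupil = 3)
  g$pupil_left_mm[200:220] <- 0
  g$pupil_right_mm[200:220] <- 0
  g$valid_left[200:220] <- FALSE
  out <- remove_blinks(g, pad_ms = 100)
  expect_equal(out$pupil_left_mm, rep(3, 600))
  expect_equal(out$pupil_right_mm, rep(3, 600))
  expect_true(all(out$blink[200:220]))
  # padding marks ~6 samples each side at 60 Hz
  expect_true(out$blink[195] && out$blink[225])
  expect_false(out$blink[190] || out$blink[230])
})

test_that("injected blinks are recovered with high interval overlap", {
  for (seed in 1:3) {
    cfg <- tiny_coupled_config(seed = seed)
    ses <- generate_session(cfg, 1, 1)
    truth <- ses$truth$blink_intervals
    clean <- remove_blinks(ses$gaze)
    found <- blink_intervals(clean)
    expect_equal(nrow(found), nrow(truth))
    expect_gte(interval_jaccard(found, truth), 0.9)
  }
})

test_that("sessions drowned in blinks are rejected", {
  g <- make_gaze(600)
  g$valid_left[1:400] <- FALSE
  expect_error(remove_blinks(g), "50%")
})

test_that("I-VT handles the degenerate limits", {
  g <- make_gaze(600)
  ev <- classify_ivt(g)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "fixation")
  # huge threshold: everything is one fixation even with jumps
  jg <- make_jump_gaze(5, n = 600)
  ev2 <- classify_ivt(jg$gaze, velocity_threshold = 1e12)
  expect_equal(nrow(ev2), 1)
  expect_error(classify_ivt(g, velocity_threshold = -1), "positive")
})

test_that("I-VT recovers scripted jumps exactly", {
  jg <- make_jump_gaze(20, n = 3600, amplitude = 5)
  ev <- classify_ivt(jg$gaze, velocity_threshold = 30)
  expect_equal(sum(ev$kind == "saccade"), 20)
  expect_equal(ev$amplitude[ev$kind == "saccade"], rep(5, 20))
})

test_that("raising the threshold never increases the saccade count", {
  cfg <- tiny_coupled_config(seed = 4)
  ses <- generate_session(cfg, 1, 1)
  clean <- remove_blinks(ses$gaze)
  # sweep stays above the ocular-drift velocity floor (~5 units/s):
  # below it, lowering the threshold merges saccade runs and the count
  # is no longer monotone in the threshold
  counts <- vapply(c(15, 20, 30, 60, 120, 500), function(th) {
    sum(classify_ivt(clean, velocity_threshold = th)$kind == "saccade")
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("events partition the recording timeline", {
  cfg <- tiny_coupled_config(seed = 5)
  ses <- generate_session(cfg, 1, 1)
  clean <- remove_blinks(ses$gaze)
  ev <- classify_ivt(clean)
  expect_true(all(ev$end_s > ev$start_s))
  expect_true(all(diff(ev$start_s) > 0))
  # consecutive events abut
  expect_equal(ev$start_s[-1], ev$end_s[-nrow(ev)])
  expect_equal(sum(ev$end_s - ev$start_s), 60, tolerance = 2 / 60)
})

test_that("fixation distance follows centroid geometry", {
  ev <- tibble::tibble(
    kind = c("fixation", "saccade", "fixation"),
    start_s = c(0, 1, 1.05),
    end_s = c(1, 1.05, 2),
    centroid_x = c(0, NA, 3),
    centroid_y = c(0, NA, 4),
    amplitude = c(NA, 5, NA),
    peak_velocity = c(1, 300, 1),
    duration_s = c(1, 0.05, 0.95),
    velocity = c(NA, 100, NA))
  s <- fixation_distance_series(ev, rate = 60, n_samples = 120)
  expect_equal(s$value[s$time_s < 1.05][1], 0)   # before second fixation
  expect_equal(s$value[s$time_s >= 1.05][1], 5)  # 3-4-5 triangle
  # identical consecutive centroids give zero distance
  ev2 <- ev
  ev2$centroid_x[3] <- 0; ev2$centroid_y[3] <- 0
  s2 <- fixation_distance_series(ev2, rate = 60, n_samples = 120)
  expect_equal(s2$value[120], 0)
  # fewer than two fixations: all-zero with a warning
  expect_warning(
    s3 <- fixation_distance_series(ev[1, ], rate = 60, n_samples = 60),
    "fewer than 2")
  expect_true(all(s3$value == 0))
})

test_that("saccade amplitude series is amplitude during saccades, else 0", {
  ev <- tibble::tibble(
    kind = c("fixation", "saccade", "fixation"),
    start_s = c(0, 1, 1.05),
    end_s = c(1, 1.05, 2),
    centroid_x = c(0, NA, 10),
    centroid_y = c(0, NA, 0),
    amplitude = c(NA, 10, NA),
    peak_velocity = c(1, 600, 1),
    duration_s = c(1, 0.05, 0.95),
    velocity = c(NA, 200, NA))
  s <- saccade_amplitude_series(ev, rate = 60, n_samples = 120)
  inside <- s$time_s >= 1 & s$time_s < 1.05
  expect_equal(sum(inside), 3)  # 3 samples at 60 Hz
  expect_true(all(s$value[inside] == 10))
  expect_true(all(s$value[!inside] == 0))
  # no saccades -> all-zero series
  s0 <- saccade_amplitude_series(ev[c(1, 3), ], rate = 60, n_samples = 60)
  expect_true(all(s0$value == 0))
})

test_that("scripted saccades carry amplitude/duration as velocity", {
  jg <- make_jump_gaze(10, n = 1200, amplitude = 4)
  ev <- classify_ivt(jg$gaze)
  sac <- ev[ev$kind == "saccade", ]
  expect_equal(sac$velocity, sac$amplitude / sac$duration_s)
  expect_equal(sac$amplitude, rep(4, 10))
})

test_that("pupil series is mean-centered and side-symmetric", {
  g <- make_gaze(600, pupil = 3)
  expect_true(all(pupil_series(g, "left")$value == 0))
  g2 <- make_gaze(600)
  wobble <- sin(seq_len(600) / 20)
  g2$pupil_left_mm <- 3 + wobble
  g2$pupil_right_mm <- 3 + wobble
  expect_equal(pupil_series(g2, "left")$value,
               pupil_series(g2, "right")$value)
  expect_equal(mean(pupil_series(g2, "left")$value), 0, tolerance = 1e-12)
  expect_error(pupil_series(g2, "up"))
})

test_that("a sinusoidal pupil modulation dominates the periodogram", {
  n <- 120 * 60
  g <- make_gaze(n)
  g$pupil_left_mm <- 3 + 0.4 * sin(2 * pi * 0.3 * g$time_s) +
    rnorm(n, sd = 0.02)
  s <- pupil_series(g, "left")
  psd <- eyesync:::periodogram_psd(s$value, 60)
  expect_equal(psd$freq[which.max(psd$psd)], 0.3, tolerance = 0.02)
})

test_that("all four feature series share length and time base", {
  cfg <- tiny_coupled_config(seed = 6)
  ses <- generate_session(cfg, 1, 1)
  clean <- remove_blinks(ses$gaze)
  feats <- eye_feature_series(clean)
  counts <- table(feats$feature)
  expect_equal(length(counts), 4)
  expect_true(all(counts == nrow(clean)))
  expect_setequal(unique(feats$feature), eye_features())
})
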