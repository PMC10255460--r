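#' Specify a planted cross-modal coupling
#'
#' Describes a ground-truth coupling between one eye-movement feature
#' and one EEG channel in one band, to be planted by the synthetic
#' generator. A shared band-limited latent source drives both sides with
#' mixing weight `strength`; `link = "monotone_nonlinear"` passes the
#' eye side through a fixed monotone nonlinearity (a rescaled cube).
#'
#' @param eye_feature One of [eye_features()].
#' @param channel One of the 18 montage channels ([eeg_channels()]).
#' @param band One of delta/theta/alpha/beta (eye-band edges drive the
#'   latent; the EEG side is amplitude-modulated inside the same-named
#'   EEG band).
#' @param strength Coupling strength in `[0, 1]`.
#' @param link `"linear"` or `"monotone_nonlinear"`.
#' @param empathic Restrict the coupling to empathic (`TRUE`) or
#'   non-empathic (`FALSE`) sessions; `NA` (default) applies everywhere.
#' @param quadrant Restrict to one valence-arousal quadrant (`NA`: all).
#' @return A one-row tibble.
#' @export
coupling_spec <- function(eye_feature, channel, band, strength,
                          link = c("linear", "monotone_nonlinear"),
                          empathic = NA, quadrant = NA_character_) {
  link <- match.arg(link)
  assert_eye_feature(eye_feature)
  assert_channel(channel)
  assert_band(band)
  if (!is.numeric(strength) || strength < 0 || strength > 1) {
    stop("coupling strength must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(quadrant) && !quadrant %in% quadrants()$quadrant) {
    stop("unknown quadrant: ", quadrant, call. = FALSE)
  }
  tibble::tibble(eye_feature = eye_feature, channel = channel, band = band,
                 strength = strength, link = link, empathic = empathic,
                 quadrant = quadrant)
}

#' Default condition labels for an eight-video session set
#'
#' One empathic and one non-empathic video per valence-arousal quadrant,
#' mirroring a stimulus set in which an empathic/non-empathic pair was
#' selected for each quadrant of the two-dimensional emotion model.
#'
#' @param n_videos Number of videos; the default 8 covers all four
#'   quadrants in both conditions, other counts recycle that pattern.
#' @return Tibble `video_id, empathic, valence, arousal, quadrant`.
#' @export
default_condition_labels <- function(n_videos = 8) {
  q <- quadrants()
  base <- tidyr::crossing(empathic = c(TRUE, FALSE), quadrant = q$quadrant)
  base <- dplyr::left_join(base, q, by = "quadrant")
  base <- base[order(base$quadrant, -base$empathic), ]
  idx <- rep_len(seq_len(8), n_videos)
  out <- base[idx, ]
  out$video_id <- seq_len(n_videos)
  out[, c("video_id", "empathic", "valence", "arousal", "quadrant")]
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles the study conditions the generator emulates: dual-rate
#' acquisition (18-channel EEG at 500 Hz, gaze/pupil at 60 Hz), videos
#' per subject with factorial empathy x valence x arousal labels,
#' blink and saccade statistics, and a list of planted couplings.
#'
#' @param n_subjects Number of subjects.
#' @param n_videos Videos per subject (default 8).
#' @param duration_s Seconds per video (default 300, comfortably longer
#'   than the 180 s analysis window).
#' @param couplings Tibble of [coupling_spec()] rows (bind with
#'   `dplyr::bind_rows()`), or `NULL` for an uncoupled cohort.
#' @param noise_sd Measurement noise scale: white-noise sd in mm on each
#'   pupil trace, and `100 * noise_sd` microvolts on each EEG channel
#'   (default 0.05).
#' @param blink_rate_per_min Poisson blink rate (default 15 per minute).
#' @param blink_duration_ms Blink duration (default 200 ms).
#' @param saccade_rate_per_s Saccade rate (default 2 per second).
#' @param condition_labels Label tibble (default
#'   [default_condition_labels()]).
#' @param seed Master seed; each session derives its own RNG stream from
#'   `(seed, subject_id, video_id)` so cohorts are reproducible even
#'   under out-of-order generation.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 6, n_videos = 8, duration_s = 300,
                         couplings = NULL, noise_sd = 0.05,
                         blink_rate_per_min = 15, blink_duration_ms = 200,
                         saccade_rate_per_s = 2, condition_labels = NULL,
                         seed = 1) {
  if (duration_s <= 0 || n_subjects < 1 || n_videos < 1) {
    stop("n_subjects, n_videos and duration_s must be positive", call. = FALSE)
  }
  if (blink_rate_per_min < 0 || blink_duration_ms < 0 ||
      saccade_rate_per_s < 0 || noise_sd < 0) {
    stop("rates, durations and noise_sd must be non-negative", call. = FALSE)
  }
  if (is.null(condition_labels)) {
    condition_labels <- default_condition_labels(n_videos)
  }
  if (!is.null(couplings)) {
    purrr::pwalk(couplings[, c("eye_feature", "channel", "band", "strength")],
                 function(eye_feature, channel, band, strength) {
                   assert_eye_feature(eye_feature); assert_channel(channel)
                   assert_band(band)
                   stopifnot(strength >= 0, strength <= 1)
                 })
  }
  structure(list(
    n_subjects = n_subjects, n_videos = n_videos, duration_s = duration_s,
    eeg_rate = 500, gaze_rate = 60, couplings = couplings,
    noise_sd = noise_sd, blink_rate_per_min = blink_rate_per_min,
    blink_duration_ms = blink_duration_ms,
    saccade_rate_per_s = saccade_rate_per_s,
    condition_labels = condition_labels, seed = seed
  ), class = "synth_config")
}

# Deterministic per-session RNG stream key; kept below 2^31 - 1.
session_seed <- function(seed, subject_id, video_id, salt = 0) {
  as.integer((abs(seed) %% 1000003) * 2017 + subject_id * 10007 +
               video_id * 101 + salt) %% 2147483629L
}

# Gaussian noise whose power lies entirely inside [f_lo, f_hi), built by
# zeroing out-of-band Fourier bins of white noise; standardized to sd 1.
bandlimited_noise <- function(n, rate, f_lo, f_hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)
  X[!(f >= f_lo & f < f_hi)] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Monotone link on the eye side of a coupling. The nonlinear link is a
# rescaled cube projected back into the latent's own band: cubing a
# narrowband signal cubes its amplitude envelope but also throws
# two-thirds of the power into the third-harmonic band, so the in-band
# projection keeps the latent spectrally placed while preserving the
# monotone amplitude distortion. The cubed trace is given 1.5x the
# linear link's amplitude: its windowed power rides the cube of the
# latent's local power, and the larger scale keeps those heavy-tailed
# excursions spanning the band ratio's sensitive range instead of
# collapsing into its flat lower end.
apply_link <- function(s, link, rate, f_lo, f_hi) {
  if (link == "monotone_nonlinear") {
    g <- s^3
    n <- length(g)
    X <- stats::fft(g)
    f <- (seq_len(n) - 1) / n * rate
    f <- pmin(f, rate - f)
    X[!(f >= f_lo & f < f_hi)] <- 0
    g <- Re(stats::fft(X, inverse = TRUE)) / n
    1.5 * g / stats::sd(g)
  } else {
    s
  }
}

couplings_for_session <- function(config, label) {
  cp <- config$couplings
  if (is.null(cp) || nrow(cp) == 0) return(cp)
  keep <- (is.na(cp$empathic) | cp$empathic == label$empathic) &
    (is.na(cp$quadrant) | cp$quadrant == label$quadrant)
  cp[keep, ]
}

#' Generate one coupled EEG + gaze session
#'
#' Draws a session from its own RNG stream keyed by
#' `(seed, subject_id, video_id)`. Each active coupling realizes a
#' shared latent source as band-limited Gaussian noise in the eye-band
#' edges of the coupling's band; the latent is added into the eye
#' feature's generative trace with weight `strength` (through the link
#' nonlinearity, eye side only) and amplitude-modulates a carrier inside
#' the same-named EEG band of the target channel, so that the EEG
#' band-ratio series tracks the eye band-ratio series. All remaining
#' variance is independent background and measurement noise. Blinks are
#' injected per the config's Poisson blink process.
#'
#' @param config A [synth_config()].
#' @param subject_id,video_id Positive integers identifying the session.
#' @return List with elements `eeg` (tibble, `time_s` + 18 channels,
#'   microvolts), `gaze` (tibble, gaze CSV schema, with ground-truth
#'   blink intervals as attribute), `label` (one-row condition tibble)
#'   and `truth` (ground-truth saccade log and active couplings).
#' @export
generate_session <- function(config, subject_id, video_id) {
  stopifnot(inherits(config, "synth_config"))
  label <- config$condition_labels[
    config$condition_labels$video_id == video_id, ]
  if (nrow(label) != 1) stop("no condition label for video ", video_id,
                             call. = FALSE)
  label$subject_id <- subject_id
  dur <- config$duration_s
  n_eeg <- round(dur * config$eeg_rate)
  n_gaze <- round(dur * config$gaze_rate)
  active <- couplings_for_session(config, label)
  eye_sch <- band_scheme("eye")
  eeg_sch <- band_scheme("eeg")

  out <- withr::with_seed(
    session_seed(config$seed, subject_id, video_id), {
      t_gaze <- (seq_len(n_gaze) - 1) / config$gaze_rate
      t_eeg <- (seq_len(n_eeg) - 1) / config$eeg_rate

      # latent sources, one per active coupling, realized at 60 Hz and
      # linearly upsampled to 500 Hz (band content is far below the
      # gaze Nyquist, so interpolation is spectrally faithful)
      latents <- list()
      if (!is.null(active) && nrow(active) > 0) {
        for (i in seq_len(nrow(active))) {
          b <- eye_sch[eye_sch$band == active$band[i], ]
          s60 <- bandlimited_noise(n_gaze, config$gaze_rate, b$f_lo, b$f_hi)
          s500 <- stats::approx(t_gaze, s60, t_eeg, rule = 2)$y
          g60 <- apply_link(s60, active$link[i], config$gaze_rate,
                            b$f_lo, b$f_hi)
          latents[[i]] <- list(s60 = s60, s500 = s500, g60 = g60)
        }
      }

      # ---- gaze stream ----
      # saccade onsets: Poisson arrivals with a 150 ms refractory gap
      gaps <- stats::rexp(ceiling(dur * config$saccade_rate_per_s * 2) + 20,
                          rate = max(config$saccade_rate_per_s, 1e-9))
      gaps <- pmax(gaps, 0.15)
      onsets <- cumsum(gaps)
      onsets <- onsets[onsets < dur - 0.1 & onsets > 0.3]
      base_amp <- stats::rlnorm(length(onsets), log(3), 0.4)
      amp <- base_amp
      if (!is.null(active) && nrow(active) > 0) {
        for (i in seq_len(nrow(active))) {
          if (active$eye_feature[i] %in% c("saccade_amplitude",
                                           "fixation_distance")) {
            g_at <- stats::approx(t_gaze, latents[[i]]$g60, onsets,
                                  rule = 2)$y
            amp <- amp * exp(active$strength[i] * g_at)
          }
        }
      }
      theta <- stats::runif(length(onsets), 0, 2 * pi)
      cx <- 0; cy <- 0
      center_x <- numeric(n_gaze); center_y <- numeric(n_gaze)
      prev_idx <- 1
      for (i in seq_along(onsets)) {
        idx <- min(n_gaze, floor(onsets[i] * config$gaze_rate) + 1)
        center_x[prev_idx:idx] <- cx
        center_y[prev_idx:idx] <- cy
        dx <- amp[i] * cos(theta[i]); dy <- amp[i] * sin(theta[i])
        if (abs(cx + dx) > 12) dx <- -dx   # keep gaze on screen
        if (abs(cy + dy) > 12) dy <- -dy
        cx <- cx + dx; cy <- cy + dy
        prev_idx <- idx + 1
      }
      if (prev_idx <= n_gaze) {
        center_x[prev_idx:n_gaze] <- cx
        center_y[prev_idx:n_gaze] <- cy
      }
      # slow ocular drift: AR(1) jitter, stationary sd 0.3 deg, smooth
      # enough that drift velocity stays well under saccade velocities
      phi <- 0.97
      jit <- function() {
        e <- stats::rnorm(n_gaze, sd = 0.3 * sqrt(1 - phi^2))
        stats::filter(e, phi, method = "recursive")
      }
      gaze_x <- center_x + as.numeric(jit())
      gaze_y <- center_y + as.numeric(jit())

      # Narrowband oscillator at a band's log-center frequency with slow
      # phase noise. Its modulus is constant, so its window band power
      # is set by the (optional) envelope alone rather than by the
      # sampling fluctuations a stochastic band-limited process shows.
      oscillator <- function(n, rate, tt, f_lo, f_hi) {
        f_c <- sqrt(f_lo * f_hi)
        phase <- cumsum(stats::rnorm(n, sd = 2 * pi * 0.02 * f_c /
                                       sqrt(rate)))
        sqrt(2) * cos(2 * pi * f_c * tt + phase)
      }

      # ---- pupil streams ----
      # background = per-band rhythmic oscillators (hippus-like slow
      # pupil rhythms) + white measurement noise; the coupled latent is
      # added on top with weight `strength`
      pupil_bg_rms <- c(delta = 0.01, theta = 0.07, alpha = 0.07,
                        beta = 0.07)
      pupil <- list()
      for (side in c("pupil_left", "pupil_right")) {
        p <- rep(3, n_gaze)
        for (bi in seq_len(nrow(eye_sch))) {
          p <- p + pupil_bg_rms[[eye_sch$band[bi]]] *
            oscillator(n_gaze, config$gaze_rate, t_gaze,
                       eye_sch$f_lo[bi], eye_sch$f_hi[bi])
        }
        p <- p + stats::rnorm(n_gaze, sd = config$noise_sd)
        if (!is.null(active) && nrow(active) > 0) {
          for (i in seq_len(nrow(active))) {
            if (active$eye_feature[i] == side) {
              p <- p + 0.2 * active$strength[i] * latents[[i]]$g60
            }
          }
        }
        pupil[[side]] <- p
      }

      # ---- EEG ----
      # each channel = per-band rhythmic oscillators (alpha rhythm and
      # kin) + weak broadband noise + white measurement noise; a coupled
      # band's oscillator is amplitude-modulated so that its window band
      # power is linear in the latent's instantaneous power -- exactly
      # the quantity the eye side's band power measures, which makes the
      # EEG band-ratio series track the eye band-ratio series
      eeg_bg_rms <- c(delta = 10, theta = 8, alpha = 12, beta = 6)
      eeg <- matrix(0, nrow = n_eeg, ncol = 18,
                    dimnames = list(NULL, eeg_channels()))
      for (ch in eeg_channels()) {
        sig <- 6 * bandlimited_noise(n_eeg, config$eeg_rate, 1, 30) +
          stats::rnorm(n_eeg, sd = 100 * config$noise_sd)
        for (bi in seq_len(nrow(eeg_sch))) {
          band <- eeg_sch$band[bi]
          osc <- eeg_bg_rms[[band]] *
            oscillator(n_eeg, config$eeg_rate, t_eeg,
                       eeg_sch$f_lo[bi], eeg_sch$f_hi[bi])
          if (!is.null(active) && nrow(active) > 0) {
            for (i in seq_len(nrow(active))) {
              if (active$channel[i] == ch && active$band[i] == band) {
                env <- sqrt(1 + active$strength[i] * latents[[i]]$s500^2)
                osc <- osc * env
              }
            }
          }
          sig <- sig + osc
        }
        eeg[, ch] <- sig
      }

      gaze <- tibble::tibble(
        time_s = t_gaze, gaze_x = gaze_x, gaze_y = gaze_y,
        pupil_left_mm = pupil$pupil_left,
        pupil_right_mm = pupil$pupil_right,
        valid_left = TRUE, valid_right = TRUE
      )
      list(
        eeg = dplyr::bind_cols(tibble::tibble(time_s = t_eeg),
                               tibble::as_tibble(eeg)),
        gaze = gaze,
        truth = list(saccade_onsets = onsets, saccade_amplitudes = amp)
      )
    })

  gaze <- inject_blinks(out$gaze, config$blink_rate_per_min,
                        config$blink_duration_ms,
                        seed = session_seed(config$seed, subject_id,
                                            video_id, salt = 7))
  list(eeg = validate_eeg(out$eeg), gaze = gaze, label = label,
       truth = c(out$truth,
                 list(couplings = active,
                      blink_intervals = blink_intervals(gaze))))
}

#' Inject blink artifacts into a gaze recording
#'
#' Places non-overlapping blink intervals by a Poisson process (count ~
#' Poisson(rate_per_min x minutes), uniform placement with overlap
#' rejection); inside each interval both pupil diameters are set to 0
#' and both validity flags to false. Ground-truth intervals are recorded
#' as attribute `"blink_intervals"`.
#'
#' @param gaze Gaze tibble.
#' @param rate_per_min Blink rate per minute; 0 returns the input
#'   unchanged.
#' @param duration_ms Blink duration, ms.
#' @param seed RNG seed for placement.
#' @return Gaze tibble with blinks injected.
#' @export
inject_blinks <- function(gaze, rate_per_min, duration_ms, seed = 1) {
  if (rate_per_min < 0 || duration_ms < 0) {
    stop("blink rate and duration must be non-negative", call. = FALSE)
  }
  n <- nrow(gaze)
  rate <- recording_rate(gaze)
  dur <- n / rate
  if (duration_ms / 1000 > dur) {
    stop("blink duration exceeds recording length", call. = FALSE)
  }
  if (rate_per_min == 0) {
    attr(gaze, "blink_intervals") <- tibble::tibble(start_s = numeric(),
                                                    end_s = numeric())
    return(gaze)
  }
  len <- max(1L, round(duration_ms / 1000 * rate))
  out <- withr::with_seed(as.integer(seed), {
    n_blinks <- stats::rpois(1, rate_per_min * dur / 60)
    starts <- integer(0)
    if (n_blinks > 0) {
      cand <- sample.int(max(n - len, 1), min(n_blinks * 4, max(n - len, 1)))
      for (s in cand) {
        if (length(starts) >= n_blinks) break
        # reject overlaps (with a 2-sample guard band)
        if (!any(abs(s - starts) < len + 2)) starts <- c(starts, s)
      }
      starts <- sort(starts)
    }
    g <- gaze
    for (s in starts) {
      idx <- s:(s + len - 1)
      g$pupil_left_mm[idx] <- 0
      g$pupil_right_mm[idx] <- 0
      g$valid_left[idx] <- FALSE
      g$valid_right[idx] <- FALSE
    }
    attr(g, "blink_intervals") <- tibble::tibble(
      start_s = gaze$time_s[starts],
      end_s = gaze$time_s[starts] + len / rate
    )
    g
  })
  attr(out, "rate") <- rate
  out
}

#' Generate and write a full synthetic cohort
#'
#' Writes `n_subjects x n_videos` session pairs to
#' `<outdir>/subject_<k>/video_<j>_eeg.csv` and `..._gaze.csv` plus a
#' `manifest.json` listing paths, condition labels, ground-truth
#' couplings, blink intervals and per-file MD5 checksums. Fully
#' deterministic under the config seed.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly (also written as JSON).
#' @export
generate_cohort <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir,
                                call. = FALSE)
  sessions <- list()
  blinks <- list()
  for (k in seq_len(config$n_subjects)) {
    subj_dir <- file.path(outdir, sprintf("subject_%d", k))
    dir.create(subj_dir, showWarnings = FALSE)
    for (j in seq_len(config$n_videos)) {
      ses <- generate_session(config, k, j)
      eeg_path <- file.path(subj_dir, sprintf("video_%d_eeg.csv", j))
      gaze_path <- file.path(subj_dir, sprintf("video_%d_gaze.csv", j))
      write_eeg(ses$eeg, eeg_path)
      write_gaze(ses$gaze, gaze_path)
      sessions[[length(sessions) + 1]] <- dplyr::bind_cols(
        ses$label,
        tibble::tibble(eeg_path = eeg_path, gaze_path = gaze_path,
                       eeg_md5 = unname(tools::md5sum(eeg_path)),
                       gaze_md5 = unname(tools::md5sum(gaze_path)))
      )
      blinks[[sprintf("s%d_v%d", k, j)]] <- ses$truth$blink_intervals
    }
  }
  manifest <- list(
    sessions = dplyr::bind_rows(sessions),
    couplings = config$couplings,
    blink_intervals = blinks,
    config = config[c("n_subjects", "n_videos", "duration_s", "eeg_rate",
                      "gaze_rate", "noise_sd", "blink_rate_per_min",
                      "blink_duration_ms", "saccade_rate_per_s", "seed")]
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
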