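#' Detect blink intervals in a gaze recording
#'
#' A sample is blink-affected when either pupil diameter is non-positive
#' or either validity flag is false. Contiguous runs of such samples
#' become half-open intervals `[start_s, end_s)`.
#'
#' @param gaze Gaze tibble (see [read_gaze()]).
#' @return Tibble `start_s, end_s`, possibly empty.
#' @export
detect_blinks <- function(gaze) {
  bad <- gaze$pupil_left_mm <= 0 | gaze$pupil_right_mm <= 0 |
    !gaze$valid_left | !gaze$valid_right
  bad[is.na(bad)] <- TRUE
  runs_to_intervals(bad, gaze$time_s)
}

runs_to_intervals <- function(flag, time_s) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  dt <- stats::median(diff(time_s))
  tibble::tibble(
    start_s = time_s[starts[keep]],
    end_s = time_s[ends[keep]] + dt
  )
}

#' Remove blinks by padded linear interpolation
#'
#' Detects blink-affected samples, pads each blink by `pad_ms` on both
#' sides (eyelid occlusion distorts the pupil estimate before the pupil
#' reading drops out entirely), and linearly interpolates pupil diameters
#' and gaze coordinates across the padded span. The returned recording
#' carries a `blink` column marking interpolated samples and the
#' detected (unpadded) intervals as attribute `"blink_intervals"`.
#'
#' @param gaze Gaze tibble.
#' @param pad_ms Padding on each side of a detected blink, ms
#'   (default 100).
#' @return Cleaned gaze tibble with logical column `blink`; validity
#'   flags set true on interpolated samples; no NAs or non-positive
#'   pupil values remain.
#' @export
remove_blinks <- function(gaze, pad_ms = 100) {
  n <- nrow(gaze)
  bad <- gaze$pupil_left_mm <= 0 | gaze$pupil_right_mm <= 0 |
    !gaze$valid_left | !gaze$valid_right
  bad[is.na(bad)] <- TRUE
  intervals <- runs_to_intervals(bad, gaze$time_s)

  rate <- recording_rate(gaze)
  pad_n <- round(pad_ms / 1000 * rate)
  mask <- bad
  if (any(bad) && pad_n > 0) {
    idx <- which(bad)
    for (k in seq(-pad_n, pad_n)) {
      shifted <- idx + k
      shifted <- shifted[shifted >= 1 & shifted <= n]
      mask[shifted] <- TRUE
    }
  }
  if (mean(mask) > 0.5) {
    stop("blink coverage exceeds 50% of the recording; session unusable",
         call. = FALSE)
  }

  out <- gaze
  if (any(mask)) {
    for (col in c("pupil_left_mm", "pupil_right_mm", "gaze_x", "gaze_y")) {
      v <- out[[col]]
      v[mask] <- NA_real_
      out[[col]] <- stats::approx(out$time_s[!mask], v[!mask], out$time_s,
                                  method = "linear", rule = 2)$y
    }
    out$valid_left[mask] <- TRUE
    out$valid_right[mask] <- TRUE
  }
  out$blink <- mask
  attr(out, "blink_intervals") <- intervals
  attr(out, "rate") <- rate
  out
}

#' Ground-truth or detected blink intervals of a recording
#'
#' @param gaze A gaze tibble returned by [remove_blinks()] or
#'   [inject_blinks()].
#' @return Tibble `start_s, end_s` (empty if none recorded).
#' @export
blink_intervals <- function(gaze) {
  iv <- attr(gaze, "blink_intervals")
  if (is.null(iv)) tibble::tibble(start_s = numeric(), end_s = numeric())
  else iv
}

#' I-VT fixation/saccade classification
#'
#' Velocity-threshold identification: point-to-point gaze velocity is
#' computed from consecutive samples; runs of samples whose velocity
#' exceeds the threshold become saccades, all other runs fixations.
#' Fixations shorter than `min_fixation_ms` sandwiched between saccades
#' are absorbed into the surrounding saccade. The resulting events
#' partition the recording's timeline.
#'
#' @param gaze Cleaned gaze tibble (blinks removed).
#' @param velocity_threshold Saccade velocity threshold in gaze units/s
#'   (default 30, the conventional deg/s setting).
#' @param min_fixation_ms Minimum fixation duration, ms (default 60).
#' @return Event tibble: `kind` (fixation/saccade), `start_s`, `end_s`,
#'   `centroid_x`, `centroid_y` (fixations), `amplitude` (saccades:
#'   point-to-point displacement magnitude), `peak_velocity`,
#'   `duration_s`, `velocity` (saccades: amplitude / duration).
#' @export
classify_ivt <- function(gaze, velocity_threshold = 30,
                         min_fixation_ms = 60) {
  if (velocity_threshold <= 0) {
    stop("velocity_threshold must be positive", call. = FALSE)
  }
  n <- nrow(gaze)
  dt <- diff(gaze$time_s)
  vel <- c(0, sqrt(diff(gaze$gaze_x)^2 + diff(gaze$gaze_y)^2) / dt)
  is_sacc <- vel > velocity_threshold

  # absorb too-short fixation runs bounded by saccades on both sides
  r <- rle(is_sacc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i] && i > 1 && i < length(r$values)) {
      dur_ms <- (gaze$time_s[ends[i]] - gaze$time_s[starts[i]] +
                   stats::median(dt)) * 1000
      if (dur_ms < min_fixation_ms) is_sacc[starts[i]:ends[i]] <- TRUE
    }
  }

  r <- rle(is_sacc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  step <- stats::median(dt)
  n_ev <- length(r$values)
  run_id <- rep.int(seq_len(n_ev), r$lengths)
  t0 <- gaze$time_s[starts]
  t1 <- gaze$time_s[ends] + step
  peak <- as.numeric(tapply(vel, run_id, max))
  cx <- as.numeric(tapply(gaze$gaze_x, run_id, mean))
  cy <- as.numeric(tapply(gaze$gaze_y, run_id, mean))
  # saccade amplitude: displacement from the last pre-saccade sample to
  # the first post-saccade sample (point-to-point amplitude)
  pre <- pmax(starts - 1, 1)
  post <- pmin(ends + 1, n)
  amp <- sqrt((gaze$gaze_x[post] - gaze$gaze_x[pre])^2 +
                (gaze$gaze_y[post] - gaze$gaze_y[pre])^2)
  sacc <- r$values
  tibble::tibble(
    kind = ifelse(sacc, "saccade", "fixation"),
    start_s = t0, end_s = t1,
    centroid_x = ifelse(sacc, NA_real_, cx),
    centroid_y = ifelse(sacc, NA_real_, cy),
    amplitude = ifelse(sacc, amp, NA_real_),
    peak_velocity = peak,
    duration_s = t1 - t0,
    velocity = ifelse(sacc, amp / (t1 - t0), NA_real_)
  )
}

#' Fixation-distance series
#'
#' For each consecutive pair of fixations (A, B) the Euclidean distance
#' between their centroids, `sqrt((xB - xA)^2 + (yB - yA)^2)`, emitted as
#' a dense step series at the gaze rate: from fixation B's onset onward
#' the series holds dist(A, B); it is 0 before the second fixation. The
#' dense step-hold encoding makes the sparse event values uniformly
#' sampled so they can be band-pass analyzed.
#'
#' @param events Event tibble from [classify_ivt()].
#' @param rate Output rate, Hz (default 60).
#' @param n_samples Series length; defaults to covering the last event.
#' @param literal_norm If `TRUE`, uses the norm-of-coordinates variant
#'   `sqrt(xA^2 + yA^2 + xB^2 + yB^2)` instead of the centroid-to-
#'   centroid distance (compatibility option; the distance form is the
#'   default because it matches the quantity's meaning).
#' @return Tibble `time_s, feature, value`.
#' @export
fixation_distance_series <- function(events, rate = 60, n_samples = NULL,
                                     literal_norm = FALSE) {
  fix <- events[events$kind == "fixation", ]
  if (is.null(n_samples)) n_samples <- ceiling(max(events$end_s) * rate)
  time_s <- (seq_len(n_samples) - 1) / rate
  values <- numeric(n_samples)
  if (nrow(fix) < 2) {
    warning("fewer than 2 fixations; fixation-distance series is all zero")
  } else {
    for (i in 2:nrow(fix)) {
      d <- if (literal_norm) {
        sqrt(fix$centroid_x[i - 1]^2 + fix$centroid_y[i - 1]^2 +
               fix$centroid_x[i]^2 + fix$centroid_y[i]^2)
      } else {
        sqrt((fix$centroid_x[i] - fix$centroid_x[i - 1])^2 +
               (fix$centroid_y[i] - fix$centroid_y[i - 1])^2)
      }
      values[time_s >= fix$start_s[i]] <- d
    }
  }
  tibble::tibble(time_s = time_s, feature = "fixation_distance",
                 value = values)
}

#' Saccade-amplitude series
#'
#' A dense 60 Hz series equal to the saccade's point-to-point amplitude
#' during that saccade's samples and 0 during fixations. Each saccade's
#' velocity (amplitude / duration) is kept in the event table; set
#' `use_velocity = TRUE` to emit velocity instead of amplitude.
#'
#' @param events Event tibble from [classify_ivt()].
#' @param rate Output rate, Hz (default 60).
#' @param n_samples Series length; defaults to covering the last event.
#' @param use_velocity Emit amplitude/duration instead of amplitude.
#' @return Tibble `time_s, feature, value`.
#' @export
saccade_amplitude_series <- function(events, rate = 60, n_samples = NULL,
                                     use_velocity = FALSE) {
  sac <- events[events$kind == "saccade", ]
  if (is.null(n_samples)) n_samples <- ceiling(max(events$end_s) * rate)
  time_s <- (seq_len(n_samples) - 1) / rate
  values <- numeric(n_samples)
  if (nrow(sac) > 0) {
    for (i in seq_len(nrow(sac))) {
      v <- if (use_velocity) sac$velocity[i] else sac$amplitude[i]
      values[time_s >= sac$start_s[i] & time_s < sac$end_s[i]] <- v
    }
  }
  tibble::tibble(time_s = time_s, feature = "saccade_amplitude",
                 value = values)
}

#' Pupil-diameter series
#'
#' The cleaned pupil trace for one eye, mean-centered per session so
#' that downstream band-power ratios reflect fluctuation structure
#' rather than baseline diameter.
#'
#' @param gaze Cleaned gaze tibble (blinks removed).
#' @param side `"left"` or `"right"`.
#' @return Tibble `time_s, feature, value` (and `blink` if present).
#' @export
pupil_series <- function(gaze, side = c("left", "right")) {
  side <- match.arg(side)
  col <- paste0("pupil_", side, "_mm")
  out <- tibble::tibble(
    time_s = gaze$time_s,
    feature = paste0("pupil_", side),
    value = gaze[[col]] - mean(gaze[[col]])
  )
  if ("blink" %in% names(gaze)) out$blink <- gaze$blink
  out
}

#' All four eye-movement feature series of a session
#'
#' Convenience wrapper: classifies events with I-VT (unless supplied)
#' and binds fixation-distance, saccade-amplitude and both pupil series
#' into one long table on the gaze time base.
#'
#' @param gaze Cleaned gaze tibble (from [remove_blinks()]).
#' @param events Optional precomputed event tibble.
#' @param velocity_threshold,min_fixation_ms I-VT settings (see
#'   [classify_ivt()]).
#' @return Tidy tibble `time_s, feature, value, blink`.
#' @export
eye_feature_series <- function(gaze, events = NULL,
                               velocity_threshold = 30,
                               min_fixation_ms = 60) {
  if (is.null(events)) {
    events <- classify_ivt(gaze, velocity_threshold, min_fixation_ms)
  }
  rate <- recording_rate(gaze)
  n <- nrow(gaze)
  blink <- if ("blink" %in% names(gaze)) gaze$blink else rep(FALSE, n)
  fd <- fixation_distance_series(events, rate, n)
  sa <- saccade_amplitude_series(events, rate, n)
  fd$time_s <- gaze$time_s
  sa$time_s <- gaze$time_s
  fd$blink <- blink
  sa$blink <- blink
  pl <- pupil_series(gaze, "left")
  pr <- pupil_series(gaze, "right")
  if (!"blink" %in% names(pl)) { pl$blink <- blink; pr$blink <- blink }
  dplyr::bind_rows(fd, sa, pl, pr)
}
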