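#' Standard 10-20 channel montage used throughout the package
#'
#' The 18 scalp electrode names (international 10-20 system) that EEG
#' recordings are expected to carry, in canonical order.
#'
#' @format Character vector of length 18.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F3", "F7", "Fz", "F4", "F8", "T3", "T4",
    "C3", "C4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Eye-movement feature names
#'
#' The four eye-movement feature series the pipeline derives at 60 Hz.
#'
#' @export
eye_features <- function() {
  c("fixation_distance", "saccade_amplitude", "pupil_left", "pupil_right")
}

#' Frequency band schemes for EEG and eye-movement signals
#'
#' Returns the band edges (Hz) used for relative band-power ratios. EEG
#' uses the conventional delta/theta/alpha/beta division up to 20 Hz; eye
#' movement and pupil series use a compressed sub-Hz scheme spanning
#' 0.12-3.6 Hz so that the same four-band structure applies to the much
#' slower oculomotor signals.
#'
#' @param modality `"eeg"` or `"eye"`.
#' @return A tibble with columns `band`, `f_lo`, `f_hi` (Hz), ordered
#'   delta, theta, alpha, beta. Bands are half-open `[f_lo, f_hi)` so a
#'   shared edge belongs to the upper band.
#' @examples
#' band_scheme("eeg")
#' band_scheme("eye")
#' @export
band_scheme <- function(modality = c("eeg", "eye")) {
  modality <- match.arg(modality)
  if (modality == "eeg") {
    tibble::tibble(
      band = c("delta", "theta", "alpha", "beta"),
      f_lo = c(1, 4, 8, 13),
      f_hi = c(4, 8, 13, 20)
    )
  } else {
    tibble::tibble(
      band = c("delta", "theta", "alpha", "beta"),
      f_lo = c(0.12, 0.48, 0.96, 1.56),
      f_hi = c(0.48, 0.96, 1.56, 3.6)
    )
  }
}

band_names <- function() c("delta", "theta", "alpha", "beta")

assert_channel <- function(channel) {
  bad <- setdiff(channel, eeg_channels())
  if (length(bad) > 0) {
    stop("unknown EEG channel name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(channel)
}

assert_band <- function(band) {
  bad <- setdiff(band, band_names())
  if (length(bad) > 0) {
    stop("unknown band name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(band)
}

assert_eye_feature <- function(feature) {
  bad <- setdiff(feature, eye_features())
  if (length(bad) > 0) {
    stop("unknown eye feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(feature)
}

#' Hemisphere of a 10-20 channel
#'
#' In the 10-20 system odd-numbered sites lie over the left hemisphere,
#' even-numbered sites over the right, and "z" sites on the midline.
#'
#' @param channel Character vector of 10-20 channel names.
#' @return Character vector: `"left"`, `"right"` or `"midline"`.
#' @examples
#' channel_hemisphere(c("F3", "F4", "Fz"))
#' @export
channel_hemisphere <- function(channel) {
  assert_channel(channel)
  last <- substr(channel, nchar(channel), nchar(channel))
  num <- suppressWarnings(as.integer(last))
  dplyr::case_when(
    tolower(last) == "z" ~ "midline",
    num %% 2L == 1L ~ "left",
    TRUE ~ "right"
  )
}

#' Hemisphere relation between an eye feature and an EEG channel
#'
#' For lateralized eye features (left/right pupil) the relation is
#' `"same"` when pupil side and channel hemisphere agree, `"crossed"`
#' when they differ, and `"midline"` for z-line channels. Fixation and
#' saccade features have no side, so the tag is the channel hemisphere.
#'
#' @param eye_feature Eye feature names (see [eye_features()]).
#' @param channel 10-20 channel names.
#' @return Character vector of tags.
#' @examples
#' hemisphere_tag("pupil_right", "F4")  # same
#' hemisphere_tag("pupil_right", "F3")  # crossed
#' @export
hemisphere_tag <- function(eye_feature, channel) {
  assert_eye_feature(eye_feature)
  side <- dplyr::case_when(
    eye_feature == "pupil_left" ~ "left",
    eye_feature == "pupil_right" ~ "right",
    TRUE ~ NA_character_
  )
  hemi <- channel_hemisphere(channel)
  dplyr::case_when(
    hemi == "midline" ~ "midline",
    is.na(side) ~ hemi,
    side == hemi ~ "same",
    TRUE ~ "crossed"
  )
}

#' Valence-arousal quadrant labels
#'
#' @return Tibble of the four quadrants of the two-dimensional emotion
#'   model with their valence and arousal levels.
#' @export
quadrants <- function() {
  tibble::tibble(
    quadrant = c("pleasant-aroused", "pleasant-relaxed",
                 "unpleasant-relaxed", "unpleasant-aroused"),
    valence = c("pleasant", "pleasant", "unpleasant", "unpleasant"),
    arousal = c("aroused", "relaxed", "relaxed", "aroused")
  )
}
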