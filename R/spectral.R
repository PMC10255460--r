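#' Zero-phase Butterworth band-pass filter
#'
#' Filters a uniformly sampled signal with the squared magnitude response
#' of a 4th-order Butterworth band-pass (equivalent to forward-backward
#' application, hence zero phase), applied in the frequency domain. The
#' frequency-domain formulation stays numerically exact for the very
#' narrow sub-Hz eye-movement bands, where time-domain high-order IIR
#' coefficients at a 500 Hz rate are ill-conditioned.
#'
#' @param x Numeric signal vector.
#' @param rate Sampling rate, Hz.
#' @param f_lo,f_hi Band edges, Hz; `0 < f_lo < f_hi < rate/2`.
#' @param order Butterworth order of the underlying analog prototype.
#' @return Filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 500)
#' x <- sin(2 * pi * 10 * t)
#' y <- bandpass(x, 500, 8, 13)   # retained
#' z <- bandpass(x, 500, 1, 4)    # suppressed
#' @export
bandpass <- function(x, rate, f_lo, f_hi, order = 4) {
  if (!(f_lo > 0 && f_hi > f_lo && f_hi < rate / 2)) {
    stop("band edges must satisfy 0 < f_lo < f_hi < rate/2", call. = FALSE)
  }
  n <- length(x)
  if (n < 2) return(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)  # two-sided frequency axis folded to [0, rate/2]
  f0 <- sqrt(f_lo * f_hi)
  bw <- f_hi - f_lo
  # |H|^2 of an order-`order` Butterworth band-pass, squared again for the
  # zero-phase forward-backward pass
  u <- ifelse(f == 0, Inf, (f^2 - f0^2) / (f * bw))
  h2 <- (1 / (1 + u^(2 * order)))^2
  Re(stats::fft(stats::fft(x) * h2, inverse = TRUE)) / n
}

#' Per-band spectral power of one window
#'
#' Computes a one-sided periodogram of the (mean-removed, Hann-tapered)
#' window and sums power-spectral-density bins into the scheme's bands.
#' Bin assignment is half-open: a bin at frequency `f` belongs to band
#' `b` when `f_lo <= f < f_hi`, so shared edges are counted once.
#'
#' @param x Numeric window of samples.
#' @param rate Sampling rate, Hz.
#' @param scheme Band scheme tibble from [band_scheme()].
#' @return Tibble with columns `band`, `power`.
#' @export
band_powers <- function(x, rate, scheme) {
  n <- length(x)
  if (n / rate < 2 / min(scheme$f_lo)) {
    stop("window too short: needs at least two cycles of the lowest band ",
         "edge (", min(scheme$f_lo), " Hz)", call. = FALSE)
  }
  psd <- periodogram_psd(x, rate)
  pw <- vapply(seq_len(nrow(scheme)), function(b) {
    sel <- psd$freq >= scheme$f_lo[b] & psd$freq < scheme$f_hi[b]
    sum(psd$psd[sel])
  }, 0)
  tibble::tibble(band = scheme$band, power = pw)
}

# One-sided periodogram PSD with mean removal and a Hann taper; DC bin
# excluded. Scaling keeps sum(psd * df) ~ variance, though only ratios of
# band sums are used downstream.
periodogram_psd <- function(x, rate) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xt <- (x - mean(x)) * w
  X <- stats::fft(xt)
  n_half <- n %/% 2
  k <- seq_len(n_half)                       # bins 1 .. n/2 (DC dropped)
  p <- (Mod(X[k + 1])^2) * 2 / (rate * sum(w^2))
  if (n %% 2 == 0) p[n_half] <- p[n_half] / 2   # Nyquist bin is not doubled
  list(freq = k * rate / n, psd = p)
}

#' Relative band-power ratios
#'
#' Divides each band's power by the total over the scheme's bands so the
#' four ratios sum to 1: `ratio_b = power_b / sum(power)`. An all-zero
#' window is undefined and returned as `NA` ratios with `defined = FALSE`.
#'
#' @param powers Tibble with columns `band`, `power` (from
#'   [band_powers()]), or a named numeric vector.
#' @return Tibble with columns `band`, `power`, `ratio`, `defined`.
#' @examples
#' band_ratios(c(delta = 3, theta = 1, alpha = 0, beta = 0))
#' @export
band_ratios <- function(powers) {
  if (is.numeric(powers)) {
    powers <- tibble::tibble(band = names(powers), power = unname(powers))
  }
  total <- sum(powers$power)
  if (!is.finite(total) || total <= 0) {
    return(dplyr::mutate(powers, ratio = NA_real_, defined = FALSE))
  }
  dplyr::mutate(powers, ratio = .data$power / total, defined = TRUE)
}

#' Sliding-window relative band-power ratio series
#'
#' Slides a window of `window_s` seconds in steps of `slide_s` seconds
#' over a uniformly sampled signal and computes relative band-power
#' ratios per window. Window `t` covers samples in `[t, t + window_s)`;
#' starts are `0, slide_s, 2*slide_s, ...`, giving
#' `floor((duration - window_s)/slide_s) + 1` windows.
#'
#' Windows in which more than `max_mask_frac` of samples are flagged by
#' `mask` (e.g. blink-interpolated samples) are kept in the output but
#' marked `excluded = TRUE` so downstream regression can drop them.
#'
#' @param x Numeric signal vector (one channel or one eye feature).
#' @param rate Sampling rate, Hz.
#' @param scheme Band scheme tibble from [band_scheme()].
#' @param window_s Window length, s (default 180).
#' @param slide_s Slide step, s (default 1).
#' @param source Optional name recorded in the `source` column.
#' @param mask Optional logical vector (same length as `x`) of
#'   low-quality samples.
#' @param max_mask_frac Masked-sample fraction above which a window is
#'   excluded (default 0.2).
#' @return Tidy tibble: `source, window_start_s, band, power, ratio,
#'   defined, excluded`.
#' @export
sliding_band_ratios <- function(x, rate, scheme, window_s = 180, slide_s = 1,
                                source = NA_character_, mask = NULL,
                                max_mask_frac = 0.2) {
  n <- length(x)
  duration <- n / rate
  if (duration + 1e-9 < window_s) {
    stop("signal duration (", round(duration, 3), " s) is shorter than the ",
         "window (", window_s, " s)", call. = FALSE)
  }
  wlen <- round(window_s * rate)
  if (wlen / rate < 2 / min(scheme$f_lo)) {
    stop("window too short: needs at least two cycles of the lowest band ",
         "edge (", min(scheme$f_lo), " Hz)", call. = FALSE)
  }
  n_windows <- floor((duration - window_s) / slide_s + 1e-9) + 1
  starts <- (seq_len(n_windows) - 1) * slide_s

  # all windows as columns of one matrix so the periodograms come from a
  # single multivariate FFT
  first <- round(starts * rate)
  W <- vapply(first, function(s0) x[(s0 + 1):(s0 + wlen)],
              numeric(wlen))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1))
  W <- (W - rep(colMeans(W), each = wlen)) * w
  X <- stats::mvfft(W)
  n_half <- wlen %/% 2
  P <- (Mod(X[1 + seq_len(n_half), , drop = FALSE])^2) * 2 /
    (rate * sum(w^2))
  if (wlen %% 2 == 0) P[n_half, ] <- P[n_half, ] / 2
  freq <- seq_len(n_half) * rate / wlen

  n_bands <- nrow(scheme)
  pw <- matrix(0, nrow = n_bands, ncol = n_windows)
  for (b in seq_len(n_bands)) {
    sel <- freq >= scheme$f_lo[b] & freq < scheme$f_hi[b]
    pw[b, ] <- colSums(P[sel, , drop = FALSE])
  }
  totals <- colSums(pw)
  defined <- is.finite(totals) & totals > 0
  ratio <- sweep(pw, 2, ifelse(defined, totals, NA_real_), "/")

  excluded <- rep(FALSE, n_windows)
  if (!is.null(mask)) {
    cm <- cumsum(as.numeric(mask))
    frac <- (cm[first + wlen] - c(0, cm)[first + 1]) / wlen
    excluded <- frac > max_mask_frac
  }
  tibble::tibble(
    source = source,
    window_start_s = rep(starts, each = n_bands),
    band = rep(scheme$band, n_windows),
    power = as.numeric(pw),
    ratio = as.numeric(ratio),
    defined = rep(defined, each = n_bands),
    excluded = rep(excluded, each = n_bands)
  )
}

#' Pair two band-ratio series on their common window grid
#'
#' Joins two tidy band-ratio tables (from [sliding_band_ratios()]) on
#' identical `window_start_s` and `band`, dropping unpaired windows (a
#' message reports how many). Both series must share the same windowing.
#'
#' @param a,b Band-ratio tibbles; `a` supplies `x` (predictor), `b`
#'   supplies `y` (response).
#' @param drop_excluded Drop window pairs either side flagged `excluded`
#'   or undefined (default `TRUE`).
#' @return Tibble `window_start_s, band, x, y`.
#' @export
align_ratio_series <- function(a, b, drop_excluded = TRUE) {
  keyed <- function(d, val) {
    d <- d[, c("window_start_s", "band", "ratio", "defined", "excluded")]
    names(d) <- c("window_start_s", "band", val,
                  paste0(c("defined_", "excluded_"), val))
    d
  }
  paired <- dplyr::inner_join(keyed(a, "x"), keyed(b, "y"),
                              by = c("window_start_s", "band"))
  if (nrow(paired) == 0) {
    stop("no common windows between the two ratio series", call. = FALSE)
  }
  n_dropped <- max(nrow(a), nrow(b)) - nrow(paired)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " unpaired window-band rows")
  }
  if (drop_excluded) {
    keep <- paired$defined_x & paired$defined_y &
      !paired$excluded_x & !paired$excluded_y
    paired <- paired[keep, ]
  }
  paired[order(paired$band, paired$window_start_s),
         c("window_start_s", "band", "x", "y")]
}

#' Band-ratio series for all EEG channels of a session
#'
#' Applies the 1-50 Hz acquisition band-pass, then computes sliding
#' relative band-power ratios per channel in the EEG scheme.
#'
#' @param eeg EEG tibble (`time_s` + channel columns).
#' @param channels Channels to process (default: all montage channels
#'   present).
#' @param window_s,slide_s Windowing (defaults 180 s / 1 s).
#' @param prefilter Apply the 1-50 Hz band-pass first (default `TRUE`).
#' @return Tidy band-ratio tibble with `source` = channel name.
#' @export
eeg_band_ratios <- function(eeg, channels = NULL, window_s = 180,
                            slide_s = 1, prefilter = TRUE) {
  rate <- recording_rate(eeg)
  if (is.null(channels)) {
    channels <- intersect(eeg_channels(), names(eeg))
  }
  assert_channel(channels)
  scheme <- band_scheme("eeg")
  purrr::map_dfr(channels, function(ch) {
    x <- eeg[[ch]]
    if (prefilter) x <- bandpass(x, rate, 1, 50)
    sliding_band_ratios(x, rate, scheme, window_s, slide_s, source = ch)
  })
}

#' Band-ratio series for eye-movement feature series
#'
#' Computes sliding relative band-power ratios in the sub-Hz eye scheme
#' for each feature of a long-format feature table (from
#' [eye_feature_series()]).
#'
#' @param features Tidy tibble `time_s, feature, value` and optionally
#'   `blink` (logical) used for window-quality exclusion.
#' @param window_s,slide_s Windowing (defaults 180 s / 1 s).
#' @return Tidy band-ratio tibble with `source` = feature name.
#' @export
eye_band_ratios <- function(features, window_s = 180, slide_s = 1) {
  scheme <- band_scheme("eye")
  purrr::map_dfr(unique(features$feature), function(f) {
    d <- features[features$feature == f, ]
    rate <- 1 / stats::median(diff(d$time_s))
    mask <- if ("blink" %in% names(d)) d$blink else NULL
    sliding_band_ratios(d$value, rate, scheme, window_s, slide_s,
                        source = f, mask = mask)
  })
}
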