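# Shared fixture builders and small oracles used across test files.

# A minimal clean gaze recording: stationary gaze, constant pupils.
make_gaze <- function(n = 600, rate = 60, pupil = 3, gx = 0, gy = 0) {
  tibble::tibble(
    time_s = (seq_len(n) - 1) / rate,
    gaze_x = rep_len(gx, n),
    gaze_y = rep_len(gy, n),
    pupil_left_mm = rep_len(pupil, n),
    pupil_right_mm = rep_len(pupil, n),
    valid_left = TRUE,
    valid_right = TRUE
  )
}

# Gaze trace with scripted instantaneous center jumps (no jitter), for
# exact I-VT recovery checks. Jumps happen between sample k and k+1.
make_jump_gaze <- function(n_jumps = 20, n = 3600, rate = 60,
                           amplitude = 5) {
  g <- make_gaze(n, rate)
  jump_at <- floor(seq(120, n - 120, length.out = n_jumps))
  x <- numeric(n)
  for (k in jump_at) x[(k + 1):n] <- x[(k + 1):n] + amplitude
  g$gaze_x <- x
  list(gaze = g, jump_samples = jump_at)
}

# Interval Jaccard index: |intersection| / |union| of two interval sets.
interval_jaccard <- function(a, b, step = 1 / 600) {
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  lo <- min(a$start_s, b$start_s)
  hi <- max(a$end_s, b$end_s)
  grid <- seq(lo, hi, by = step)
  in_set <- function(iv) {
    hit <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(iv))) {
      hit <- hit | (grid >= iv$start_s[i] & grid < iv$end_s[i])
    }
    hit
  }
  ia <- in_set(a); ib <- in_set(b)
  sum(ia & ib) / sum(ia | ib)
}

# Brute-force one-sided periodogram band power: direct DFT summation,
# independent of the fft-based implementation under test.
brute_band_power <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xt <- (x - mean(x)) * w
  total <- 0
  for (k in seq_len(n %/% 2)) {
    f <- k * rate / n
    if (f >= f_lo && f < f_hi) {
      re <- sum(xt * cos(-2 * pi * k * (seq_len(n) - 1) / n))
      im <- sum(xt * sin(-2 * pi * k * (seq_len(n) - 1) / n))
      p <- (re^2 + im^2) * 2 / (rate * sum(w^2))
      if (n %% 2 == 0 && k == n %/% 2) p <- p / 2
      total <- total + p
    }
  }
  total
}

# Tiny deterministic session config used by several files.
tiny_coupled_config <- function(strength = 0.95, seed = 1, ...) {
  synth_config(
    n_subjects = 1, n_videos = 1, duration_s = 60,
    couplings = coupling_spec("pupil_right", "F3", "delta", strength),
    seed = seed, ...)
}
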