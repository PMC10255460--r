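test_that("band-pass retains in-band tones and suppresses out-of-band", {
  t <- seq(0, 4, by = 1 / 500)[-1]
  x <- sin(2 * pi * 10 * t)
  amp <- function(y) sqrt(mean(y[500:1500]^2)) * sqrt(2)
  expect_gt(amp(bandpass(x, 500, 8, 13)), 0.95)
  expect_lt(amp(bandpass(x, 500, 1, 4)), 0.05)
  expect_equal(bandpass(numeric(2000), 500, 8, 13), numeric(2000))
  expect_error(bandpass(x, 500, 13, 8), "band edges")
  expect_error(bandpass(x, 500, 100, 300), "band edges")
})

test_that("band powers match a brute-force DFT oracle", {
  set.seed(5)
  for (n in c(64, 250)) {
    x <- rnorm(n)
    sch <- band_scheme("eeg")
    bp <- band_powers(x, 50, tibble::tibble(band = c("lo", "hi"),
                                            f_lo = c(2, 8),
                                            f_hi = c(8, 20)))
    expect_equal(bp$power[1], brute_band_power(x, 50, 2, 8),
                 tolerance = 1e-8)
    expect_equal(bp$power[2], brute_band_power(x, 50, 8, 20),
                 tolerance = 1e-8)
  }
})

test_that("a pure 10 Hz tone concentrates in the EEG alpha band", {
  t <- seq(0, 20, by = 1 / 500)[-1]
  x <- sin(2 * pi * 10 * t)
  rb <- band_ratios(band_powers(x, 500, band_scheme("eeg")))
  expect_gte(rb$ratio[rb$band == "alpha"], 0.95)
})

test_that("white-noise band powers are proportional to bandwidths", {
  set.seed(7)
  x <- rnorm(200000)
  bp <- band_powers(x, 500, band_scheme("eeg"))
  widths <- c(3, 4, 5, 7)
  rel <- (bp$power / sum(bp$power)) / (widths / sum(widths))
  expect_true(all(abs(rel - 1) < 0.1))
})

test_that("zero input yields zero powers and a flagged undefined window", {
  bp <- band_powers(numeric(5000), 500, band_scheme("eeg"))
  expect_true(all(bp$power == 0))
  rb <- band_ratios(bp)
  expect_false(any(rb$defined))
  expect_true(all(is.na(rb$ratio)))
})

test_that("band ratios normalize and handle simple cases exactly", {
  r <- band_ratios(c(delta = 1, theta = 1, alpha = 1, beta = 1))
  expect_equal(r$ratio, rep(0.25, 4))
  r2 <- band_ratios(c(delta = 3, theta = 1, alpha = 0, beta = 0))
  expect_equal(r2$ratio, c(0.75, 0.25, 0, 0))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(4)
    expect_equal(sum(band_ratios(stats::setNames(p, band_names()))$ratio),
                 1, tolerance = 1e-12)
  }
})

test_that("sliding windows follow the stated grid arithmetic", {
  # 300 s at 60 Hz: (300 - 180)/1 + 1 = 121 windows of 10800 samples
  x <- rnorm(300 * 60)
  rb <- sliding_band_ratios(x, 60, band_scheme("eye"))
  expect_equal(length(unique(rb$window_start_s)), 121)
  expect_equal(sort(unique(rb$window_start_s)), as.numeric(0:120))
  expect_equal(round(180 * 60), 10800)   # eye window sample count
  expect_equal(round(180 * 500), 90000)  # EEG window sample count
  # every window's four ratios sum to 1
  sums <- tapply(rb$ratio, rb$window_start_s, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(sliding_band_ratios(rnorm(100 * 60), 60, band_scheme("eye")),
               "shorter than the window")
})

test_that("EEG windows hold the 60/500-scaled sample count", {
  x <- rnorm(200 * 500)
  rb <- sliding_band_ratios(x, 500, band_scheme("eeg"))
  expect_equal(length(unique(rb$window_start_s)), 21)
  sums <- tapply(rb$ratio, rb$window_start_s, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a stationary narrowband signal gives a stable ratio trajectory", {
  set.seed(9)
  t <- seq_len(120 * 60) / 60
  x <- sin(2 * pi * 0.3 * t) + 0.05 * rnorm(length(t))
  rb <- sliding_band_ratios(x, 60, band_scheme("eye"), window_s = 20)
  delta <- rb$ratio[rb$band == "delta"]
  expect_lt(sd(delta) / mean(delta), 0.1)
})

test_that("ratio series pair on their common grid and report drops", {
  x <- rnorm(60 * 60)
  a <- sliding_band_ratios(x, 60, band_scheme("eye"), 20, 1, source = "a")
  b <- sliding_band_ratios(x, 60, band_scheme("eye"), 20, 1, source = "b")
  p <- align_ratio_series(a[a$band == "delta", ], b[b$band == "delta", ])
  expect_equal(nrow(p), 41)
  expect_equal(p$x, p$y)

  b_late <- b
  b_late$window_start_s <- b_late$window_start_s + 5
  expect_message(
    p2 <- align_ratio_series(a[a$band == "delta", ],
                             b_late[b_late$band == "delta", ]),
    "dropped")
  expect_equal(nrow(p2), 41 - 5)

  b_off <- b
  b_off$window_start_s <- b_off$window_start_s + 0.5
  expect_error(align_ratio_series(a, b_off), "no common windows")
})

test_that("masked windows are excluded above the masking threshold", {
  x <- rnorm(60 * 60)
  mask <- rep(FALSE, length(x))
  mask[1:600] <- TRUE  # first 10 s masked
  rb <- sliding_band_ratios(x, 60, band_scheme("eye"), 20, 1, mask = mask)
  first <- rb[rb$window_start_s == 0, ]  # 50% masked
  late <- rb[rb$window_start_s == 30, ]  # 0% masked
  expect_true(all(first$excluded))
  expect_false(any(late$excluded))
})

test_that("the sliding path reproduces single-window band powers", {
  set.seed(17)
  x <- rnorm(40 * 60)
  rb <- sliding_band_ratios(x, 60, band_scheme("eye"), 20, 1)
  for (t0 in c(0, 7, 20)) {
    idx <- (t0 * 60 + 1):(t0 * 60 + 1200)
    ref <- band_ratios(band_powers(x[idx], 60, band_scheme("eye")))
    got <- rb[rb$window_start_s == t0, ]
    expect_equal(got$power, ref$power, tolerance = 1e-10)
    expect_equal(got$ratio, ref$ratio, tolerance = 1e-10)
  }
})
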