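#' @importFrom rlang .data
NULL

GAZE_COLUMNS <- c("time_s", "gaze_x", "gaze_y", "pupil_left_mm",
                  "pupil_right_mm", "valid_left", "valid_right")

#' Read an EEG recording
#'
#' Reads a multichannel EEG recording from a long-running CSV export
#' (one `time_s` column plus one column per channel, values in microvolts)
#' or from an EDF file. Channel columns beyond the standard 18-name 10-20
#' montage are preserved and reported via a message; missing expected
#' channels raise an error naming them.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"edf"`.
#' @param channels Channel names expected in the file. Defaults to the
#'   18-channel montage in [eeg_channels()].
#' @return A tibble with `time_s` plus one numeric column per channel,
#'   with attributes `rate` (Hz, inferred from the time column) and
#'   `channels`.
#' @seealso [write_eeg()], [read_gaze()]
#' @export
read_eeg <- function(path, format = c("csv", "edf"),
                     channels = eeg_channels()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") {
    return(read_eeg_edf(path, channels = channels))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("EEG CSV is missing required column: time_s", call. = FALSE)
  }
  missing <- setdiff(channels, names(df))
  if (length(missing) > 0) {
    stop("EEG CSV is missing channel column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c("time_s", channels))
  if (length(extra) > 0) {
    message("EEG CSV has ", length(extra), " unexpected column(s) kept ",
            "as-is: ", paste(extra, collapse = ", "))
  }
  validate_eeg(df, channels)
}

validate_eeg <- function(df, channels = intersect(eeg_channels(), names(df))) {
  if (nrow(df) < 2) stop("EEG recording needs at least 2 samples", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-monotonic time in EEG recording", call. = FALSE)
  step <- stats::median(dt)
  if (any(abs(dt - step) > step * 1.0001)) {
    stop("non-uniform EEG timestamps (gap exceeds one sample period)",
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "rate") <- 1 / step
  attr(out, "channels") <- channels
  out
}

#' Write an EEG recording
#'
#' @param eeg A tibble as returned by [read_eeg()] or
#'   [generate_session()]: `time_s` plus channel columns in microvolts.
#' @param path Output path.
#' @param format `"csv"` or `"edf"`. CSV round-trips losslessly (values
#'   written in full precision); EDF quantizes to 16 bits over the data
#'   range of each channel.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(eeg, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  chans <- setdiff(names(eeg), "time_s")
  if (length(chans) == 0 || nrow(eeg) == 0) {
    stop("refusing to write an empty EEG recording", call. = FALSE)
  }
  if (format == "edf") {
    return(write_eeg_edf(eeg, path))
  }
  readr::write_csv(eeg, path, progress = FALSE)
  invisible(path)
}

#' Read a gaze/pupil recording
#'
#' Reads a 60 Hz gaze CSV with columns `time_s, gaze_x, gaze_y,
#' pupil_left_mm, pupil_right_mm, valid_left, valid_right` (one
#' documented dialect of the many GazePoint-style exports). Rows with
#' unparseable fields are dropped with a message giving the count.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble with attribute `rate` (Hz).
#' @export
read_gaze <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  spec <- list(
    time_s = readr::col_double(), gaze_x = readr::col_double(),
    gaze_y = readr::col_double(), pupil_left_mm = readr::col_double(),
    pupil_right_mm = readr::col_double(),
    valid_left = readr::col_logical(), valid_right = readr::col_logical())
  spec <- spec[intersect(names(spec), header)]
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = do.call(readr::cols,
                                            c(spec, .default = list(
                                              readr::col_guess()))))
  missing <- setdiff(GAZE_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("gaze CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !stats::complete.cases(df[, c("time_s", "gaze_x", "gaze_y")])
  if (any(bad)) {
    message("dropping ", sum(bad), " unparseable gaze row(s)")
    df <- df[!bad, ]
  }
  validate_gaze(df)
}

validate_gaze <- function(df) {
  if (nrow(df) < 2) stop("gaze recording needs at least 2 samples", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-monotonic time in gaze recording", call. = FALSE)
  out <- tibble::as_tibble(df)
  attr(out, "rate") <- 1 / stats::median(dt)
  out
}

#' Write a gaze recording
#'
#' @param gaze Gaze tibble (see [read_gaze()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(gaze, path) {
  missing <- setdiff(GAZE_COLUMNS, names(gaze))
  if (length(missing) > 0 || nrow(gaze) == 0) {
    stop("refusing to write an empty or incomplete gaze recording",
         call. = FALSE)
  }
  readr::write_csv(gaze[, GAZE_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Sampling rate of a recording tibble
#'
#' @param recording Tibble with a `time_s` column.
#' @return Sampling rate in Hz (median reciprocal time step).
#' @export
recording_rate <- function(recording) {
  r <- attr(recording, "rate")
  if (!is.null(r)) return(r)
  1 / stats::median(diff(recording$time_s))
}

# ---- EDF ------------------------------------------------------------------
# Minimal EDF (European Data Format) writer/reader: fixed 256-byte ASCII
# header + 256 bytes per signal, then 1 s data records of little-endian
# int16 samples. No installed R package reads EDF, so the container is
# implemented here; round-trip fidelity is bounded by the 16-bit
# quantization of each channel's physical range.

pad_field <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

write_eeg_edf <- function(eeg, path) {
  chans <- setdiff(names(eeg), "time_s")
  rate <- round(recording_rate(eeg))
  n <- nrow(eeg)
  n_rec <- n %/% rate
  if (n_rec < 1) stop("EDF export needs at least one full second of data",
                      call. = FALSE)
  ns <- length(chans)
  pmin_ <- vapply(chans, function(ch) min(eeg[[ch]]), 0)
  pmax_ <- vapply(chans, function(ch) max(eeg[[ch]]), 0)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin_ <- -32768; dmax_ <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(paste("EEG", chans), 16)                       # labels
  field(rep("", ns), 80)                               # transducer
  field(rep("uV", ns), 8)                              # physical dimension
  field(formatC(pmin_, digits = 6, format = "g"), 8)   # physical min
  field(formatC(pmax_, digits = 6, format = "g"), 8)   # physical max
  field(rep(dmin_, ns), 8)                             # digital min
  field(rep(dmax_, ns), 8)                             # digital max
  field(rep("", ns), 80)                               # prefiltering
  field(rep(rate, ns), 8)                              # samples per record
  field(rep("", ns), 32)                               # reserved

  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    for (k in seq_len(ns)) {
      dig <- round((eeg[[chans[k]]][idx] - pmin_[k]) / gain[k]) + dmin_
      writeBin(as.integer(pmin(pmax(dig, dmin_), dmax_)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_eeg_edf <- function(path, channels = eeg_channels()) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr) < 256) stop("unreadable EDF header: file too short",
                             call. = FALSE)
  take <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(take(hdr, 237, 8))
  rec_dur <- as.numeric(take(hdr, 245, 8))
  ns <- as.integer(take(hdr, 253, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) {
    stop("unreadable EDF header: bad signal/record counts", call. = FALSE)
  }
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  # per-signal header field groups, each stored for all ns signals in a
  # row: labels 16, transducer 80, dim 8, pmin 8, pmax 8, dmin 8, dmax 8,
  # prefilter 80, nsamp 8, reserved 32 (byte offsets of each group below)
  off <- c(labels = 0, transducer = 16, dim = 96, pmin = 104, pmax = 112,
           dmin = 120, dmax = 128, prefilter = 136, nsamp = 216)
  grab <- function(name, width) {
    vapply(seq_len(ns), function(k) {
      take(sig_hdr, off[[name]] * ns + (k - 1) * width + 1, width)
    }, "")
  }
  labels <- sub("^EEG ", "", grab("labels", 16))
  pmin_ <- as.numeric(grab("pmin", 8))
  pmax_ <- as.numeric(grab("pmax", 8))
  dmin_ <- as.numeric(grab("dmin", 8))
  dmax_ <- as.numeric(grab("dmax", 8))
  nsamp <- as.integer(grab("nsamp", 8))

  data <- matrix(0, nrow = n_rec * nsamp[1], ncol = ns)
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[k], size = 2,
                     endian = "little", signed = TRUE)
      phys <- (dig - dmin_[k]) * (pmax_[k] - pmin_[k]) / (dmax_[k] - dmin_[k]) +
        pmin_[k]
      data[((r - 1) * nsamp[k] + 1):(r * nsamp[k]), k] <- phys
    }
  }
  rate <- nsamp[1] / rec_dur
  df <- tibble::as_tibble(as.data.frame(data))
  names(df) <- labels
  df <- dplyr::bind_cols(tibble::tibble(time_s = (seq_len(nrow(df)) - 1) / rate),
                         df)
  missing <- setdiff(channels, labels)
  if (length(missing) > 0) {
    stop("EDF is missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_eeg(df, channels = labels)
}
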