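# Monitor-export waveform records: CSV read/write and the Butterworth
# preprocessing chain (50 Hz powerline notch, then 60 Hz low-pass).

#' Construct a waveform record
#'
#' Container for a uniformly sampled ICP recording, optionally paired with
#' the balloon-volume track that drove the experiment.
#'
#' @param icp Numeric vector, intracranial pressure in mmHg.
#' @param fs Sampling rate in Hz (default 200, the monitor export rate).
#' @param t Optional time vector in seconds; synthesized as
#'   `(0:(n-1))/fs` when absent. Must be uniform with step `1/fs`.
#' @param volume Optional numeric vector, balloon volume in mL, same
#'   length as `icp`.
#' @return Object of class `"waveform_record"`: list with `t`, `icp`,
#'   `volume` (or `NULL`) and `fs`.
#' @export
waveform_record <- function(icp, fs = 200, t = NULL, volume = NULL) {
  if (!is.numeric(icp) || length(icp) == 0L)
    stop("`icp` must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  n <- length(icp)
  if (is.null(t)) {
    t <- (seq_len(n) - 1) / fs
  } else {
    if (length(t) != n)
      stop("`t` and `icp` must have the same length", call. = FALSE)
    dt <- diff(t)
    if (n > 1 && (any(dt <= 0) || any(abs(dt - 1 / fs) > 1e-6 / fs)))
      stop("`t` must be strictly increasing with uniform step 1/fs",
           call. = FALSE)
  }
  if (!is.null(volume) && length(volume) != n)
    stop("`volume` must match `icp` in length", call. = FALSE)
  structure(list(t = as.numeric(t), icp = as.numeric(icp),
                 volume = if (is.null(volume)) NULL else as.numeric(volume),
                 fs = as.numeric(fs)),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf(
    "Waveform record: %d samples at %g Hz (%.1f s), mean ICP %.2f mmHg%s\n",
    length(x$icp), x$fs, length(x$icp) / x$fs, mean(x$icp),
    if (is.null(x$volume)) "" else ", with balloon volume"))
  invisible(x)
}

#' @export
length.waveform_record <- function(x) length(x$icp)

#' Read a monitor-export waveform CSV
#'
#' Parses a comma-separated waveform export with a header row. The time
#' column is optional; when absent, time is synthesized from `fs`. Rows
#' whose ICP value fails to parse are dropped with a message reporting the
#' count. Lines starting with `#` (provenance headers written by
#' [run_analyze()] / [write_waveform_csv()]) are ignored.
#'
#' @param path Path to the CSV file.
#' @param columns Named list mapping the roles `time`, `icp`, `volume` to
#'   column names in the file.
#' @param fs Sampling rate used when no time column is present, and to
#'   validate the time step when one is.
#' @return A [waveform_record()].
#' @export
read_waveform_csv <- function(path,
                              columns = list(time = "time_s",
                                             icp = "icp_mmhg",
                                             volume = "balloon_ml"),
                              fs = 200) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!(columns$icp %in% names(df)))
    stop("required column '", columns$icp, "' not found in ", path,
         call. = FALSE)
  icp <- suppressWarnings(as.numeric(df[[columns$icp]]))
  bad <- is.na(icp)
  if (any(bad)) {
    message("read_waveform_csv: dropped ", sum(bad),
            " rows with unparseable ICP")
    df <- df[!bad, , drop = FALSE]
    icp <- icp[!bad]
  }
  if (length(icp) == 0L) stop("no parseable ICP samples in ", path,
                              call. = FALSE)
  t <- NULL
  if (!is.null(columns$time) && columns$time %in% names(df)) {
    t <- as.numeric(df[[columns$time]])
    if (length(t) > 1) {
      dt <- diff(t)
      if (any(dt <= 0)) stop("time column is not strictly increasing",
                             call. = FALSE)
      fs <- 1 / stats::median(dt)
      if (any(abs(dt - 1 / fs) > 1e-6 / fs))
        stop("inconsistent sampling step in time column", call. = FALSE)
    }
  }
  vol <- NULL
  if (!is.null(columns$volume) && columns$volume %in% names(df))
    vol <- as.numeric(df[[columns$volume]])
  waveform_record(icp, fs = fs, t = t, volume = vol)
}

#' Write a waveform record to CSV
#'
#' Inverse of [read_waveform_csv()]: round-trips losslessly at the stated
#' precision (full double precision by default).
#'
#' @param record A [waveform_record()].
#' @param path Output path.
#' @param columns Column names, as in [read_waveform_csv()].
#' @param header Optional character vector of provenance lines written as
#'   `#`-prefixed comments before the CSV header.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(record, path,
                               columns = list(time = "time_s",
                                              icp = "icp_mmhg",
                                              volume = "balloon_ml"),
                               header = NULL) {
  stopifnot(inherits(record, "waveform_record"))
  df <- data.frame(record$t, record$icp)
  names(df) <- c(columns$time, columns$icp)
  if (!is.null(record$volume)) df[[columns$volume]] <- record$volume
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# odd (antisymmetric) reflection padding, as is conventional before
# zero-phase filtering, so edge transients decay inside the pad
.reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  if (p < 1L) return(list(x = x, p = 0L))
  left <- 2 * x[1] - x[(p + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - p)]
  list(x = c(left, x, right), p = p)
}

.apply_butter <- function(x, filt, zero_phase, pad) {
  padded <- .reflect_pad(x, pad)
  y <- if (zero_phase) signal::filtfilt(filt, padded$x)
       else signal::filter(filt, padded$x)
  if (padded$p > 0L) y <- y[(padded$p + 1L):(padded$p + length(x))]
  as.numeric(y)
}

#' Filter an ICP waveform (powerline notch + low-pass)
#'
#' Applies the monitor preprocessing chain: an order-4 Butterworth
#' band-stop centred on the powerline frequency, followed by an order-4
#' Butterworth low-pass. Both are applied zero-phase (forward-backward)
#' by default so windowed statistics stay aligned with the raw waveform;
#' note this doubles the effective filter order. Signals are odd-reflected
#' at both ends before filtering to suppress edge transients.
#'
#' @param record A [waveform_record()].
#' @param notch_center_hz Centre of the band-stop (default 50, European
#'   mains).
#' @param notch_halfwidth_hz Half-width of the stop band (default 2 Hz,
#'   i.e. a 48-52 Hz notch).
#' @param lowpass_hz Low-pass cutoff (default 60 Hz). Must be below the
#'   Nyquist frequency `fs/2`.
#' @param order Filter order for both filters (default 4).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return A new [waveform_record()] with filtered `icp`; length, time
#'   base and volume are unchanged.
#' @export
filter_icp <- function(record, notch_center_hz = 50, notch_halfwidth_hz = 2,
                       lowpass_hz = 60, order = 4, zero_phase = TRUE) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$fs
  nyq <- fs / 2
  if (lowpass_hz >= nyq)
    stop(sprintf("low-pass cutoff %g Hz is not below Nyquist %g Hz",
                 lowpass_hz, nyq), call. = FALSE)
  hi <- notch_center_hz + notch_halfwidth_hz
  lo <- notch_center_hz - notch_halfwidth_hz
  if (hi >= nyq || lo <= 0)
    stop("band-stop edges must lie strictly inside (0, fs/2)", call. = FALSE)
  bs <- signal::butter(order, c(lo, hi) / nyq, type = "stop")
  lp <- signal::butter(order, lowpass_hz / nyq, type = "low")
  pad <- as.integer(min(length(record$icp) - 1L, round(3 * fs)))
  y <- .apply_butter(record$icp, bs, zero_phase, pad)
  y <- .apply_butter(y, lp, zero_phase, pad)
  if (anyNA(y) || any(!is.finite(y)))
    stop("filtering produced non-finite values", call. = FALSE)
  waveform_record(y, fs = fs, t = record$t, volume = record$volume)
}
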