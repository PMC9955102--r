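# Sliding-window complexity tracks: per-window permutation entropy,
# normalized missing-pattern fraction, p(ascending), p(descending) and
# mean ICP.

#' Start indices of sliding windows
#'
#' 0-based, half-open windows `[start, start + window_len)` advancing by
#' `shift`; a trailing incomplete window is dropped, never padded.
#'
#' @param n Series length in samples.
#' @param window_len Window length in samples.
#' @param shift Displacement between consecutive window starts.
#' @return Integer vector of 0-based start indices (possibly empty).
#' @examples
#' window_starts(5600, 3600, 1000)  # 0 1000 2000
#' @export
window_starts <- function(n, window_len, shift) {
  if (window_len < 1 || shift < 1)
    stop("`window_len` and `shift` must be >= 1", call. = FALSE)
  if (n < window_len) return(integer(0))
  as.integer(seq.int(0L, n - window_len, by = shift))
}

#' Sliding-window ordinal analysis of an ICP waveform
#'
#' Symbolizes the whole series once, then for every window tabulates the
#' pattern distribution and derives the monitoring features: normalized
#' permutation entropy `pe`, normalized missing-pattern fraction
#' `nmp_norm`, the probabilities `p_first` / `p_last` of the fully
#' ascending / fully descending pattern, and the window-mean ICP of the
#' signal being symbolized.
#'
#' The defaults reproduce the 200 Hz monitoring protocol: `m = 6`,
#' `tau = 1`, 3600-sample windows (5 * 6!) shifted by 1000 samples.
#'
#' @param record A [waveform_record()] (typically already passed through
#'   [filter_icp()]; the mean-ICP column describes the same signal that is
#'   symbolized).
#' @param m,tau Embedding dimension and delay, see [symbolize()].
#' @param window_len Window length in samples (default 3600).
#' @param shift Window displacement in samples (default 1000).
#' @return A `data.frame` of class `"window_track"` with one row per
#'   window and columns `window_start_idx` (0-based), `t_start_s`,
#'   `mean_icp`, `pe`, `nmp_norm`, `p_first`, `p_last`. The embedding and
#'   windowing parameters are attached as attributes `m`, `tau`,
#'   `window_len`, `shift`.
#' @export
analyze_windows <- function(record, m = 6L, tau = 1L,
                            window_len = 3600L, shift = 1000L) {
  stopifnot(inherits(record, "waveform_record"))
  m <- .check_m(m)
  tau <- .check_tau(tau)
  n <- length(record$icp)
  starts <- window_starts(n, window_len, shift)
  if (length(starts) == 0L)
    stop(sprintf("series of %d samples has no complete %d-sample window",
                 n, window_len), call. = FALSE)
  span <- (m - 1L) * tau
  n_vec <- window_len - span  # embedded vectors fully inside one window
  if (n_vec < 1L)
    stop("window shorter than one embedded vector", call. = FALSE)
  N <- factorial(m)
  if (n_vec < N)
    warning(sprintf(
      "window holds %d embedded vectors, fewer than m! = %d patterns; %s",
      n_vec, N, "entropy estimates will be heavily undersampled"),
      call. = FALSE)
  ranks <- symbolize(record$icp, m = m, tau = tau)
  k <- length(starts)
  pe <- nmp <- p1 <- pN <- mean_icp <- numeric(k)
  for (i in seq_len(k)) {
    s <- starts[i]
    dist <- pattern_distribution(ranks[(s + 1L):(s + n_vec)], m = m)
    pe[i] <- permutation_entropy(dist)
    nmp[i] <- missing_patterns(dist)$normalized
    p1[i] <- dist$probs[1L]
    pN[i] <- dist$probs[N]
    mean_icp[i] <- mean(record$icp[(s + 1L):(s + window_len)])
  }
  out <- data.frame(window_start_idx = starts,
                    t_start_s = starts / record$fs,
                    mean_icp = mean_icp,
                    pe = pe, nmp_norm = nmp,
                    p_first = p1, p_last = pN)
  class(out) <- c("window_track", "data.frame")
  attr(out, "m") <- m
  attr(out, "tau") <- tau
  attr(out, "window_len") <- as.integer(window_len)
  attr(out, "shift") <- as.integer(shift)
  out
}

#' Mean permutation entropy across embedding dimensions
#'
#' Convenience sweep over candidate embedding dimensions, using the
#' conventional window size of `5 * m!` embedded-vector capacity for each
#' `m`, to choose a dimension that balances tracking resolution against
#' the `m!`-sized pattern space.
#'
#' @param record A [waveform_record()].
#' @param m_values Integer vector of embedding dimensions (default 3:7).
#' @param tau Embedding delay (default 1).
#' @param shift Window displacement; defaults to the window length
#'   (non-overlapping windows).
#' @return `data.frame` with columns `m`, `window_len` (= 5 * m!),
#'   `n_windows`, `mean_pe` and `ok`. Dimensions whose window exceeds the
#'   record length are flagged `ok = FALSE` with `NA` entropy rather than
#'   dropped.
#' @export
sweep_m <- function(record, m_values = 3:7, tau = 1L, shift = NULL) {
  stopifnot(inherits(record, "waveform_record"))
  rows <- lapply(m_values, function(m) {
    m <- .check_m(m)
    wl <- 5L * as.integer(factorial(m))
    if (length(record$icp) < wl)
      return(data.frame(m = m, window_len = wl, n_windows = 0L,
                        mean_pe = NA_real_, ok = FALSE))
    tr <- analyze_windows(record, m = m, tau = tau, window_len = wl,
                          shift = if (is.null(shift)) wl else shift)
    data.frame(m = m, window_len = wl, n_windows = nrow(tr),
               mean_pe = mean(tr$pe), ok = TRUE)
  })
  do.call(rbind, rows)
}

#' Write a window track (and optional compliance columns) to CSV
#'
#' @param track A `"window_track"` data frame from [analyze_windows()],
#'   possibly augmented with compliance columns.
#' @param path Output path.
#' @param header Optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(format(as.data.frame(track), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a window track CSV written by [write_track_csv()]
#'
#' @param path Path to the track CSV.
#' @return A `data.frame`; `#` comment lines are skipped.
#' @export
read_track_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
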