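# Windowed intracranial compliance: ICC = dVolume / dICP estimated by
# finite differences of window means, which averages out pulse-level
# oscillation before differencing.

#' Windowed intracranial compliance track
#'
#' Estimates intracranial compliance `ICC = dVolume/dICP` between
#' consecutive sliding windows: `dv` and `dicp` are the differences of
#' window-mean balloon volume and window-mean ICP, and `icc = dv/dicp`
#' wherever `|dicp|` exceeds the degeneracy threshold `eps`. The first
#' window and degenerate windows carry `NA` (never infinities).
#'
#' Windowing matches [analyze_windows()] so the two tracks align row by
#' row.
#'
#' @param record A [waveform_record()] with a `volume` track.
#' @param window_len,shift Windowing, as in [analyze_windows()].
#' @param eps Minimum `|dicp|` in mmHg for the ratio to be defined
#'   (default 0.1).
#' @return `data.frame` with columns `window_start_idx`, `dv` (mL),
#'   `dicp` (mmHg), `icc` (mL/mmHg, `NA` where undefined).
#' @export
compliance_track <- function(record, window_len = 3600L, shift = 1000L,
                             eps = 0.1) {
  stopifnot(inherits(record, "waveform_record"))
  if (is.null(record$volume))
    stop("record has no volume track; compliance needs paired volume",
         call. = FALSE)
  starts <- window_starts(length(record$icp), window_len, shift)
  if (length(starts) == 0L)
    stop("record too short for a single window", call. = FALSE)
  k <- length(starts)
  mv <- mp <- numeric(k)
  for (i in seq_len(k)) {
    idx <- (starts[i] + 1L):(starts[i] + window_len)
    mv[i] <- mean(record$volume[idx])
    mp[i] <- mean(record$icp[idx])
  }
  dv <- c(NA_real_, diff(mv))
  dicp <- c(NA_real_, diff(mp))
  icc <- ifelse(!is.na(dicp) & abs(dicp) >= eps, dv / dicp, NA_real_)
  data.frame(window_start_idx = starts, dv = dv, dicp = dicp, icc = icc)
}
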