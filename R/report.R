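# Pipeline orchestration and summary reporting: compose filtering,
# sliding-window analysis, compliance and classification, and summarize a
# classified track per stage.

#' Run the full waveform-to-track pipeline
#'
#' Reads (or accepts) a waveform, applies the Butterworth preprocessing
#' chain, computes the sliding-window ordinal track, appends windowed
#' compliance columns when a volume track is present, classifies every
#' window, and optionally writes the result to CSV with a provenance
#' header recording all parameters.
#'
#' @param input Path to a waveform CSV or a [waveform_record()].
#' @param output Optional path for the track CSV.
#' @param m,tau Embedding parameters (defaults 6 and 1).
#' @param window_len,shift Windowing in samples (defaults 3600 and 1000).
#' @param filter Apply [filter_icp()] first (default `TRUE`).
#' @param thresholds [stage_thresholds()] for classification.
#' @param eps Compliance degeneracy threshold in mmHg, see
#'   [compliance_track()].
#' @return The classified track `data.frame` (invisibly if `output` is
#'   written): window features plus `stage_label` and, when volume is
#'   available, `dv`, `dicp`, `icc`.
#' @export
run_analyze <- function(input, output = NULL, m = 6L, tau = 1L,
                        window_len = 3600L, shift = 1000L, filter = TRUE,
                        thresholds = stage_thresholds(), eps = 0.1) {
  rec <- if (inherits(input, "waveform_record")) input
         else read_waveform_csv(input)
  filtered <- if (filter) filter_icp(rec) else rec
  track <- analyze_windows(filtered, m = m, tau = tau,
                           window_len = window_len, shift = shift)
  if (!is.null(rec$volume)) {
    comp <- compliance_track(filtered, window_len = window_len,
                             shift = shift, eps = eps)
    track$dv <- comp$dv
    track$dicp <- comp$dicp
    track$icc <- comp$icc
  }
  track$stage_label <- as.character(classify_track(track, thresholds))
  message(sprintf("run_analyze: %d windows (m=%d, tau=%d, window=%d, shift=%d)",
                  nrow(track), m, tau, window_len, shift))
  if (!is.null(output)) {
    hdr <- c(sprintf("icpentropy window track"),
             sprintf("m: %d", m), sprintf("tau: %d", tau),
             sprintf("window_len: %d", window_len),
             sprintf("shift: %d", shift),
             sprintf("fs: %g", rec$fs),
             sprintf("filtered: %s", filter))
    write_track_csv(track, output, header = hdr)
    return(invisible(track))
  }
  track
}

#' Summarize and plot a classified window track
#'
#' Produces the per-stage summary (median PE, median normalized NMP,
#' median mean-ICP, window count per stage label) and the standard
#' diagnostic figures: ICP with the PE track, ICP with the normalized NMP
#' track, and a box plot of normalized NMP per stage.
#'
#' @param track A classified track (with `stage_label`), e.g. from
#'   [run_analyze()].
#' @param output_dir Optional directory; when given, writes
#'   `stage_summary.csv` and the three plots as PNG files.
#' @return List with `summary` (`data.frame`) and `plots` (named list of
#'   ggplot objects), invisibly when `output_dir` is written.
#' @export
run_report <- function(track, output_dir = NULL) {
  if (!is.data.frame(track) || nrow(track) == 0L)
    stop("`track` must be a non-empty classified track", call. = FALSE)
  if (is.null(track$stage_label))
    stop("`track` has no stage_label column; classify it first",
         call. = FALSE)
  med <- function(x) stats::median(x)
  summ <- do.call(rbind, lapply(split(track, track$stage_label), function(d)
    data.frame(stage_label = d$stage_label[1], n_windows = nrow(d),
               median_pe = med(d$pe), median_nmp_norm = med(d$nmp_norm),
               median_mean_icp = med(d$mean_icp))))
  rownames(summ) <- NULL

  sc <- max(track$mean_icp)  # scale unit-interval features onto the ICP axis
  p_pe <- ggplot2::ggplot(track, ggplot2::aes(x = t_start_s)) +
    ggplot2::geom_line(ggplot2::aes(y = mean_icp, colour = "mean ICP (mmHg)")) +
    ggplot2::geom_line(ggplot2::aes(y = pe * .env$sc,
                                    colour = "PE (scaled)")) +
    ggplot2::labs(x = "window start (s)", y = "mean ICP (mmHg)",
                  colour = NULL,
                  title = "Mean ICP and permutation entropy per window")
  p_nmp <- ggplot2::ggplot(track, ggplot2::aes(x = t_start_s)) +
    ggplot2::geom_line(ggplot2::aes(y = mean_icp, colour = "mean ICP (mmHg)")) +
    ggplot2::geom_line(ggplot2::aes(y = nmp_norm * .env$sc,
                                    colour = "normalized NMP (scaled)")) +
    ggplot2::labs(x = "window start (s)", y = "mean ICP (mmHg)",
                  colour = NULL,
                  title = "Mean ICP and normalized missing patterns")
  p_box <- ggplot2::ggplot(track,
                           ggplot2::aes(x = stage_label, y = nmp_norm)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "stage", y = "normalized NMP",
                  title = "Normalized NMP per stage")
  plots <- list(icp_pe = p_pe, icp_nmp = p_nmp, nmp_box = p_box)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summ, file.path(output_dir, "stage_summary.csv"),
                     row.names = FALSE)
    for (nm in names(plots))
      suppressMessages(ggplot2::ggsave(
        file.path(output_dir, paste0(nm, ".png")), plots[[nm]],
        width = 8, height = 4, dpi = 120))
    return(invisible(list(summary = summ, plots = plots)))
  }
  list(summary = summ, plots = plots)
}
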