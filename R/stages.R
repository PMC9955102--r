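# Three-stage rule classifier over the ordinal monitoring features.
#
# The rules summarize the observed regimes: in injury-free periods PE is
# typically above 0.3, normalized NMP below 90% and the ascending pattern
# dominates the descending one; in terminal stages normalized NMP reaches
# 95% or more and the descending pattern dominates; in between, normalized
# NMP sits in the 90-95% band. The rules are neither mutually exclusive
# nor exhaustive, so windows matching none are labelled indeterminate
# rather than forced into a stage.

.STAGE_LEVELS <- c("injury_free", "intermediate", "terminal", "indeterminate")

#' Stage-classification thresholds
#'
#' @param pe_min_healthy Minimum PE for the injury-free rule (default 0.3).
#' @param nmp_max_healthy Normalized-NMP ceiling for injury-free (default
#'   0.90, exclusive).
#' @param nmp_min_terminal Normalized-NMP floor for terminal eligibility
#'   (default 0.95, inclusive).
#' @return List of class `"stage_thresholds"`.
#' @export
stage_thresholds <- function(pe_min_healthy = 0.3, nmp_max_healthy = 0.90,
                             nmp_min_terminal = 0.95) {
  if (!(pe_min_healthy > 0 && pe_min_healthy < 1))
    stop("`pe_min_healthy` must lie in (0, 1)", call. = FALSE)
  if (!(nmp_max_healthy > 0 && nmp_max_healthy <= nmp_min_terminal &&
        nmp_min_terminal < 1))
    stop("need 0 < nmp_max_healthy <= nmp_min_terminal < 1", call. = FALSE)
  structure(list(pe_min_healthy = pe_min_healthy,
                 nmp_max_healthy = nmp_max_healthy,
                 nmp_min_terminal = nmp_min_terminal),
            class = "stage_thresholds")
}

#' Classify monitoring windows into physiological stages
#'
#' Applies the rule table, in fixed order, to each window's features:
#' \describe{
#'   \item{injury_free}{`pe > pe_min_healthy` and
#'     `nmp_norm < nmp_max_healthy` and `p_first > p_last`.}
#'   \item{terminal}{`nmp_norm >= nmp_min_terminal` and
#'     `p_last > p_first`.}
#'   \item{intermediate}{`nmp_max_healthy <= nmp_norm < nmp_min_terminal`.}
#'   \item{indeterminate}{anything else.}
#' }
#' The boundary semantics follow the stated inequalities: a window at
#' exactly 90% normalized NMP is intermediate, one at exactly 95% is
#' terminal-eligible. Exactly one label is assigned per window.
#'
#' @param pe,nmp_norm,p_first,p_last Numeric vectors of equal length with
#'   values in `[0, 1]`.
#' @param thresholds A [stage_thresholds()] object.
#' @return Factor with levels `injury_free`, `intermediate`, `terminal`,
#'   `indeterminate`.
#' @examples
#' classify_window(0.35, 0.88, 0.5, 0.3)  # injury_free
#' @export
classify_window <- function(pe, nmp_norm, p_first, p_last,
                            thresholds = stage_thresholds()) {
  stopifnot(inherits(thresholds, "stage_thresholds"))
  if (length(unique(c(length(pe), length(nmp_norm), length(p_first),
                      length(p_last)))) != 1L)
    stop("feature vectors must have equal length", call. = FALSE)
  feats <- cbind(pe, nmp_norm, p_first, p_last)
  if (anyNA(feats) || any(feats < 0) || any(feats > 1))
    stop("all features must be in [0, 1]", call. = FALSE)
  lab <- rep.int("indeterminate", nrow(feats))
  inter <- nmp_norm >= thresholds$nmp_max_healthy &
    nmp_norm < thresholds$nmp_min_terminal
  lab[inter] <- "intermediate"
  term <- nmp_norm >= thresholds$nmp_min_terminal & p_last > p_first
  lab[term] <- "terminal"
  free <- pe > thresholds$pe_min_healthy &
    nmp_norm < thresholds$nmp_max_healthy & p_first > p_last
  lab[free] <- "injury_free"
  factor(lab, levels = .STAGE_LEVELS)
}

#' Classify a whole window track
#'
#' Element-wise [classify_window()] over the rows of a track from
#' [analyze_windows()].
#'
#' @param track A `"window_track"` data frame (or any data frame with
#'   columns `pe`, `nmp_norm`, `p_first`, `p_last`).
#' @param thresholds A [stage_thresholds()] object.
#' @return Factor of stage labels, one per row (length 0 for an empty
#'   track).
#' @export
classify_track <- function(track, thresholds = stage_thresholds()) {
  need <- c("pe", "nmp_norm", "p_first", "p_last")
  if (!all(need %in% names(track)))
    stop("track lacks columns: ",
         paste(setdiff(need, names(track)), collapse = ", "), call. = FALSE)
  if (nrow(track) == 0L) return(factor(character(0), levels = .STAGE_LEVELS))
  classify_window(track$pe, track$nmp_norm, track$p_first, track$p_last,
                  thresholds)
}
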