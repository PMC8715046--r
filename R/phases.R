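#' Early/late phase means of a condition-average trace
#'
#' Time-means of the baseline-corrected response in the early phase
#' (default 0.5-1.48 s after cue onset, the interval between the dilation
#' onset and the initial peak) and the late phase (from 1.48 s to trial
#' offset).  Windows are half-open `[start, end)` on the sample grid and
#' clipped to the trial duration; only non-missing samples enter the means.
#'
#' @param trace a `condition_average`.
#' @param duration trial duration in seconds (taken from `trace$meta` when
#'   absent).
#' @param config a [pupil_config()].
#' @return one-row data frame: `early_mean`, `late_mean`, `n_early`,
#'   `n_late` (numbers of contributing samples; a fully missing window
#'   yields `NA` mean and `n = 0`).
#' @export
phase_means <- function(trace, duration = NULL, config = pupil_config()) {
  if (is.null(duration)) duration <- trace$meta$duration
  if (is.null(duration) || is.na(duration))
    stop("trial duration required for the late-phase window")
  duration <- as.numeric(duration)
  x <- trace$rel_time
  y <- trace$mean
  eps <- 1e-9
  win_mean <- function(a, b) {
    sel <- x >= a - eps & x < b - eps & !is.na(y)
    if (!any(sel)) return(c(NA_real_, 0))
    c(mean(y[sel]), sum(sel))
  }
  e <- win_mean(config$early_phase[1], min(config$early_phase[2], duration))
  l <- win_mean(config$late_phase_start, duration)
  data.frame(early_mean = e[1], late_mean = l[1],
             n_early = e[2], n_late = l[2])
}

#' Phase-summary table over condition averages
#'
#' Applies [phase_means()] to every per-duration condition average and
#' binds the grouping metadata, giving the long-format table consumed by
#' [rm_anova()] (factors phase x eye x duration within participant).
#'
#' @param averages list of `condition_average` objects whose `meta` includes
#'   `duration` (see [average_epochs()]).
#' @param config a [pupil_config()].
#' @return data frame: the meta columns plus `early_mean`, `late_mean`,
#'   `n_early`, `n_late`.
#' @export
phase_table <- function(averages, config = pupil_config()) {
  rows <- lapply(averages, function(a) {
    pm <- phase_means(a, config = config)
    cbind(as.data.frame(a$meta, stringsAsFactors = FALSE), pm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape a phase-summary table to one row per phase
#'
#' Stacks `early_mean`/`late_mean` into a `value` column with a `phase`
#' factor, the layout [rm_anova()] expects.
#'
#' @param ptab output of [phase_table()].
#' @return long data frame with columns of `ptab` (minus the means) plus
#'   `phase` (`"early"`/`"late"`) and `value`.
#' @export
phase_long <- function(ptab) {
  keep <- setdiff(names(ptab),
                  c("early_mean", "late_mean", "n_early", "n_late"))
  long <- rbind(
    cbind(ptab[keep], phase = "early", value = ptab$early_mean),
    cbind(ptab[keep], phase = "late", value = ptab$late_mean))
  rownames(long) <- NULL
  long
}
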