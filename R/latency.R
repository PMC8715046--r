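#' Dilation onset latency by the 25/75%-of-peak extrapolation method
#'
#' Finds the peak of a baseline-corrected mean trace inside the search
#' window after cue onset (default 0-3 s, the shortest trial length, which
#' captures the initial dilation peak while excluding late sustained
#' drift), locates the first up-crossings of 25% and 75% of the peak value
#' before the peak (linear interpolation between samples), and extrapolates
#' the straight line through those two points down to zero.  The
#' intersection time is the dilation onset latency.
#'
#' Estimation fails, with a recorded reason, when the trace is entirely
#' missing in the window, when the peak is non-positive or smaller than
#' `latency_min_peak_sd` baseline standard deviations ("no apparent
#' increase"), when the trace already exceeds the lower threshold at the
#' window start (no crossing exists), or when the extrapolated latency is
#' negative.
#'
#' @param trace a `condition_average` (or any list with `rel_time` and
#'   `mean`), baseline-corrected, covering the search window.
#' @param config a [pupil_config()]; uses `latency_search`, `latency_fracs`
#'   and `latency_min_peak_sd`.
#' @return a `latency_result`: list with `latency`, `peak_time`,
#'   `peak_value`, `t25`, `t75`, `status` (`"estimated"` or `"failed"`) and
#'   `failure_reason`.
#' @examples
#' ramp <- list(rel_time = seq(-1, 3, by = 0.004),
#'              mean = pmax(0, pmin(seq(-1, 3, by = 0.004) - 0.6, 0.88)) / 0.88)
#' estimate_latency(ramp)$latency   # 0.6: the chord lies on the ramp
#' @export
estimate_latency <- function(trace, config = pupil_config()) {
  failed <- function(reason)
    structure(list(latency = NA_real_, peak_time = NA_real_,
                   peak_value = NA_real_, t25 = NA_real_, t75 = NA_real_,
                   status = "failed", failure_reason = reason),
              class = "latency_result")

  x <- trace$rel_time
  y <- trace$mean
  w <- config$latency_search
  fr <- config$latency_fracs

  sel <- which(x >= w[1] & x <= w[2] & !is.na(y))
  if (!length(sel)) return(failed("trace fully missing in search window"))

  peak_i <- sel[which.max(y[sel])]
  peak <- y[peak_i]
  peak_time <- x[peak_i]
  if (!is.finite(peak) || peak <= 0) return(failed("no apparent increase"))
  base <- y[x < 0 & !is.na(y)]
  if (length(base) >= 2) {
    sd_base <- stats::sd(base)
    if (is.finite(sd_base) && peak < config$latency_min_peak_sd * sd_base)
      return(failed("no apparent increase"))
  }

  # samples from window start up to the peak, non-missing
  rise <- sel[sel <= peak_i]
  xr <- x[rise]
  yr <- y[rise]
  cross <- function(thr) {
    if (yr[1] >= thr) return(NA_real_)  # starts above: no up-crossing
    j <- which(yr[-1] >= thr & yr[-length(yr)] < thr)
    if (!length(j)) return(NA_real_)
    j <- j[1]
    xr[j] + (thr - yr[j]) / (yr[j + 1] - yr[j]) * (xr[j + 1] - xr[j])
  }
  t_lo <- cross(fr[1] * peak)
  t_hi <- cross(fr[2] * peak)
  if (is.na(t_lo) || is.na(t_hi))
    return(failed("threshold crossing not found"))

  # zero intersection of the chord through (t_lo, f1*P), (t_hi, f2*P)
  latency <- t_lo - fr[1] * (t_hi - t_lo) / (fr[2] - fr[1])
  if (latency < 0) return(failed("extrapolated onset before cue"))

  structure(list(latency = latency, peak_time = peak_time,
                 peak_value = peak, t25 = t_lo, t75 = t_hi,
                 status = "estimated", failure_reason = ""),
            class = "latency_result")
}

#' @export
print.latency_result <- function(x, ...) {
  if (x$status == "estimated")
    cat(sprintf(
      "<latency_result> latency %.3f s (peak %.3f at %.3f s; t25 %.3f, t75 %.3f)\n",
      x$latency, x$peak_value, x$peak_time, x$t25, x$t75))
  else
    cat("<latency_result> failed:", x$failure_reason, "\n")
  invisible(x)
}

#' Movement (button-press) latencies
#'
#' Per trial, the latency of the first button press inside the trial window
#' `[onset, offset]` relative to cue onset.  Presses outside every trial
#' window are ignored; trials without a press are flagged and excluded from
#' summaries.
#'
#' @param events an `event_log` with `trials` and `presses`.
#' @return list with
#'   \item{trials}{data frame `trial_id`, `duration`, `session`, `latency`
#'     (`NA` when no press), `n_press`;}
#'   \item{summary}{per-duration `mean`, `sd`, `n` over trials with a
#'     press.}
#' @export
movement_latencies <- function(events) {
  trials <- events$trials
  presses <- events$presses
  if (is.null(trials) || nrow(trials) == 0) stop("no trials in event log")
  pt <- if (is.null(presses)) numeric(0) else presses$time
  lat <- rep(NA_real_, nrow(trials))
  np <- integer(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset[i]
    off <- trials$onset[i] + trials$duration[i]
    inside <- pt[pt >= on & pt <= off]
    np[i] <- length(inside)
    if (length(inside)) lat[i] <- min(inside) - on
  }
  tr <- data.frame(trial_id = trials$trial_id,
                   duration = trials$duration,
                   session = if ("session" %in% names(trials)) trials$session
                             else NA_character_,
                   latency = lat, n_press = np,
                   stringsAsFactors = FALSE)
  ok <- !is.na(lat)
  summ <- do.call(rbind, lapply(split(tr[ok, ], tr$duration[ok]), function(d)
    data.frame(duration = d$duration[1], mean = mean(d$latency),
               sd = stats::sd(d$latency), n = nrow(d))))
  rownames(summ) <- NULL
  list(trials = tr, summary = summ)
}
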