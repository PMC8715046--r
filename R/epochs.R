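#' Extract cue-locked, baseline-corrected epochs
#'
#' Cuts one epoch per trial from 1 s before cue onset to 1 s after cue
#' offset (configurable), on the sample grid: the cue onset is snapped to
#' the nearest sample so that all epochs share an exact `1/fs` relative-time
#' grid (alignment bias at most half a sample, 2 ms at 250 Hz).  Each epoch
#' is adjusted by its own baseline, the mean of the non-missing samples in
#' the `baseline_window` (0.1 s) immediately before the cue.  Epochs whose
#' baseline window is entirely missing are flagged unusable; epochs
#' extending past either end of the recording are flagged truncated.  Both
#' are retained (so they can be reported) but excluded from averages.
#'
#' @param series a preprocessed `diameter_series` (see
#'   [preprocess_samples()]).
#' @param events an `event_log` from [read_event_log()] (or a compatible
#'   list with a `trials` data frame).
#' @param config a [pupil_config()].
#' @return a `pupil_epochs` object: list with
#'   \item{fs, pre_n}{grid parameters (epoch sample `i` sits at relative
#'     time `(i - 1 - pre_n) / fs`);}
#'   \item{values}{list of numeric vectors, baseline-corrected diameter with
#'     `NA` where masked;}
#'   \item{meta}{data frame: participant, eye, drug, session, duration,
#'     trial_id, baseline, usable, truncated.}
#' @export
extract_epochs <- function(series, events, config = pupil_config()) {
  trials <- events$trials
  if (is.null(trials) || nrow(trials) == 0) stop("no trials in event log")
  fs <- attr(series, "fs") %||% config$fs
  t0 <- series$time[1]
  n <- nrow(series)
  x <- series$diameter
  x[series$missing] <- NA_real_

  pre_n <- round(config$epoch_pre * fs)
  base_n <- round(config$baseline_window * fs)

  values <- vector("list", nrow(trials))
  meta <- data.frame(
    participant = rep(attr(series, "participant") %||% NA_character_,
                      nrow(trials)),
    eye = rep(attr(series, "eye") %||% NA_character_, nrow(trials)),
    drug = if ("drug" %in% names(trials)) trials$drug else NA_character_,
    session = if ("session" %in% names(trials)) trials$session
              else NA_character_,
    duration = trials$duration,
    trial_id = trials$trial_id,
    baseline = NA_real_,
    usable = FALSE,
    truncated = FALSE,
    stringsAsFactors = FALSE)

  for (i in seq_len(nrow(trials))) {
    onset_idx <- round((trials$onset[i] - t0) * fs) + 1L
    post_n <- round((trials$duration[i] + config$epoch_post) * fs)
    lo <- onset_idx - pre_n
    hi <- onset_idx + post_n
    if (lo < 1 || hi > n) {
      meta$truncated[i] <- TRUE
      values[[i]] <- rep(NA_real_, hi - lo + 1L)
      next
    }
    seg <- x[lo:hi]
    bwin <- x[(onset_idx - base_n):(onset_idx - 1L)]
    if (all(is.na(bwin))) {
      values[[i]] <- seg   # unusable: baseline unknown, left uncorrected
      next
    }
    b <- mean(bwin, na.rm = TRUE)
    meta$baseline[i] <- b
    meta$usable[i] <- TRUE
    values[[i]] <- seg - b
  }
  structure(list(fs = fs, pre_n = pre_n, values = values, meta = meta),
            class = "pupil_epochs")
}

#' @export
print.pupil_epochs <- function(x, ...) {
  cat(sprintf("<pupil_epochs> %d epochs (%d usable, %d truncated), fs = %g Hz\n",
              nrow(x$meta), sum(x$meta$usable), sum(x$meta$truncated), x$fs))
  invisible(x)
}

#' Combine epoch collections
#'
#' @param ... `pupil_epochs` objects on the same grid.
#' @return a single `pupil_epochs` object.
#' @export
bind_epochs <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "pupil_epochs"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1)
  fs <- parts[[1]]$fs
  pre_n <- parts[[1]]$pre_n
  for (p in parts)
    if (p$fs != fs || p$pre_n != pre_n)
      stop("epoch collections are on different grids")
  structure(list(fs = fs, pre_n = pre_n,
                 values = do.call(c, lapply(parts, `[[`, "values")),
                 meta = do.call(rbind, lapply(parts, `[[`, "meta"))),
            class = "pupil_epochs")
}

#' Per-condition mean traces
#'
#' Averages usable, non-truncated epochs pointwise (non-missing values only)
#' within each combination of the grouping keys.  Epochs are aligned at cue
#' onset; when a group mixes trial durations (e.g. pooling over durations),
#' the mean at relative time `t` uses every epoch whose span covers `t`, so
#' the trace extends to the longest epoch and `n` drops where shorter trials
#' no longer contribute.
#'
#' @param epochs a `pupil_epochs` object.
#' @param by character vector of `meta` column names defining the cells
#'   (default participant, eye, drug, duration).  Drop `"duration"` to pool
#'   across trial lengths.
#' @return list of `condition_average` objects, each a list with `rel_time`,
#'   `mean` (mm change from baseline), `n` (contributing trials per time
#'   point) and `meta` (the grouping key values).  Empty cells are absent.
#' @export
average_epochs <- function(epochs,
                           by = c("participant", "eye", "drug", "duration")) {
  keep <- epochs$meta$usable & !epochs$meta$truncated
  if (!any(keep)) {
    warning("no usable epochs to average")
    return(list())
  }
  meta <- epochs$meta[keep, , drop = FALSE]
  values <- epochs$values[keep]
  missing_by <- setdiff(by, names(meta))
  if (length(missing_by))
    stop("unknown grouping key(s): ", paste(missing_by, collapse = ", "))
  key <- do.call(paste, c(meta[by], sep = "\r"))
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    len <- max(lengths(values[idx]))
    s <- numeric(len)
    cnt <- integer(len)
    for (i in idx) {
      v <- values[[i]]
      g <- which(!is.na(v))
      s[g] <- s[g] + v[g]
      cnt[g] <- cnt[g] + 1L
    }
    m <- s / cnt
    m[cnt == 0] <- NA_real_
    info <- as.list(meta[idx[1], by, drop = FALSE])
    out[[length(out) + 1L]] <- structure(
      list(rel_time = (seq_len(len) - 1L - epochs$pre_n) / epochs$fs,
           mean = m, n = cnt, meta = info),
      class = "condition_average")
  }
  out
}

#' @export
print.condition_average <- function(x, ...) {
  cat("<condition_average>",
      paste(names(x$meta), unlist(lapply(x$meta, as.character)),
            sep = "=", collapse = " "),
      sprintf("| %d points, max n = %d\n", length(x$mean), max(x$n)))
  invisible(x)
}
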