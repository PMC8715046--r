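#' Convert pupil area to diameter
#'
#' The diameter of a circle of area `a` is `sqrt(4 a / pi)`; applied
#' elementwise so a measured pupil area series (mm^2) becomes a diameter
#' series (mm).  `NA` (missing/masked) values propagate.
#'
#' @param area numeric vector of pupil areas; must be non-negative wherever
#'   not `NA`.
#' @return numeric vector of pupil diameters, same length.
#' @examples
#' area_to_diameter(pi)   # a circle of area pi has diameter 2
#' @seealso [diameter_to_area()] for the inverse map.
#' @export
area_to_diameter <- function(area) {
  if (!is.numeric(area)) stop("area must be numeric")
  if (any(area < 0, na.rm = TRUE))
    stop("negative pupil area at index ",
         which(!is.na(area) & area < 0)[1])
  sqrt(area * 4 / pi)
}

#' Convert pupil diameter to area
#'
#' Inverse of [area_to_diameter()]: `pi d^2 / 4`.
#'
#' @param diameter numeric vector, non-negative where not `NA`.
#' @return numeric vector of areas.
#' @export
diameter_to_area <- function(diameter) {
  if (any(diameter < 0, na.rm = TRUE)) stop("negative diameter")
  pi * diameter^2 / 4
}

#' Build a diameter series from raw samples
#'
#' Applies the device-unit scale, converts area to diameter, and turns
#' tracker-invalid samples into mask entries (values are kept `NA`, never a
#' sentinel number).
#'
#' @param samples a `pupil_samples` object from [read_pupil_samples()] (or a
#'   data frame with columns `time`, `area`, `valid`).
#' @param config a [pupil_config()].
#' @return a `diameter_series`: data frame with columns `time`, `diameter`,
#'   `missing`, carrying attributes `fs`, `participant`, `eye`.
#' @export
as_diameter_series <- function(samples, config = pupil_config()) {
  need <- c("time", "area", "valid")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples missing column(s): ",
                         paste(miss, collapse = ", "))
  area <- samples$area * config$area_unit_scale
  missing <- !samples$valid
  if (any(area[!missing] < 0))
    stop("negative valid pupil area at index ",
         which(!missing & area < 0)[1])
  area[missing] <- NA_real_
  out <- data.frame(time = samples$time,
                    diameter = area_to_diameter(area),
                    missing = missing)
  structure(out,
            fs = config$fs,
            participant = attr(samples, "participant"),
            eye = attr(samples, "eye"),
            class = c("diameter_series", "data.frame"))
}

# Centered nan-aware moving mean with shrinking windows at the boundaries.
# n must be odd; complexity O(length(x)) via cumulative sums.
moving_average_na <- function(x, n) {
  good <- !is.na(x)
  xs <- x
  xs[!good] <- 0
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(good))
  h <- (n - 1L) %/% 2L
  i <- seq_along(x)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, length(x))
  s <- cs[hi + 1L] - cs[lo]
  k <- cn[hi + 1L] - cn[lo]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Smooth a diameter series with a centered moving average
#'
#' Each output sample is the mean of the non-missing samples inside a
#' centered window (5 samples for the default 20 ms at 250 Hz).  Samples
#' whose whole window is missing stay missing; at the two boundaries the
#' window shrinks to the available samples.
#'
#' @param series a `diameter_series`.
#' @param window window length in seconds; must be at least one sample
#'   period.  Defaults to `config$smooth_window`.
#' @param config a [pupil_config()].
#' @return the smoothed `diameter_series`.
#' @export
smooth_diameter <- function(series, window = NULL, config = pupil_config()) {
  fs <- attr(series, "fs") %||% config$fs
  if (is.null(window)) window <- config$smooth_window
  n <- round(window * fs)
  if (n < 1) stop("smoothing window shorter than one sample period")
  if (n %% 2 == 0) n <- n + 1L   # keep the window centered
  x <- series$diameter
  x[series$missing] <- NA_real_
  sm <- moving_average_na(x, as.integer(n))
  series$diameter <- sm
  series$missing <- is.na(sm)
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect blinks and mask the contaminated samples
#'
#' A blink appears in the diameter trace as a rapid decrease followed,
#' within `blink_pair_window` (500 ms), by a rapid increase.  "Rapid" is
#' judged on the first-difference velocity (mm/s) of the smoothed trace:
#' samples whose velocity falls below `-k * sigma_v` (above `+k * sigma_v`)
#' are decrease (increase) candidates, where `sigma_v` is a robust scale
#' (median absolute deviation, consistent for the normal) of the velocity
#' over the whole recording, floored at `blink_vel_floor` so that noise-free
#' recordings produce no spurious candidates.  A run of decrease candidates
#' opens a blink; it closes at the end of the first increase run starting
#' within the pairing window; decreases that never pair are masked for the
#' full pairing window as a precaution and returned with `paired = FALSE`.
#' Every blink masks `[onset - blink_pad_pre, offset + blink_pad_post]`
#' (default -40/+80 ms); overlapping padded masks are merged.
#'
#' @param series a smoothed `diameter_series`.
#' @param config a [pupil_config()].
#' @return list with elements
#'   \item{series}{the input with blink samples set missing (masking is
#'     monotone: it only ever adds missing samples);}
#'   \item{blinks}{data frame `onset`, `offset`, `mask_start`, `mask_end`,
#'     `paired`, sorted and non-overlapping after merging.  Zero rows when
#'     the trace is clean.}
#' @export
mask_blinks <- function(series, config = pupil_config()) {
  fs <- attr(series, "fs") %||% config$fs
  t <- series$time
  x <- series$diameter
  x[series$missing] <- NA_real_
  v <- diff(x) * fs                      # mm/s over (t[i], t[i+1])
  sigma <- stats::mad(v, na.rm = TRUE)
  thr <- max(config$blink_k * sigma, config$blink_vel_floor)
  dec <- !is.na(v) & v < -thr
  inc <- !is.na(v) & v > thr

  runs <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  }
  dr <- runs(dec)
  ir <- runs(inc)

  b_on <- b_off <- numeric(0)
  b_paired <- logical(0)
  if (nrow(dr)) {
    last_off <- -Inf
    j <- 1L
    for (i in seq_len(nrow(dr))) {
      onset <- t[dr[i, "start"]]
      if (onset <= last_off) next      # decrease inside the previous blink
      # first increase run beginning after onset and within the pair window
      while (j <= nrow(ir) && t[ir[j, "start"]] <= onset) j <- j + 1L
      if (j <= nrow(ir) &&
          t[ir[j, "start"]] - onset <= config$blink_pair_window) {
        offset <- min(t[ir[j, "end"] + 1L], onset + config$blink_pair_window)
        paired <- TRUE
      } else {
        offset <- onset + config$blink_pair_window
        paired <- FALSE
      }
      last_off <- offset
      b_on <- c(b_on, onset)
      b_off <- c(b_off, offset)
      b_paired <- c(b_paired, paired)
    }
  }
  blinks <- data.frame(onset = b_on, offset = b_off, paired = b_paired)
  blinks$mask_start <- blinks$onset - config$blink_pad_pre
  blinks$mask_end <- blinks$offset + config$blink_pad_post
  blinks <- blinks[order(blinks$onset),
                   c("onset", "offset", "mask_start", "mask_end", "paired"),
                   drop = FALSE]

  # merge overlapping padded masks
  if (nrow(blinks) > 1) {
    keep <- rep(TRUE, nrow(blinks))
    for (i in 2:nrow(blinks)) {
      prev <- max(which(keep[seq_len(i - 1)]))
      if (blinks$mask_start[i] <= blinks$mask_end[prev]) {
        blinks$mask_end[prev] <- max(blinks$mask_end[prev],
                                     blinks$mask_end[i])
        blinks$offset[prev] <- max(blinks$offset[prev], blinks$offset[i])
        keep[i] <- FALSE
      }
    }
    blinks <- blinks[keep, , drop = FALSE]
    rownames(blinks) <- NULL
  }

  for (i in seq_len(nrow(blinks))) {   # closed mask interval, grid indices
    lo <- max(1L, as.integer(ceiling((blinks$mask_start[i] - t[1]) * fs
                                     - 1e-6)) + 1L)
    hi <- min(length(t), as.integer(floor((blinks$mask_end[i] - t[1]) * fs
                                          + 1e-6)) + 1L)
    if (hi >= lo) series$missing[lo:hi] <- TRUE
  }
  series$diameter[series$missing] <- NA_real_
  list(series = series, blinks = blinks)
}

#' Preprocess one eye's raw samples
#'
#' Convenience chain: area-to-diameter conversion, 20 ms moving-average
#' smoothing, then blink detection and masking, in that order.
#'
#' @param samples a `pupil_samples` object.
#' @param config a [pupil_config()].
#' @return list with `series` (preprocessed `diameter_series`) and `blinks`
#'   (the blink-interval table from [mask_blinks()]).
#' @export
preprocess_samples <- function(samples, config = pupil_config()) {
  d <- as_diameter_series(samples, config)
  d <- smooth_diameter(d, config = config)
  mask_blinks(d, config)
}
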