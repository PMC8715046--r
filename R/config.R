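#' Pipeline configuration
#'
#' Builds the configuration object consumed by every pipeline stage.  All
#' temporal constants default to the values used throughout the analysis:
#' 250 Hz sampling, 20 ms smoothing, a 500 ms blink-pairing window with
#' -40/+80 ms mask padding, epochs from 1 s before cue onset to 1 s after cue
#' offset, a 0.1 s pre-cue baseline, an early response phase of 0.5-1.48 s
#' and a late phase from 1.48 s to trial offset, and onset-latency
#' extrapolation through the 25% and 75%-of-peak points.
#'
#' Precedence is built-in defaults < `file` < `...`: a flat `key: value`
#' text file (one field per line, `#` comments allowed, comma-separated
#' numeric vectors) overrides defaults, and named arguments override both.
#'
#' @param file optional path to a flat `key: value` configuration file whose
#'   keys mirror the field names below.
#' @param ... named overrides for individual fields.
#'
#' @return An object of class `pupil_config`: a named list with fields
#' \describe{
#'   \item{fs}{sampling rate, Hz (250).}
#'   \item{smooth_window}{moving-average window, s (0.020).}
#'   \item{blink_pair_window}{max decrease-to-increase pairing gap, s (0.500).}
#'   \item{blink_pad_pre, blink_pad_post}{mask padding before onset / after
#'     offset, s (0.040 / 0.080).}
#'   \item{blink_k}{velocity threshold in robust (MAD) SD units (5).}
#'   \item{blink_vel_floor}{absolute velocity floor, mm/s (25); keeps a
#'     noise-free recording from flagging slow evoked drift.}
#'   \item{epoch_pre, epoch_post}{epoch extent around the cue, s (1, 1).}
#'   \item{baseline_window}{pre-cue baseline length, s (0.100).}
#'   \item{early_phase}{early analysis window, s (c(0.5, 1.48)).}
#'   \item{late_phase_start}{late window start, s (1.48); late window runs to
#'     trial offset.}
#'   \item{latency_fracs}{peak fractions for the extrapolation chord
#'     (c(0.25, 0.75)).}
#'   \item{latency_search}{peak search window after cue onset, s (c(0, 3)).}
#'   \item{latency_min_peak_sd}{peak must exceed this multiple of the
#'     baseline-segment SD, else "no apparent increase" (3).}
#'   \item{alpha}{significance level (0.05).}
#'   \item{area_unit_scale}{factor converting device area units to mm^2 (1).}
#'   \item{durations}{admissible trial durations, s (c(3, 6, 9)).}
#'   \item{iti_range}{admissible inter-trial interval, s (c(5, 8)).}
#'   \item{rng_seed}{seed recorded in pipeline provenance (1).}
#' }
#' @examples
#' cfg <- pupil_config(smooth_window = 0.04)
#' cfg$smooth_window
#' @export
pupil_config <- function(file = NULL, ...) {
  cfg <- list(
    fs                 = 250,
    smooth_window      = 0.020,
    blink_pair_window  = 0.500,
    blink_pad_pre      = 0.040,
    blink_pad_post     = 0.080,
    blink_k            = 5,
    blink_vel_floor    = 25,
    epoch_pre          = 1.0,
    epoch_post         = 1.0,
    baseline_window    = 0.100,
    early_phase        = c(0.5, 1.48),
    late_phase_start   = 1.48,
    latency_fracs      = c(0.25, 0.75),
    latency_search     = c(0, 3),
    latency_min_peak_sd = 3,
    alpha              = 0.05,
    area_unit_scale    = 1,
    durations          = c(3, 6, 9),
    iti_range          = c(5, 8),
    rng_seed           = 1
  )
  if (!is.null(file)) {
    kv <- read_key_value(file)
    unknown <- setdiff(names(kv), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(kv)] <- kv
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "pupil_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("fs", "smooth_window", "blink_pair_window", "blink_pad_pre",
           "blink_pad_post", "epoch_pre", "epoch_post", "baseline_window",
           "area_unit_scale")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar")
  fr <- cfg$latency_fracs
  if (length(fr) != 2 || !(0 < fr[1] && fr[1] < fr[2] && fr[2] <= 1))
    stop("latency_fracs must satisfy 0 < f1 < f2 <= 1")
  if (!(cfg$alpha > 0 && cfg$alpha < 1))
    stop("alpha must lie in (0, 1)")
  if (length(cfg$early_phase) != 2 || cfg$early_phase[1] >= cfg$early_phase[2])
    stop("early_phase must be an increasing pair of times")
  if (length(cfg$latency_search) != 2 ||
      cfg$latency_search[1] >= cfg$latency_search[2])
    stop("latency_search must be an increasing pair of times")
  if (cfg$smooth_window < 1 / cfg$fs)
    stop("smooth_window shorter than one sample period")
  invisible(cfg)
}

#' Read a flat key:value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments are ignored.
#' Values that parse as numbers (scalars or comma-separated vectors) are
#' converted; everything else stays character.
#'
#' @param path file path.
#' @return named list.
#' @keywords internal
read_key_value <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0) stop("malformed configuration line (no ':'): ", ln)
    key <- trimws(substr(ln, 1, m - 1))
    val <- trimws(substr(ln, m + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (length(parts) && !anyNA(num)) num else val
  }
  out
}

write_key_value <- function(x, path) {
  fmt <- vapply(x, function(v) paste(format(v, digits = 15), collapse = ","),
                character(1))
  writeLines(paste0(names(x), ": ", fmt), path)
  invisible(path)
}

#' @export
print.pupil_config <- function(x, ...) {
  cat("<pupil_config>\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-20s %s\n", f, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
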