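#' Read a sample-level eye-tracker export
#'
#' Plain-text comma/tab-separated file with a one-line header and columns
#' `time` (s), `eye`, `area` (device units or mm^2) and `valid` (0/1 or
#' logical); both eyes live in one file, distinguished by the `eye` column.
#' Device units are multiplied by `config$area_unit_scale`; invalid samples
#' are flagged, never dropped.
#'
#' @param path file path.
#' @param config a [pupil_config()].
#' @param participant optional participant label attached to each series.
#' @return named list (one entry per eye) of `pupil_samples` data frames
#'   (`time`, `area`, `valid`) with attributes `participant`, `eye`, `fs`.
#'   Errors name a missing column, or report the first non-monotonic time
#'   index within an eye block.
#' @export
read_pupil_samples <- function(path, config = pupil_config(),
                               participant = NA_character_) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("time", "eye", "area", "valid")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("sample file format error: missing column(s) ",
         paste(miss, collapse = ", "))
  out <- list()
  for (eye in unique(raw$eye)) {
    blk <- raw[raw$eye == eye, , drop = FALSE]
    dt <- diff(blk$time)
    if (any(dt <= 0))
      stop("non-monotonic time in eye '", eye, "' at index ",
           which(dt <= 0)[1] + 1)
    step <- stats::median(dt)
    if (abs(step - 1 / config$fs) > 0.01 / config$fs)
      warning(sprintf(
        "median sample step %.6f s differs from 1/fs = %.6f s", step,
        1 / config$fs))
    valid <- as.logical(blk$valid)
    area <- blk$area * config$area_unit_scale
    if (any(area[valid] < 0))
      stop("negative valid area in eye '", eye, "' at index ",
           which(valid & area < 0)[1])
    out[[eye]] <- structure(
      data.frame(time = blk$time, area = area, valid = valid),
      participant = participant, eye = eye, fs = config$fs,
      class = c("pupil_samples", "data.frame"))
  }
  out
}

#' Write sample series back to disk
#'
#' Inverse of [read_pupil_samples()] (numeric content round-trips to the
#' written precision); areas are divided by `area_unit_scale` so the file
#' stays in the original device units.
#'
#' @param series named list of `pupil_samples` (one per eye).
#' @param path output path.
#' @param config a [pupil_config()].
#' @return `path`, invisibly.
#' @export
write_pupil_samples <- function(series, path, config = pupil_config()) {
  blocks <- lapply(names(series), function(eye) {
    s <- series[[eye]]
    data.frame(time = s$time, eye = eye,
               area = s$area / config$area_unit_scale,
               valid = as.integer(s$valid))
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trial/event table
#'
#' Columns `trial_id`, `onset` (s), `duration` (s), `session`,
#' `eye_treatment`, `drug`; an optional second file with button presses
#' (`time`, `button`).  Trials are returned sorted by onset.  Overlapping
#' trials are an error; durations outside the configured set are kept but
#' flagged (`nonstandard = TRUE`) with a warning.
#'
#' @param path trial table path.
#' @param press_path optional press table path.
#' @param config a [pupil_config()]; supplies the admissible duration set
#'   and ITI bounds.
#' @return an `event_log`: list with data frames `trials` (plus computed
#'   `offset` and `nonstandard`) and `presses`.
#' @export
read_event_log <- function(path, press_path = NULL, config = pupil_config()) {
  if (!file.exists(path)) stop("event file not found: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "onset", "duration", "session", "eye_treatment",
            "drug")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("event file format error: missing column(s) ",
         paste(miss, collapse = ", "))
  tr <- tr[order(tr$onset), , drop = FALSE]
  rownames(tr) <- NULL
  tr$offset <- tr$onset + tr$duration
  if (nrow(tr) > 1 && any(tr$onset[-1] < tr$offset[-nrow(tr)]))
    stop("overlapping trials at onset ",
         tr$onset[-1][which(tr$onset[-1] < tr$offset[-nrow(tr)])[1]])
  tr$nonstandard <- !tr$duration %in% config$durations
  if (any(tr$nonstandard))
    warning(sum(tr$nonstandard),
            " trial(s) with duration outside the configured set retained",
            " with nonstandard flag")
  presses <- if (!is.null(press_path) && file.exists(press_path) &&
                 length(readLines(press_path)) > 1)
    utils::read.csv(press_path, stringsAsFactors = FALSE)
  else data.frame(time = numeric(0), button = character(0))
  structure(list(trials = tr, presses = presses), class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d trials (%d nonstandard), %d presses\n",
              nrow(x$trials), sum(x$trials$nonstandard), nrow(x$presses)))
  invisible(x)
}

#' Write an epoch collection as a long-format CSV store
#'
#' One row per epoch sample (`participant`, `eye`, `drug`, `session`,
#' `duration`, `trial_id`, `rel_time`, `value`, `missing`), keeping the
#' intermediate stage file-based and inspectable.
#'
#' @param epochs a `pupil_epochs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epoch_store <- function(epochs, path) {
  keep <- which(epochs$meta$usable & !epochs$meta$truncated)
  rows <- lapply(keep, function(i) {
    v <- epochs$values[[i]]
    cbind(epochs$meta[i, c("participant", "eye", "drug", "session",
                           "duration", "trial_id")],
          data.frame(rel_time = (seq_along(v) - 1L - epochs$pre_n) / epochs$fs,
                     value = v, missing = as.integer(is.na(v))),
          row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full pipeline over an on-disk dataset
#'
#' Chains every stage — ingestion, preprocessing (conversion, smoothing,
#' blink masking), cue-locked epoching with baseline correction,
#' per-condition averaging, onset-latency estimation, movement latencies,
#' phase summaries, the within-subject phase x eye x duration ANOVA with
#' pooled-error simple effects of eye within each phase, and the one-way
#' latency comparison across eyes with Ryan's post-hoc — and writes tidy
#' CSV outputs plus a provenance sidecar (configuration values, their MD5
#' hash and the recorded seed).  The pipeline is a pure function of the
#' inputs and configuration: reruns produce identical tables.
#'
#' @param input directory containing an `index.csv` (as written by
#'   [simulate_study()]/[write_study()]), or the path of the index file.
#' @param out_dir output directory for the result tables.
#' @param config a [pupil_config()].
#' @return invisibly, a list with the computed tables: `condition_means`,
#'   `latency`, `movement`, `phase_summary`, `anova` (per drug),
#'   `simple_effects`, `posthoc`, `blinks`.
#' @export
run_pipeline <- function(input, out_dir, config = pupil_config()) {
  index_path <- if (dir.exists(input)) file.path(input, "index.csv") else input
  if (!file.exists(index_path)) stop("index file not found: ", index_path)
  base <- dirname(index_path)
  index <- utils::read.csv(index_path, stringsAsFactors = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("output directory not writable: ", out_dir)

  stage <- function(what, pid, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed for participant ", pid, ": ",
           conditionMessage(e), call. = FALSE))
  }

  all_epochs <- list()
  blink_rows <- NULL
  movement_rows <- NULL
  for (r in seq_len(nrow(index))) {
    pid <- index$participant[r]
    samples <- stage("read", pid,
      read_pupil_samples(file.path(base, index$samples[r]), config,
                         participant = pid))
    press_path <- if ("presses" %in% names(index))
      file.path(base, index$presses[r]) else NULL
    events <- stage("read", pid,
      read_event_log(file.path(base, index$events[r]), press_path, config))
    for (eye in names(samples)) {
      pre <- stage("preprocess", pid, preprocess_samples(samples[[eye]],
                                                         config))
      if (nrow(pre$blinks))
        blink_rows <- rbind(blink_rows,
                            cbind(participant = pid,
                                  session = index$session[r], eye = eye,
                                  pre$blinks))
      ep <- stage("epoch", pid, extract_epochs(pre$series, events, config))
      all_epochs[[length(all_epochs) + 1L]] <- ep
    }
    ml <- stage("movement", pid, movement_latencies(events))
    movement_rows <- rbind(movement_rows, cbind(participant = pid,
                                                ml$trials))
  }
  epochs <- bind_epochs(all_epochs)
  out <- analyse_epochs(epochs, config)
  out$movement <- movement_rows
  out$blinks <- blink_rows
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  wr(out$condition_means, "condition_means.csv")
  wr(out$latency, "latency.csv")
  wr(movement_rows, "movement_latency.csv")
  wr(out$phase_summary, "phase_summary.csv")
  wr(out$anova, "anova.csv")
  wr(out$simple_effects, "simple_effects.csv")
  if (!is.null(out$posthoc)) wr(as.data.frame(out$posthoc), "posthoc.csv")
  wr(blink_rows, "blink_report.csv")

  cfg_path <- file.path(out_dir, "config_used.txt")
  write_key_value(unclass(config), cfg_path)
  writeLines(c(paste0("config_md5: ", unname(tools::md5sum(cfg_path))),
               paste0("rng_seed: ", config$rng_seed)),
             file.path(out_dir, "provenance.txt"))
  invisible(out)
}

#' Condition averages, latencies and statistics from an epoch collection
#'
#' The analysis half of the pipeline, shared by [run_pipeline()] and
#' [process_study()]: per-duration and duration-pooled condition averages,
#' onset latency per participant x eye (on the pooled average trace),
#' phase summaries, the within-subject phase x eye x duration ANOVA per
#' drug with pooled-error simple effects of eye within each phase, and the
#' one-way latency comparison across eye/drug groups with Ryan's post-hoc
#' (when at least two groups yield estimable latencies).
#'
#' @param epochs a `pupil_epochs` collection.
#' @param config a [pupil_config()].
#' @return list with `condition_means`, `averages` (per-duration
#'   `condition_average` objects), `pooled` (duration-pooled),
#'   `latency`, `phase_summary`, `anova`, `simple_effects`, `posthoc`.
#' @export
analyse_epochs <- function(epochs, config = pupil_config()) {
  by_dur <- average_epochs(epochs,
                           by = c("participant", "eye", "drug", "duration"))
  pooled <- average_epochs(epochs, by = c("participant", "eye", "drug"))

  cm <- do.call(rbind, lapply(by_dur, function(a)
    cbind(as.data.frame(a$meta),
          data.frame(rel_time = a$rel_time, mean = a$mean, n = a$n))))

  lat <- do.call(rbind, lapply(pooled, function(a) {
    lr <- estimate_latency(a, config)
    cbind(as.data.frame(a$meta),
          data.frame(latency = lr$latency, peak_time = lr$peak_time,
                     peak_value = lr$peak_value, status = lr$status,
                     failure_reason = lr$failure_reason))
  }))

  ptab <- phase_table(by_dur, config)
  long <- phase_long(ptab)

  anova_rows <- NULL
  se_rows <- NULL
  for (dg in unique(long$drug)) {
    sub <- long[long$drug == dg & !is.na(long$value), , drop = FALSE]
    fit <- tryCatch(
      rm_anova(sub, "value", "participant", c("phase", "eye", "duration")),
      error = function(e) NULL)
    if (is.null(fit)) next
    anova_rows <- rbind(anova_rows, cbind(drug = dg, fit$effects))
    se <- simple_effects(fit, "eye", at = list(phase = c("early", "late")))
    se_rows <- rbind(se_rows, cbind(drug = dg, se))
  }

  post <- NULL
  est <- lat[lat$status == "estimated", , drop = FALSE]
  groups <- split(est$latency, paste(est$drug, est$eye, sep = ":"))
  if (length(groups) >= 2 && sum(lengths(groups)) > length(groups))
    post <- tryCatch(ryan_test(groups, alpha = config$alpha),
                     warning = function(w) NULL,
                     error = function(e) NULL)

  list(condition_means = cm, averages = by_dur, pooled = pooled,
       latency = lat, phase_summary = ptab, anova = anova_rows,
       simple_effects = se_rows, posthoc = post)
}

#' Run the pipeline on an in-memory simulated study
#'
#' Identical analysis to [run_pipeline()] but consuming a `pupil_study`
#' object directly (no file round-trip), which keeps simulation-heavy
#' validation runs fast.
#'
#' @param study a `pupil_study` from [simulate_study()].
#' @param config a [pupil_config()].
#' @return the [analyse_epochs()] result list, plus `movement` (per-trial
#'   button-press latencies) and `blinks` (detected blink report).
#' @export
process_study <- function(study, config = pupil_config()) {
  all_epochs <- list()
  blink_rows <- NULL
  movement_rows <- NULL
  for (p in study$participants) {
    for (sname in names(p$sessions)) {
      ses <- p$sessions[[sname]]
      events <- list(trials = ses$events, presses = ses$presses)
      for (eye in c("treated", "control")) {
        blk <- ses$samples[ses$samples$eye == eye, , drop = FALSE]
        sam <- structure(
          data.frame(time = blk$time, area = blk$area, valid = blk$valid),
          participant = p$id, eye = eye, fs = config$fs,
          class = c("pupil_samples", "data.frame"))
        pre <- preprocess_samples(sam, config)
        if (nrow(pre$blinks))
          blink_rows <- rbind(blink_rows,
                              cbind(participant = p$id, session = sname,
                                    eye = eye, pre$blinks))
        all_epochs[[length(all_epochs) + 1L]] <-
          extract_epochs(pre$series, events, config)
      }
      ml <- movement_latencies(events)
      movement_rows <- rbind(movement_rows,
                             cbind(participant = p$id, ml$trials))
    }
  }
  out <- analyse_epochs(bind_epochs(all_epochs), config)
  out$movement <- movement_rows
  out$blinks <- blink_rows
  out
}

#' Read an epoch store written by [write_epoch_store()]
#'
#' Reconstructs the `pupil_epochs` collection from the long-format CSV so
#' downstream stages (averaging, latency, statistics) can run file-based.
#'
#' @param path epoch-store CSV path.
#' @param config a [pupil_config()] (supplies the sampling rate).
#' @return a `pupil_epochs` object (all stored epochs are usable by
#'   construction).
#' @export
read_epoch_store <- function(path, config = pupil_config()) {
  if (!file.exists(path)) stop("epoch store not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "eye", "drug", "session", "duration", "trial_id",
            "rel_time", "value", "missing")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("epoch store format error: missing column(s) ",
         paste(miss, collapse = ", "))
  fs <- config$fs
  pre_n <- round(-min(df$rel_time) * fs)
  key <- paste(df$participant, df$eye, df$drug, df$session, df$trial_id,
               sep = "\r")
  ord <- order(key, df$rel_time)
  df <- df[ord, ]
  key <- key[ord]
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  values <- lapply(idx, function(i) {
    v <- df$value[i]
    v[df$missing[i] > 0] <- NA_real_
    v
  })
  first <- vapply(idx, `[`, integer(1), 1)
  meta <- data.frame(participant = df$participant[first],
                     eye = df$eye[first], drug = df$drug[first],
                     session = df$session[first],
                     duration = df$duration[first],
                     trial_id = df$trial_id[first],
                     baseline = NA_real_, usable = TRUE, truncated = FALSE,
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  structure(list(fs = fs, pre_n = pre_n, values = unname(values),
                 meta = meta),
            class = "pupil_epochs")
}
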