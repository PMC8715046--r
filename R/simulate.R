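#' Simulator parameters
#'
#' Loads the versioned default parameter table shipped with the package and
#' applies a drug preset and any overrides.  The design constants (250 Hz
#' sampling, 10 trials per duration in {3, 6, 9} s per session, inter-trial
#' intervals uniform on 5-8 s) mirror the emulated experiment; the waveform
#' constants (a fast transient rising linearly from its onset latency to an
#' initial peak 0.88 s later, then relaxing toward a plateau fraction, plus
#' a sustained component from 1.48 s held until trial offset), blink,
#' hippus, noise and jitter levels are the simulator's own calibration.
#'
#' Presets act on the treated eye: `tropicamide` halves the fast amplitude,
#' delays its onset by 0.35 s, halves the sustained amplitude and enlarges
#' the baseline; `phenylephrine` removes the sustained component and
#' enlarges the baseline, leaving the fast transient untouched; `control`
#' leaves both eyes identical in expectation.
#'
#' @param preset `"control"`, `"tropicamide"` or `"phenylephrine"`.
#' @param file defaults table (a flat `key: value` file); the packaged
#'   `sim-defaults-v1.conf` unless overridden.
#' @param ... named overrides of individual parameters.
#' @return a `sim_params` list.
#' @export
sim_params <- function(preset = c("control", "tropicamide", "phenylephrine"),
                       file = NULL, ...) {
  preset <- match.arg(preset)
  if (is.null(file))
    file <- system.file("extdata", "sim-defaults-v1.conf",
                        package = "pupilphase", mustWork = TRUE)
  kv <- read_key_value(file)
  base <- kv[!grepl(".", names(kv), fixed = TRUE)]
  pick <- function(key, default) {
    k <- paste0(preset, ".", key)
    if (!is.null(kv[[k]])) kv[[k]] else default
  }
  p <- base
  p$preset <- preset
  p$baseline_treated <- pick("baseline", p$baseline_control)
  p$gamma_fast <- pick("gamma_fast", 1)
  p$delta_latency <- pick("delta_latency", 0)
  p$slow_scale <- pick("slow_scale", 1)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    p[names(dots)] <- dots
  }
  num <- c("fs", "n_participants", "sessions", "trials_per_duration",
           "fast_amp", "fast_rise", "slow_amp", "slow_tau", "blink_rate",
           "hippus_amp", "noise_sd_area", "rt_mean", "rt_sd")
  for (f in num)
    if (!is.numeric(p[[f]]) || any(p[[f]] < 0))
      stop("simulator parameter '", f, "' must be non-negative numeric")
  if (p$fs <= 0) stop("fs must be positive")
  if (p$fast_latency < 0 || p$slow_latency < 0)
    stop("component latencies must be non-negative")
  class(p) <- "sim_params"
  p
}

#' Deterministic evoked pupil waveform
#'
#' Closed-form two-component dilation (mm change from baseline) at relative
#' times `t` for a trial of the given duration.  The fast component is zero
#' before its onset latency, rises linearly to its amplitude at
#' `latency + rise` (so the 25/75%-of-peak chord lies exactly on the rise
#' and extrapolates to the true onset), then relaxes exponentially toward
#' `plateau_frac * amplitude`; the sustained component follows a saturating
#' exponential from its own onset.  Both decay exponentially to zero after
#' trial offset with time constant `offset_tau`.
#'
#' @param t numeric vector of times relative to cue onset, s.
#' @param duration trial duration, s.
#' @param fast_amp,fast_latency,fast_rise,fast_plateau_frac,fast_decay_tau
#'   fast-component amplitude (mm), onset (s), linear rise time (s),
#'   post-peak plateau fraction, post-peak relaxation tau (s).
#' @param slow_amp,slow_latency,slow_tau sustained-component amplitude (mm),
#'   onset (s), rise tau (s).
#' @param offset_tau post-offset return-to-baseline tau, s.
#' @return numeric vector of evoked dilation, mm.
#' @export
evoked_waveform <- function(t, duration,
                            fast_amp = 0.35, fast_latency = 0.6,
                            fast_rise = 0.88, fast_plateau_frac = 0.5,
                            fast_decay_tau = 0.8,
                            slow_amp = 0.30, slow_latency = 1.48,
                            slow_tau = 1.5, offset_tau = 1.0) {
  fast_on <- function(u) {   # fast component while the movement lasts
    peak <- fast_latency + fast_rise
    out <- numeric(length(u))
    ris <- u >= fast_latency & u < peak
    out[ris] <- fast_amp * (u[ris] - fast_latency) / fast_rise
    dec <- u >= peak
    out[dec] <- fast_amp * (fast_plateau_frac + (1 - fast_plateau_frac) *
                              exp(-(u[dec] - peak) / fast_decay_tau))
    out
  }
  slow_on <- function(u) {
    out <- numeric(length(u))
    on <- u >= slow_latency
    out[on] <- slow_amp * (1 - exp(-(u[on] - slow_latency) / slow_tau))
    out
  }
  y <- numeric(length(t))
  during <- t >= 0 & t < duration
  y[during] <- fast_on(t[during]) + slow_on(t[during])
  after <- t >= duration
  if (any(after)) {
    end_val <- fast_on(duration) + slow_on(duration)
    y[after] <- end_val * exp(-(t[after] - duration) / offset_tau)
  }
  y
}

# truncated-at-zero normal draws
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate one recording session (both eyes)
#'
#' Generates the continuous area time series at `fs` for one participant
#' and session: per-trial evoked dilation on top of the eye's baseline,
#' slow hippus oscillation, binocular blinks as brief multiplicative area
#' collapses with sharp edges, additive Gaussian sensor noise on the area,
#' and button presses with normally distributed (truncated at zero)
#' reaction times.  Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param params a [sim_params()].
#' @param eye_params named list `treated`/`control`, each with `baseline`,
#'   `fast_amp`, `fast_latency`, `slow_amp`, `hippus_phase` (as drawn by
#'   [simulate_study()]); defaults to the noiseless preset values.
#' @param session session label.
#' @param participant participant label.
#' @param trials_per_duration trial count per duration (defaults from
#'   `params`; the short pre-instillation session uses fewer).
#' @param drug drug label written to the event table.
#' @return list with `samples` (data frame `time`, `eye`, `area`, `valid`),
#'   `events` (trial table), `presses`, and `truth` (trial onsets, blink
#'   intervals, reaction times, per-eye waveform parameters).
#' @export
simulate_session <- function(params, eye_params = NULL, session = "1",
                             participant = "P01",
                             trials_per_duration = NULL,
                             drug = params$preset) {
  fs <- params$fs
  if (is.null(trials_per_duration))
    trials_per_duration <- params$trials_per_duration
  if (is.null(eye_params))
    eye_params <- default_eye_params(params)

  dur <- sample(rep(params$durations, each = trials_per_duration))
  n_tr <- length(dur)
  iti <- stats::runif(n_tr, params$iti_range[1], params$iti_range[2])
  onset <- numeric(n_tr)
  onset[1] <- params$lead_in
  for (i in seq_len(n_tr - 1))
    onset[i + 1] <- onset[i] + dur[i] + iti[i]
  total <- onset[n_tr] + dur[n_tr] + params$tail
  nsamp <- floor(total * fs) + 1L
  t <- (seq_len(nsamp) - 1L) / fs

  # binocular blink process: Poisson count, uniform onsets, minimum gap
  n_b <- stats::rpois(1, params$blink_rate * total)
  b_on <- sort(stats::runif(n_b, 1, total - 1))
  b_dur <- stats::runif(n_b, params$blink_dur_range[1],
                        params$blink_dur_range[2])
  keep <- rep(TRUE, n_b)
  last_off <- -Inf
  for (i in seq_len(n_b)) {
    if (b_on[i] - last_off < params$blink_gap_min) { keep[i] <- FALSE; next }
    last_off <- b_on[i] + b_dur[i]
  }
  blinks <- data.frame(onset = b_on[keep], offset = (b_on + b_dur)[keep])

  idx_range <- function(a, b) {   # grid indices with t = (i-1)/fs in [a, b)
    lo <- max(1L, as.integer(ceiling(a * fs + 1 - 1e-9)))
    hi <- min(nsamp, as.integer(ceiling(b * fs + 1 - 1e-9)) - 1L)
    if (hi < lo) integer(0) else lo:hi
  }

  collapse <- rep(1, nsamp)
  for (i in seq_len(nrow(blinks)))
    collapse[idx_range(blinks$onset[i], blinks$offset[i])] <-
      params$blink_collapse

  sample_blocks <- lapply(c("treated", "control"), function(eye) {
    ep <- eye_params[[eye]]
    d <- rep(ep$baseline, nsamp)
    for (i in seq_len(n_tr)) {
      # the waveform is < 1e-13 of its end value past 30 offset taus
      rng <- idx_range(onset[i], onset[i] + dur[i] + 30 * params$offset_tau)
      d[rng] <- d[rng] + evoked_waveform(
        t[rng] - onset[i], dur[i],
        fast_amp = ep$fast_amp, fast_latency = ep$fast_latency,
        fast_rise = params$fast_rise,
        fast_plateau_frac = params$fast_plateau_frac,
        fast_decay_tau = params$fast_decay_tau,
        slow_amp = ep$slow_amp, slow_latency = params$slow_latency,
        slow_tau = params$slow_tau, offset_tau = params$offset_tau)
    }
    if (params$hippus_amp > 0)
      d <- d + params$hippus_amp *
        sin(2 * pi * params$hippus_freq * t + ep$hippus_phase)
    area <- diameter_to_area(d) * collapse
    if (params$noise_sd_area > 0)
      area <- area + stats::rnorm(nsamp, 0, params$noise_sd_area)
    data.frame(time = t, eye = eye, area = pmax(area, 0), valid = TRUE)
  })
  samples <- do.call(rbind, sample_blocks)

  rt <- rnorm_pos(n_tr, params$rt_mean, params$rt_sd)
  press_list <- lapply(seq_len(n_tr), function(i) {
    if (onset[i] + rt[i] > onset[i] + dur[i]) return(NULL)
    times <- seq(onset[i] + rt[i], onset[i] + dur[i],
                 by = params$press_interval)
    data.frame(time = times,
               button = rep(c("a", "b"), length.out = length(times)))
  })
  presses <- do.call(rbind, press_list)
  if (is.null(presses))
    presses <- data.frame(time = numeric(0), button = character(0))

  events <- data.frame(trial_id = seq_len(n_tr), onset = onset,
                       duration = dur, session = session,
                       eye_treatment = "nondominant", drug = drug,
                       stringsAsFactors = FALSE)
  list(samples = samples, events = events, presses = presses,
       truth = list(participant = participant, session = session,
                    onsets = onset, durations = dur, blinks = blinks,
                    rt = rt, eye_params = eye_params))
}

default_eye_params <- function(params) {
  list(
    treated = list(
      baseline = params$baseline_treated,
      fast_amp = params$fast_amp * params$gamma_fast,
      fast_latency = params$fast_latency + params$delta_latency,
      slow_amp = params$slow_amp * params$slow_scale,
      hippus_phase = 0),
    control = list(
      baseline = params$baseline_control,
      fast_amp = params$fast_amp,
      fast_latency = params$fast_latency,
      slow_amp = params$slow_amp,
      hippus_phase = 0))
}

draw_eye_params <- function(params, pre = FALSE) {
  jit <- function(base) {
    list(
      baseline = base$baseline + stats::rnorm(1, 0, params$jitter_baseline_sd),
      fast_amp = base$fast_amp * exp(stats::rnorm(1, 0, params$jitter_amp_cv)),
      fast_latency = max(0, base$fast_latency +
                           stats::rnorm(1, 0, params$jitter_latency_sd)),
      slow_amp = base$slow_amp * exp(stats::rnorm(1, 0, params$jitter_amp_cv)),
      hippus_phase = stats::runif(1, 0, 2 * pi))
  }
  def <- default_eye_params(params)
  if (pre) {   # before instillation both eyes follow the control waveform
    def$treated$baseline <- params$baseline_pre_treated
    def$treated$fast_amp <- params$fast_amp
    def$treated$fast_latency <- params$fast_latency
    def$treated$slow_amp <- params$slow_amp
  }
  list(treated = jit(def$treated), control = jit(def$control))
}

#' Simulate a complete study
#'
#' Generates a full multi-participant dataset under the configured design
#' (participants x sessions x 30 trials), with per-participant, per-eye
#' parameter jitter (log-normal amplitude factors, normal latency and
#' baseline shifts) drawn once per participant and shared across that
#' participant's sessions.  Identical seeds give identical datasets.  When
#' `out_dir` is supplied the dataset is also written in the CSV dialect
#' [read_pupil_samples()]/[read_event_log()] ingest, together with an
#' `index.csv` and a ground-truth `manifest.txt` (flat key:value) recording
#' the seed, every drawn waveform parameter and every injected blink.
#'
#' @param params a [sim_params()].
#' @param seed integer RNG seed.
#' @param out_dir optional output directory (created if needed).
#' @param presession add a short (6 trials per duration) session labelled
#'   `"pre"` in which the treated eye is not yet under the drug.
#' @return a `pupil_study`: list with `params`, `seed`, and `participants`,
#'   each participant holding drawn `eye_params` and a list of sessions from
#'   [simulate_session()]; `dir` when written to disk.
#' @export
simulate_study <- function(params = sim_params(), seed = 1, out_dir = NULL,
                           presession = FALSE) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(params$n_participants))
  participants <- list()
  for (pid in ids) {
    ep <- draw_eye_params(params)
    sessions <- list()
    if (presession) {
      ep_pre <- draw_eye_params(params, pre = TRUE)
      sessions[["pre"]] <- simulate_session(
        params, ep_pre, session = "pre", participant = pid,
        trials_per_duration = 6, drug = params$preset)
    }
    for (s in seq_len(params$sessions)) {
      lab <- as.character(s)
      sessions[[lab]] <- simulate_session(
        params, ep, session = lab, participant = pid, drug = params$preset)
    }
    participants[[pid]] <- list(id = pid, eye_params = ep,
                                sessions = sessions)
  }
  study <- structure(list(params = params, seed = seed,
                          participants = participants),
                     class = "pupil_study")
  if (!is.null(out_dir)) {
    write_study(study, out_dir)
    study$dir <- out_dir
  }
  study
}

#' @export
print.pupil_study <- function(x, ...) {
  n_sess <- length(x$participants[[1]]$sessions)
  cat(sprintf("<pupil_study> preset '%s': %d participants x %d sessions, seed %d\n",
              x$params$preset, length(x$participants), n_sess, x$seed))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' One samples/events/presses CSV trio per participant-session, an
#' `index.csv` tying them together, and a `manifest.txt` with every drawn
#' ground-truth value (waveform parameters per eye, blink intervals,
#' reaction times).
#'
#' @param study a `pupil_study`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("output directory not writable: ", out_dir)
  index <- NULL
  manifest <- list(seed = study$seed, preset = study$params$preset)
  fnum <- function(x) format(x, digits = 15)
  for (p in study$participants) {
    for (eye in c("treated", "control"))
      for (f in names(p$eye_params[[eye]]))
        manifest[[paste(p$id, eye, f, sep = ".")]] <-
          p$eye_params[[eye]][[f]]
    for (s in names(p$sessions)) {
      ses <- p$sessions[[s]]
      stem <- paste0(p$id, "_s", s)
      sf <- paste0(stem, "_samples.csv")
      ef <- paste0(stem, "_events.csv")
      pf <- paste0(stem, "_presses.csv")
      utils::write.csv(ses$samples, file.path(out_dir, sf),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(ses$events, file.path(out_dir, ef),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(ses$presses, file.path(out_dir, pf),
                       row.names = FALSE, quote = FALSE)
      index <- rbind(index, data.frame(
        participant = p$id, session = s, drug = study$params$preset,
        samples = sf, events = ef, presses = pf, stringsAsFactors = FALSE))
      b <- ses$truth$blinks
      manifest[[paste(p$id, s, "blinks", sep = ".")]] <-
        paste(paste0(fnum(b$onset), "/", fnum(b$offset)), collapse = ";")
      manifest[[paste(p$id, s, "rt", sep = ".")]] <-
        paste(fnum(ses$truth$rt), collapse = ";")
      manifest[[paste(p$id, s, "onsets", sep = ".")]] <-
        paste(fnum(ses$truth$onsets), collapse = ";")
    }
  }
  utils::write.csv(index, file.path(out_dir, "index.csv"),
                   row.names = FALSE, quote = FALSE)
  man_chr <- vapply(manifest, function(v)
    paste(as.character(v), collapse = ","), character(1))
  writeLines(paste0(names(manifest), ": ", man_chr),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
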