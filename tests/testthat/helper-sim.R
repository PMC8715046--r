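# shared fixtures, built in code

make_series <- function(diameter, fs = 250, missing = NULL, t0 = 0,
                        participant = "P01", eye = "control") {
  n <- length(diameter)
  if (is.null(missing)) missing <- rep(FALSE, n)
  structure(data.frame(time = t0 + (seq_len(n) - 1) / fs,
                       diameter = ifelse(missing, NA_real_, diameter),
                       missing = missing),
            fs = fs, participant = participant, eye = eye,
            class = c("diameter_series", "data.frame"))
}

make_trials <- function(onsets, durations, session = "1",
                        drug = "control") {
  list(trials = data.frame(trial_id = seq_along(onsets), onset = onsets,
                           duration = durations, session = session,
                           eye_treatment = "nondominant", drug = drug,
                           offset = onsets + durations,
                           nonstandard = FALSE,
                           stringsAsFactors = FALSE),
       presses = data.frame(time = numeric(0), button = character(0)))
}

# deterministic simulator parameters: no noise, no hippus, no blinks,
# no inter-individual jitter
clean_params <- function(preset = "control", ...) {
  sim_params(preset, noise_sd_area = 0, hippus_amp = 0, blink_rate = 0,
             jitter_amp_cv = 0, jitter_latency_sd = 0,
             jitter_baseline_sd = 0, ...)
}

# one eye of a simulated session as a pupil_samples object
eye_samples <- function(session, eye, participant = "P01", fs = 250) {
  blk <- session$samples[session$samples$eye == eye, , drop = FALSE]
  structure(data.frame(time = blk$time, area = blk$area, valid = blk$valid),
            participant = participant, eye = eye, fs = fs,
            class = c("pupil_samples", "data.frame"))
}

# interval-overlap matching of detected vs injected blinks
blink_match <- function(detected, truth) {
  if (nrow(truth) == 0)
    return(c(tp = 0, fn = 0, fp = nrow(detected)))
  hit_true <- vapply(seq_len(nrow(truth)), function(i)
    any(detected$onset <= truth$offset[i] &
          detected$offset >= truth$onset[i]), logical(1))
  hit_det <- vapply(seq_len(nrow(detected)), function(i)
    any(truth$onset <= detected$offset[i] &
          truth$offset >= detected$onset[i]), logical(1))
  c(tp = sum(hit_true), fn = sum(!hit_true), fp = sum(!hit_det))
}
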