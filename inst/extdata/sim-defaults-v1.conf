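# pupilphase simulator defaults, table version 1
# design constants (sampling, trial counts, durations, ITI) follow the
# emulated experiment; waveform/noise values are simulator choices.
version: 1
fs: 250
n_participants: 14
sessions: 3
trials_per_duration: 10
durations: 3,6,9
iti_range: 5,8
lead_in: 5
tail: 2.5
baseline_control: 4.7
baseline_pre_treated: 4.5
fast_amp: 0.35
fast_latency: 0.6
fast_rise: 0.88
fast_plateau_frac: 0.5
fast_decay_tau: 0.8
offset_tau: 1.0
slow_amp: 0.30
slow_latency: 1.48
slow_tau: 1.5
blink_rate: 0.15
blink_gap_min: 0.6
blink_dur_range: 0.08,0.18
blink_collapse: 0.02
hippus_amp: 0.03
hippus_freq: 0.2
noise_sd_area: 0.3
rt_mean: 0.56
rt_sd: 0.09
press_interval: 0.3
jitter_amp_cv: 0.15
jitter_latency_sd: 0.08
jitter_baseline_sd: 0.3
control.baseline: 4.7
control.gamma_fast: 1.0
control.delta_latency: 0.0
control.slow_scale: 1.0
tropicamide.baseline: 7.0
tropicamide.gamma_fast: 0.5
tropicamide.delta_latency: 0.35
tropicamide.slow_scale: 0.5
phenylephrine.baseline: 6.4
phenylephrine.gamma_fast: 1.0
phenylephrine.delta_latency: 0.0
phenylephrine.slow_scale: 0.0
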