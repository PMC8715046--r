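test_that("null components give a constant trace at baseline", {
  p <- clean_params(fast_amp = 0, slow_amp = 0)
  set.seed(61)
  ses <- simulate_session(p, trials_per_duration = 1)
  for (eye in c("treated", "control")) {
    a <- ses$samples$area[ses$samples$eye == eye]
    b <- if (eye == "treated") p$baseline_treated else p$baseline_control
    expect_equal(a, rep(diameter_to_area(b), length(a)), tolerance = 1e-12)
  }
})

test_that("the evoked waveform has the advertised geometry", {
  t <- seq(-1, 10, by = 0.004)
  y <- evoked_waveform(t, duration = 9)
  expect_true(all(y[t < 0.6] == 0))                      # silent before onset
  expect_equal(y[t == 1.48], 0.35, tolerance = 1e-9)     # ramp peak = A_f
  # linear on the rise: second differences vanish
  ris <- t > 0.62 & t < 1.46
  expect_true(all(abs(diff(diff(y[ris]))) < 1e-12))
  # sustained component holds dilation up: level at 8 s above fast plateau
  expect_gt(y[t == 8], 0.35 * 0.5)
  # decays toward zero after offset
  expect_lt(y[length(y)], y[t == 9][1])
})

test_that("removing the sustained component suppresses the late phase only", {
  cfg <- pupil_config()
  t <- seq(-1, 10, by = 1 / 250)
  ctrl <- list(rel_time = t, mean = evoked_waveform(t, 9, slow_amp = 0.30))
  phe <- list(rel_time = t, mean = evoked_waveform(t, 9, slow_amp = 0))
  pm_c <- phase_means(ctrl, duration = 9, cfg)
  pm_p <- phase_means(phe, duration = 9, cfg)
  expect_equal(pm_c$early_mean, pm_p$early_mean, tolerance = 1e-12)
  expect_lt(pm_p$late_mean, pm_c$late_mean)
})

test_that("identical seeds give identical datasets, on disk and in memory", {
  p <- sim_params("control", n_participants = 2, sessions = 1,
                  trials_per_duration = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_study(p, seed = 99, out_dir = d1)
  s2 <- simulate_study(p, seed = 99, out_dir = d2)
  expect_equal(s1$participants, s2$participants, tolerance = 0)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  s3 <- simulate_study(p, seed = 100)
  expect_false(identical(s1$participants, s3$participants))
})

test_that("dataset bookkeeping: files, index and manifest blocks per participant", {
  p <- clean_params(n_participants = 2, sessions = 1)
  d <- withr::local_tempdir()
  simulate_study(p, seed = 5, out_dir = d)
  idx <- read.csv(file.path(d, "index.csv"))
  expect_equal(nrow(idx), 2)
  expect_true(all(file.exists(file.path(d, idx$samples))))
  expect_true(all(file.exists(file.path(d, idx$events))))
  man <- readLines(file.path(d, "manifest.txt"))
  expect_true(any(grepl("^P01\\.treated\\.fast_latency:", man)))
  expect_true(any(grepl("^P02\\.control\\.baseline:", man)))
  expect_true(any(grepl("^P01\\.1\\.onsets:", man)))
})

test_that("event timing respects the configured design", {
  p <- sim_params("control")
  set.seed(62)
  ses <- simulate_session(p)
  ev <- ses$events
  expect_equal(sort(unique(ev$duration)), c(3, 6, 9))
  expect_equal(as.vector(table(ev$duration)), rep(10, 3))
  gaps <- ev$onset[-1] - (ev$onset + ev$duration)[-nrow(ev)]
  expect_true(all(gaps >= 5 - 1e-9 & gaps <= 8 + 1e-9))
})

test_that("emitted area is non-negative and round-trips through the conversion", {
  p <- clean_params()
  set.seed(63)
  ses <- simulate_session(p, trials_per_duration = 1)
  expect_true(all(ses$samples$area >= 0))
  blk <- ses$samples[ses$samples$eye == "control", ]
  d <- area_to_diameter(blk$area)
  ep <- st <- NULL
  # reconstruct the generator's diameter: baseline + waveform sum
  tr <- ses$events
  truth <- rep(p$baseline_control, nrow(blk))
  for (i in seq_len(nrow(tr)))
    truth <- truth + evoked_waveform(
      blk$time - tr$onset[i], tr$duration[i],
      fast_amp = p$fast_amp, fast_latency = p$fast_latency,
      fast_rise = p$fast_rise, fast_plateau_frac = p$fast_plateau_frac,
      fast_decay_tau = p$fast_decay_tau, slow_amp = p$slow_amp,
      slow_latency = p$slow_latency, slow_tau = p$slow_tau,
      offset_tau = p$offset_tau)
  expect_lt(max(abs(d - truth)), 1e-9)
})

test_that("stronger fast-component attenuation monotonically lowers the early phase", {
  cfg <- pupil_config()
  early <- vapply(c(1, 0.8, 0.6, 0.4, 0.2), function(gam) {
    p <- sim_params("tropicamide", n_participants = 1, sessions = 1,
                    gamma_fast = gam, delta_latency = 0,
                    jitter_amp_cv = 0, jitter_latency_sd = 0,
                    jitter_baseline_sd = 0, trials_per_duration = 2)
    st <- simulate_study(p, seed = 64)
    res <- process_study(st, cfg)
    mean(res$phase_summary$early_mean[res$phase_summary$eye == "treated"])
  }, numeric(1))
  expect_true(all(diff(early) < 0))
})
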