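cfg <- pupil_config()

ramp_trace <- function(onset = 0.6, peak_t = 1.48, amp = 1, fs = 250,
                       span = c(-1, 3)) {
  t <- seq(span[1], span[2], by = 1 / fs)
  y <- pmin(pmax((t - onset) / (peak_t - onset), 0), 1) * amp
  list(rel_time = t, mean = y)
}

test_that("the 25/75 chord of a linear rise extrapolates to the exact onset", {
  lr <- estimate_latency(ramp_trace(), cfg)
  expect_equal(lr$status, "estimated")
  expect_equal(lr$latency, 0.6, tolerance = 1e-9)
  expect_equal(lr$peak_value, 1)
  # analytic two-point case: t25 = 0.8, t75 = 1.2 (slope 1.25/s) -> 0.6
  lr2 <- estimate_latency(ramp_trace(onset = 0.6, peak_t = 1.4), cfg)
  expect_equal(lr2$t25, 0.8, tolerance = 1e-9)
  expect_equal(lr2$t75, 1.2, tolerance = 1e-9)
  expect_equal(lr2$latency, 0.8 - 0.25 / 1.25, tolerance = 1e-9)
})

test_that("a logistic rise matches a dense-grid brute-force oracle", {
  P <- 0.8; m <- 1.0; s <- 0.15
  logi <- function(t) P / (1 + exp(-(t - m) / s))
  t <- seq(-1, 3, by = 1 / 250)
  est <- estimate_latency(list(rel_time = t, mean = logi(t)), cfg)

  # oracle: analytic crossings on a 10-kHz grid, same chord construction
  td <- seq(0, 3, by = 1e-4)
  yd <- logi(td)
  pk <- max(yd)
  xing <- function(thr) {
    j <- which(yd[-1] >= thr & yd[-length(yd)] < thr)[1]
    td[j] + (thr - yd[j]) / (yd[j + 1] - yd[j]) * 1e-4
  }
  t25 <- xing(0.25 * pk); t75 <- xing(0.75 * pk)
  oracle <- t25 - 0.25 * (t75 - t25) / 0.5
  expect_lt(abs(est$latency - oracle), 1 / 250)
})

test_that("latency is shift-equivariant and amplitude-invariant", {
  base <- ramp_trace(span = c(-1, 4))
  l0 <- estimate_latency(base, cfg)$latency
  shifted <- base
  shifted$mean <- c(rep(0, 50), base$mean[1:(length(base$mean) - 50)])
  expect_equal(estimate_latency(shifted, cfg)$latency, l0 + 50 / 250,
               tolerance = 1e-9)
  scaled <- base
  scaled$mean <- base$mean * 3.7
  expect_equal(estimate_latency(scaled, cfg)$latency, l0, tolerance = 1e-12)
})

test_that("degenerate traces fail with informative reasons", {
  t <- seq(-1, 3, by = 1 / 250)
  expect_equal(estimate_latency(list(rel_time = t, mean = rep(0, length(t))),
                                cfg)$failure_reason, "no apparent increase")
  expect_equal(estimate_latency(list(rel_time = t,
                                     mean = rep(NA_real_, length(t))),
                                cfg)$failure_reason,
               "trace fully missing in search window")
  # already above 25% of peak at the window start: no crossing exists
  high <- ifelse(t < 1, 0.6, 1)
  expect_equal(estimate_latency(list(rel_time = t, mean = high),
                                cfg)$failure_reason,
               "threshold crossing not found")
  # a peak buried in baseline noise is "no apparent increase"
  set.seed(5)
  noisy <- rnorm(length(t), 0, 0.2)
  expect_equal(estimate_latency(list(rel_time = t, mean = noisy),
                                cfg)$status, "failed")
})

test_that("the full pipeline recovers the generator onset on noiseless traces", {
  p <- clean_params()
  set.seed(31)
  ses <- simulate_session(p, trials_per_duration = 2)
  pre <- preprocess_samples(eye_samples(ses, "control"), cfg)
  ep <- extract_epochs(pre$series, list(trials = ses$events), cfg)
  lr <- estimate_latency(average_epochs(ep, by = "eye")[[1]], cfg)
  expect_equal(lr$status, "estimated")
  expect_lt(abs(lr$latency - p$fast_latency), 1 / 250)
})

test_that("latency error stays small under 10%-of-peak additive noise", {
  errs <- vapply(1:25, function(seed) {
    set.seed(seed)
    tr <- ramp_trace(amp = 0.35)
    peak <- max(tr$mean)
    noisy <- make_series(tr$mean + rnorm(length(tr$mean), 0, 0.1 * peak),
                         t0 = tr$rel_time[1])
    sm <- smooth_diameter(noisy, config = cfg)   # pipeline smoothing
    est <- estimate_latency(list(rel_time = tr$rel_time,
                                 mean = sm$diameter), cfg)
    abs(est$latency - 0.6)
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 0.05)
})

test_that("movement latency is the first press inside the trial window", {
  ev <- make_trials(10, 3)
  ev$presses <- data.frame(time = c(9.5, 10.55, 10.9),
                           button = c("a", "a", "b"))
  ml <- movement_latencies(ev)
  expect_equal(ml$trials$latency[1], 0.55)
  expect_equal(ml$trials$n_press[1], 2)    # pre-onset press ignored

  ev2 <- make_trials(c(10, 20), c(3, 3))
  ev2$presses <- data.frame(time = 10.5, button = "a")
  ml2 <- movement_latencies(ev2)
  expect_true(is.na(ml2$trials$latency[2]))
  expect_equal(ml2$summary$n, 1)           # missing trial excluded
})

test_that("simulated reaction times are recovered exactly and match their target", {
  p <- clean_params()
  set.seed(77)
  lat <- unlist(lapply(1:5, function(i) {
    ses <- simulate_session(p)   # 30 trials each
    ml <- movement_latencies(list(trials = ses$events,
                                  presses = ses$presses))
    expect_equal(ml$trials$latency, ses$truth$rt, tolerance = 1e-9)
    ml$trials$latency
  }))
  expect_equal(length(lat), 150)
  expect_lt(abs(mean(lat) - 0.56), 0.02)
})
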