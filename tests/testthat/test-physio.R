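test_that("zero-phase band-pass attenuates drift, preserves passband, is symmetric", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  drift <- sin(2 * pi * 0.001 * t)
  out <- bandpass_zero_phase(drift, fs, 1, 100)
  expect_lt(max(abs(out[5000:15000])), 0.1 * max(abs(drift)))
  tone <- sin(2 * pi * 10 * t)
  out10 <- bandpass_zero_phase(tone, fs, 1, 100)
  mid <- 5000:15000
  expect_equal(max(abs(out10[mid])), 1, tolerance = 0.05)
  ## zero phase: cross-correlation peak at lag 0
  cc <- ccf(out10[mid], tone[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  ## impulse response of forward-backward filtering is symmetric in time
  x <- numeric(4001); x[2001] <- 1
  ir <- bandpass_zero_phase(x, fs, 1, 100)
  expect_lt(max(abs(ir[2001 + 1:500] - ir[2001 - 1:500])), 1e-6)
  expect_error(bandpass_zero_phase(tone, fs, 1, 600), "Nyquist")
})

test_that("R-peak detection finds planted beats exactly and is scale invariant", {
  set.seed(41)
  fs <- 1000
  beat_truth <- cumsum(c(1, rnorm(120, 0.8, 0.05)))
  n_s <- ceiling(max(beat_truth) * fs) + 500
  ecg <- rnorm(n_s, 0, 0.01)
  tpl <- exp(-((-30:30) / 8)^2 / 2)
  for (b in round(beat_truth * fs)) ecg[(b - 30):(b + 30)] <-
      ecg[(b - 30):(b + 30)] + tpl
  found <- detect_r_peaks(ecg, fs)
  expect_equal(length(found), length(beat_truth))
  expect_lt(max(abs(found - beat_truth)), 0.002)
  ## scale invariance of the quantile-calibrated threshold
  found2 <- detect_r_peaks(2 * ecg, fs)
  expect_equal(found, found2)
  ## flat zero signal: quality error
  expect_error(detect_r_peaks(rep(0, 60000), fs), "quality")
})

test_that("IBI computation and the 30% artifact rule match fixtures", {
  ib <- compute_ibis(c(0, 0.8, 1.6, 2.4))
  expect_equal(ib$ibis, c(800, 800, 800))
  ## 1200 after 800 is a 50% jump: flagged and spline-replaced near 800
  s <- correct_ibis(c(800, 800, 1200, 800, 800))
  expect_equal(s$artifact_flags, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_lt(abs(s$ibis[3] - 800), 20)
  ## a 25% change is kept
  s2 <- correct_ibis(c(800, 1000, 1000, 1000, 1000))
  expect_false(any(s2$artifact_flags))
  expect_equal(s2$ibis, c(800, 1000, 1000, 1000, 1000))
  ## constant series unchanged
  s3 <- correct_ibis(rep(750, 10))
  expect_equal(s3$ibis, rep(750, 10))
  ## flagging is sequential against the last accepted value
  s4 <- suppressWarnings(correct_ibis(c(800, 1200, 1150, 820, 800)))
  expect_true(s4$artifact_flags[2] && s4$artifact_flags[3])
  expect_error(correct_ibis(c(800, 800)), "at least 4")
})

test_that("iHR conversion is 60000 / IBI", {
  expect_equal(ibi_to_ihr(800), 75)
  expect_equal(ibi_to_ihr(1000), 60)
  expect_equal(ibi_to_ihr(600), 100)
  expect_error(ibi_to_ihr(c(800, -1)), "nonpositive")
})

test_that("iHR epoching: constant input is flat, baseline is zeroed pre-filter", {
  beats <- seq(0, 120, by = 0.8)
  ibi <- compute_ibis(beats)
  ev <- data.frame(trial_index = 1:3, onset_time_s = c(20, 50, 80))
  ep <- epoch_ihr(ibi, ev)
  expect_equal(dim(ep$values), c(3, 141))
  expect_lt(max(abs(ep$values)), 0.2)       # constant 75 bpm -> ~0 everywhere
  bsel <- ep$time >= -2 & ep$time <= -1
  expect_lt(max(abs(rowMeans(ep$values_prefilter[, bsel]))), 1e-9)
  ## out-of-bounds trials dropped with a log entry
  ev2 <- rbind(ev, data.frame(trial_index = 4, onset_time_s = 119))
  ep2 <- epoch_ihr(ibi, ev2)
  expect_equal(ep2$dropped, 4)
})

test_that("a planted cardiac deceleration is recovered in the epochs", {
  set.seed(42)
  pr <- participant_profile("P001", "GD")
  pr$hr_baseline <- 70
  pr$decel_kernel_gain <- c(predictable_threat = -5, unpredictable_threat = -5,
                            predictable_neutral = -5, unpredictable_neutral = -5)
  cfg <- study_config(n_blocks = 1, trials_per_block = 12)
  tr <- simulate_choices(pr, generate_trial_schedule(pr, cfg), cfg)
  ecg <- synthesize_ecg(pr, tr, cfg, trial_gain_sd = 0, hrv_sd = 0.3,
                        ibi_noise_sd = 0.003)
  filt <- bandpass_zero_phase(ecg$samples, ecg$fs, 1, 100)
  beats <- detect_r_peaks(filt, ecg$fs)
  ibi <- correct_ibis(compute_ibis(beats))
  ep <- epoch_ihr(ibi, ecg$event_markers)
  avg <- colMeans(ep$values)
  ## kernel peaks at +1.5 s with amplitude about -5 bpm; the closing-peak
  ## iHR assignment convention lags the true modulation by ~half an IBI
  expect_lt(abs(min(avg) - (-5)), 1.5)
  expect_lt(abs(ep$time[which.min(avg)] - 1.5), 0.55)
  ## null kernel: recovered change near zero at all lags
  pr$decel_kernel_gain[] <- 0
  ecg0 <- synthesize_ecg(pr, tr, cfg, trial_gain_sd = 0, hrv_sd = 0.3,
                         ibi_noise_sd = 0.003)
  f0 <- bandpass_zero_phase(ecg0$samples, ecg0$fs, 1, 100)
  ep0 <- epoch_ihr(correct_ibis(compute_ibis(detect_r_peaks(f0, ecg0$fs))),
                   ecg0$event_markers)
  expect_lt(max(abs(colMeans(ep0$values))), 1)
})

test_that("spectral interpolation removes 50 Hz while sparing neighbours", {
  set.seed(43)
  fs <- 2000
  t <- seq(0, 20, by = 1 / fs)
  x <- rnorm(length(t), 0, 1) + 3 * sin(2 * pi * 50 * t)
  y <- remove_line_noise(x, fs)
  bandpow <- function(sig, f0, hw = 0.4) {
    X <- Mod(fft(sig))^2
    fr <- (seq_along(sig) - 1) * fs / length(sig)
    mean(X[fr >= f0 - hw & fr <= f0 + hw])
  }
  expect_gt(10 * log10(bandpow(x, 50) / bandpow(y, 50)), 20)
  ## neighbouring band within 1 dB
  expect_lt(abs(10 * log10(bandpow(x, 46) / bandpow(y, 46))), 1)
  ## signal with no line component barely changes
  x2 <- rnorm(20000)
  y2 <- remove_line_noise(x2, fs)
  expect_lt(sd(y2 - x2) / sd(x2), 0.05)
})

test_that("EMG envelope is nonnegative and tracks burst plateaus", {
  set.seed(44)
  fs <- 2000
  x <- rnorm(3 * fs, 0, 0.1)
  ## 1 s high-variance burst with 100 ms tapered edges (muscle activity
  ## does not switch on instantaneously)
  ramp <- c(seq(0, 1, length.out = 200),
            rep(1, fs + 1 - 400),
            seq(1, 0, length.out = 200))
  x[fs:(2 * fs)] <- rnorm(fs + 1, 0, 0.1 + 1.9 * ramp)
  env <- emg_envelope(x, fs)
  expect_gt(min(env), -0.02 * max(env))     # ringing tolerance
  ## plateau near the mean rectified amplitude of N(0,2): 2*sqrt(2/pi)
  plateau <- mean(env[(1.3 * fs):(1.7 * fs)])
  expect_equal(plateau, 2 * sqrt(2 / pi), tolerance = 0.15)
  expect_equal(mean(emg_envelope(rep(0, fs), fs)), 0, tolerance = 1e-12)
})

test_that("burst detection applies threshold, merge and minimum-duration rules", {
  fs <- 1000
  base <- rep(0.1, 5000)
  mk_env <- function(spans) {
    env <- base + rnorm(5000, 0, 0.005)
    for (s in spans) env[s] <- 1
    env
  }
  ## single burst spanning the response time
  env <- mk_env(list(2480:2720))
  det <- detect_bursts(env, fs, stim_onset = 2, rt = 0.6)
  expect_equal(nrow(det$bursts), 1)
  expect_true(det$bursts$contains_rt[1])
  expect_equal(det$rt_burst, 1)
  expect_lt(abs(det$bursts$onset - 2.48), 0.01)
  ## two runs separated by 10 ms merge into one
  env2 <- mk_env(list(2480:2600, 2611:2720))
  det2 <- detect_bursts(env2, fs, stim_onset = 2, rt = 0.6)
  expect_equal(nrow(det2$bursts), 1)
  ## an isolated 20 ms run is discarded (minimum 25 ms)
  env3 <- mk_env(list(2500:2519))
  det3 <- detect_bursts(env3, fs, stim_onset = 2, rt = 0.6)
  expect_equal(nrow(det3$bursts), 0)
  expect_true(is.na(det3$rt_burst))
  expect_error(detect_bursts(env, fs, stim_onset = 2, rt = NA), "rt missing")
  expect_error(detect_bursts(env[1:100], fs, stim_onset = 2, rt = 0.6),
               "baseline|cover")
})

test_that("Tukey fences reject extreme peaks and respect affine invariance", {
  amps <- c(rep(1, 10), 10)
  keep <- reject_outlier_peaks(amps)
  expect_false(keep[11])
  expect_true(all(keep[1:10]))
  ## identical amplitudes: none rejected
  expect_true(all(reject_outlier_peaks(rep(3, 12))))
  ## affine rescaling leaves the mask unchanged
  set.seed(45)
  a <- rnorm(30)
  expect_equal(reject_outlier_peaks(a), reject_outlier_peaks(5 * a + 2))
})

test_that("within-participant z-scoring is definitional and idempotent", {
  set.seed(46)
  m <- matrix(rnorm(200, 5, 3), 10, 20)
  z <- zscore_within_participant(m)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(z)), 1, tolerance = 1e-12)
  expect_equal(zscore_within_participant(z), z, tolerance = 1e-10)
  ## two participants with identical shapes at different scales give the
  ## same z-pattern
  z2 <- zscore_within_participant(4 * m + 7)
  expect_equal(z, z2, tolerance = 1e-10)
  expect_error(zscore_within_participant(matrix(1, 5, 5)), "zero SD")
  expect_error(zscore_within_participant(m[1, , drop = FALSE]), "2 trials")
})

test_that("full EMG chain recovers planted bursts and the SR threat effect", {
  set.seed(47)
  pr <- participant_profile("P001", "SR")
  cfg <- study_config(n_blocks = 1, trials_per_block = 24)
  tr <- simulate_choices(pr, generate_trial_schedule(pr, cfg), cfg)
  emg <- synthesize_emg(pr, tr, cfg)
  chain <- function(ch) {
    x <- bandpass_zero_phase(ch$samples, ch$fs, 20, 500)
    x <- remove_line_noise(x, ch$fs)
    emg_envelope(x, ch$fs)
  }
  env_l <- chain(emg$emg_left); env_r <- chain(emg$emg_right)
  fs <- emg$emg_left$fs
  amps <- c(); types <- c()
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$rt[i]) || is.na(tr$choice[i])) next
    env <- if (tr$choice[i] == "left") env_l else env_r
    det <- detect_bursts(env, fs, emg$emg_left$event_markers$onset_time_s[i],
                         tr$rt[i])
    if (is.na(det$rt_burst)) next
    amps <- c(amps, det$bursts$peak_amplitude[det$rt_burst])
    types <- c(types, tr$trial_type[i])
  }
  expect_gt(length(amps), 0.8 * sum(!is.na(tr$rt)))
  ## SR profiles put extra amplitude on threat trials
  expect_gt(mean(amps[types == "threat"]), mean(amps[types == "neutral"]))
})
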