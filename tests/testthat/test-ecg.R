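test_that("band-pass filter matches the Butterworth magnitude response", {
  fs <- 512
  tt <- (0:(fs * 60 - 1)) / fs
  # zero in -> zero out
  zero <- ecg_bandpass(waveform_record(rep(0, fs * 10), fs))
  expect_true(all(abs(zero$samples) < 1e-12))
  # 0.05 Hz drift: deep in the high-pass stopband, > 90% attenuated
  slow <- ecg_bandpass(waveform_record(sin(2 * pi * 0.05 * tt), fs))
  mid <- seq(fs * 20, fs * 40)   # avoid edges
  expect_lt(max(abs(slow$samples[mid])), 0.1)
  # 10 Hz: passband, amplitude within 5%
  fast <- ecg_bandpass(waveform_record(sin(2 * pi * 10 * tt), fs))
  expect_equal(max(abs(fast$samples[mid])), 1, tolerance = 0.05)
})

test_that("band edge above Nyquist is rejected", {
  rec <- waveform_record(rnorm(1280), 128)
  expect_error(ecg_bandpass(rec, 0.5, 100), "Nyquist")
  expect_error(ecg_bandpass(rec, 50, 0.5), "low_hz")
})

test_that("segmentation tiles the record and drops the partial tail", {
  fs <- 4   # sampling rate is irrelevant to tiling; keep memory small
  long <- waveform_record(numeric(8.25 * 3600 * fs), fs)
  expect_length(segment_windows(long, 300), 99)
  expect_length(segment_windows(waveform_record(numeric(299 * fs), fs)), 0)
  two <- segment_windows(waveform_record(seq_len(600 * fs), fs))
  expect_length(two, 2)
  expect_equal(two[[1]]$samples, as.numeric(seq_len(300 * fs)))
  expect_equal(two[[2]]$start_time_s, 300)
})

test_that("round 1 returns above-mean local maxima (superset of R peaks)", {
  syn <- make_clean_ecg(1000)
  ch <- detect_chain(syn$record)
  expect_gte(length(ch$r1$peak_indices), 300)
  # every true R peak has a round-1 candidate within 1 sample
  truth <- syn$truth$beat_times_s
  truth <- truth[truth > 0.5]   # boundary beat at t=0 is half-truncated
  nearest <- vapply(truth, function(t)
    min(abs(ch$r1$peak_times_s - t)), numeric(1))
  expect_true(all(nearest <= 1 / 512))
  # flat window -> empty series
  flat <- waveform_record(rep(1, 1000), 512)
  expect_length(detect_peaks_round1(flat)$peak_indices, 0)
})

test_that("round 2 isolates R peaks on clean ECG with P/T waves", {
  syn <- make_clean_ecg(1000)
  ch <- detect_chain(syn$record)
  truth <- syn$truth$beat_times_s
  ev <- evaluate_peak_detection(ch$r2$peak_times_s, truth, tol_s = 0.02)
  expect_gte(ev$sensitivity, 0.995)
  expect_gte(ev$ppv, 0.995)
  expect_lte(ev$mean_abs_error_s, 1 / 512)
})

test_that("search-back restores an attenuated R peak", {
  # R-spike-only morphology so the mean round-1 peak amplitude is ~1:
  # an R attenuated to 40% then sits below theta = 0.5 but above
  # theta' = 0.3 and must come back via search-back
  syn <- make_clean_ecg(1000, duration_s = 300, p_amplitude = 0,
                        t_amplitude = 0)
  rec <- syn$record
  fs <- rec$sampling_rate_hz
  idx <- seq(round(149.9 * fs), round(150.1 * fs))
  peak_at <- idx[which.max(rec$samples[idx])]
  scale_region <- seq(peak_at - 15, peak_at + 15)
  rec$samples[scale_region] <- rec$samples[scale_region] * 0.40
  ch <- detect_chain(rec)
  expect_true(any(abs(ch$r2$peak_times_s - 150) < 0.02))
  expect_true(all(diff(ch$r2$peak_times_s) <= 1.2))
  # without search-back the peak stays lost
  no_sb <- detect_peaks_round2(ch$window, ch$r1, theta_prime = 1.1)
  expect_false(any(abs(no_sb$peak_times_s - 150) < 0.02))
})

test_that("refractory rule removes near-R noise spikes", {
  syn <- make_clean_ecg(1000, duration_s = 300)
  rec <- syn$record
  fs <- rec$sampling_rate_hz
  # add two spikes 100 ms after the R peaks at t = 50 and t = 120
  for (t0 in c(50.1, 120.1)) {
    i <- round(t0 * fs) + 1
    rec$samples[i] <- 0.9
  }
  ch <- detect_chain(rec)
  expect_false(any(abs(ch$r2$peak_times_s - 50.1) < 0.005))
  expect_false(any(abs(ch$r2$peak_times_s - 120.1) < 0.005))
  # the true R peaks survive
  expect_true(any(abs(ch$r2$peak_times_s - 50) < 0.005))
  expect_true(any(abs(ch$r2$peak_times_s - 120) < 0.005))
})

test_that("round 2 only ever keeps round-1 positions", {
  syn <- make_clean_ecg(800, seed = 7)
  ch <- detect_chain(syn$record)
  expect_true(all(ch$r2$peak_indices %in% ch$r1$peak_indices))
})

test_that("round 2 is idempotent on its own output", {
  syn <- make_clean_ecg(1000, seed = 8)
  ch <- detect_chain(syn$record)
  again <- detect_peaks_round2(ch$window, ch$r2)
  expect_identical(again$peak_indices, ch$r2$peak_indices)
})

test_that("detection is invariant to uniform amplitude scaling", {
  syn <- make_clean_ecg(900, seed = 9)
  ch1 <- detect_chain(syn$record)
  scaled <- waveform_record(syn$record$samples * 7.3, 512)
  ch2 <- detect_chain(scaled)
  expect_identical(ch2$r2$peak_indices, ch1$r2$peak_indices)
})

test_that("window validation applies the HR and RR-range rules", {
  syn <- make_clean_ecg(1000)
  ch <- detect_chain(syn$record)
  q <- validate_window(ch$window, ch$r2, round1 = ch$r1)
  expect_true(q$is_valid)
  expect_equal(q$fraction_rr_in_range, 1.0)
  expect_identical(q$reject_reason, "")
  expect_gte(q$n_removed, 0)

  # rhythm at 250 bpm -> HR out of range
  fs <- 512
  fast <- peak_series_for_test(seq(0, 299, by = 0.24), fs)
  qf <- validate_window(waveform_record(numeric(fs * 300), fs), fast)
  expect_false(qf$is_valid)
  expect_identical(qf$reject_reason, "HR out of range")

  # 30% of intervals stretched to 2000 ms -> below the 0.8 valid fraction
  # (800 ms base intervals keep the mean HR inside 50-200 bpm so the
  # fraction rule, not the HR rule, fires)
  tt <- cumsum(c(rep(0.8, 141), rep(2, 60)))
  qs <- validate_window(waveform_record(numeric(fs * 300), fs),
                        peak_series_for_test(tt, fs))
  expect_false(qs$is_valid)
  expect_identical(qs$reject_reason, "low valid RR fraction")
  expect_equal(qs$fraction_rr_in_range, 140 / 200, tolerance = 1e-9)

  # fewer than 2 peaks
  q1 <- validate_window(waveform_record(numeric(fs * 300), fs),
                        peak_series_for_test(1, fs))
  expect_false(q1$is_valid)
  expect_identical(q1$reject_reason, "insufficient peaks")
})

test_that("more artifact bursts never yield more valid windows", {
  n_valid <- vapply(c(0L, 2L, 4L), function(nb) {
    bursts <- if (nb > 0)
      lapply(seq_len(nb), function(k) c(120 + 300 * (k - 1), 40, 3))
    else list()
    spec <- ecg_spec(tachogram_spec(duration_s = 1500, jitter_sd_ms = 10,
                                    seed = 31),
                     artifact_bursts = bursts)
    syn <- synthesize_ecg(spec)
    filt <- ecg_bandpass(syn$record)
    sum(vapply(segment_windows(filt), function(w) {
      r2 <- detect_peaks_round2(w, detect_peaks_round1(w))
      validate_window(w, r2)$is_valid
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(n_valid) <= 0))
  expect_equal(n_valid[1], 5)   # clean record: all windows valid
})
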