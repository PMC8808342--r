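test_that("nn_from_peaks flags out-of-range intervals and breaks adjacency", {
  fs <- 512
  pk <- peak_series_for_test(0:3, fs)
  q <- validate_window(waveform_record(numeric(fs), fs), pk)
  nn <- nn_from_peaks(pk, q)
  expect_equal(nn$nn_ms, c(1000, 1000, 1000), tolerance = 1e-9)

  pk2 <- peak_series_for_test(c(0, 0.8, 2.6, 3.4), fs)
  nn2 <- nn_from_peaks(pk2, NULL)
  expect_equal(nn2$valid, c(TRUE, FALSE, TRUE))
  td <- hrv_time_domain(nn2)
  expect_equal(td$avnn_ms, 800, tolerance = 1e-6)
  expect_equal(td$n_nn, 2)
  expect_equal(td$n_pairs, 0)          # the invalid middle breaks adjacency
  expect_true(is.na(td$rmssd_ms))

  expect_error(nn_from_peaks(peak_series_for_test(1, fs), NULL),
               "at least 2")
})

test_that("time-domain parameters match the hand-worked example", {
  nn <- nn_from_values(c(800, 860, 870, 805))
  td <- hrv_time_domain(nn)
  expect_equal(td$avnn_ms, 833.75, tolerance = 1e-9)
  expect_equal(td$rmssd_ms, sqrt((60^2 + 10^2 + 65^2) / 3), tolerance = 1e-9)
  expect_equal(td$pnn50, 0.5, tolerance = 1e-12)
  expect_equal(td$sdnn_ms, sd(c(800, 860, 870, 805)), tolerance = 1e-12)

  const <- hrv_time_domain(nn_from_values(rep(1000, 300)))
  expect_equal(const$hr_bpm, 60, tolerance = 1e-9)
  expect_equal(const$rmssd_ms, 0)
  expect_equal(const$sdnn_ms, 0)
  expect_equal(const$pnn50, 0)

  two <- hrv_time_domain(nn_from_values(c(900, 1100)))
  expect_equal(two$avnn_ms, 1000, tolerance = 1e-9)
  expect_equal(two$hr_bpm, 60, tolerance = 1e-9)
})

test_that("time domain agrees with the brute-force oracle incl. validity", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:80, 1)
    vals <- runif(n, 350, 1150)
    valid <- if (i %% 2 == 0) runif(n) > 0.2 else rep(TRUE, n)
    if (!any(valid)) valid[1] <- TRUE
    nn <- nn_from_values(vals, valid = valid)
    td <- hrv_time_domain(nn)
    or <- td_oracle(nn$nn_ms, valid)
    expect_lt(rel_err(td$avnn_ms, or$avnn), 1e-9)
    if (!is.na(or$sdnn)) expect_lt(rel_err(td$sdnn_ms, or$sdnn), 1e-9)
    if (!is.na(or$rmssd)) expect_lt(rel_err(td$rmssd_ms, or$rmssd), 1e-9)
    expect_lt(abs(td$pnn50 - or$pnn50), 1e-12)
  }
})

test_that("RMSSD/SDNN are shift-invariant, AVNN shifts exactly", {
  set.seed(7)
  vals <- runif(60, 600, 1000)
  a <- hrv_time_domain(nn_from_values(vals))
  b <- hrv_time_domain(nn_from_values(vals + 150))
  expect_equal(b$rmssd_ms, a$rmssd_ms, tolerance = 1e-9)
  expect_equal(b$sdnn_ms, a$sdnn_ms, tolerance = 1e-9)
  expect_equal(b$avnn_ms, a$avnn_ms + 150, tolerance = 1e-9)
})

test_that("Lomb-Scargle periodogram matches an independent reference", {
  # frozen oracle: scipy.signal.lombscargle on this exact series
  t <- cumsum(0.8 + 0.1 * sin(2 * pi * 0.1 * (0:39)))
  y <- 800 + 60 * sin(2 * pi * 0.1 * t) + 10 * cos(2 * pi * 0.27 * t)
  p <- lomb_scargle(t, y, c(0.05, 0.1, 0.2, 0.27, 0.35))
  expected <- c(1634.01917245827, 34934.048322604765, 66.52690001748242,
                369.12442937695096, 32.21370599500306)
  expect_equal(p, expected, tolerance = 1e-10)
})

test_that("frequency domain recovers sinusoidal band power (A^2/2)", {
  lf <- generate_tachogram(tachogram_spec(duration_s = 300, lf_amp_ms = 50,
                                          lf_freq_hz = 0.1, seed = 1))
  fd <- hrv_frequency_domain(lf$nn)
  expect_gt(fd$lf_ms2 / (fd$lf_ms2 + fd$hf_ms2), 0.9)
  expect_equal(fd$lf_ms2, 1250, tolerance = 0.1)

  hf <- generate_tachogram(tachogram_spec(duration_s = 300, hf_amp_ms = 50,
                                          hf_freq_hz = 0.25, seed = 1))
  fdh <- hrv_frequency_domain(hf$nn)
  expect_gt(fdh$hf_ms2 / (fdh$lf_ms2 + fdh$hf_ms2), 0.9)
  expect_equal(fdh$hf_ms2, 1250, tolerance = 0.1)
})

test_that("frequency domain handles degenerate and short inputs", {
  const <- nn_from_values(rep(1000, 300))
  fd <- hrv_frequency_domain(const)
  expect_lt(fd$lf_ms2, 1e-6 * 1000^2)
  expect_lt(fd$hf_ms2, 1e-6 * 1000^2)
  expect_true(is.na(fd$lf_hf_ratio))   # undefined, not infinite
  expect_error(hrv_frequency_domain(nn_from_values(rep(1000, 10))),
               "valid NN")
})

test_that("wearable gate boundary is inclusive at 30%", {
  mk <- function(frac) {
    nn_from_values(rep(1000, 100),
                   valid = c(rep(TRUE, round(100 * frac)),
                             rep(FALSE, 100 - round(100 * frac))),
                   source = "wearable")
  }
  expect_false(gate_wearable_window(mk(0.29)))
  expect_true(gate_wearable_window(mk(0.30)))
  expect_true(gate_wearable_window(mk(1.0)))
})

test_that("hrv_windows gates wearable windows and fills HRV elsewhere", {
  g <- generate_tachogram(tachogram_spec(duration_s = 900,
                                         jitter_sd_ms = 20, seed = 13))
  valid <- rep(TRUE, length(g$nn$nn_ms))
  win_of <- floor(g$nn$beat_times_s[-length(g$nn$beat_times_s)] / 300)
  valid[win_of == 1][seq_len(round(0.8 * sum(win_of == 1)))] <- FALSE
  wearable <- nn_series(g$nn$beat_times_s, valid = valid,
                        source = "wearable")
  tab <- hrv_windows(wearable, gate_threshold = 0.30)
  expect_equal(nrow(tab), 3)
  expect_identical(tab$gated_out, c(FALSE, TRUE, FALSE))
  expect_true(is.na(tab$hr_bpm[2]))
  expect_false(anyNA(tab$hr_bpm[c(1, 3)]))
})

test_that("window HRV estimates recover ground truth on clean nights", {
  spec <- tachogram_spec(duration_s = 1200, lf_amp_ms = 40, hf_amp_ms = 30,
                         jitter_sd_ms = 5, seed = 17)
  syn <- synthesize_ecg(ecg_spec(spec))
  filt <- ecg_bandpass(syn$record)
  truth <- syn$truth$window_params
  wins <- segment_windows(filt)
  for (w in seq_along(wins)) {
    win <- wins[[w]]
    r2 <- detect_peaks_round2(win, detect_peaks_round1(win))
    q <- validate_window(win, r2)
    expect_true(q$is_valid)
    nn <- nn_from_peaks(r2, q)
    td <- hrv_time_domain(nn)
    expect_equal(td$rmssd_ms, truth$rmssd_ms[w], tolerance = 0.05)
    expect_equal(td$avnn_ms, truth$avnn_ms[w], tolerance = 0.01)
    fd <- hrv_frequency_domain(nn)
    # LF-dominant world: band ordering must be preserved
    expect_gt(fd$lf_ms2, fd$hf_ms2)
  }
})

test_that("nightly averages skip missing values per parameter", {
  w <- rbind(hrv_windows(nn_from_values(rep(1000, 60))),
             hrv_windows(nn_from_values(rep(860, 70))))
  w$gated_out <- FALSE
  w$lf_hf_ratio <- c(2.0, NA)
  w2 <- w; w2$lf_hf_ratio <- c(2.0, 4.0)
  avg <- nightly_average(w)
  expect_equal(avg$hr_bpm, mean(c(60000 / 1000, 60000 / 860)),
               tolerance = 1e-9)
  expect_equal(avg$lf_hf_ratio, 2.0)
  expect_equal(nightly_average(w2)$lf_hf_ratio, 3.0)
  expect_equal(avg$n_windows_used, 2)

  w$gated_out <- TRUE
  expect_error(nightly_average(w), "no usable")

  k <- rbind(w2[1, ], w2[1, ], w2[1, ])
  k$gated_out <- FALSE
  expect_equal(nightly_average(k)$hr_bpm, w2$hr_bpm[1], tolerance = 1e-12)
})
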