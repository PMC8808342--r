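# Brute-force time-domain HRV oracle: explicit loops, independent of the
# package implementation. Adjacency semantics: an invalid interval breaks
# both neighbouring successive-difference pairs.
td_oracle <- function(nn_ms, valid = rep(TRUE, length(nn_ms))) {
  v <- c()
  for (i in seq_along(nn_ms)) if (valid[i]) v <- c(v, nn_ms[i])
  n <- length(v)
  avnn <- sum(v) / n
  ss <- 0
  for (x in v) ss <- ss + (x - avnn)^2
  sdnn <- if (n > 1) sqrt(ss / (n - 1)) else NA_real_
  d <- c()
  for (i in seq_len(length(nn_ms) - 1)) {
    if (valid[i] && valid[i + 1]) d <- c(d, nn_ms[i + 1] - nn_ms[i])
  }
  sq <- 0; over50 <- 0
  for (x in d) {
    sq <- sq + x^2
    if (abs(x) > 50) over50 <- over50 + 1
  }
  list(avnn = avnn, sdnn = sdnn,
       rmssd = if (length(d)) sqrt(sq / length(d)) else NA_real_,
       pnn50 = over50 / n, hr = 60000 / avnn)
}

# nn_series from a vector of interval values (ms), beats starting at 0
nn_from_values <- function(nn_ms, valid = NULL, source = "ecg") {
  nn_series(c(0, cumsum(nn_ms) / 1000), valid = valid, source = source)
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

# clean constant-rate synthetic ECG window plus its in-record truth beats
make_clean_ecg <- function(mean_nn_ms, duration_s = 300, fs = 512,
                           seed = 1, ...) {
  spec <- ecg_spec(tachogram_spec(duration_s = duration_s,
                                  mean_nn_ms = mean_nn_ms, seed = seed),
                   sampling_rate_hz = fs, ...)
  synthesize_ecg(spec)
}

# detection chain on one window
detect_chain <- function(record, ...) {
  filt <- ecg_bandpass(record)
  w <- segment_windows(filt)[[1]]
  r1 <- detect_peaks_round1(w, window_id = 1)
  r2 <- detect_peaks_round2(w, r1, ...)
  list(window = w, r1 = r1, r2 = r2)
}

# minimal peak_series stand-in from explicit peak times
peak_series_for_test <- function(times_s, fs) {
  structure(list(peak_indices = as.integer(round(times_s * fs)) + 1L,
                 peak_times_s = as.numeric(times_s),
                 amplitudes = rep(1, length(times_s)),
                 sampling_rate_hz = fs, window_id = 1L),
            class = "peak_series")
}
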