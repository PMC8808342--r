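#' Construct a waveform record
#'
#' A uniformly sampled single-channel waveform with its sampling rate and
#' start time. NA samples are not allowed; gaps must be encoded as flat
#' segments by the reader.
#'
#' @param samples numeric amplitude vector.
#' @param sampling_rate_hz sampling rate in Hz (> 0).
#' @param start_time_s start time in seconds (default 0).
#' @return object of class \code{waveform_record}.
#' @export
waveform_record <- function(samples, sampling_rate_hz, start_time_s = 0) {
  if (sampling_rate_hz <= 0)
    stop("waveform_record: 'sampling_rate_hz' must be > 0", call. = FALSE)
  if (length(samples) < 1)
    stop("waveform_record: empty sample vector", call. = FALSE)
  if (anyNA(samples))
    stop("waveform_record: NA samples not allowed", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 start_time_s = start_time_s),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$start_time_s))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the squared magnitude response of an analog Butterworth band-pass
#' (the response realized by forward-backward filtering) in the frequency
#' domain, with reflection padding to suppress wrap-around transients. Zero
#' phase means R-peak latencies are preserved exactly.
#'
#' @param record a \code{\link{waveform_record}}.
#' @param low_hz,high_hz band edges in Hz; defaults 0.5 and 100.
#' @param order filter order (default 4).
#' @return a filtered \code{waveform_record} of the same length.
#' @export
ecg_bandpass <- function(record, low_hz = 0.5, high_hz = 100, order = 4) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$sampling_rate_hz
  if (!(0 < low_hz && low_hz < high_hz))
    stop("ecg_bandpass: need 0 < low_hz < high_hz", call. = FALSE)
  if (high_hz >= fs / 2)
    stop("ecg_bandpass: 'high_hz' (", high_hz,
         ") must be below the Nyquist frequency ", fs / 2, " Hz",
         call. = FALSE)
  x <- record$samples
  n <- length(x)
  pad <- min(n - 1L, as.integer(10 * fs))   # reflect ~10 s at each end
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  # zero-pad to a 2-3-5-smooth length: fft is O(n log n) only then
  np <- stats::nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, rep(0, np - length(xp)))
  f <- (seq_len(np) - 1) / np * fs
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  hp <- 1 / (1 + (low_hz / pmax(f, .Machine$double.eps))^(2 * order))
  lp <- 1 / (1 + (f / high_hz)^(2 * order))
  gain <- hp * lp                            # |H|^2: forward-backward pass
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / np
  waveform_record(y[pad + seq_len(n)], fs, record$start_time_s)
}

#' Segment a record into consecutive fixed-length windows
#'
#' Windows are aligned to the record start; a trailing partial window is
#' dropped. A record shorter than one window yields an empty list.
#'
#' @param record a \code{\link{waveform_record}}.
#' @param window_s window length in seconds (default 300, i.e. 5 minutes).
#' @return list of \code{waveform_record}s with \code{start_time_s} set.
#' @export
segment_windows <- function(record, window_s = 300) {
  stopifnot(inherits(record, "waveform_record"))
  if (window_s <= 0) stop("segment_windows: 'window_s' must be > 0",
                          call. = FALSE)
  fs <- record$sampling_rate_hz
  wlen <- round(window_s * fs)
  n_win <- floor(length(record$samples) / wlen)
  if (n_win == 0) return(list())
  lapply(seq_len(n_win) - 1L, function(w) {
    waveform_record(record$samples[w * wlen + seq_len(wlen)], fs,
                    start_time_s = record$start_time_s + w * window_s)
  })
}

# strict-rise local maxima (plateau resolved to its first sample)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

peak_series <- function(idx, record, window_id = NA) {
  structure(list(peak_indices = as.integer(idx),
                 peak_times_s = record$start_time_s +
                   (as.integer(idx) - 1) / record$sampling_rate_hz,
                 amplitudes = record$samples[idx],
                 sampling_rate_hz = record$sampling_rate_hz,
                 window_id = window_id),
            class = "peak_series")
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("<peak_series> %d peaks, window %s\n",
              length(x$peak_indices), as.character(x$window_id)))
  invisible(x)
}

#' First-round R-peak candidate detection
#'
#' Returns all strict local maxima whose amplitude exceeds the mean
#' amplitude of the window. By design this includes the true R peaks plus
#' possible P/T-wave and noise peaks; the second round prunes them.
#'
#' @param window a (filtered) \code{\link{waveform_record}}, typically one
#'   5-minute window.
#' @param window_id optional identifier attached to the result.
#' @return a \code{peak_series} (possibly empty for constant signals).
#' @export
detect_peaks_round1 <- function(window, window_id = NA) {
  stopifnot(inherits(window, "waveform_record"))
  x <- window$samples
  idx <- local_maxima(x)
  idx <- idx[x[idx] > mean(x)]
  peak_series(idx, window, window_id)
}

#' Second-round R-peak refinement
#'
#' Prunes and completes the first-round candidates using the mean candidate
#' amplitude and the normal 50-200 bpm heart-rate range: (i) peaks below
#' \code{theta} times the mean peak amplitude are removed (P/T/noise); the
#' mean is seeded from the round-1 candidates and then iterated over the
#' retained set, so the cut converges to a fraction of the R amplitude;
#' (ii) of any two retained peaks closer than the refractory period
#' (300 ms = 60/200 bpm) the larger is kept (tie: earlier); (iii) for any
#' remaining gap longer than \code{max_gap_s} (1.2 s = 60/50 bpm) the
#' largest round-1 peak inside the gap is re-admitted if it exceeds
#' \code{theta_prime} times the mean round-1 peak amplitude (search-back;
#' re-admissions are exempt from (i)). Steps (i)-(iii) repeat until a
#' fixed point.
#'
#' @param window the \code{\link{waveform_record}} the peaks refer to.
#' @param round1 a \code{peak_series} from \code{\link{detect_peaks_round1}}.
#' @param theta amplitude fraction for retention (default 0.5).
#' @param theta_prime amplitude fraction for search-back re-admission
#'   (default 0.3).
#' @param refractory_s minimum peak spacing in seconds (default 0.3).
#' @param max_gap_s gap length triggering search-back (default 1.2).
#' @return a refined \code{peak_series}; positions are always a subset of
#'   the round-1 positions.
#' @export
detect_peaks_round2 <- function(window, round1, theta = 0.5,
                                theta_prime = 0.3, refractory_s = 0.3,
                                max_gap_s = 1.2) {
  stopifnot(inherits(window, "waveform_record"),
            inherits(round1, "peak_series"))
  fs <- window$sampling_rate_hz
  cand_idx <- round1$peak_indices
  if (length(cand_idx) == 0) return(round1)
  amp <- window$samples[cand_idx]
  mean_amp <- mean(amp)

  keep <- cand_idx[amp >= theta * mean_amp]
  sb_admitted <- integer(0)   # search-back peaks are exempt from re-thresholding

  refractory_pass <- function(idx) {
    if (length(idx) < 2) return(idx)
    a <- window$samples[idx]
    kept <- idx[1]
    for (k in seq_along(idx)[-1]) {
      last <- kept[length(kept)]
      if ((idx[k] - last) / fs < refractory_s) {
        # keep the larger of the conflicting pair; tie keeps the earlier
        if (window$samples[idx[k]] > window$samples[last])
          kept[length(kept)] <- idx[k]
      } else {
        kept <- c(kept, idx[k])
      }
    }
    kept
  }

  searchback_pass <- function(idx, banned) {
    if (length(idx) < 2) return(idx)
    gaps <- which(diff(idx) / fs > max_gap_s)
    added <- integer(0)
    for (g in gaps) {
      inside <- cand_idx[cand_idx > idx[g] & cand_idx < idx[g + 1]]
      inside <- inside[window$samples[inside] >= theta_prime * mean_amp]
      inside <- setdiff(inside, c(idx, banned))
      if (length(inside))
        added <- c(added, inside[which.max(window$samples[inside])])
    }
    sb_admitted <<- union(sb_admitted, added)
    sort(unique(c(idx, added)))
  }

  # The amplitude threshold is iterated over the retained set: the round-1
  # candidate mean is pulled down by P/T/noise peaks, so re-thresholding
  # against the retained mean converges the cut to a fraction of the R
  # amplitude and sheds stragglers (e.g. a T wave whose R fell outside the
  # window). Search-back re-admissions passed theta_prime deliberately and
  # are exempt. Refractory rejects are barred from re-admission; together
  # these make the remove/re-admit loop terminate.
  banned <- integer(0)
  for (it in seq_len(100L)) {
    before <- keep
    if (length(keep)) {
      m <- mean(window$samples[keep])
      keep <- keep[window$samples[keep] >= theta * m |
                     keep %in% sb_admitted]
    }
    after_ref <- refractory_pass(keep)
    banned <- union(banned, setdiff(keep, after_ref))
    keep <- searchback_pass(after_ref, banned)
    if (identical(keep, before)) break
  }
  peak_series(keep, window, round1$window_id)
}

#' Validate a window's detected rhythm
#'
#' Marks RR intervals outside the normal 300-1200 ms range (50-200 bpm) as
#' invalid; the window is valid iff its mean heart rate lies in
#' \code{hr_range_bpm} and the fraction of in-range RR intervals is at
#' least \code{min_valid_fraction}. Invalid windows are excluded from HRV
#' extraction.
#'
#' @param window the \code{\link{waveform_record}}.
#' @param peaks refined \code{peak_series} from round 2.
#' @param rr_range_ms acceptable RR interval range in ms (default
#'   \code{c(300, 1200)}).
#' @param hr_range_bpm acceptable mean-HR range (default \code{c(50, 200)}).
#' @param min_valid_fraction minimum fraction of in-range RR intervals for
#'   window acceptance (default 0.8).
#' @param round1 optional round-1 series for removed/added accounting.
#' @return object of class \code{window_quality}: \code{window_id},
#'   \code{n_peaks}, \code{n_removed}, \code{n_added},
#'   \code{fraction_rr_in_range}, \code{is_valid}, \code{reject_reason},
#'   \code{rr_valid} (per-interval flags).
#' @export
validate_window <- function(window, peaks, rr_range_ms = c(300, 1200),
                            hr_range_bpm = c(50, 200),
                            min_valid_fraction = 0.8, round1 = NULL) {
  stopifnot(inherits(peaks, "peak_series"))
  n_removed <- if (!is.null(round1))
    length(setdiff(round1$peak_indices, peaks$peak_indices)) else NA_integer_
  n_added <- if (!is.null(round1))
    length(setdiff(peaks$peak_indices, round1$peak_indices)) else NA_integer_
  quality <- function(frac, valid, reason, rr_valid = logical(0)) {
    structure(list(window_id = peaks$window_id,
                   n_peaks = length(peaks$peak_indices),
                   n_removed = n_removed, n_added = n_added,
                   fraction_rr_in_range = frac, is_valid = valid,
                   reject_reason = reason, rr_valid = rr_valid),
              class = "window_quality")
  }
  if (length(peaks$peak_indices) < 2)
    return(quality(NA_real_, FALSE, "insufficient peaks"))
  rr <- diff(peaks$peak_times_s) * 1000
  rr_valid <- rr >= rr_range_ms[1] & rr <= rr_range_ms[2]
  frac <- mean(rr_valid)
  hr <- 60000 / mean(rr)
  if (hr < hr_range_bpm[1] || hr > hr_range_bpm[2])
    return(quality(frac, FALSE, "HR out of range", rr_valid))
  if (frac < min_valid_fraction)
    return(quality(frac, FALSE, "low valid RR fraction", rr_valid))
  quality(frac, TRUE, "", rr_valid)
}

#' @export
print.window_quality <- function(x, ...) {
  cat(sprintf("<window_quality> window %s: %d peaks, %.1f%% RR in range, %s\n",
              as.character(x$window_id), x$n_peaks,
              100 * x$fraction_rr_in_range,
              if (x$is_valid) "valid" else paste0("INVALID (", x$reject_reason, ")")))
  invisible(x)
}

#' Evaluate detected peaks against ground-truth beat times
#'
#' Greedy one-to-one matching of detected to true beats within a tolerance:
#' matched pairs are true positives; unmatched true beats are misses and
#' unmatched detections false positives.
#'
#' @param detected_times_s detected peak times (seconds).
#' @param true_times_s ground-truth beat times (seconds).
#' @param tol_s matching tolerance in seconds (default 0.05).
#' @return list: \code{sensitivity} (TP / n true), \code{ppv}
#'   (TP / n detected), \code{mean_abs_error_s} over matched pairs,
#'   \code{n_true}, \code{n_detected}, \code{n_matched}.
#' @export
evaluate_peak_detection <- function(detected_times_s, true_times_s,
                                    tol_s = 0.05) {
  nd <- length(detected_times_s); nt <- length(true_times_s)
  used <- rep(FALSE, nd)
  err <- numeric(0)
  for (t0 in true_times_s) {
    d <- abs(detected_times_s - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      err <- c(err, d[j])
    }
  }
  list(sensitivity = sum(used) / nt, ppv = sum(used) / nd,
       mean_abs_error_s = if (length(err)) mean(err) else NA_real_,
       n_true = nt, n_detected = nd, n_matched = sum(used))
}
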