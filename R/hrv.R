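#' NN series from detected peaks
#'
#' Successive differences of peak times (ms) with per-interval validity
#' flags: intervals outside \code{rr_range_ms} are flagged invalid, and both
#' neighbours of an invalid interval lose adjacency for successive-
#' difference statistics (handled downstream by \code{\link{hrv_time_domain}}).
#'
#' @param peaks a \code{peak_series} (round-2 output).
#' @param quality the \code{window_quality} for the same window; must be
#'   valid.
#' @param rr_range_ms normal RR range in ms (default \code{c(300, 1200)}).
#' @return an \code{\link{nn_series}} with source \code{"ecg"}.
#' @export
nn_from_peaks <- function(peaks, quality, rr_range_ms = c(300, 1200)) {
  stopifnot(inherits(peaks, "peak_series"))
  if (length(peaks$peak_times_s) < 2)
    stop("nn_from_peaks: need at least 2 peaks", call. = FALSE)
  if (!missing(quality) && !is.null(quality) && !quality$is_valid)
    stop("nn_from_peaks: window failed validation (",
         quality$reject_reason, ")", call. = FALSE)
  nn <- diff(peaks$peak_times_s) * 1000
  valid <- nn >= rr_range_ms[1] & nn <= rr_range_ms[2]
  nn_series(peaks$peak_times_s, valid = valid, source = "ecg")
}

#' Time-domain HRV parameters
#'
#' Over the valid (normal-to-normal) intervals of an \code{\link{nn_series}}:
#' AVNN = mean, SDNN = sample SD (n-1 denominator),
#' RMSSD = root mean square of successive differences over adjacent valid
#' pairs, pNN50 = number of adjacent pairs differing by more than 50 ms
#' divided by the total number of NN intervals (a proportion), and
#' HR = 60000 / AVNN. An interval flagged invalid breaks adjacency: neither
#' neighbouring pair contributes a successive difference.
#'
#' @param nn an \code{\link{nn_series}}.
#' @return named list: \code{hr_bpm}, \code{rmssd_ms}, \code{avnn_ms},
#'   \code{sdnn_ms}, \code{pnn50}, \code{n_nn}, \code{n_pairs}.
#' @export
hrv_time_domain <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  v <- nn$nn_ms[nn$valid]
  if (length(v) == 0)
    stop("hrv_time_domain: no valid NN intervals", call. = FALSE)
  adj <- which(nn$valid[-length(nn$valid)] & nn$valid[-1])
  d <- nn$nn_ms[adj + 1L] - nn$nn_ms[adj]
  avnn <- mean(v)
  list(hr_bpm = 60000 / avnn,
       rmssd_ms = if (length(d)) sqrt(mean(d^2)) else NA_real_,
       avnn_ms = avnn,
       sdnn_ms = if (length(v) > 1) stats::sd(v) else NA_real_,
       pnn50 = sum(abs(d) > 50) / length(v),
       n_nn = length(v), n_pairs = length(d))
}

#' Lomb-Scargle periodogram
#'
#' Classic Scargle normalization-free periodogram of an unevenly sampled
#' series, evaluated at the given frequencies. Used internally for
#' frequency-domain HRV, where the power is rescaled so the periodogram
#' integrates to the sample variance.
#'
#' @param t sample times (seconds).
#' @param y sample values (centred internally).
#' @param freq_hz frequencies at which to evaluate (Hz, > 0).
#' @return numeric vector of periodogram powers, one per frequency.
#' @export
lomb_scargle <- function(t, y, freq_hz) {
  stopifnot(length(t) == length(y), all(freq_hz > 0))
  yc <- y - mean(y)
  vapply(freq_hz, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Frequency-domain HRV parameters
#'
#' Lomb-Scargle spectral analysis of the NN series on its natural uneven
#' time base (no resampling): power is integrated over the LF band
#' [0.04, 0.15) Hz and the HF band [0.15, 0.4] Hz (0.15 Hz counted once).
#' The periodogram is normalized so that its integral over the evaluated
#' grid equals the sample variance of the NN values; a pure sinusoidal
#' modulation of amplitude A therefore recovers band power close to A^2/2.
#'
#' @param nn an \code{\link{nn_series}}; only valid intervals are used.
#' @param min_nn minimum number of valid NN intervals (default 30).
#' @param min_span_s minimum time span in seconds (default 120).
#' @param lf_band,hf_band band edges in Hz.
#' @param oversample frequency-grid oversampling factor (default 4).
#' @return named list: \code{lf_ms2}, \code{hf_ms2}, \code{lf_hf_ratio}
#'   (NA when HF power is zero).
#' @export
hrv_frequency_domain <- function(nn, min_nn = 30, min_span_s = 120,
                                 lf_band = c(0.04, 0.15),
                                 hf_band = c(0.15, 0.4), oversample = 4) {
  stopifnot(inherits(nn, "nn_series"))
  sel <- nn$valid
  t <- nn$beat_times_s[-1][sel]
  y <- nn$nn_ms[sel]
  span <- if (length(t) > 1) diff(range(t)) else 0
  if (length(y) < min_nn || span < min_span_s)
    stop("hrv_frequency_domain: need >= ", min_nn, " valid NN intervals ",
         "spanning >= ", min_span_s, " s (have ", length(y), " over ",
         round(span, 1), " s)", call. = FALSE)
  v <- stats::var(y)
  if (v < 1e-12 * mean(y)^2)
    return(list(lf_ms2 = 0, hf_ms2 = 0, lf_hf_ratio = NA_real_))
  df <- 1 / (oversample * span)
  f_max <- max(hf_band[2], 0.5 / stats::median(diff(t)))
  freq <- seq(df, f_max, by = df)
  p <- lomb_scargle(t, y, freq)
  scale <- v / (sum(p) * df)            # integral over grid = variance
  lf <- sum(p[freq >= lf_band[1] & freq < lf_band[2]]) * df * scale
  hf <- sum(p[freq >= hf_band[1] & freq <= hf_band[2]]) * df * scale
  list(lf_ms2 = lf, hf_ms2 = hf,
       lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
}

#' Wearable 5-minute validity gate
#'
#' A wearable IBI window is retained iff the fraction of valid samples is
#' at least \code{threshold} (default 0.30, boundary inclusive: a window
#' with exactly 30\% valid signal is kept). Gated-out windows carry no HRV
#' values and are excluded from pairing and nightly means.
#'
#' @param nn an \code{\link{nn_series}} with wearable validity flags.
#' @param threshold minimum valid fraction (default 0.30).
#' @return logical: TRUE if the window is retained.
#' @export
gate_wearable_window <- function(nn, threshold = 0.30) {
  stopifnot(inherits(nn, "nn_series"))
  mean(nn$valid) >= threshold
}

# one HRVWindow row; freq-domain NAs when its preconditions are unmet
hrv_window_row <- function(nn, window_start_s, freq = TRUE, ...) {
  td <- hrv_time_domain(nn)
  fd <- if (freq) tryCatch(hrv_frequency_domain(nn, ...),
                           error = function(e)
                             list(lf_ms2 = NA_real_, hf_ms2 = NA_real_,
                                  lf_hf_ratio = NA_real_))
        else list(lf_ms2 = NA_real_, hf_ms2 = NA_real_,
                  lf_hf_ratio = NA_real_)
  data.frame(window_start_s = window_start_s,
             hr_bpm = td$hr_bpm, rmssd_ms = td$rmssd_ms,
             avnn_ms = td$avnn_ms, sdnn_ms = td$sdnn_ms, pnn50 = td$pnn50,
             lf_ms2 = fd$lf_ms2, hf_ms2 = fd$hf_ms2,
             lf_hf_ratio = fd$lf_hf_ratio,
             n_nn = td$n_nn, valid_fraction = mean(nn$valid),
             gated_out = FALSE)
}

#' Per-window HRV table from a full-night NN series
#'
#' Splits an NN series into consecutive windows (intervals assigned by
#' their start beat time), applies the wearable validity gate when
#' \code{gate_threshold} is given, and computes the eight HRV parameters
#' per retained window. Windows failing a computation precondition carry
#' NA for the affected parameters; gated-out windows carry NA throughout
#' and \code{gated_out = TRUE}.
#'
#' @param nn a full-night \code{\link{nn_series}}.
#' @param window_s window length in seconds (default 300).
#' @param gate_threshold optional minimum valid fraction (wearable gate);
#'   \code{NULL} disables gating.
#' @param night_id optional identifier column.
#' @return data frame, one row per window, columns
#'   \code{window_start_s}, the eight parameters, \code{n_nn},
#'   \code{valid_fraction}, \code{gated_out} (and \code{night_id}).
#' @export
hrv_windows <- function(nn, window_s = 300, gate_threshold = NULL,
                        night_id = NULL) {
  stopifnot(inherits(nn, "nn_series"))
  start_t <- nn$beat_times_s[-length(nn$beat_times_s)]
  win_of <- floor(start_t / window_s)   # aligned to absolute time 0
  rows <- lapply(sort(unique(win_of)), function(w) {
    idx <- which(win_of == w)
    ws <- w * window_s
    if (length(idx) < 2) return(empty_window_row(ws, "too few intervals"))
    sub <- nn_series(nn$beat_times_s[c(idx, idx[length(idx)] + 1L)],
                     valid = nn$valid[idx], source = nn$source)
    if (!is.null(gate_threshold) && !gate_wearable_window(sub, gate_threshold))
      return(empty_window_row(ws, "gated", valid_fraction = mean(sub$valid),
                              n_nn = sum(sub$valid)))
    if (!any(sub$valid)) return(empty_window_row(ws, "no valid intervals"))
    hrv_window_row(sub, ws)
  })
  out <- do.call(rbind, rows)
  if (!is.null(night_id)) out$night_id <- night_id
  out
}

empty_window_row <- function(ws, reason, valid_fraction = NA_real_,
                             n_nn = NA_integer_) {
  data.frame(window_start_s = ws, hr_bpm = NA_real_, rmssd_ms = NA_real_,
             avnn_ms = NA_real_, sdnn_ms = NA_real_, pnn50 = NA_real_,
             lf_ms2 = NA_real_, hf_ms2 = NA_real_, lf_hf_ratio = NA_real_,
             n_nn = n_nn, valid_fraction = valid_fraction,
             gated_out = identical(reason, "gated"))
}

#' Nightly average of per-window HRV parameters
#'
#' Unweighted arithmetic mean of each parameter over non-gated windows,
#' with per-parameter missingness handled independently (a window missing
#' LF:HF still contributes to HR).
#'
#' @param windows a per-window data frame from \code{\link{hrv_windows}}.
#' @param night_id optional identifier for the output row.
#' @return one-row data frame of per-parameter means plus
#'   \code{n_windows_used}.
#' @export
nightly_average <- function(windows, night_id = NULL) {
  stopifnot(is.data.frame(windows))
  use <- windows[!windows$gated_out, , drop = FALSE]
  pars <- hrv_parameter_names()
  usable <- rowSums(!is.na(use[, pars, drop = FALSE])) > 0
  use <- use[usable, , drop = FALSE]
  if (nrow(use) == 0)
    stop("nightly_average: no usable (non-gated, non-missing) windows",
         call. = FALSE)
  out <- as.data.frame(lapply(use[, pars, drop = FALSE],
                              function(x) mean(x, na.rm = TRUE)))
  out[vapply(out, is.nan, logical(1))] <- NA_real_
  out$n_windows_used <- nrow(use)
  if (!is.null(night_id)) out <- cbind(night_id = night_id, out)
  out
}
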