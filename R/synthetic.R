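#' Specify a synthetic tachogram (NN-interval series)
#'
#' A tachogram spec describes a beat-interval process with sinusoidal
#' autonomic modulation in the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands
#' plus white beat-to-beat jitter:
#' \deqn{NN_k = \mu + A_{LF}\sin(2\pi f_{LF} t_k) + A_{HF}\sin(2\pi f_{HF} t_k) + \epsilon_k}
#' with \eqn{t_k} the cumulative beat time and
#' \eqn{\epsilon_k \sim N(0, \sigma^2)}.
#'
#' @param duration_s recording duration in seconds (> 0). Default 29700 s
#'   (8.25 h, a typical full night of sleep).
#' @param mean_nn_ms mean NN interval in ms; must lie in [300, 1200], the
#'   50-200 bpm normal heart-rate range.
#' @param lf_amp_ms,lf_freq_hz amplitude (ms) and frequency (Hz) of the
#'   low-frequency modulation; frequency must lie in [0.04, 0.15).
#' @param hf_amp_ms,hf_freq_hz amplitude (ms) and frequency (Hz) of the
#'   high-frequency modulation; frequency must lie in [0.15, 0.4].
#' @param jitter_sd_ms SD of white beat-to-beat noise in ms (>= 0).
#' @param seed RNG seed; all randomness in generation flows from it.
#' @return an object of class \code{tachogram_spec}.
#' @export
tachogram_spec <- function(duration_s = 29700, mean_nn_ms = 1000,
                           lf_amp_ms = 0, lf_freq_hz = 0.1,
                           hf_amp_ms = 0, hf_freq_hz = 0.25,
                           jitter_sd_ms = 0, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("tachogram_spec: 'duration_s' must be > 0", call. = FALSE)
  if (mean_nn_ms < 300 || mean_nn_ms > 1200)
    stop("tachogram_spec: 'mean_nn_ms' must lie in [300, 1200] ms (50-200 bpm)",
         call. = FALSE)
  if (lf_freq_hz < 0.04 || lf_freq_hz >= 0.15)
    stop("tachogram_spec: 'lf_freq_hz' must lie in [0.04, 0.15)", call. = FALSE)
  if (hf_freq_hz < 0.15 || hf_freq_hz > 0.4)
    stop("tachogram_spec: 'hf_freq_hz' must lie in [0.15, 0.4]", call. = FALSE)
  for (fld in c("lf_amp_ms", "hf_amp_ms")) {
    a <- get(fld)
    if (a < 0 || a >= mean_nn_ms / 2)
      stop("tachogram_spec: '", fld, "' must be >= 0 and < mean_nn_ms/2",
           call. = FALSE)
  }
  if (jitter_sd_ms < 0)
    stop("tachogram_spec: 'jitter_sd_ms' must be >= 0", call. = FALSE)
  structure(list(duration_s = duration_s, mean_nn_ms = mean_nn_ms,
                 lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz,
                 hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
                 jitter_sd_ms = jitter_sd_ms, seed = as.integer(seed)),
            class = "tachogram_spec")
}

#' Construct an NN-interval series
#'
#' @param beat_times_s strictly increasing beat times in seconds (length
#'   n + 1 for n intervals).
#' @param valid logical per-interval validity flags (default all TRUE).
#' @param source one of \code{"ecg"}, \code{"wearable"}, \code{"truth"}.
#' @return object of class \code{nn_series} with fields \code{beat_times_s},
#'   \code{nn_ms}, \code{valid}, \code{source}.
#' @export
nn_series <- function(beat_times_s, valid = NULL, source = "ecg") {
  if (length(beat_times_s) < 2)
    stop("nn_series: need at least 2 beat times", call. = FALSE)
  if (any(diff(beat_times_s) <= 0))
    stop("nn_series: beat times must be strictly increasing", call. = FALSE)
  nn_ms <- diff(beat_times_s) * 1000
  if (is.null(valid)) valid <- rep(TRUE, length(nn_ms))
  stopifnot(length(valid) == length(nn_ms))
  structure(list(beat_times_s = as.numeric(beat_times_s),
                 nn_ms = as.numeric(nn_ms),
                 valid = as.logical(valid),
                 source = match.arg(source, c("ecg", "wearable", "truth"))),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d intervals, %.1f s, source=%s, %.1f%% valid\n",
              length(x$nn_ms), diff(range(x$beat_times_s)), x$source,
              100 * mean(x$valid)))
  invisible(x)
}

# Time-domain parameters of a clean interval vector, used for ground truth.
# Adjacency is taken as given (no invalid breaks).
td_direct <- function(nn) {
  d <- diff(nn)
  list(hr_bpm = 60000 / mean(nn),
       rmssd_ms = if (length(d)) sqrt(mean(d^2)) else NA_real_,
       avnn_ms = mean(nn),
       sdnn_ms = if (length(nn) > 1) stats::sd(nn) else NA_real_,
       pnn50 = sum(abs(d) > 50) / length(nn))
}

#' Generate a tachogram with ground truth
#'
#' Simulates the beat process of \code{\link{tachogram_spec}} and returns
#' both the NN series and a ground-truth record with per-window parameter
#' values (5-minute windows): time-domain values computed directly from the
#' clean generated intervals, and analytic band powers
#' \eqn{LF = A_{LF}^2/2}, \eqn{HF = A_{HF}^2/2}.
#'
#' @param spec a \code{\link{tachogram_spec}}.
#' @param window_s ground-truth windowing period in seconds (default 300).
#' @return list with elements \code{nn} (an \code{\link{nn_series}} with
#'   source \code{"truth"}) and \code{truth} (beat times, the NN series and
#'   a per-window parameter data frame).
#' @export
generate_tachogram <- function(spec, window_s = 300) {
  stopifnot(inherits(spec, "tachogram_spec"))
  n_max <- ceiling(spec$duration_s * 1000 / (spec$mean_nn_ms -
                     spec$lf_amp_ms - spec$hf_amp_ms - 4 * spec$jitter_sd_ms)) + 16L
  eps <- with_seed(spec$seed, stats::rnorm(n_max, 0, spec$jitter_sd_ms))
  times <- numeric(n_max + 1L)
  t_cur <- 0
  k <- 0L
  while (k < n_max) {
    nn_k <- spec$mean_nn_ms +
      spec$lf_amp_ms * sin(2 * pi * spec$lf_freq_hz * t_cur) +
      spec$hf_amp_ms * sin(2 * pi * spec$hf_freq_hz * t_cur) +
      eps[k + 1L]
    if (nn_k <= 0)
      stop("generate_tachogram: non-positive NN interval generated; reduce ",
           "amplitudes/jitter relative to 'mean_nn_ms'", call. = FALSE)
    t_next <- t_cur + nn_k / 1000
    if (t_next > spec$duration_s) break
    k <- k + 1L
    times[k + 1L] <- t_next
    t_cur <- t_next
  }
  beat_times <- times[seq_len(k + 1L)]
  nn <- nn_series(beat_times, source = "truth")
  truth <- ground_truth(nn, spec, window_s = window_s)
  list(nn = nn, truth = truth)
}

# Ground-truth container: per-window parameters from the clean NN series;
# frequency-domain truth is the analytic sinusoid band power amp^2/2.
# `beat_times_s` may exclude beats outside the sampled record (e.g. a beat
# at exactly t = duration) while `nn` keeps the full interval series.
ground_truth <- function(nn, spec, window_s = 300, in_gap = NULL,
                         beat_times_s = NULL) {
  n_win <- floor(spec$duration_s / window_s)
  win_of <- floor(nn$beat_times_s[-length(nn$beat_times_s)] / window_s)
  rows <- lapply(seq_len(n_win) - 1L, function(w) {
    v <- nn$nn_ms[win_of == w]
    td <- td_direct(v)
    data.frame(window_start_s = w * window_s,
               hr_bpm = td$hr_bpm, rmssd_ms = td$rmssd_ms,
               avnn_ms = td$avnn_ms, sdnn_ms = td$sdnn_ms, pnn50 = td$pnn50,
               lf_ms2 = spec$lf_amp_ms^2 / 2, hf_ms2 = spec$hf_amp_ms^2 / 2,
               lf_hf_ratio = if (spec$hf_amp_ms > 0)
                 spec$lf_amp_ms^2 / spec$hf_amp_ms^2 else NA_real_,
               n_nn = length(v))
  })
  if (is.null(beat_times_s)) beat_times_s <- nn$beat_times_s
  structure(list(beat_times_s = beat_times_s, nn = nn,
                 window_params = do.call(rbind, rows),
                 in_gap = in_gap, spec = spec),
            class = "ground_truth")
}

#' Specify a synthetic single-lead ECG waveform
#'
#' Morphology is a template per beat: a narrow Gaussian R spike flanked by
#' smaller P and T bumps, plus sinusoidal baseline wander, additive white
#' noise, optional high-energy artifact bursts and flat electrode-dropout
#' gaps. This is not a physiological PQRST simulator; it provides a dominant
#' R deflection with exactly known timing.
#'
#' @param tachogram a \code{\link{tachogram_spec}} driving beat times.
#' @param sampling_rate_hz sampling rate in Hz (>= 128; default 512).
#' @param r_amplitude R-spike amplitude, arbitrary units (> 0).
#' @param p_amplitude,t_amplitude P/T bump amplitudes (defaults 0.15 and 0.3
#'   of \code{r_amplitude}).
#' @param baseline_wander_amp,baseline_wander_freq_hz slow sinusoidal drift.
#' @param noise_sd additive white-noise SD.
#' @param artifact_bursts list of \code{c(start_s, duration_s, amplitude)}
#'   high-energy noise segments.
#' @param dropout_gaps list of \code{c(start_s, duration_s)} flat segments.
#' @param seed RNG seed for waveform noise; defaults to a stream derived
#'   from the tachogram seed.
#' @return object of class \code{ecg_spec}.
#' @export
ecg_spec <- function(tachogram, sampling_rate_hz = 512, r_amplitude = 1,
                     p_amplitude = 0.15 * r_amplitude,
                     t_amplitude = 0.3 * r_amplitude,
                     baseline_wander_amp = 0, baseline_wander_freq_hz = 0.33,
                     noise_sd = 0, artifact_bursts = list(),
                     dropout_gaps = list(), seed = NULL) {
  stopifnot(inherits(tachogram, "tachogram_spec"))
  if (sampling_rate_hz < 128)
    stop("ecg_spec: 'sampling_rate_hz' must be >= 128", call. = FALSE)
  if (r_amplitude <= 0)
    stop("ecg_spec: 'r_amplitude' must be > 0", call. = FALSE)
  dur <- tachogram$duration_s
  for (b in artifact_bursts) {
    if (length(b) != 3 || b[1] < 0 || b[1] + b[2] > dur)
      stop("ecg_spec: artifact burst must be c(start_s, duration_s, amplitude) within [0, duration_s]",
           call. = FALSE)
  }
  for (g in dropout_gaps) {
    if (length(g) != 2 || g[1] < 0 || g[1] + g[2] > dur)
      stop("ecg_spec: dropout gap must be c(start_s, duration_s) within [0, duration_s]",
           call. = FALSE)
  }
  if (is.null(seed)) seed <- child_seed(tachogram$seed, 7L)
  structure(list(tachogram = tachogram, sampling_rate_hz = sampling_rate_hz,
                 r_amplitude = r_amplitude, p_amplitude = p_amplitude,
                 t_amplitude = t_amplitude,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq_hz = baseline_wander_freq_hz,
                 noise_sd = noise_sd, artifact_bursts = artifact_bursts,
                 dropout_gaps = dropout_gaps, seed = as.integer(seed)),
            class = "ecg_spec")
}

# add Gaussian bumps of one width/amplitude at many centers, vectorized;
# overlapping bumps (e.g. T waves at high heart rates) accumulate
add_kernels <- function(x, fs, centers, amp, sd_s) {
  if (length(centers) == 0 || amp == 0) return(x)
  half <- ceiling(4 * sd_s * fs)
  idx <- outer(as.integer(round(centers * fs)), (-half):half, "+") + 1L
  vals <- amp * exp(-0.5 * (((idx - 1) / fs - centers) / sd_s)^2)
  keep <- idx >= 1L & idx <= length(x)
  acc <- rowsum(as.numeric(vals[keep]), idx[keep])
  i <- as.integer(rownames(acc))
  x[i] <- x[i] + acc[, 1]
  x
}

#' Synthesize an ECG waveform with known beat times
#'
#' @param spec an \code{\link{ecg_spec}}.
#' @return list with \code{record} (a \code{\link{waveform_record}}) and
#'   \code{truth} (ground truth incl. beat times and per-window parameters;
#'   beats inside dropout gaps are flagged in \code{truth$in_gap}).
#' @export
synthesize_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_spec"))
  fs <- spec$sampling_rate_hz
  gen <- generate_tachogram(spec$tachogram)
  # beats at t >= duration fall outside the sampled record
  beats <- gen$nn$beat_times_s[gen$nn$beat_times_s < spec$tachogram$duration_s]
  nn_s <- diff(beats)
  r_sd <- 0.012                       # QRS width scale, seconds
  if (min(nn_s) < 10 * r_sd)
    stop("synthesize_ecg: beats denser than template width (min NN ",
         round(min(nn_s) * 1000), " ms)", call. = FALSE)
  n <- round(spec$tachogram$duration_s * fs)
  x <- numeric(n)
  nn_prev <- c(nn_s[1], nn_s)         # per-beat local interval context
  nn_next <- c(nn_s, nn_s[length(nn_s)])
  x <- add_kernels(x, fs, beats, spec$r_amplitude, r_sd)
  if (spec$p_amplitude > 0)
    x <- add_kernels(x, fs, beats - pmin(0.16, 0.3 * nn_prev),
                     spec$p_amplitude, 0.025)
  if (spec$t_amplitude > 0)
    x <- add_kernels(x, fs, beats + pmin(0.25, 0.45 * nn_next),
                     spec$t_amplitude, 0.05)
  tt <- (seq_len(n) - 1) / fs
  if (spec$baseline_wander_amp > 0)
    x <- x + spec$baseline_wander_amp *
      sin(2 * pi * spec$baseline_wander_freq_hz * tt)
  with_seed(spec$seed, {
    if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd)
    for (b in spec$artifact_bursts) {
      idx <- which(tt >= b[1] & tt < b[1] + b[2])
      x[idx] <- x[idx] + stats::rnorm(length(idx), 0, b[3])
    }
  })
  in_gap <- rep(FALSE, length(beats))
  for (g in spec$dropout_gaps) {
    x[tt >= g[1] & tt < g[1] + g[2]] <- 0
    in_gap <- in_gap | (beats >= g[1] & beats < g[1] + g[2])
  }
  truth <- ground_truth(gen$nn, spec$tachogram, in_gap = in_gap,
                        beat_times_s = beats)
  list(record = waveform_record(x, fs), truth = truth)
}

#' Specify the wearable device-error model
#'
#' Additive per-parameter bias and Gaussian noise applied to the true
#' window-level parameter values, plus a per-window fraction of IBI samples
#' flagged invalid (as one contiguous run, mimicking motion-artifact
#' episodes). Defaults are parameterized from a published window-level
#' validation of a PPG ring against reference ECG: bias = reported mean
#' bias, noise SD = (upper - lower limit of agreement) / (2 * 1.96).
#'
#' @param bias named numeric vector of additive biases; names must be among
#'   the canonical parameter names \code{hr_bpm, rmssd_ms, avnn_ms, sdnn_ms,
#'   pnn50, lf_ms2, hf_ms2, lf_hf_ratio}.
#' @param sd named numeric vector of noise SDs (>= 0), same names.
#' @param invalid_fraction proportion of IBI samples flagged invalid per
#'   window, in [0, 1].
#' @param seed RNG seed.
#' @return object of class \code{device_error_spec}.
#' @export
device_error_spec <- function(bias = NULL, sd = NULL, invalid_fraction = 0.05,
                              seed = 2L) {
  pars <- hrv_parameter_names()
  def_bias <- c(hr_bpm = -0.44, rmssd_ms = -14.97, avnn_ms = -13.39,
                sdnn_ms = -0.96, pnn50 = 0.06, lf_ms2 = 23.61,
                hf_ms2 = 30.23, lf_hf_ratio = -0.11)
  def_sd <- c(hr_bpm = (1.93 + 2.81) / 3.92,
              rmssd_ms = (14.13 + 44.07) / 3.92,
              avnn_ms = (183.24 + 210.01) / 3.92,
              sdnn_ms = (86.52 + 88.45) / 3.92,
              pnn50 = (0.35 + 0.23) / 3.92,
              lf_ms2 = (1806.12 + 1758.9) / 3.92,
              hf_ms2 = (1484.38 + 1423.92) / 3.92,
              lf_hf_ratio = (2.31 + 2.53) / 3.92)
  b <- def_bias[pars]; s <- def_sd[pars]
  if (!is.null(bias)) {
    if (!all(names(bias) %in% pars))
      stop("device_error_spec: unknown parameter in 'bias': ",
           paste(setdiff(names(bias), pars), collapse = ", "), call. = FALSE)
    b[names(bias)] <- bias
  }
  if (!is.null(sd)) {
    if (!all(names(sd) %in% pars))
      stop("device_error_spec: unknown parameter in 'sd': ",
           paste(setdiff(names(sd), pars), collapse = ", "), call. = FALSE)
    s[names(sd)] <- sd
  }
  if (any(s < 0))
    stop("device_error_spec: noise SDs must be >= 0", call. = FALSE)
  if (invalid_fraction < 0 || invalid_fraction > 1)
    stop("device_error_spec: 'invalid_fraction' must lie in [0, 1]",
         call. = FALSE)
  structure(list(bias = b, sd = s, invalid_fraction = invalid_fraction,
                 seed = as.integer(seed)),
            class = "device_error_spec")
}

#' Canonical HRV parameter (column) names
#' @return character vector of the eight per-window parameter names.
#' @export
hrv_parameter_names <- function() {
  c("hr_bpm", "rmssd_ms", "avnn_ms", "sdnn_ms", "pnn50",
    "lf_ms2", "hf_ms2", "lf_hf_ratio")
}

# flag one contiguous invalid run per window covering ~frac of its intervals
flag_invalid_runs <- function(nn, frac, window_s = 300) {
  valid <- rep(TRUE, length(nn$nn_ms))
  if (frac <= 0) return(valid)
  win_of <- floor(nn$beat_times_s[-length(nn$beat_times_s)] / window_s)
  for (w in unique(win_of)) {
    idx <- which(win_of == w)
    n_inv <- round(frac * length(idx))
    if (n_inv == 0) next
    start <- idx[1] + floor(stats::runif(1) * (length(idx) - n_inv + 1))
    valid[start:(start + n_inv - 1)] <- FALSE
  }
  valid
}

#' Simulate a paired wearable/reference study
#'
#' For each night: generates a tachogram, derives ground-truth per-window
#' parameters, builds the wearable channel at window level as
#' truth + bias + noise for all eight parameters (so agreement-statistic
#' recovery has analytically known targets), builds a wearable IBI series
#' whose validity flags carry contiguous invalid runs totalling
#' \code{invalid_fraction} of each window, and (optionally) synthesizes and
#' writes the reference ECG waveform.
#'
#' @param tacho a \code{\link{tachogram_spec}}; per-night seeds are derived
#'   from its seed.
#' @param err a \code{\link{device_error_spec}}.
#' @param n_nights number of nights (>= 1).
#' @param ecg optional \code{\link{ecg_spec}} template; when supplied, a
#'   waveform is synthesized per night (its tachogram is replaced by the
#'   night's tachogram).
#' @param out_dir optional directory; when supplied, per-night ECG/IBI/
#'   wearable-window files and a JSON manifest are written.
#' @param window_s window length in seconds (default 300).
#' @return object of class \code{device_pair_study}: list of per-night
#'   bundles (\code{truth}, \code{wearable_windows}, \code{ibi},
#'   \code{ecg}) plus the generating specs.
#' @export
simulate_device_pair <- function(tacho, err, n_nights, ecg = NULL,
                                 out_dir = NULL, window_s = 300) {
  stopifnot(inherits(tacho, "tachogram_spec"),
            inherits(err, "device_error_spec"))
  if (n_nights < 1) stop("simulate_device_pair: 'n_nights' must be >= 1",
                         call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("simulate_device_pair: cannot create output directory '",
                  out_dir, "'", call. = FALSE)
  }
  pars <- hrv_parameter_names()
  nights <- vector("list", n_nights)
  manifest <- list(n_nights = n_nights, window_s = window_s,
                   tachogram = unclass(tacho), error_model = unclass(err),
                   nights = list())
  for (i in seq_len(n_nights)) {
    tacho_i <- tacho
    tacho_i$seed <- child_seed(tacho$seed, i)
    ecg_i <- NULL
    if (!is.null(ecg)) {
      ecg_i <- ecg
      ecg_i$tachogram <- tacho_i
      ecg_i$seed <- child_seed(tacho_i$seed, 7L)
      syn <- synthesize_ecg(ecg_i)
      truth <- syn$truth
      record <- syn$record
    } else {
      gen <- generate_tachogram(tacho_i, window_s = window_s)
      truth <- gen$truth
      record <- NULL
    }
    tw <- truth$window_params
    ww <- with_seed(child_seed(err$seed, i), {
      out <- tw[, c("window_start_s", pars)]
      for (p in pars) {
        out[[p]] <- out[[p]] + err$bias[[p]] +
          stats::rnorm(nrow(out), 0, err$sd[[p]])
      }
      out
    })
    valid <- with_seed(child_seed(err$seed, 100000L + i),
                       flag_invalid_runs(truth$nn, err$invalid_fraction,
                                         window_s))
    ibi <- nn_series(truth$nn$beat_times_s, valid = valid,
                     source = "wearable")
    ww$valid_fraction <- vapply(ww$window_start_s, function(ws) {
      sel <- floor(ibi$beat_times_s[-length(ibi$beat_times_s)] /
                     window_s) * window_s == ws
      if (!any(sel)) return(NA_real_)
      mean(ibi$valid[sel])
    }, numeric(1))
    ww$night_id <- i
    files <- list()
    if (!is.null(out_dir)) {
      ibi_f <- file.path(out_dir, sprintf("night_%02d_ibi.tsv", i))
      ww_f <- file.path(out_dir, sprintf("night_%02d_wearable_windows.tsv", i))
      write_ibi_file(ibi, ibi_f)
      write_tsv_with_header(ww, ww_f)
      files <- list(ibi = ibi_f, wearable_windows = ww_f)
      if (!is.null(record)) {
        ecg_f <- file.path(out_dir, sprintf("night_%02d_ecg.tsv", i))
        write_ecg_file(record, ecg_f)
        files$ecg <- ecg_f
      }
    }
    nights[[i]] <- list(night_id = i, truth = truth, wearable_windows = ww,
                        ibi = ibi, ecg = record, ecg_spec = ecg_i,
                        files = files)
    manifest$nights[[i]] <- list(night_id = i, seed = tacho_i$seed,
                                 files = lapply(files, basename))
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(nights = nights, tacho = tacho, err = err, ecg = ecg,
                 window_s = window_s, out_dir = out_dir),
            class = "device_pair_study")
}
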