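#' Assemble a study configuration
#'
#' Collects every analysis parameter — generator specs, filter settings,
#' detector thresholds, validity rules, the wearable gate and the spectral
#' floor — into one validated object that fully determines a run
#' (reproducible from config + seed alone).
#'
#' @param tacho a \code{\link{tachogram_spec}} for the synthetic nights.
#' @param err a \code{\link{device_error_spec}}.
#' @param n_nights number of synthetic nights (default 35).
#' @param reference \code{"truth"} derives reference windows from the
#'   ground-truth NN series; \code{"ecg"} synthesizes the ECG waveform per
#'   night and runs the full cleaning/detection/validation chain.
#' @param ecg optional \code{\link{ecg_spec}} template (required when
#'   \code{reference = "ecg"}; a clean default is built if omitted).
#' @param window_s window length in seconds (default 300).
#' @param filter list: \code{low_hz}, \code{high_hz}, \code{order}.
#' @param detector list: \code{theta}, \code{theta_prime},
#'   \code{refractory_s}, \code{max_gap_s}.
#' @param validity list: \code{rr_range_ms}, \code{hr_range_bpm},
#'   \code{min_valid_fraction}.
#' @param gate_threshold wearable IBI validity gate (default 0.30).
#' @param out_dir optional output directory for tables/files.
#' @param make_plots write agreement plots when \code{out_dir} is set.
#' @param seed optional master seed overriding the spec seeds
#'   (tachogram seed = seed, error-model seed = seed + 1).
#' @return object of class \code{study_config}.
#' @export
study_config <- function(tacho = tachogram_spec(duration_s = 4800,
                                                lf_amp_ms = 40,
                                                hf_amp_ms = 30,
                                                jitter_sd_ms = 15),
                         err = device_error_spec(),
                         n_nights = 35,
                         reference = c("truth", "ecg"),
                         ecg = NULL, window_s = 300,
                         filter = list(low_hz = 0.5, high_hz = 100,
                                       order = 4),
                         detector = list(theta = 0.5, theta_prime = 0.3,
                                         refractory_s = 0.3,
                                         max_gap_s = 1.2),
                         validity = list(rr_range_ms = c(300, 1200),
                                         hr_range_bpm = c(50, 200),
                                         min_valid_fraction = 0.8),
                         gate_threshold = 0.30, out_dir = NULL,
                         make_plots = FALSE, seed = NULL) {
  reference <- match.arg(reference)
  if (!is.null(seed)) {
    tacho$seed <- as.integer(seed)
    err$seed <- as.integer(seed) + 1L
  }
  if (reference == "ecg" && is.null(ecg)) ecg <- ecg_spec(tacho)
  if (gate_threshold < 0 || gate_threshold > 1)
    stop("study_config: 'gate_threshold' must lie in [0, 1]", call. = FALSE)
  structure(list(tacho = tacho, err = err, n_nights = n_nights,
                 reference = reference, ecg = ecg, window_s = window_s,
                 filter = filter, detector = detector, validity = validity,
                 gate_threshold = gate_threshold, out_dir = out_dir,
                 make_plots = make_plots),
            class = "study_config")
}

# hash of the scientific configuration; output location and plot toggles
# do not affect results and are excluded so reruns into different
# directories remain byte-identical
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$make_plots <- NULL
  cfg <- rapply(cfg, unclass, how = "replace")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# full ECG chain for one night's waveform -> per-window HRV rows + exclusions
process_ecg_night <- function(record, config, night_id) {
  filt <- ecg_bandpass(record, config$filter$low_hz, config$filter$high_hz,
                       config$filter$order)
  wins <- segment_windows(filt, config$window_s)
  rows <- list(); excl <- list()
  for (w in seq_along(wins)) {
    win <- wins[[w]]
    ws <- win$start_time_s
    r1 <- detect_peaks_round1(win, window_id = w)
    r2 <- detect_peaks_round2(win, r1, theta = config$detector$theta,
                              theta_prime = config$detector$theta_prime,
                              refractory_s = config$detector$refractory_s,
                              max_gap_s = config$detector$max_gap_s)
    q <- validate_window(win, r2, rr_range_ms = config$validity$rr_range_ms,
                         hr_range_bpm = config$validity$hr_range_bpm,
                         min_valid_fraction = config$validity$min_valid_fraction,
                         round1 = r1)
    if (!q$is_valid) {
      rows[[w]] <- empty_window_row(ws, q$reject_reason)
      excl[[length(excl) + 1L]] <-
        data.frame(stage = "ecg_validate", night_id = night_id,
                   unit_id = as.character(ws), reason = q$reject_reason)
      next
    }
    nn <- nn_from_peaks(r2, q, rr_range_ms = config$validity$rr_range_ms)
    rows[[w]] <- hrv_window_row(nn, ws)
  }
  list(windows = cbind(do.call(rbind, rows), night_id = night_id),
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL)
}

#' Run a full validation study
#'
#' Orchestrates synthetic generation, reference-channel processing (ground
#' truth NN or full ECG chain), wearable gating, per-window and per-night
#' HRV tables, pairing, and window- plus night-level agreement tables.
#' With \code{out_dir} set, all tables are written as delimited text with
#' the config hash in a comment header, and agreement plots optionally as
#' PNG.
#'
#' @param config a \code{\link{study_config}}.
#' @return object of class \code{hrv_study_run}: \code{windows} and
#'   \code{nights} (each wearable/reference), \code{agreement} (window and
#'   night tables), \code{exclusions}, \code{counts}, \code{config},
#'   \code{config_hash}, and the simulation \code{bundle}.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  hash <- config_hash(config)
  bundle <- simulate_device_pair(config$tacho, config$err, config$n_nights,
                                 ecg = if (config$reference == "ecg")
                                   config$ecg else NULL,
                                 out_dir = config$out_dir,
                                 window_s = config$window_s)
  pars <- hrv_parameter_names()
  w_all <- list(); r_all <- list(); excl <- list()
  for (night in bundle$nights) {
    i <- night$night_id
    # wearable channel: device window table, 30% IBI-validity gate
    ww <- night$wearable_windows
    ww$gated_out <- !is.na(ww$valid_fraction) &
      ww$valid_fraction < config$gate_threshold
    for (p in pars) ww[[p]][ww$gated_out] <- NA_real_
    for (ws in ww$window_start_s[ww$gated_out]) {
      excl[[length(excl) + 1L]] <-
        data.frame(stage = "wearable_gate", night_id = i,
                   unit_id = as.character(ws),
                   reason = "IBI valid fraction below gate")
    }
    w_all[[i]] <- ww
    # reference channel
    if (config$reference == "ecg") {
      pr <- process_ecg_night(night$ecg, config, i)
      r_all[[i]] <- pr$windows
      if (!is.null(pr$exclusions))
        excl[[length(excl) + 1L]] <- pr$exclusions
    } else {
      r_all[[i]] <- hrv_windows(night$truth$nn, window_s = config$window_s,
                                night_id = i)
    }
  }
  w_windows <- do.call(rbind, w_all)
  r_windows <- do.call(rbind, r_all)

  night_summary <- function(windows, channel) {
    out <- list()
    for (i in sort(unique(windows$night_id))) {
      sub <- windows[windows$night_id == i, , drop = FALSE]
      row <- tryCatch(nightly_average(sub, night_id = i),
                      error = function(e) {
                        excl[[length(excl) + 1L]] <<-
                          data.frame(stage = paste0(channel, "_night"),
                                     night_id = i, unit_id = "night",
                                     reason = conditionMessage(e))
                        NULL
                      })
      if (!is.null(row)) out[[length(out) + 1L]] <- row
    }
    do.call(rbind, out)
  }
  w_nights <- night_summary(w_windows, "wearable")
  r_nights <- night_summary(r_windows, "reference")

  agreement_window <- agreement_table(w_windows, r_windows,
                                      key = "window_start_s",
                                      granularity = "window")
  agreement_night <- if (!is.null(w_nights) && !is.null(r_nights))
    agreement_table(w_nights, r_nights, key = "night_id",
                    granularity = "night") else NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(stage = character(0), night_id = integer(0),
               unit_id = character(0), reason = character(0))
  counts <- list(
    windows_total = nrow(r_windows),
    windows_used_reference = sum(!is.na(r_windows$hr_bpm)),
    windows_used_wearable = sum(!is.na(w_windows$hr_bpm)),
    windows_excluded = nrow(exclusions[exclusions$stage %in%
                              c("ecg_validate", "wearable_gate"), ]),
    nights_total = config$n_nights,
    nights_used = if (is.null(w_nights)) 0L else nrow(w_nights))
  run <- structure(list(config = config, config_hash = hash,
                        bundle = bundle,
                        windows = list(wearable = w_windows,
                                       reference = r_windows),
                        nights = list(wearable = w_nights,
                                      reference = r_nights),
                        agreement = list(window = agreement_window,
                                         night = agreement_night),
                        exclusions = exclusions, counts = counts),
                   class = "hrv_study_run")
  if (!is.null(config$out_dir)) write_run_outputs(run)
  run
}

write_run_outputs <- function(run) {
  dir <- run$config$out_dir
  hdr <- paste0("config_md5: ", run$config_hash)
  write_tsv_with_header(run$windows$wearable,
                        file.path(dir, "windows_wearable.tsv"), hdr)
  write_tsv_with_header(run$windows$reference,
                        file.path(dir, "windows_reference.tsv"), hdr)
  if (!is.null(run$nights$wearable))
    write_tsv_with_header(run$nights$wearable,
                          file.path(dir, "nights_wearable.tsv"), hdr)
  if (!is.null(run$nights$reference))
    write_tsv_with_header(run$nights$reference,
                          file.path(dir, "nights_reference.tsv"), hdr)
  if (!is.null(run$agreement$window))
    write_tsv_with_header(run$agreement$window,
                          file.path(dir, "agreement_window.tsv"), hdr)
  if (!is.null(run$agreement$night))
    write_tsv_with_header(run$agreement$night,
                          file.path(dir, "agreement_night.tsv"), hdr)
  write_tsv_with_header(run$exclusions, file.path(dir, "exclusions.tsv"),
                        hdr)
  if (isTRUE(run$config$make_plots) && !is.null(run$agreement$window)) {
    for (p in run$agreement$window$parameter) {
      pr <- pair_windows(run$windows$wearable, run$windows$reference, p)
      ggplot2::ggsave(file.path(dir, paste0("scatter_", p, ".png")),
                      plot_agreement_scatter(pr), width = 5, height = 4,
                      dpi = 120)
      ggplot2::ggsave(file.path(dir, paste0("bland_altman_", p, ".png")),
                      plot_bland_altman(pr), width = 5, height = 4,
                      dpi = 120)
    }
  }
  invisible(run)
}

#' @export
print.hrv_study_run <- function(x, ...) {
  cat(sprintf("<hrv_study_run> %d nights, %d reference windows (%d used), %d exclusions\n",
              x$counts$nights_total, x$counts$windows_total,
              x$counts$windows_used_reference, nrow(x$exclusions)))
  if (!is.null(x$agreement$window)) {
    cat("window-level agreement:\n")
    print(x$agreement$window[, c("parameter", "n", "pearson_r", "r_squared",
                                 "mean_bias", "loa_low", "loa_high")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Exclusion accounting for a run
#'
#' One row per excluded unit with its pipeline stage and reason. Counts
#' reconcile: used + excluded = total, per channel.
#'
#' @param run an \code{hrv_study_run}.
#' @return data frame of exclusions with a \code{counts} attribute.
#' @export
exclusion_report <- function(run) {
  stopifnot(inherits(run, "hrv_study_run"))
  structure(run$exclusions, counts = run$counts)
}
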