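#' Pair wearable and reference values for one parameter
#'
#' Inner join on the unit key (window start time or night id). Units
#' missing on either side — gated, invalid, or absent — are dropped and
#' counted.
#'
#' @param wearable,reference data frames with the key column and the
#'   parameter column (per-window tables from \code{\link{hrv_windows}} or
#'   per-night tables from \code{\link{nightly_average}}).
#' @param parameter one of \code{\link{hrv_parameter_names}()}.
#' @param key join key column name (default \code{"window_start_s"}; use
#'   \code{"night_id"} for per-night pairing).
#' @param granularity \code{"window"} or \code{"night"} (metadata only).
#' @return object of class \code{paired_samples}: a data frame with
#'   columns \code{unit_id}, \code{wearable}, \code{reference}, with
#'   attributes \code{parameter}, \code{granularity}, \code{n_dropped}.
#' @export
pair_windows <- function(wearable, reference, parameter,
                         key = "window_start_s",
                         granularity = c("window", "night")) {
  granularity <- match.arg(granularity)
  for (d in list(wearable, reference)) {
    if (!key %in% names(d) || !parameter %in% names(d))
      stop("pair_windows: inputs need columns '", key, "' and '",
           parameter, "'", call. = FALSE)
  }
  keys <- c(key, intersect("night_id", intersect(names(wearable),
                                                 names(reference))))
  if (key == "night_id") keys <- key
  wk <- do.call(paste, c(wearable[keys], sep = "/"))
  rk <- do.call(paste, c(reference[keys], sep = "/"))
  w_ok <- !is.na(wearable[[parameter]])
  r_ok <- !is.na(reference[[parameter]])
  shared <- intersect(wk[w_ok], rk[r_ok])
  total_units <- length(union(wk, rk))
  if (length(shared) == 0)
    stop("pair_windows: no complete pairs for parameter '", parameter, "'",
         call. = FALSE)
  wi <- match(shared, wk)
  ri <- match(shared, rk)
  out <- data.frame(unit_id = shared,
                    wearable = wearable[[parameter]][wi],
                    reference = reference[[parameter]][ri])
  structure(out, parameter = parameter, granularity = granularity,
            n_dropped = total_units - length(shared),
            class = c("paired_samples", "data.frame"))
}

check_pairs <- function(pairs, n_min = 3) {
  stopifnot(inherits(pairs, "paired_samples"))
  if (nrow(pairs) < n_min)
    stop("need at least ", n_min, " pairs (have ", nrow(pairs), ")",
         call. = FALSE)
}

#' Pearson correlation between devices
#'
#' Product-moment correlation of wearable vs reference values with a
#' two-sided p-value.
#'
#' @param pairs a \code{paired_samples} object.
#' @return list: \code{r}, \code{p}, \code{n}.
#' @export
agree_pearson <- function(pairs) {
  check_pairs(pairs)
  if (stats::var(pairs$wearable) == 0 || stats::var(pairs$reference) == 0)
    stop("agree_pearson: degenerate sample (zero variance)", call. = FALSE)
  ct <- stats::cor.test(pairs$wearable, pairs$reference)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
}

#' Linear regression of wearable on reference with r-squared
#'
#' Ordinary least squares with the reference (ECG) values on the abscissa
#' and the wearable values on the ordinate; r-squared is
#' 1 - SS_res / SS_tot of that fit. The identity line y = x is the ideal
#' against which the fit is plotted.
#'
#' @param pairs a \code{paired_samples} object.
#' @param swap_axes fit reference on wearable instead (alternative
#'   orientation, off by default).
#' @return list: \code{slope}, \code{intercept}, \code{r_squared}, \code{n}.
#' @export
agree_regression <- function(pairs, swap_axes = FALSE) {
  check_pairs(pairs)
  x <- if (swap_axes) pairs$wearable else pairs$reference
  y <- if (swap_axes) pairs$reference else pairs$wearable
  if (stats::var(x) == 0)
    stop("agree_regression: zero variance on the abscissa", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
       n = nrow(pairs))
}

#' Bland-Altman agreement analysis
#'
#' Differences are wearable minus reference, so a device that
#' underestimates shows negative bias. Limits of agreement are
#' bias +/- 1.96 * SD of the differences (the interval expected to contain
#' 95\% of between-device differences).
#'
#' @param pairs a \code{paired_samples} object.
#' @return list: \code{mean_bias}, \code{sd_diff}, \code{loa_low},
#'   \code{loa_high}, \code{n}, and \code{plot_data} (pair means vs
#'   differences).
#' @export
agree_bland_altman <- function(pairs) {
  check_pairs(pairs)
  d <- pairs$wearable - pairs$reference
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_bias = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = nrow(pairs),
       plot_data = data.frame(mean = (pairs$wearable + pairs$reference) / 2,
                              diff = d))
}

# interpretive correlation strength label
correlation_label <- function(r) {
  if (is.na(r)) NA_character_
  else if (abs(r) >= 0.7) "high"
  else if (abs(r) >= 0.5) "moderate"
  else "low"
}

#' Full agreement report for one parameter
#'
#' Combines Pearson correlation, regression r-squared and Bland-Altman
#' statistics into one row.
#'
#' @param pairs a \code{paired_samples} object.
#' @return one-row data frame: \code{parameter}, \code{n}, \code{pearson_r},
#'   \code{p_value}, \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{mean_bias}, \code{sd_diff}, \code{loa_low}, \code{loa_high},
#'   \code{correlation} (interpretive label).
#' @export
agreement_report <- function(pairs) {
  pe <- agree_pearson(pairs)
  rg <- agree_regression(pairs)
  ba <- agree_bland_altman(pairs)
  data.frame(parameter = attr(pairs, "parameter"), n = pe$n,
             pearson_r = pe$r, p_value = pe$p,
             slope = rg$slope, intercept = rg$intercept,
             r_squared = rg$r_squared,
             mean_bias = ba$mean_bias, sd_diff = ba$sd_diff,
             loa_low = ba$loa_low, loa_high = ba$loa_high,
             correlation = correlation_label(pe$r))
}

#' Agreement table over all parameters
#'
#' One \code{\link{agreement_report}} row per parameter, mirroring the
#' layout of a published device-validation table (parameter, n, r, p,
#' limits of agreement, mean bias).
#'
#' @param wearable,reference per-window or per-night tables.
#' @param parameters parameter names (default all eight).
#' @param key join key (default \code{"window_start_s"}).
#' @param granularity \code{"window"} or \code{"night"}.
#' @return data frame, one row per parameter that could be paired;
#'   parameters with no complete pairs are skipped with a warning.
#' @export
agreement_table <- function(wearable, reference,
                            parameters = hrv_parameter_names(),
                            key = "window_start_s",
                            granularity = c("window", "night")) {
  granularity <- match.arg(granularity)
  rows <- lapply(parameters, function(p) {
    tryCatch(agreement_report(pair_windows(wearable, reference, p,
                                           key = key,
                                           granularity = granularity)),
             error = function(e) {
               warning("agreement_table: skipping '", p, "': ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  do.call(rbind, rows)
}

#' Scatter + regression agreement plot
#'
#' Reference on x, wearable on y, OLS fit in red, identity (ideal) line in
#' black, annotated with r-squared.
#'
#' @param pairs a \code{paired_samples} object.
#' @return a ggplot object.
#' @export
plot_agreement_scatter <- function(pairs) {
  rg <- agree_regression(pairs)
  p <- attr(pairs, "parameter")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$reference,
                                      y = .data$wearable)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_abline(slope = rg$slope, intercept = rg$intercept,
                         colour = "red") +
    ggplot2::labs(x = paste0("reference (ECG) ", p),
                  y = paste0("wearable ", p),
                  title = sprintf("%s  (r² = %.3f, n = %d)", p,
                                  rg$r_squared, rg$n)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Pair means vs differences with the mean bias (solid) and 95\% limits of
#' agreement (dashed).
#'
#' @param pairs a \code{paired_samples} object.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(pairs) {
  ba <- agree_bland_altman(pairs)
  ggplot2::ggplot(ba$plot_data, ggplot2::aes(x = .data$mean,
                                             y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$mean_bias, colour = "red") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "pair mean", y = "difference (wearable - reference)",
                  title = sprintf("%s  (bias = %.3g, LoA = [%.3g, %.3g])",
                                  attr(pairs, "parameter"), ba$mean_bias,
                                  ba$loa_low, ba$loa_high)) +
    ggplot2::theme_minimal()
}
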