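## Binning-based nonlinearity detection and compensation.
##
## For one channel-trial, samples are placed in the (predicted, measured)
## plane.  The 20 smallest and 20 largest *predicted* samples are treated
## as outliers and excluded; the retained predicted range is split into
## three equal-width bins; a chord is fitted through the two outer-bin mean
## points; and all middle-bin measured samples receive a single additive
## shift that puts the middle-bin mean exactly on the chord.  The pre-shift
## deviation r = mean(y_mid) - L(mean(x_mid)) is the nonlinearity residual:
## positive = concave, negative = convex.

#' Binning configuration
#'
#' @param n_outliers_per_tail predicted-value outliers excluded per tail
#'   (default 20, an absolute count regardless of trial length).
#' @param n_bins number of equal-width bins (odd, >= 3; default 3).
#' @param tolerance microvolt threshold for labelling a mean residual as
#'   concave/convex rather than neutral (default 0).
#' @return Object of class `binning_config`.
#' @export
binning_config <- function(n_outliers_per_tail = 20L, n_bins = 3L,
                           tolerance = 0) {
  check_number(n_outliers_per_tail, "n_outliers_per_tail", nonneg = TRUE,
               integerish = TRUE)
  check_number(n_bins, "n_bins", positive = TRUE, integerish = TRUE)
  if (n_bins < 3 || n_bins %% 2 == 0)
    stop_invalid("`n_bins` must be odd and >= 3")
  check_number(tolerance, "tolerance", nonneg = TRUE)
  structure(list(n_outliers_per_tail = as.integer(n_outliers_per_tail),
                 n_bins = as.integer(n_bins), tolerance = tolerance),
            class = "binning_config")
}

#' Partition samples into equal-width predicted-value bins
#'
#' Ranks samples by predicted value (stable on ties), drops
#' `n_outliers_per_tail` from each tail, and splits the retained predicted
#' range into `n_bins` equal-width intervals (left-closed; the last
#' interval also closed on the right).
#'
#' @param predicted,measured equal-length numeric vectors (one
#'   channel-trial).
#' @param config a [binning_config()].
#' @return Object of class `bin_summary`: per-bin `count`,
#'   `mean_predicted`, `mean_measured`; plus `retained_index`, `bin_of`
#'   (bin id per retained sample), `edges`.
#' @export
partition_bins <- function(predicted, measured, config = binning_config()) {
  predicted <- as.numeric(predicted); measured <- as.numeric(measured)
  if (length(predicted) != length(measured))
    stop_invalid("`predicted` and `measured` must have equal length")
  check_no_na(predicted, "predicted"); check_no_na(measured, "measured")
  T <- length(predicted)
  nt <- config$n_outliers_per_tail
  if (T <= 2 * nt + config$n_bins)
    stop_invalid("too few samples for the requested outlier count and bins")
  ord <- order(predicted)              # stable for ties (radix)
  retained <- sort(ord[(nt + 1L):(T - nt)])
  px <- predicted[retained]
  lo <- min(px); hi <- max(px)
  if (hi <= lo)
    stop(structure(class = c("trfcomp_degenerate_binning", "error", "condition"),
                   list(message = "retained predicted range is degenerate",
                        call = sys.call())))
  edges <- seq(lo, hi, length.out = config$n_bins + 1L)
  bin_of <- findInterval(px, edges, all.inside = TRUE)
  counts <- tabulate(bin_of, nbins = config$n_bins)
  if (counts[1] == 0 || counts[config$n_bins] == 0 ||
        counts[(config$n_bins + 1L) %/% 2L] == 0)
    stop(structure(class = c("trfcomp_degenerate_binning", "error", "condition"),
                   list(message = "empty outer or middle bin",
                        call = sys.call())))
  structure(list(
    count = counts,
    mean_predicted = vapply(seq_len(config$n_bins), function(b)
      if (counts[b]) mean(px[bin_of == b]) else NA_real_, numeric(1)),
    mean_measured = vapply(seq_len(config$n_bins), function(b)
      if (counts[b]) mean(measured[retained][bin_of == b]) else NA_real_,
      numeric(1)),
    retained_index = retained, bin_of = bin_of, edges = edges,
    n_bins = config$n_bins), class = "bin_summary")
}

#' Compensate one channel-trial
#'
#' Fits the chord L through the outer-bin mean points and adds the constant
#' `shift = L(mean(x_mid)) - mean(y_mid)` to every middle-bin measured
#' sample, so the new middle-bin mean falls exactly on the chord.  Samples
#' outside the middle bin (including excluded outliers) are unmodified.
#'
#' @inheritParams partition_bins
#' @return Object of class `compensation_result`: `compensated_measured`,
#'   `residual` (microvolts; `= -shift`), `shift`, `line` (slope,
#'   intercept), `summary` (the [partition_bins()] output).
#' @export
compensate_channel_trial <- function(predicted, measured,
                                     config = binning_config()) {
  s <- partition_bins(predicted, measured, config)
  nb <- s$n_bins
  mid <- (nb + 1L) %/% 2L
  x1 <- s$mean_predicted[1]; y1 <- s$mean_measured[1]
  x3 <- s$mean_predicted[nb]; y3 <- s$mean_measured[nb]
  if (x3 == x1)
    stop(structure(class = c("trfcomp_degenerate_line", "error", "condition"),
                   list(message = "outer-bin mean predicted values coincide",
                        call = sys.call())))
  slope <- (y3 - y1) / (x3 - x1)
  intercept <- y1 - slope * x1
  line_at_mid <- slope * s$mean_predicted[mid] + intercept
  residual <- s$mean_measured[mid] - line_at_mid
  shift <- -residual
  compensated <- as.numeric(measured)
  mid_idx <- s$retained_index[s$bin_of == mid]
  compensated[mid_idx] <- compensated[mid_idx] + shift
  structure(list(compensated_measured = compensated, residual = residual,
                 shift = shift, line = c(slope = slope, intercept = intercept),
                 summary = s), class = "compensation_result")
}

#' Aggregate nonlinearity residuals into a channel map
#'
#' Arithmetic mean of the per-channel-trial residuals over subjects and
#' trials, per channel and condition, with a concave/convex/neutral sign
#' label.
#'
#' @param residuals data.frame with columns `channel`, `condition`,
#'   `residual` (one row per subject x trial x channel x condition; extra
#'   columns ignored).
#' @param config a [binning_config()] (supplies the sign tolerance).
#' @return data.frame of class `nonlinearity_map` with columns `channel`,
#'   `condition`, `mean_residual`, `sign` (`"concave"`, `"convex"`,
#'   `"neutral"`).
#' @export
aggregate_residuals <- function(residuals, config = binning_config()) {
  if (!is.data.frame(residuals) || nrow(residuals) == 0)
    stop_invalid("`residuals` must be a non-empty data.frame")
  if (!all(c("channel", "condition", "residual") %in% names(residuals)))
    stop_invalid("`residuals` needs channel, condition, residual columns")
  check_no_na(residuals$residual, "residual")
  agg <- stats::aggregate(residual ~ channel + condition, data = residuals,
                          FUN = mean)
  names(agg)[names(agg) == "residual"] <- "mean_residual"
  tol <- config$tolerance
  agg$sign <- ifelse(agg$mean_residual > tol, "concave",
                     ifelse(agg$mean_residual < -tol, "convex", "neutral"))
  class(agg) <- c("nonlinearity_map", "data.frame")
  agg
}

#' Compensate every channel of a trial
#'
#' Convenience wrapper: runs [compensate_channel_trial()] channel-wise on a
#' measured/predicted recording pair.
#'
#' @param measured,predicted [eeg_recording()]s of identical shape.
#' @param config a [binning_config()].
#' @return List: `compensated` ([eeg_recording()]) and `residuals` (named
#'   numeric vector per channel).
#' @export
compensate_recording <- function(measured, predicted,
                                 config = binning_config()) {
  if (!all(dim(measured$data) == dim(predicted$data)))
    stop_invalid("`measured` and `predicted` must have identical shape")
  N <- n_channels(measured)
  comp <- measured$data
  res <- stats::setNames(numeric(N), measured$channels)
  for (ch in seq_len(N)) {
    cr <- compensate_channel_trial(predicted$data[ch, ], measured$data[ch, ],
                                   config)
    comp[ch, ] <- cr$compensated_measured
    res[ch] <- cr$residual
  }
  list(compensated = eeg_recording(comp, measured$fs, measured$channels,
                                   measured$subject, measured$trial,
                                   measured$condition),
       residuals = res)
}
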