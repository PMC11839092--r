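## SNR differences, N1/P2 peak extraction, TRF variance profiles, and
## channel-group averaging on an idealized 64-channel 10-20 montage.

#' SNR difference between compensated and original EEG
#'
#' `SNR_diff = 10 log10(P_comp / kappa) - 10 log10(P_orig / kappa)` where
#' powers are means of element-wise squared absolute values.  The noise
#' power kappa cancels exactly, so the difference is computed in the
#' cancelled form `10 log10(P_comp / P_orig)` and is bit-identical for any
#' kappa; the per-kappa SNR levels are still reported.
#'
#' @param orig,comp [eeg_recording()]s of identical shape.
#' @param kappa mean squared noise, microvolts^2 (> 0).  Default 1; by
#'   construction it only shifts the two SNR levels, never the difference.
#' @return List of class `snr_result`: `kappa`, `power_orig`, `power_comp`
#'   (per channel), `snr_orig_db`, `snr_comp_db`, `snr_diff_db`.
#' @export
snr_difference <- function(orig, comp, kappa = 1) {
  if (!all(dim(orig$data) == dim(comp$data)))
    stop_invalid("`orig` and `comp` must have identical shape")
  check_number(kappa, "kappa", positive = TRUE)
  p_orig <- rowMeans(abs(orig$data)^2)
  p_comp <- rowMeans(abs(comp$data)^2)
  if (any(p_orig == 0))
    stop(structure(class = c("trfcomp_undefined_ratio", "error", "condition"),
                   list(message = "zero original power: SNR ratio undefined",
                        call = sys.call())))
  structure(list(kappa = kappa,
                 power_orig = p_orig, power_comp = p_comp,
                 snr_orig_db = 10 * log10(p_orig / kappa),
                 snr_comp_db = 10 * log10(p_comp / kappa),
                 snr_diff_db = 10 * log10(p_comp / p_orig)),
            class = "snr_result")
}

#' Extract N1 and P2 peaks from a TRF curve
#'
#' N1 is the most negative deflection within its window (default
#' \[0.08, 0.12\] s), P2 the most positive within its (default
#' \[0.18, 0.25\] s); ties break toward the earliest lag.
#'
#' @param trf_curve numeric vector of TRF values on `lags_ms`.
#' @param lags_ms lag grid in milliseconds.
#' @param windows named list with two-element second vectors `n1` and `p2`.
#' @return List of class `peak_result`: `n1_amplitude`, `n1_latency_s`,
#'   `p2_amplitude`, `p2_latency_s`.
#' @examples
#' g <- lag_grid(100)
#' curve <- -exp(-0.5 * ((g$lags_ms - 100) / 15)^2)
#' extract_peaks(curve, g$lags_ms)
#' @export
extract_peaks <- function(trf_curve, lags_ms,
                          windows = list(n1 = c(0.08, 0.12),
                                         p2 = c(0.18, 0.25))) {
  if (length(trf_curve) != length(lags_ms))
    stop_invalid("curve and lag grid must have equal length")
  lags_s <- lags_ms / 1000
  pick <- function(win, fun) {
    idx <- which(lags_s >= win[1] & lags_s <= win[2])
    if (!length(idx))
      stop_invalid("peak window lies outside the lag grid")
    i <- idx[fun(trf_curve[idx])]     # which.min/max: first index on ties
    c(amplitude = trf_curve[i], latency_s = lags_s[i])
  }
  n1 <- pick(windows$n1, which.min)
  p2 <- pick(windows$p2, which.max)
  structure(list(n1_amplitude = unname(n1["amplitude"]),
                 n1_latency_s = unname(n1["latency_s"]),
                 p2_amplitude = unname(p2["amplitude"]),
                 p2_latency_s = unname(p2["latency_s"]),
                 windows = windows), class = "peak_result")
}

#' Across-subject TRF variance profile
#'
#' For each lag, the variance across subjects (sample convention, divisor
#' n - 1) of the subject-level TRF curve; subject curves are expected to be
#' trial- and channel-group-averaged already (see [group_average()]).
#'
#' @param subject_curves numeric matrix, subjects x lags.
#' @return Numeric vector of per-lag variances (microvolts^2).
#' @export
trf_variance <- function(subject_curves) {
  if (!is.matrix(subject_curves) || nrow(subject_curves) < 2)
    stop_invalid("need a subjects x lags matrix with >= 2 subjects")
  apply(subject_curves, 2L, stats::var)
}

#' Average channel-indexed values within channel groups
#'
#' @param values named numeric vector (names are channel labels), or a
#'   channels x k matrix with rownames.
#' @param groups named list mapping group name to channel labels (see
#'   [default_channel_groups()]).
#' @return Named numeric vector (or groups x k matrix) of group means.
#' @export
group_average <- function(values, groups = default_channel_groups()) {
  if (is.matrix(values)) {
    out <- t(vapply(groups, function(chs) {
      missing <- setdiff(chs, rownames(values))
      if (length(missing))
        stop(structure(class = c("trfcomp_key_error", "error", "condition"),
                       list(message = paste("unknown channel(s):",
                                            paste(missing, collapse = ", ")),
                            call = sys.call())))
      colMeans(values[chs, , drop = FALSE])
    }, numeric(ncol(values))))
    rownames(out) <- names(groups)
    return(out)
  }
  vapply(groups, function(chs) {
    missing <- setdiff(chs, names(values))
    if (length(missing))
      stop(structure(class = c("trfcomp_key_error", "error", "condition"),
                     list(message = paste("unknown channel(s):",
                                          paste(missing, collapse = ", ")),
                          call = sys.call())))
    mean(values[chs])
  }, numeric(1))
}

#' Idealized 64-channel montage
#'
#' Schematic 2-D positions (unit head circle, nose up) for the standard
#' 64-label 10-20 set used by BioSemi caps, read from the editable TSV
#' shipped in `inst/extdata/montage64.tsv`.
#'
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage64.tsv", package = "trfcomp",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Default six-way channel grouping
#'
#' Disjoint partition of the 64-channel montage into left temporal,
#' frontal, right temporal, central, parietal and occipital groups,
#' read from the editable TSV in `inst/extdata/channel_groups.tsv`.
#'
#' @return Named list of character vectors of channel labels.
#' @export
default_channel_groups <- function() {
  path <- system.file("extdata", "channel_groups.tsv", package = "trfcomp",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(tab$channel, tab$group)
}
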