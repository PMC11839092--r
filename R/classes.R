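## Core data containers.  Lightweight S3, in the style of ts/phylo: plain
## vectors/matrices carrying attributes, with constructors that validate.

#' Sampled stimulus envelope
#'
#' A nonnegative, regularly sampled amplitude envelope of one speech stream,
#' together with its sampling rate and stream role (attended target or
#' ignored masker).
#'
#' @param x numeric vector of envelope samples (must be nonnegative).
#' @param fs sampling rate in Hz.
#' @param role stream role, `"target"` or `"masker"`.
#' @return An object of class `envelope_series`: the numeric vector with
#'   `fs` and `role` attributes.
#' @examples
#' env <- envelope_series(abs(sin(seq(0, 2 * pi, length.out = 100))), fs = 100)
#' env_fs(env)
#' @export
envelope_series <- function(x, fs, role = c("target", "masker")) {
  role <- match.arg(role)
  check_number(fs, "fs", positive = TRUE)
  if (!is.numeric(x)) stop_invalid("envelope samples must be numeric")
  check_no_na(x, "x")
  if (any(x < 0)) stop_invalid("envelope samples must be nonnegative")
  structure(as.numeric(x), fs = fs, role = role, class = "envelope_series")
}

#' @rdname envelope_series
#' @param env an `envelope_series`.
#' @export
env_fs <- function(env) attr(env, "fs")

#' @rdname envelope_series
#' @export
env_role <- function(env) attr(env, "role")

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %s stream, %d samples @ %g Hz (%.2f s)\n",
              env_role(x), length(x), env_fs(x), length(x) / env_fs(x)))
  invisible(x)
}

#' Multichannel EEG recording
#'
#' A channels-by-time matrix of EEG samples (microvolts) with sampling rate,
#' channel labels, and subject/trial/condition provenance.
#'
#' @param data numeric matrix, channels in rows, time in columns.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels (default `ch01`...).
#' @param subject,trial,condition optional provenance metadata.
#' @return An object of class `eeg_recording`.
#' @examples
#' eeg <- eeg_recording(matrix(rnorm(200), nrow = 2), fs = 100)
#' dim(eeg$data)
#' @export
eeg_recording <- function(data, fs, channels = NULL, subject = NA,
                          trial = NA, condition = NA) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_invalid("`data` must be a numeric channels x time matrix")
  check_number(fs, "fs", positive = TRUE)
  if (is.null(channels))
    channels <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channels) != nrow(data))
    stop_invalid("`channels` length must equal nrow(data)")
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 subject = subject, trial = trial, condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz [subject=%s trial=%s condition=%s]\n",
    nrow(x$data), ncol(x$data), x$fs, x$subject, x$trial, x$condition))
  invisible(x)
}

n_channels <- function(eeg) nrow(eeg$data)
n_samples <- function(eeg) ncol(eeg$data)

#' Time-lag grid for TRF estimation
#'
#' Uniform grid of stimulus-to-response lags covering -100 to 400 ms (the
#' span that contains the P1, N1 and P2 components) at the sample spacing of
#' the working rate.  At 100 Hz this yields K = 51 lags including 0.
#'
#' @param fs sampling rate in Hz.
#' @param tmin_ms,tmax_ms grid limits in milliseconds (defaults -100, 400).
#' @return Object of class `lag_grid` with fields `lags_ms`, `lags_samples`,
#'   `K`, `fs`.
#' @examples
#' g <- lag_grid(100)
#' g$K  # 51
#' @export
lag_grid <- function(fs, tmin_ms = -100, tmax_ms = 400) {
  check_number(fs, "fs", positive = TRUE)
  if (tmin_ms > 0 || tmax_ms <= tmin_ms)
    stop_invalid("lag grid must satisfy tmin_ms <= 0 < tmax_ms")
  step <- 1000 / fs
  lags_samples <- seq(round(tmin_ms / step), round(tmax_ms / step))
  lags_ms <- lags_samples * step
  structure(list(lags_ms = lags_ms, lags_samples = as.integer(lags_samples),
                 K = length(lags_ms), fs = fs),
            class = "lag_grid")
}

#' @export
print.lag_grid <- function(x, ...) {
  cat(sprintf("<lag_grid> K=%d lags, [%g, %g] ms @ %g Hz\n",
              x$K, min(x$lags_ms), max(x$lags_ms), x$fs))
  invisible(x)
}

#' Set of estimated temporal response functions
#'
#' Per-channel, per-predictor TRF coefficients on a lag grid
#' (microvolts per unit envelope).
#'
#' @param coefficients numeric array channels x predictors x K.
#' @param grid a [lag_grid()].
#' @param predictors character vector of distinct predictor roles
#'   (e.g. `c("target", "masker")`).
#' @param channels channel labels (default from array dimnames or `ch..`).
#' @param provenance named list of subject/trial/condition metadata.
#' @return Object of class `trf_set`.
#' @export
trf_set <- function(coefficients, grid, predictors,
                    channels = NULL, provenance = list()) {
  if (!is.array(coefficients) || length(dim(coefficients)) != 3L)
    stop_invalid("`coefficients` must be a 3-d array (channels x predictors x lags)")
  check_no_na(coefficients, "coefficients")
  if (dim(coefficients)[3] != grid$K)
    stop_invalid("third dimension of `coefficients` must equal grid$K")
  if (dim(coefficients)[2] != length(predictors))
    stop_invalid("second dimension must match length(predictors)")
  if (anyDuplicated(predictors))
    stop_invalid("predictor roles must be distinct")
  if (is.null(channels))
    channels <- dimnames(coefficients)[[1]] %||%
      sprintf("ch%02d", seq_len(dim(coefficients)[1]))
  dimnames(coefficients) <- list(channels, predictors, NULL)
  structure(list(coefficients = coefficients, grid = grid,
                 predictors = predictors, channels = channels,
                 provenance = provenance),
            class = "trf_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trf_set <- function(x, ...) {
  cat(sprintf("<trf_set> %d channels x %d predictors (%s) x %d lags\n",
              dim(x$coefficients)[1], dim(x$coefficients)[2],
              paste(x$predictors, collapse = ", "), x$grid$K))
  invisible(x)
}
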