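## Envelope extraction and EEG conditioning.
##
## The pre-installed stack has no IIR filter-design package, so filtering is
## done by applying the analytic Butterworth magnitude response in the
## frequency domain (with reflection padding against wrap-around).  This is
## exactly zero-phase and has the same magnitude response as the
## forward-backward (filtfilt) application of the corresponding time-domain
## filter, which is what peak-latency analysis requires.

#' Filter specification
#'
#' @param kind `"bandpass"` or `"notch"` (band-stop).
#' @param band two-element Hz vector, low < high.
#' @param order Butterworth order of the effective (zero-phase) magnitude
#'   response; default 6.  Must be even when `zero_phase = TRUE` so that the
#'   response can be realized as a forward-backward pass of order/2.
#' @param zero_phase logical; zero-phase application (default `TRUE`).
#' @return Object of class `filter_spec`.
#' @examples
#' filter_spec("bandpass", c(1, 8))
#' @export
filter_spec <- function(kind = c("bandpass", "notch"), band, order = 6L,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (length(band) != 2L || !is.numeric(band) || band[1] >= band[2] ||
      band[1] < 0)
    stop_invalid("`band` must be an increasing nonnegative Hz pair")
  check_number(order, "order", positive = TRUE, integerish = TRUE)
  if (zero_phase && order %% 2 != 0)
    stop_invalid("`order` must be even for zero-phase application")
  structure(list(kind = kind, band = as.numeric(band),
                 order = as.integer(order), zero_phase = zero_phase),
            class = "filter_spec")
}

#' Stimulus/EEG alignment specification
#'
#' @param stimulus_delay_ms acoustic presentation delay of the stimulus
#'   relative to the EEG event markers, in milliseconds (default 49.1, the
#'   measured loudspeaker-path latency).
#' @param edge_trim_s seconds removed from each end of both series to
#'   suppress filter edge effects (default 1).
#' @return Object of class `alignment_spec`.
#' @export
alignment_spec <- function(stimulus_delay_ms = 49.1, edge_trim_s = 1) {
  check_number(stimulus_delay_ms, "stimulus_delay_ms")
  check_number(edge_trim_s, "edge_trim_s", nonneg = TRUE)
  structure(list(stimulus_delay_ms = stimulus_delay_ms,
                 edge_trim_s = edge_trim_s),
            class = "alignment_spec")
}

## Butterworth squared magnitude response at frequencies f (Hz).
## bandpass:  |H|^2 = 1 / (1 + W^(2n)),  W = (f^2 - f1 f2) / (f (f2 - f1))
## band-stop: power complement, |H|^2 = W^(2n) / (1 + W^(2n))
butter_mag2 <- function(f, band, order, kind) {
  f1 <- band[1]; f2 <- band[2]
  W <- ifelse(f == 0, Inf, (f^2 - f1 * f2) / (f * (f2 - f1)))
  W2n <- abs(W)^(2 * order)
  if (kind == "bandpass") {
    ifelse(is.infinite(W2n), 0, 1 / (1 + W2n))
  } else {
    ifelse(is.infinite(W2n), 1, W2n / (1 + W2n))
  }
}

## Zero-phase frequency-domain filter with reflection padding.
apply_filter <- function(x, fs, spec) {
  n <- length(x)
  if (n < 4L) stop_invalid("signal too short to filter")
  npad <- min(n - 1L, max(16L, ceiling(3 * fs / max(spec$band[1], 0.5))))
  xp <- c(2 * x[1] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  m <- length(xp)
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)             # fold to [0, fs/2]
  H <- sqrt(butter_mag2(f, spec$band, spec$order, spec$kind))
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / m
  y[(npad + 1L):(npad + n)]
}

## Analytic signal via the FFT construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Band-limited (spectral truncation/zero-padding) resampling to m samples.
resample_fft <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  Y[1] <- X[1]
  if (m < n) {
    hk <- ceiling(m / 2) - 1       # positive bins strictly below new Nyquist
    if (hk >= 1) {
      k <- 1:hk
      Y[k + 1] <- X[k + 1]
      Y[m - k + 1] <- X[n - k + 1]
    }
    ## conjugate source bins +/- m/2 fold onto the (real) new Nyquist bin
    if (m %% 2 == 0) Y[m / 2 + 1] <- X[m / 2 + 1] + X[n - m / 2 + 1]
  } else {
    hk <- ceiling(n / 2) - 1
    if (hk >= 1) {
      k <- 1:hk
      Y[k + 1] <- X[k + 1]
      Y[m - k + 1] <- X[n - k + 1]
    }
    ## the old (real) Nyquist bin splits symmetrically into +/- n/2
    if (n %% 2 == 0) {
      Y[n / 2 + 1] <- X[n / 2 + 1] / 2
      Y[m - n / 2 + 1] <- X[n / 2 + 1] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Extract a speech envelope
#'
#' Computes the magnitude of the analytic (Hilbert) signal, band-pass
#' filters it (default 1-8 Hz, 6th-order Butterworth magnitude, zero
#' phase), and resamples to the working rate.  Small negative excursions
#' introduced by band-pass filtering are clipped to zero so the result is a
#' valid nonnegative envelope.
#'
#' @param signal numeric vector, the acoustic waveform (or any series whose
#'   envelope is wanted).
#' @param fs_in input sampling rate in Hz.
#' @param fs_out output rate in Hz (default 100); must not exceed `fs_in`.
#' @param spec a [filter_spec()]; default band-pass 1-8 Hz, order 6.
#' @param role stream role recorded on the result.
#' @return An [envelope_series()] at `fs_out`.
#' @examples
#' fs <- 1000
#' t <- seq(0, 4, by = 1 / fs)
#' x <- (1 + 0.8 * cos(2 * pi * 4 * t)) * sin(2 * pi * 200 * t)
#' env <- extract_envelope(x, fs, 100)
#' @export
extract_envelope <- function(signal, fs_in, fs_out = 100,
                             spec = filter_spec("bandpass", c(1, 8)),
                             role = "target") {
  check_number(fs_in, "fs_in", positive = TRUE)
  check_number(fs_out, "fs_out", positive = TRUE)
  if (fs_out > fs_in)
    stop_invalid("`fs_out` must not exceed `fs_in`")
  if (fs_in < 2 * spec$band[2])
    stop_invalid("`fs_in` must be at least twice the filter band's upper edge")
  check_no_na(signal, "signal")
  if (length(signal) < 10L * spec$order)
    stop_invalid("signal too short for requested filter order")
  if (all(signal == 0)) {
    m <- round(length(signal) * fs_out / fs_in)
    return(envelope_series(numeric(m), fs_out, role))
  }
  env <- Mod(analytic_signal(signal))
  env_f <- apply_filter(env, fs_in, spec)
  ## band-pass removes DC; restore the mean so the envelope stays positive
  env_f <- env_f + mean(env)
  m <- round(length(signal) * fs_out / fs_in)
  out <- resample_fft(env_f, m)
  envelope_series(pmax(out, 0), fs_out, role)
}

#' Align a stimulus envelope with an EEG recording
#'
#' Advances the envelope by the stimulus presentation delay (rounded to the
#' nearest sample at the working rate), crops both series to their common
#' support, and trims `edge_trim_s` seconds from both ends of each.
#'
#' @param env an [envelope_series()].
#' @param eeg an [eeg_recording()] at the same rate.
#' @param spec an [alignment_spec()].
#' @return List with elements `env` and `eeg`, equal length.
#' @export
trim_and_align <- function(env, eeg, spec = alignment_spec()) {
  if (!inherits(env, "envelope_series") || !inherits(eeg, "eeg_recording"))
    stop_invalid("`env`/`eeg` must be envelope_series / eeg_recording")
  fs <- env_fs(env)
  if (abs(fs - eeg$fs) > 1e-9)
    stop_invalid("envelope and EEG must share a sampling rate")
  shift <- round(spec$stimulus_delay_ms * fs / 1000)
  ev <- as.numeric(env)
  if (shift > 0) ev <- ev[-seq_len(shift)]
  if (shift < 0) ev <- c(numeric(-shift), ev)
  L <- min(length(ev), n_samples(eeg))
  ntrim <- round(spec$edge_trim_s * fs)
  keep <- if (L > 2 * ntrim) seq.int(ntrim + 1L, L - ntrim) else integer(0)
  if (length(keep) < 2 * fs)
    stop(structure(class = c("trfcomp_alignment_error", "error", "condition"),
                   list(message = "insufficient overlap after shift/trim (< 2 s)",
                        call = sys.call())))
  list(env = envelope_series(ev[keep], fs, env_role(env)),
       eeg = eeg_recording(eeg$data[, keep, drop = FALSE], fs, eeg$channels,
                           eeg$subject, eeg$trial, eeg$condition))
}

#' Re-reference and filter a raw EEG recording
#'
#' Subtracts the mean of the reference channels (e.g. the two mastoids)
#' from every channel, then applies the given filters in order.  With empty
#' filter and reference lists this is the identity.
#'
#' @param eeg an [eeg_recording()].
#' @param filters list of [filter_spec()] applied in order.
#' @param reference_channels character vector of channel labels to use as
#'   reference; empty for no re-referencing.
#' @return An [eeg_recording()] at the same rate.
#' @export
preprocess_raw_eeg <- function(eeg, filters = list(),
                               reference_channels = character(0)) {
  if (!inherits(eeg, "eeg_recording"))
    stop_invalid("`eeg` must be an eeg_recording")
  dat <- eeg$data
  if (length(reference_channels)) {
    missing <- setdiff(reference_channels, eeg$channels)
    if (length(missing))
      stop(structure(class = c("trfcomp_key_error", "error", "condition"),
                     list(message = paste("unknown reference channel(s):",
                                          paste(missing, collapse = ", ")),
                          call = sys.call())))
    ref <- colMeans(dat[reference_channels, , drop = FALSE])
    dat <- sweep(dat, 2L, ref, "-")
  }
  for (sp in filters) {
    if (!inherits(sp, "filter_spec")) stop_invalid("filters must be filter_spec")
    dat <- t(apply(dat, 1L, apply_filter, fs = eeg$fs, spec = sp))
    if (n_channels(eeg) == 1L) dat <- matrix(dat, nrow = 1L)
  }
  eeg_recording(dat, eeg$fs, eeg$channels, eeg$subject, eeg$trial,
                eeg$condition)
}
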