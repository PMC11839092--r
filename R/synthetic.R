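## Synthetic auditory-EEG generator.
##
## Emulates the design of a two-talker selective-attention experiment:
## 30 subjects x 40 trials x 2 hearing-aid noise-reduction (NR) conditions,
## 64-channel EEG at 100 Hz, trials of ~31 s usable duration.  Each trial's
## clean EEG is the sum of target- and masker-envelope convolutions with
## P1/N1/P2-shaped channel kernels; a configurable static nonlinearity and
## additive white noise produce the observed EEG.  NR_on raises the
## target-to-masker gain contrast and lowers the noise level.

#' Simulation configuration
#'
#' Defaults encode the emulated experimental design: 30 subjects, 40 trials
#' per NR condition (80 per subject), 64 channels at 100 Hz, 31 s usable
#' trials.  Condition gains follow the qualitative NR ordering: NR on
#' amplifies the attended target relative to the ignored masker and lowers
#' the noise floor.
#'
#' @param n_subjects,n_trials_per_condition,n_channels design counts.
#' @param conditions condition labels (default `NR_on`, `NR_off`).
#' @param fs sampling rate, Hz.
#' @param trial_duration usable trial duration, seconds;
#'   `trial_duration * fs` must be an integer sample count.
#' @param target_gain,masker_gain named per-condition gains (dimensionless).
#' @param noise_sd named per-condition additive noise SD, microvolts.
#' @param nonlinearity_kind `"none"`, `"quadratic"` (`v + gamma * v^2`) or
#'   `"saturating"` (`tanh(gamma * v) / gamma`).
#' @param nonlinearity_strength signed curvature parameter gamma;
#'   with `kind = "none"` it is ignored and the regime is exactly linear.
#' @param seed integer master seed; all outputs are pure functions of
#'   (config, seed).
#' @return Object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_channels = 4, trial_duration = 5)
#' @export
sim_config <- function(n_subjects = 30, n_trials_per_condition = 40,
                       conditions = c("NR_on", "NR_off"),
                       n_channels = 64, fs = 100, trial_duration = 31,
                       target_gain = c(NR_on = 1.0, NR_off = 0.7),
                       masker_gain = c(NR_on = 0.5, NR_off = 0.7),
                       noise_sd = c(NR_on = 1.0, NR_off = 1.5),
                       nonlinearity_kind = c("none", "quadratic", "saturating"),
                       nonlinearity_strength = 0,
                       seed = 1L) {
  nonlinearity_kind <- match.arg(nonlinearity_kind)
  check_number(n_subjects, "n_subjects", positive = TRUE, integerish = TRUE)
  check_number(n_trials_per_condition, "n_trials_per_condition",
               positive = TRUE, integerish = TRUE)
  check_number(n_channels, "n_channels", positive = TRUE, integerish = TRUE)
  check_number(fs, "fs", positive = TRUE)
  check_number(trial_duration, "trial_duration", positive = TRUE)
  if (abs(trial_duration * fs - round(trial_duration * fs)) > 1e-8)
    stop_invalid("trial_duration * fs must be an integer sample count")
  check_number(nonlinearity_strength, "nonlinearity_strength")
  check_number(seed, "seed", integerish = TRUE)
  if (!length(conditions) || anyDuplicated(conditions))
    stop_invalid("`conditions` must be distinct labels")
  pick <- function(x, name) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, length(conditions)),
                                                conditions)
    if (!all(conditions %in% names(x)))
      stop_invalid(sprintf("`%s` must name every condition", name))
    x[conditions]
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    conditions = conditions,
    n_channels = as.integer(n_channels),
    fs = fs, trial_duration = trial_duration,
    target_gain = pick(target_gain, "target_gain"),
    masker_gain = pick(masker_gain, "masker_gain"),
    noise_sd = pick(noise_sd, "noise_sd"),
    nonlinearity_kind = nonlinearity_kind,
    nonlinearity_strength = nonlinearity_strength,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d subjects x %d trials x %d conditions (%s), %d ch @ %g Hz, %g s, nonlinearity=%s\n",
    x$n_subjects, x$n_trials_per_condition, length(x$conditions),
    paste(x$conditions, collapse = "/"), x$n_channels, x$fs,
    x$trial_duration, x$nonlinearity_kind))
  invisible(x)
}

#' Theoretical chance level of a c-alternative forced choice, percent
#' @param c number of alternatives (default 2).
#' @export
theoretical_chance_level <- function(c = 2) {
  check_number(c, "c", positive = TRUE, integerish = TRUE)
  if (c < 2) stop_invalid("`c` must be >= 2")
  100 / c
}

#' Generate a synthetic speech envelope
#'
#' Rectified, band-limited (1-8 Hz Butterworth magnitude) Gaussian noise
#' with a positive floor: unit-SD band-limited noise shifted up by one SD
#' and clipped at zero.  This matches the spectral passband of the
#' preprocessed speech envelopes without requiring audio.
#'
#' @param duration seconds (> 0).
#' @param fs sampling rate in Hz (>= 20).
#' @param seed integer seed; output is deterministic given the seed.
#' @param role stream role recorded on the result.
#' @return An [envelope_series()] of `round(duration * fs)` samples.
#' @examples
#' env <- gen_envelope(31, 100, seed = 1)
#' length(env)  # 3100
#' @export
gen_envelope <- function(duration, fs, seed, role = "target") {
  check_number(duration, "duration", positive = TRUE)
  check_number(fs, "fs", positive = TRUE)
  if (fs < 20) stop_invalid("`fs` must be >= 20 Hz")
  check_number(seed, "seed", integerish = TRUE)
  n <- round(duration * fs)
  z <- with_seed(seed, stats::rnorm(n))
  z <- apply_filter(z, fs, filter_spec("bandpass", c(1, 8)))
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  envelope_series(pmax(z + 1, 0), fs, role)
}

#' Ground-truth TRF kernels
#'
#' Each channel kernel is the sum of three Gaussian bumps — P1 (positive),
#' N1 (negative), P2 (positive) — at the configured latencies, scaled by a
#' per-channel gain, and identically zero at negative lags (causality).
#' Default latencies sit on the 10-ms grid at 100 Hz: P1 60 ms, N1 100 ms,
#' P2 200 ms, inside the canonical component windows.
#'
#' @param config a [sim_config()] (supplies `n_channels` and `fs`).
#' @param seed integer seed (used only for `region_gains = "random"`).
#' @param peak_params data.frame with columns `component`, `latency_ms`,
#'   `width_ms`, `amplitude` (microvolts; N1 negative, P1/P2 positive).
#' @param region_gains per-channel scaling: numeric vector of length
#'   `n_channels`, or `"topographic"` (default; smooth fronto-central
#'   maximum), or `"uniform"`.
#' @param grid a [lag_grid()]; must cover at least \[-100, 400\] ms.
#' @return Object of class `ground_truth_trf` with fields `kernel`
#'   (channels x K), `lag_grid`, `peak_params`, `region_gains`.
#' @export
gen_ground_truth_trf <- function(config, seed = config$seed,
                                 peak_params = default_peak_params(),
                                 region_gains = "topographic",
                                 grid = lag_grid(config$fs)) {
  if (min(grid$lags_ms) > -100 || max(grid$lags_ms) < 400)
    stop_invalid("lag grid must cover at least [-100, 400] ms")
  stopifnot(all(c("component", "latency_ms", "width_ms", "amplitude") %in%
                  names(peak_params)))
  if (any(peak_params$latency_ms < min(grid$lags_ms) |
            peak_params$latency_ms > max(grid$lags_ms)))
    stop_invalid("peak latency outside the lag grid")
  n1 <- peak_params$amplitude[peak_params$component == "N1"]
  if (length(n1) && any(n1 >= 0))
    stop_invalid("N1 amplitude must be negative")
  pp <- peak_params$amplitude[peak_params$component %in% c("P1", "P2")]
  if (length(pp) && any(pp <= 0))
    stop_invalid("P1/P2 amplitudes must be positive")

  nch <- config$n_channels
  gains <- if (is.numeric(region_gains)) {
    if (length(region_gains) != nch)
      stop_invalid("`region_gains` must have one value per channel")
    region_gains
  } else if (identical(region_gains, "uniform")) {
    rep(1, nch)
  } else if (identical(region_gains, "topographic")) {
    ## smooth fronto-central topography in [0.4, 1]
    0.4 + 0.6 * (0.5 + 0.5 * cos(2 * pi * (seq_len(nch) - 1) / nch))
  } else stop_invalid("unknown `region_gains` specification")

  shape <- numeric(grid$K)
  for (i in seq_len(nrow(peak_params))) {
    shape <- shape + peak_params$amplitude[i] *
      exp(-0.5 * ((grid$lags_ms - peak_params$latency_ms[i]) /
                    peak_params$width_ms[i])^2)
  }
  shape[grid$lags_ms < 0] <- 0
  kernel <- outer(gains, shape)
  structure(list(kernel = kernel, lag_grid = grid, peak_params = peak_params,
                 region_gains = gains),
            class = "ground_truth_trf")
}

#' @rdname gen_ground_truth_trf
#' @export
default_peak_params <- function() {
  data.frame(component = c("P1", "N1", "P2"),
             latency_ms = c(60, 100, 200),
             width_ms = c(12, 16, 30),
             amplitude = c(0.5, -1.0, 0.8))
}

## Per-subject kernel variation: component latencies jittered +/-10 ms,
## amplitudes +/-20%, uniformly.
jitter_peak_params <- function(peak_params, seed) {
  with_seed(seed, {
    pp <- peak_params
    pp$latency_ms <- pp$latency_ms + stats::runif(nrow(pp), -10, 10)
    pp$amplitude <- pp$amplitude * (1 + stats::runif(nrow(pp), -0.2, 0.2))
    pp
  })
}

apply_nonlinearity <- function(v, kind, gamma) {
  switch(kind,
         none = v,
         quadratic = v + gamma * v^2,
         saturating = if (gamma == 0) v else tanh(gamma * v) / gamma,
         stop_invalid("unknown nonlinearity kind"))
}

#' Simulate one trial
#'
#' Clean EEG is `target_gain * (kernel * x_T) + masker_gain * (kernel *
#' x_M)` (convolution over the kernel's lag grid, zero-padded edges);
#' the observed EEG applies the configured static nonlinearity sample-wise
#' and adds white Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param trf a `ground_truth_trf` with `n_channels` rows.
#' @param seed integer seed for envelopes and noise.
#' @param condition condition label (selects gains and noise SD).
#' @param subject,trial provenance metadata.
#' @param target_env,masker_env optional [envelope_series()] overriding the
#'   generated envelopes (e.g. an impulse for convolution identity checks).
#' @return Object of class `synthetic_trial`: list with `target_env`,
#'   `masker_env`, `clean_eeg`, `observed_eeg`, `metadata`.
#' @export
simulate_trial <- function(config, trf, seed, condition = config$conditions[1],
                           subject = 1L, trial = 1L,
                           target_env = NULL, masker_env = NULL) {
  if (!condition %in% config$conditions)
    stop_invalid("unknown condition label")
  if (nrow(trf$kernel) != config$n_channels)
    stop(structure(class = c("trfcomp_dimension_error", "error", "condition"),
                   list(message = "kernel channel count does not match config",
                        call = sys.call())))
  fs <- config$fs
  n <- round(config$trial_duration * fs)
  if (is.null(target_env))
    target_env <- gen_envelope(config$trial_duration, fs,
                               derive_seed(seed, "envT"), role = "target")
  if (is.null(masker_env))
    masker_env <- gen_envelope(config$trial_duration, fs,
                               derive_seed(seed, "envM"), role = "masker")
  if (length(target_env) != n || length(masker_env) != n)
    stop(structure(class = c("trfcomp_dimension_error", "error", "condition"),
                   list(message = "envelope length does not match trial duration",
                        call = sys.call())))
  XT <- build_lag_matrix(target_env, trf$lag_grid)
  XM <- build_lag_matrix(masker_env, trf$lag_grid)
  gT <- config$target_gain[[condition]]
  gM <- config$masker_gain[[condition]]
  clean <- gT * (trf$kernel %*% XT) + gM * (trf$kernel %*% XM)
  sdn <- config$noise_sd[[condition]]
  kind <- config$nonlinearity_kind
  gamma <- if (kind == "none") 0 else config$nonlinearity_strength
  observed <- apply_nonlinearity(clean, kind, gamma)
  if (sdn > 0) {
    noise <- with_seed(derive_seed(seed, "noise"),
                       matrix(stats::rnorm(length(clean), sd = sdn),
                              nrow = nrow(clean)))
    observed <- observed + noise
  }
  labels <- sprintf("ch%02d", seq_len(config$n_channels))
  structure(list(
    target_env = target_env, masker_env = masker_env,
    clean_eeg = eeg_recording(clean, fs, labels, subject, trial, condition),
    observed_eeg = eeg_recording(observed, fs, labels, subject, trial,
                                 condition),
    metadata = list(subject = subject, trial = trial, condition = condition)),
    class = "synthetic_trial")
}

#' Trial design table of a configuration
#'
#' Enumerates the (subject, condition, trial) design without simulating
#' any data; `gen_dataset()` materializes exactly these rows in this order.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `subject`, `condition`, `trial`.
#' @examples
#' nrow(dataset_design(sim_config()))  # 2400
#' @export
dataset_design <- function(config) {
  expand.grid(trial = seq_len(config$n_trials_per_condition),
              condition = config$conditions,
              subject = seq_len(config$n_subjects),
              KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("subject", "condition", "trial")]
}

#' Generate a full synthetic dataset
#'
#' Draws one jittered kernel per subject (deterministic in the config
#' seed), then simulates every (subject, condition, trial) cell of
#' [dataset_design()] in stable order.
#'
#' @param config a [sim_config()].
#' @param region_gains forwarded to [gen_ground_truth_trf()].
#' @return List of class `synthetic_dataset`: `trials` (list of
#'   `synthetic_trial`), `design` (data.frame), `subject_trfs` (list of
#'   `ground_truth_trf` keyed by subject), `config`.
#' @export
gen_dataset <- function(config, region_gains = "topographic") {
  design <- dataset_design(config)
  subject_trfs <- lapply(seq_len(config$n_subjects), function(s) {
    pp <- jitter_peak_params(default_peak_params(),
                             derive_seed(config$seed, "subject_trf", s))
    gen_ground_truth_trf(config, peak_params = pp,
                         region_gains = region_gains)
  })
  trials <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    s <- design$subject[i]; cond <- design$condition[i]; tr <- design$trial[i]
    trials[[i]] <- simulate_trial(
      config, subject_trfs[[s]],
      seed = derive_seed(config$seed, "trial", s, cond, tr),
      condition = cond, subject = s, trial = tr)
  }
  structure(list(trials = trials, design = design,
                 subject_trfs = subject_trfs, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d trials (%d subjects x %d conditions x %d trials)\n",
              length(x$trials), x$config$n_subjects,
              length(x$config$conditions), x$config$n_trials_per_condition))
  invisible(x)
}
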