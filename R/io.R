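## Plain-text serialization: envelopes as single-column delimited series
## with a header, EEG as delimited matrices with a JSON sidecar, TRFs as
## long tables (channel, predictor, lag_ms, coefficient) + JSON metadata.

#' Write / read an envelope series
#'
#' Single-column TSV with `fs` and `role` header comment lines.
#'
#' @param env an [envelope_series()].
#' @param path file path.
#' @return `read_envelope` returns an [envelope_series()];
#'   `write_envelope` returns `path` invisibly.
#' @export
write_envelope <- function(env, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", env_fs(env)),
               sprintf("# role=%s", env_role(env)), "value"), con)
  writeLines(format(as.numeric(env), digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("# fs=", "", hdr[1], fixed = TRUE))
  role <- sub("# role=", "", hdr[2], fixed = TRUE)
  vals <- utils::read.table(path, skip = 2, header = TRUE)$value
  envelope_series(vals, fs, role)
}

#' Write / read an EEG recording
#'
#' Data as a channels x time TSV (channel label column first), metadata
#' (`fs`, subject/trial/condition) in a `.json` sidecar.
#'
#' @param eeg an [eeg_recording()].
#' @param path data file path; the sidecar is `paste0(path, ".json")`.
#' @export
write_eeg <- function(eeg, path) {
  dt <- data.table::data.table(channel = eeg$channels)
  dt <- cbind(dt, data.table::as.data.table(eeg$data))
  data.table::fwrite(dt, path, sep = "\t")
  meta <- list(fs = eeg$fs, subject = eeg$subject, trial = eeg$trial,
               condition = eeg$condition, n_channels = n_channels(eeg),
               n_samples = n_samples(eeg))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(path, sep = "\t")
  channels <- dt$channel
  dat <- as.matrix(dt[, -1])
  dimnames(dat) <- NULL
  eeg_recording(dat, meta$fs, channels,
                meta$subject %||% NA, meta$trial %||% NA,
                meta$condition %||% NA)
}

#' Write / read a TRF set
#'
#' Long-format TSV (channel, predictor, lag_ms, coefficient) with a JSON
#' metadata sidecar (rate, lag-grid limits, provenance).
#'
#' @param trf a [trf_set()].
#' @param path data file path; sidecar at `paste0(path, ".json")`.
#' @export
write_trf <- function(trf, path) {
  g <- trf$grid
  long <- data.table::CJ(lag_idx = seq_len(g$K),
                         predictor = trf$predictors,
                         channel = trf$channels, sorted = FALSE)
  long[, `:=`(lag_ms = g$lags_ms[lag_idx],
              coefficient = trf$coefficients[cbind(
                match(channel, trf$channels),
                match(predictor, trf$predictors), lag_idx)])]
  data.table::fwrite(long[, list(channel, predictor, lag_ms, coefficient)],
                     path, sep = "\t")
  meta <- list(fs = g$fs, tmin_ms = min(g$lags_ms), tmax_ms = max(g$lags_ms),
               predictors = trf$predictors, provenance = trf$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trf
#' @export
read_trf <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- data.table::fread(path, sep = "\t")
  grid <- lag_grid(meta$fs, meta$tmin_ms, meta$tmax_ms)
  channels <- unique(long$channel)
  predictors <- unique(long$predictor)
  coefs <- array(0, dim = c(length(channels), length(predictors), grid$K))
  coefs[cbind(match(long$channel, channels),
              match(long$predictor, predictors),
              match(round(long$lag_ms, 6), round(grid$lags_ms, 6)))] <-
    long$coefficient
  trf_set(coefs, grid, predictors, channels,
          provenance = as.list(meta$provenance %||% list()))
}
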