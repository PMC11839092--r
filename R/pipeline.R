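## Six-step pipeline orchestration:
##   (1) SNR of original EEG  (2) TRFs beta_orig from original EEG
##   (3) predicted EEG        (4) binning-based compensation -> Y_comp
##   (5) SNR of compensated   (6) TRFs beta_comp from compensated EEG
## plus evaluation (peaks, variance, residual maps, SNR differences) and
## cluster permutation tests against mismatched-pair noise TRFs.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] (the pipeline simulates its input dataset;
#'   pass a dataset produced elsewhere to [run_pipeline()] directly via
#'   `dataset`).
#' @param boost a [boost_config()].
#' @param binning a [binning_config()].
#' @param permutation a [permutation_config()].
#' @param windows peak windows in seconds (named list `n1`, `p2`).
#' @param groups channel grouping (named list; default
#'   [default_channel_groups()] when the montage matches, else a single
#'   `all` group).
#' @param out_dir output directory for stage artifacts.
#' @param seed global seed; every stage seed is derived from it
#'   deterministically.
#' @param run_cluster_tests logical; cluster permutation tests against the
#'   noise TRF (the most expensive stage) can be disabled.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), boost = boost_config(),
                            binning = binning_config(),
                            permutation = permutation_config(min_neighbors = 1L),
                            windows = list(n1 = c(0.08, 0.12),
                                           p2 = c(0.18, 0.25)),
                            groups = NULL, out_dir = tempfile("trfcomp_run_"),
                            seed = 1L, run_cluster_tests = TRUE) {
  check_number(seed, "seed", integerish = TRUE)
  structure(list(sim = sim, boost = boost, binning = binning,
                 permutation = permutation, windows = windows,
                 groups = groups, out_dir = out_dir,
                 seed = as.integer(seed),
                 run_cluster_tests = isTRUE(run_cluster_tests)),
            class = "pipeline_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

config_fingerprint <- function(config) {
  semantic <- config[setdiff(names(config), "out_dir")]  # paths are not semantic
  fnv1a_hex(jsonlite::toJSON(strip_classes(semantic), auto_unbox = TRUE,
                             digits = NA, null = "null"))
}

stage_log <- function(verbose, stage, ...) {
  if (verbose)
    message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the six-step pipeline
#'
#' Simulates (or consumes) a dataset, then per trial: computes original
#' SNR, estimates `beta_orig` by boosting, predicts the EEG, compensates
#' nonlinearities channel-wise, computes compensated SNR, and re-estimates
#' `beta_comp`.  Aggregates peaks, variance profiles, residual maps and
#' SNR differences per condition and channel group, runs cluster
#' permutation tests against mismatched-pair noise TRFs, and persists every
#' table under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional pre-built `synthetic_dataset`; default
#'   `gen_dataset(config$sim)` (with the sim seed re-derived from the
#'   global seed).
#' @param verbose log stage progress to stderr.
#' @return Object of class `run_manifest`: stage timestamps, config
#'   fingerprint, seeds, output inventory, and a `results` list with all
#'   in-memory tables.
#' @export
run_pipeline <- function(config, dataset = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamps <- list()
  tick <- function(stage) stamps[[stage]] <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")

  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "simulate")
  if (is.null(dataset)) dataset <- gen_dataset(sim)
  trials <- dataset$trials
  design <- dataset$design
  fs <- dataset$config$fs
  grid <- lag_grid(fs)
  tick("simulate")
  stage_log(verbose, "simulate", length(trials), " trials")

  channels <- trials[[1]]$observed_eeg$channels
  groups <- config$groups
  if (is.null(groups)) {
    mont <- default_montage()
    groups <- if (all(channels %in% mont$channel))
      default_channel_groups() else list(all = channels)
  }

  n_tr <- length(trials)
  snr_rows <- vector("list", n_tr)
  resid_rows <- vector("list", n_tr)
  trf_orig <- vector("list", n_tr)
  trf_comp <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    tr <- trials[[i]]
    y <- tr$observed_eeg
    envs <- list(tr$target_env, tr$masker_env)
    ## (1) original SNR -- noise power taken as the TRF-prediction
    ## residual MSE; it cancels in the SNR difference by construction
    b_orig <- boost_trf(y, envs, config$boost, grid)          # (2)
    pred <- predict_eeg(b_orig, envs, measured = y)           # (3)
    kappa <- mean(pred$mse_per_channel)
    comp <- compensate_recording(y, pred$predicted, config$binning)  # (4)
    snr <- snr_difference(y, comp$compensated, kappa = max(kappa, 1e-12)) # (1+5)
    b_comp <- boost_trf(comp$compensated, envs, config$boost, grid)  # (6)
    trf_orig[[i]] <- b_orig
    trf_comp[[i]] <- b_comp
    snr_rows[[i]] <- data.frame(
      subject = tr$metadata$subject, trial = tr$metadata$trial,
      condition = tr$metadata$condition, channel = channels,
      power_orig = snr$power_orig, power_comp = snr$power_comp,
      snr_diff_db = snr$snr_diff_db, kappa = snr$kappa,
      row.names = NULL)
    resid_rows[[i]] <- data.frame(
      subject = tr$metadata$subject, trial = tr$metadata$trial,
      condition = tr$metadata$condition, channel = channels,
      residual = unname(comp$residuals), row.names = NULL)
    if (verbose && (i %% 10 == 0 || i == n_tr))
      stage_log(verbose, "trf", i, "/", n_tr, " trials done")
  }
  tick("per_trial")

  snr_table <- do.call(rbind, snr_rows)
  resid_table <- do.call(rbind, resid_rows)
  resid_map <- aggregate_residuals(resid_table, config$binning)

  ## subject-level TRF curves: subjects x lags x channels per condition,
  ## per predictor, trial-averaged; for both original and compensated fits
  subject_curves <- function(trfs, predictor) {
    out <- list()
    for (cond in dataset$config$conditions) {
      arr <- array(0, dim = c(dataset$config$n_subjects, grid$K,
                              length(channels)))
      for (s in seq_len(dataset$config$n_subjects)) {
        idx <- which(design$subject == s & design$condition == cond)
        acc <- 0
        for (i in idx)
          acc <- acc + t(trfs[[i]]$coefficients[, predictor, , drop = TRUE])
        arr[s, , ] <- acc / length(idx)
      }
      out[[cond]] <- arr
    }
    out
  }

  peak_tab <- list(); var_tab <- list()
  for (origin in c("orig", "comp")) {
    trfs <- if (origin == "orig") trf_orig else trf_comp
    for (pred_role in trf_orig[[1]]$predictors) {
      curves <- subject_curves(trfs, pred_role)
      for (cond in names(curves)) {
        arr <- curves[[cond]]
        for (g in names(groups)) {
          ch_idx <- match(groups[[g]], channels)
          gc <- apply(arr[, , ch_idx, drop = FALSE], c(1, 2), mean)
          mean_curve <- colMeans(gc)
          pk <- extract_peaks(mean_curve, grid$lags_ms, config$windows)
          peak_tab[[length(peak_tab) + 1L]] <- data.frame(
            origin = origin, predictor = pred_role, condition = cond,
            group = g, n1_amplitude = pk$n1_amplitude,
            n1_latency_s = pk$n1_latency_s,
            p2_amplitude = pk$p2_amplitude,
            p2_latency_s = pk$p2_latency_s)
          if (nrow(gc) >= 2) {
            v <- trf_variance(gc)
            var_tab[[length(var_tab) + 1L]] <- data.frame(
              origin = origin, predictor = pred_role, condition = cond,
              group = g, lag_ms = grid$lags_ms, variance = v)
          }
        }
      }
    }
  }
  peak_table <- do.call(rbind, peak_tab)
  var_table <- if (length(var_tab)) do.call(rbind, var_tab) else NULL
  tick("evaluate")

  ## cluster permutation tests: each condition's target-TRF vs noise TRF
  cluster_results <- list()
  if (config$run_cluster_tests && dataset$config$n_subjects >= 2) {
    pairing <- make_noise_pairing(trials)
    trf_noise <- vector("list", n_tr)
    for (r in seq_len(nrow(pairing))) {
      i <- pairing$eeg_index[r]; j <- pairing$env_index[r]
      tr <- trials[[i]]
      envs <- list(trials[[j]]$target_env, tr$masker_env)
      trf_noise[[i]] <- boost_trf(tr$observed_eeg, envs, config$boost, grid)
    }
    noise_curves <- subject_curves(trf_noise, "target")
    cond_curves <- subject_curves(trf_orig, "target")
    mont <- default_montage()
    adjacency <- if (all(channels %in% mont$channel))
      adjacency_graph(mont[match(channels, mont$channel), ])
    else adjacency_graph(data.frame(channel = channels,
                                    x = seq_along(channels), y = 0),
                         threshold = 1.5)
    pc <- config$permutation
    pc$seed <- derive_seed(config$seed, "permutation")
    for (cond in dataset$config$conditions) {
      cluster_results[[cond]] <- cluster_permutation_test(
        cond_curves[[cond]], noise_curves[[cond]], adjacency, pc,
        lags_s = grid$lags_ms / 1000, channels = channels)
    }
  }
  tick("stats")

  results <- list(snr = snr_table, residual_map = resid_map,
                  residuals = resid_table, peaks = peak_table,
                  variance = var_table, cluster_tests = cluster_results,
                  grid = grid, groups = groups)
  paths <- list(
    snr = file.path(config$out_dir, "snr.tsv"),
    residual_map = file.path(config$out_dir, "residual_map.tsv"),
    residuals = file.path(config$out_dir, "residuals.tsv"),
    peaks = file.path(config$out_dir, "peaks.tsv"),
    variance = file.path(config$out_dir, "variance.tsv"))
  data.table::fwrite(snr_table, paths$snr, sep = "\t")
  data.table::fwrite(as.data.frame(resid_map), paths$residual_map, sep = "\t")
  data.table::fwrite(resid_table, paths$residuals, sep = "\t")
  data.table::fwrite(peak_table, paths$peaks, sep = "\t")
  if (!is.null(var_table))
    data.table::fwrite(var_table, paths$variance, sep = "\t")
  tick("persist")

  manifest <- structure(list(
    config_hash = config_fingerprint(config),
    seed = config$seed,
    stage_seeds = list(simulate = sim$seed,
                       permutation = derive_seed(config$seed, "permutation")),
    timestamps = stamps,
    outputs = paths[file.exists(unlist(paths))],
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    results = results), class = "run_manifest")
  manifest
}

#' Write the run summary
#'
#' One JSON summary (per-condition peaks, SNR differences by group,
#' significant-cluster intervals, residual-map extrema) next to the stage
#' tables.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param path output JSON path.
#' @return The summary list, invisibly.
#' @export
write_summary <- function(manifest, path) {
  res <- manifest$results
  if (is.null(res$peaks) || is.null(res$snr))
    stop(structure(class = c("trfcomp_missing_input", "error", "condition"),
                   list(message = "manifest lacks required stage outputs",
                        call = sys.call())))
  snr_by <- stats::aggregate(snr_diff_db ~ condition + channel,
                             data = res$snr, FUN = mean)
  snr_grp <- lapply(split(snr_by, snr_by$condition), function(d) {
    v <- stats::setNames(d$snr_diff_db, d$channel)
    as.list(group_average(v, res$groups))
  })
  rm_ext <- res$residual_map[order(res$residual_map$mean_residual), ]
  intervals <- lapply(res$cluster_tests, function(ct)
    ct$significant_intervals)
  summary <- list(
    peaks = res$peaks,
    snr_diff_db_by_group = snr_grp,
    significant_intervals = intervals,
    residual_map_extrema = list(
      most_convex = rm_ext[1, , drop = FALSE],
      most_concave = rm_ext[nrow(rm_ext), , drop = FALSE]),
    config_hash = manifest$config_hash)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(summary)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher intended for
#' `Rscript -e 'trfcomp::trfcomp_cli()' <subcommand> --flag value`.
#' Subcommands: `simulate` (write a synthetic dataset), `run-all` (full
#' pipeline + summary), `chance` (empirical chance level).
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly.
#' @export
trfcomp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: trfcomp_cli <simulate|run-all|chance> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  kv <- list()
  rest <- args[-1]
  while (length(rest) >= 2 && startsWith(rest[1], "--")) {
    kv[[sub("^--", "", rest[1])]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  num <- function(key, default) if (is.null(kv[[key]])) default else
    as.numeric(kv[[key]])
  if (cmd == "chance") {
    cat(sprintf("%.4f\n", empirical_chance_level(num("n", 30), num("c", 2),
                                                 num("alpha", 0.05))))
    return(invisible(0L))
  }
  seed <- as.integer(num("seed", 1))
  sim <- sim_config(n_subjects = num("subjects", 2),
                    n_trials_per_condition = num("trials", 2),
                    n_channels = num("channels", 8),
                    trial_duration = num("duration", 10),
                    seed = seed)
  out <- kv[["out"]] %||% "trfcomp_out"
  if (cmd == "simulate") {
    ds <- gen_dataset(sim)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(ds$trials)) {
      tr <- ds$trials[[i]]
      base <- file.path(out, sprintf("trial_%04d", i))
      write_eeg(tr$observed_eeg, paste0(base, "_eeg.tsv"))
      write_envelope(tr$target_env, paste0(base, "_target.tsv"))
      write_envelope(tr$masker_env, paste0(base, "_masker.tsv"))
    }
    message("wrote ", length(ds$trials), " trials to ", out)
    return(invisible(0L))
  }
  if (cmd == "run-all") {
    cfg <- pipeline_config(sim = sim, out_dir = out, seed = seed)
    man <- run_pipeline(cfg, verbose = TRUE)
    write_summary(man, file.path(out, "summary.json"))
    message("pipeline complete; outputs in ", out)
    return(invisible(0L))
  }
  message("unknown subcommand: ", cmd)
  invisible(1L)
}
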