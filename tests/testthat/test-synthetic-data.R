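# Synthetic auditory-EEG generator: envelopes, ground-truth kernels,
# trials, datasets.

test_that("gen_envelope honours its length, nonnegativity and determinism contract", {
  env <- gen_envelope(31, 100, seed = 1)
  expect_s3_class(env, "envelope_series")
  expect_length(env, 3100)
  expect_true(all(env >= 0))
  expect_identical(as.numeric(env), as.numeric(gen_envelope(31, 100, seed = 1)))
  expect_false(identical(as.numeric(env),
                         as.numeric(gen_envelope(31, 100, seed = 2))))
  expect_error(gen_envelope(-1, 100, 1), class = "trfcomp_invalid_argument")
  expect_error(gen_envelope(10, 0, 1), class = "trfcomp_invalid_argument")
})

test_that("envelope spectral power is dominated by the 1-8 Hz band (periodogram oracle)", {
  env <- gen_envelope(310, 100, seed = 5)
  x <- as.numeric(env) - mean(env)
  # direct discrete-Fourier periodogram, one-sided
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 100 / length(x)
  half <- f > 0 & f <= 50
  frac <- sum(p[half & f >= 1 & f <= 8]) / sum(p[half])
  expect_gt(frac, 0.8)
})

test_that("ground-truth kernels have the configured component structure", {
  cfg <- sim_config(n_channels = 8, trial_duration = 5)
  trf <- gen_ground_truth_trf(cfg, region_gains = "uniform")
  g <- trf$lag_grid
  # N1 at 100 ms: most negative value on every channel with nonzero gain
  for (ch in c(1, 5))
    expect_equal(g$lags_ms[which.min(trf$kernel[ch, ])], 100)
  # causality
  expect_true(all(trf$kernel[, g$lags_ms < 0] == 0))
  # all-zero gains -> all-zero kernel
  trf0 <- gen_ground_truth_trf(cfg, region_gains = rep(0, 8))
  expect_true(all(trf0$kernel == 0))
})

test_that("kernel grid sum matches the closed-form Gaussian areas within 1%", {
  cfg <- sim_config(n_channels = 1, trial_duration = 5)
  pp <- default_peak_params()
  trf <- gen_ground_truth_trf(cfg, peak_params = pp, region_gains = "uniform")
  step <- 1000 / cfg$fs
  grid_area <- sum(trf$kernel[1, ]) * step
  closed_form <- sum(pp$amplitude * pp$width_ms * sqrt(2 * pi))
  expect_lt(abs(grid_area - closed_form) / abs(closed_form), 0.01)
})

test_that("invalid kernel requests are rejected", {
  cfg <- sim_config(n_channels = 2, trial_duration = 5)
  pp <- default_peak_params()
  pp$latency_ms[3] <- 900
  expect_error(gen_ground_truth_trf(cfg, peak_params = pp),
               class = "trfcomp_invalid_argument")
  pp <- default_peak_params()
  pp$amplitude[pp$component == "N1"] <- 0.5
  expect_error(gen_ground_truth_trf(cfg, peak_params = pp),
               class = "trfcomp_invalid_argument")
  expect_error(gen_ground_truth_trf(cfg, grid = lag_grid(100, -50, 400)),
               class = "trfcomp_invalid_argument")
})

test_that("simulate_trial is the identity chain in the clean linear regime", {
  tl <- tiny_linear_trial()
  expect_identical(tl$trial$observed_eeg$data, tl$trial$clean_eeg$data)
})

test_that("an impulse target envelope reproduces the translated kernel", {
  cfg <- sim_config(n_subjects = 1, n_channels = 3, trial_duration = 2,
                    noise_sd = c(NR_on = 0, NR_off = 0),
                    target_gain = c(NR_on = 1, NR_off = 1),
                    masker_gain = c(NR_on = 0, NR_off = 0))
  trf0 <- gen_ground_truth_trf(cfg, region_gains = "uniform")
  t0 <- 60
  imp <- numeric(200); imp[t0] <- 1
  tr <- simulate_trial(cfg, trf0, seed = 1,
                       target_env = envelope_series(imp, 100),
                       masker_env = envelope_series(rep(1e-12, 200), 100))
  g <- trf0$lag_grid
  for (k in which(g$lags_samples >= 0 & t0 + g$lags_samples <= 200)) {
    expect_equal(unname(tr$observed_eeg$data[2, t0 + g$lags_samples[k]]),
                 trf0$kernel[2, k], tolerance = 1e-12)
  }
})

test_that("regressing observed on clean gives slope 1, intercept 0 in the linear regime", {
  tl <- tiny_linear_trial()
  for (ch in 1:2) {
    fit <- lm(tl$trial$observed_eeg$data[ch, ] ~ tl$trial$clean_eeg$data[ch, ])
    expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-10)
  }
})

test_that("dimension mismatches and bad conditions are rejected", {
  cfg <- sim_config(n_subjects = 1, n_channels = 4, trial_duration = 2)
  trf0 <- gen_ground_truth_trf(sim_config(n_channels = 2, trial_duration = 2))
  expect_error(simulate_trial(cfg, trf0, seed = 1),
               class = "trfcomp_dimension_error")
  trf4 <- gen_ground_truth_trf(cfg)
  expect_error(simulate_trial(cfg, trf4, seed = 1, condition = "nope"),
               class = "trfcomp_invalid_argument")
})

test_that("dataset design arithmetic matches the experimental design", {
  d_default <- dataset_design(sim_config())
  expect_equal(nrow(d_default), 2400)                     # 30 x 2 x 40
  per_subject <- table(d_default$subject)
  expect_true(all(per_subject == 80))                     # 80 trials/subject
  expect_equal(length(unique(d_default$condition)), 2)
})

test_that("gen_dataset is deterministic and ordered like its design", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 2,
                    n_channels = 2, trial_duration = 2, seed = 9)
  ds1 <- gen_dataset(cfg)
  ds2 <- gen_dataset(cfg)
  expect_equal(length(ds1$trials), 8)
  expect_identical(ds1$design, dataset_design(cfg))
  for (i in seq_along(ds1$trials)) {
    expect_identical(ds1$trials[[i]]$observed_eeg$data,
                     ds2$trials[[i]]$observed_eeg$data)
    expect_identical(ds1$trials[[i]]$metadata,
                     as.list(ds1$design[i, c("subject", "trial", "condition")])[
                       c("subject", "trial", "condition")])
  }
  # per-subject kernels differ (jitter) but are deterministic
  expect_false(identical(ds1$subject_trfs[[1]]$kernel,
                         ds1$subject_trfs[[2]]$kernel))
})

test_that("injected curvature sign propagates to the middle-bin residual", {
  # brute-force conditional-mean oracle: on quadratic data the middle-bin
  # residual sign must follow -sign(gamma)
  resid_for <- function(gamma, seed) {
    ct <- random_channel_trial(seed, T = 3100, curvature = gamma)
    compensate_channel_trial(ct$predicted, ct$measured)$residual
  }
  rn <- vapply(1:30, function(s) resid_for(-0.3, s), numeric(1))
  rp <- vapply(31:60, function(s) resid_for(+0.3, s), numeric(1))
  expect_gte(mean(rn > 0), 0.95)
  expect_gte(mean(rp < 0), 0.95)
})
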