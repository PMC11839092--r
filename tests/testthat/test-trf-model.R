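# Lagged design matrices, boosting estimation, prediction, noise pairings.

test_that("build_lag_matrix places impulses per the lag convention", {
  g <- lag_grid(100)
  expect_equal(g$K, 51)
  expect_true(0 %in% g$lags_ms)
  x <- numeric(60); x[10] <- 1
  X <- build_lag_matrix(envelope_series(x, 100), g)
  k0 <- which(g$lags_ms == 0)
  expect_equal(which(X[k0, ] != 0), 10)
  expect_equal(which(X[which(g$lags_ms == 10), ] != 0), 11)   # +10 ms
  expect_equal(which(X[which(g$lags_ms == -10), ] != 0), 9)   # future sample
  expect_error(build_lag_matrix(envelope_series(numeric(50), 100), g),
               class = "trfcomp_invalid_argument")
})

test_that("lag-matrix products equal the nested-loop convolution oracle", {
  g <- lag_grid(100, -30, 100)
  set.seed(1)
  x <- abs(rnorm(50))
  beta <- rnorm(g$K)
  X <- build_lag_matrix(envelope_series(x, 100), g)
  got <- drop(beta %*% X)
  oracle <- numeric(50)
  for (t in 1:50) for (k in seq_len(g$K)) {
    src <- t - g$lags_samples[k]
    if (src >= 1 && src <= 50) oracle[t] <- oracle[t] + beta[k] * x[src]
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("boosting returns a zero TRF for a zero response", {
  env1 <- gen_envelope(5, 100, 1)
  env2 <- gen_envelope(5, 100, 2, role = "masker")
  eeg <- eeg_recording(matrix(0, 2, 500), 100)
  fit <- boost_trf(eeg, list(env1, env2))
  expect_true(all(fit$coefficients == 0))
})

test_that("boosting rejects degenerate inputs", {
  eeg <- eeg_recording(matrix(rnorm(200), 1), 100)
  flat <- envelope_series(rep(1, 200), 100)
  expect_error(boost_trf(eeg, list(flat)), class = "trfcomp_estimation_error")
  bad <- eeg; bad$data[1, 5] <- NaN
  expect_error(boost_trf(bad, list(gen_envelope(2, 100, 1))),
               class = "trfcomp_invalid_argument")
})

test_that("noiseless boosting recovers the generating kernel (truth oracle)", {
  tl <- tiny_linear_fit()
  gT <- tl$cfg$target_gain[["NR_on"]]
  gM <- tl$cfg$masker_gain[["NR_on"]]
  for (ch in 1:2) {
    expect_gt(cor(tl$fit$coefficients[ch, "target", ],
                  gT * tl$trf0$kernel[ch, ]), 0.9)
    expect_gt(cor(tl$fit$coefficients[ch, "masker", ],
                  gM * tl$trf0$kernel[ch, ]), 0.9)
  }
})

test_that("accepted-iteration training SSE is non-increasing and beats the zero model", {
  tl <- tiny_linear_fit()
  for (fold in tl$fit$fit_info[[1]]) {
    trace <- fold$train_sse_trace
    if (length(trace) > 1)
      expect_true(all(diff(trace) <= 1e-9))
  }
  pr <- predict_eeg(tl$fit, list(tl$trial$target_env, tl$trial$masker_env),
                    measured = tl$trial$observed_eeg)
  expect_true(all(pr$mse_per_channel <=
                    rowMeans(tl$trial$observed_eeg$data^2)))
})

test_that("predict_eeg satisfies its identity and oracle contracts", {
  g <- lag_grid(100)
  env <- gen_envelope(2, 100, 3)
  # zero TRF -> zero prediction
  z <- trf_set(array(0, c(1, 1, g$K)), g, "target")
  expect_true(all(predict_eeg(z, list(env))$predicted$data == 0))
  # unit coefficient at lag 0 -> prediction equals the envelope
  coefs <- array(0, c(1, 1, g$K)); coefs[1, 1, which(g$lags_ms == 0)] <- 1
  ident <- trf_set(coefs, g, "target")
  expect_equal(predict_eeg(ident, list(env))$predicted$data[1, ],
               as.numeric(env), tolerance = 1e-12)
  # random TRF equals the brute-force convolution oracle on 100 samples
  set.seed(4)
  coefs2 <- array(rnorm(2 * g$K), c(2, 1, g$K))
  trf2 <- trf_set(coefs2, g, "target")
  x <- abs(rnorm(100))
  got <- predict_eeg(trf2, list(envelope_series(x, 100)))$predicted$data
  oracle <- matrix(0, 2, 100)
  for (ch in 1:2) for (t in 1:100) for (k in seq_len(g$K)) {
    src <- t - g$lags_samples[k]
    if (src >= 1 && src <= 100)
      oracle[ch, t] <- oracle[ch, t] + coefs2[ch, 1, k] * x[src]
  }
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  # residual reconstructs the measurement exactly
  meas <- eeg_recording(matrix(rnorm(200), 2), 100)
  pr <- predict_eeg(trf2, list(envelope_series(x, 100)), measured = meas)
  expect_equal(pr$predicted$data + pr$residual, meas$data, tolerance = 1e-14)
})

test_that("make_noise_pairing is a fixed-point-free bijection per cell", {
  mk <- function(s, cond, tr) list(metadata = list(subject = s, trial = tr,
                                                   condition = cond))
  trials <- c(lapply(1:3, function(i) mk(1, "NR_on", i)),
              lapply(1:2, function(i) mk(1, "NR_off", i)),
              lapply(1:3, function(i) mk(2, "NR_on", i)))
  p <- make_noise_pairing(trials)
  expect_true(all(p$eeg_index != p$env_index))
  expect_setequal(p$env_index, p$eeg_index)          # bijection
  s1 <- p[p$subject == 1 & p$condition == "NR_on", ]
  expect_equal(s1$env_index[match(1:3, s1$eeg_index)], c(2, 3, 1))
  expect_error(make_noise_pairing(list(mk(1, "a", 1))),
               class = "trfcomp_invalid_argument")
})

test_that("mismatched noise TRFs are much weaker than matched TRFs", {
  # strongly driven 1-channel world, a handful of trials
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 6,
                    conditions = "NR_on", n_channels = 1,
                    trial_duration = 15, noise_sd = c(NR_on = 0.2),
                    target_gain = c(NR_on = 1), masker_gain = c(NR_on = 0.3),
                    seed = 5)
  ds <- gen_dataset(cfg, region_gains = "uniform")
  pairing <- make_noise_pairing(ds$trials)
  peak_amp <- function(trf) max(abs(trf$coefficients[1, "target", ]))
  matched <- mismatched <- numeric(length(ds$trials))
  for (i in seq_along(ds$trials)) {
    tr <- ds$trials[[i]]
    matched[i] <- peak_amp(boost_trf(tr$observed_eeg,
                                     list(tr$target_env, tr$masker_env)))
    j <- pairing$env_index[pairing$eeg_index == i]
    mismatched[i] <- peak_amp(boost_trf(tr$observed_eeg,
                                        list(ds$trials[[j]]$target_env,
                                             tr$masker_env)))
  }
  expect_lt(mean(mismatched), 0.5 * mean(matched))
})

test_that("matched TRFs predict held-out-style data better than noise TRFs", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 2,
                    conditions = "NR_on", n_channels = 4,
                    trial_duration = 15, noise_sd = c(NR_on = 0.5),
                    target_gain = c(NR_on = 1), masker_gain = c(NR_on = 0.3),
                    seed = 11)
  ds <- gen_dataset(cfg)
  tr1 <- ds$trials[[1]]; tr2 <- ds$trials[[2]]
  envs1 <- list(tr1$target_env, tr1$masker_env)
  fit_matched <- boost_trf(tr1$observed_eeg, envs1)
  fit_noise <- boost_trf(tr1$observed_eeg, list(tr2$target_env, tr1$masker_env))
  mse_m <- predict_eeg(fit_matched, envs1, measured = tr1$observed_eeg)$mse_per_channel
  mse_n <- predict_eeg(fit_noise, list(tr2$target_env, tr1$masker_env),
                       measured = tr1$observed_eeg)$mse_per_channel
  expect_gte(mean(mse_m < mse_n), 0.95)
})

test_that("TRF tables round-trip through the text serialization", {
  tl <- tiny_linear_fit()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trf(tl$fit, path)
  back <- read_trf(path)
  expect_equal(back$coefficients, tl$fit$coefficients,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$predictors, tl$fit$predictors)
})
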