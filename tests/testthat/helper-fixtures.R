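# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# small linear, noiseless world: 2 channels, 31 s
tiny_linear_cfg <- function(seed = 42) {
  sim_config(n_subjects = 1, n_trials_per_condition = 1, n_channels = 2,
             trial_duration = 31, noise_sd = c(NR_on = 0, NR_off = 0),
             seed = seed)
}

tiny_linear_trial <- function() {
  memo("tiny_linear_trial", {
    cfg <- tiny_linear_cfg()
    trf0 <- gen_ground_truth_trf(cfg, region_gains = "uniform")
    list(cfg = cfg, trf0 = trf0,
         trial = simulate_trial(cfg, trf0, seed = 7))
  })
}

# a boosting fit of the tiny linear trial (reused by several files)
tiny_linear_fit <- function() {
  memo("tiny_linear_fit", {
    tl <- tiny_linear_trial()
    fit <- boost_trf(tl$trial$observed_eeg,
                     list(tl$trial$target_env, tl$trial$masker_env),
                     keep_fit_info = TRUE)
    c(tl, list(fit = fit))
  })
}

# random (predicted, measured) channel-trial pair for binning tests
random_channel_trial <- function(seed, T = 500, curvature = 0) {
  set.seed(seed)
  v <- rnorm(T, sd = 2)
  list(predicted = v,
       measured = v + curvature * v^2 + rnorm(T, sd = 0.5))
}

central_adjacency <- function() {
  memo("central_adjacency", {
    mont <- default_montage()
    chs <- default_channel_groups()$central
    adjacency_graph(mont[match(chs, mont$channel), ])
  })
}
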