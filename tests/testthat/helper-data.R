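# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# The study-condition synthetic dataset: one full run (8 blocks x 13 trials,
# 96 target epochs), high SNR with a class variance ratio of 4, preprocessed
# with the standard chain. Simulated inter-block breaks are 1 s (breaks
# carry no signal).
study_run <- function() {
  if (is.null(.fixtures$study)) {
    sched <- generate_schedule(paradigm_config(inter_block_break = 1),
                               seed = 101)
    sim <- simulate_run(sched, generator_params(seed = 101,
                                                lateral_power_ratio = 4))
    rec <- bandpass(rereference(sim$recording), 0.5, 30)
    ev <- schedule_to_events_table(sched)
    epochs <- epoch_recording(rec, ev[ev$kind == "target", ])
    post <- filter_epochs(epochs,
                          labels = c("left_attended", "right_attended"),
                          window = c(0, 1000))
    .fixtures$study <- list(
      sched = sched, sim = sim, events = ev, epochs = epochs, post = post,
      band420 = bandpass(post, 4, 20)
    )
  }
  .fixtures$study
}

# Small high-SNR run for planted-parameter recovery (strong lateral sources).
recovery_run <- function() {
  if (is.null(.fixtures$recovery)) {
    sched <- generate_schedule(paradigm_config(inter_block_break = 1),
                               seed = 5)
    sim <- simulate_run(sched, generator_params(seed = 5,
                                                lateral_power_ratio = 16,
                                                lateral_scale = 8))
    rec <- bandpass(rereference(sim$recording), 0.5, 30)
    ev <- schedule_to_events_table(sched)
    epochs <- epoch_recording(rec, ev[ev$kind == "target", ])
    post <- filter_epochs(epochs,
                          labels = c("left_attended", "right_attended"),
                          window = c(0, 1000))
    .fixtures$recovery <- list(sched = sched, sim = sim, post = post)
  }
  .fixtures$recovery
}

# Epochs with exact sample covariances diag(4, 1) (class a) and diag(1, 4)
# (class b): orthogonal sinusoids over whole periods have exactly zero
# cross-covariance and variance amp^2 / 2.
toy_csp_epochs <- function(n_per_class = 4, t_len = 120) {
  tt <- seq_len(t_len)
  s1 <- sin(2 * pi * 3 * tt / t_len)
  s2 <- cos(2 * pi * 5 * tt / t_len)
  v <- stats::var(s1) # == var(s2) == amp^2/2 up to same factor
  e_a <- rbind(2 * s1 / sqrt(v), s2 / sqrt(v)) # var 4, 1
  e_b <- rbind(s1 / sqrt(v), 2 * s2 / sqrt(v)) # var 1, 4
  mk <- function(e, lab) {
    arr <- array(0, c(n_per_class, 2, t_len))
    for (i in seq_len(n_per_class)) arr[i, , ] <- e
    epoch_set(arr, fs = 100, tmin = 0, tmax = (t_len - 1) * 10,
              labels = rep(lab, n_per_class), channel_names = c("c1", "c2"))
  }
  list(a = mk(e_a, "a"), b = mk(e_b, "b"))
}

# Two-class epoch set with class-dependent oscillatory variance planted on
# two channels, restricted to a time interval; white noise elsewhere.
planted_band_epochs <- function(n_per_class = 20, n_ch = 8, fs = 250,
                                tmin = -200, tmax = 1000, freq = 10,
                                amp = 3, interval = c(0, 1000), seed = 1) {
  withr::with_seed(seed, {
    times <- seq(tmin, tmax, by = 1000 / fs)
    n_smp <- length(times)
    gate <- times >= interval[1] & times <= interval[2]
    n <- 2 * n_per_class
    arr <- array(rnorm(n * n_ch * n_smp), c(n, n_ch, n_smp))
    labels <- rep(c("left_attended", "right_attended"), each = n_per_class)
    for (i in seq_len(n)) {
      ch <- if (labels[i] == "left_attended") 3 else 4
      osc <- amp * sin(2 * pi * freq * times / 1000 + runif(1, 0, 2 * pi))
      arr[i, ch, gate] <- arr[i, ch, gate] + osc[gate]
    }
    epoch_set(arr, fs, tmin, tmax, labels,
              paste0("ch", seq_len(n_ch)))
  })
}

# random symmetric positive definite matrix
random_spd <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n * n), n)
    crossprod(a) + diag(0.5, n)
  })
}

# brute-force CSP oracle: generalized eigenproblem cov_a w = lambda
# (cov_a + cov_b) w solved via the (non-symmetric) matrix inverse route,
# rows normalized to w' (cov_a + cov_b) w = 1.
csp_oracle <- function(cov_a, cov_b) {
  comp <- cov_a + cov_b
  eg <- eigen(solve(comp) %*% cov_a)
  ord <- order(Re(eg$values), decreasing = TRUE)
  vals <- Re(eg$values)[ord]
  vecs <- Re(eg$vectors)[, ord, drop = FALSE]
  w <- t(apply(vecs, 2, function(v) v / sqrt(drop(t(v) %*% comp %*% v))))
  list(eigenvalues = vals, W = w)
}
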