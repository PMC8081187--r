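sine_recording <- function(freq, fs = 1000, dur = 10, n_ch = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  continuous_recording(matrix(rep(sin(2 * pi * freq * t), each = n_ch),
                              n_ch, byrow = FALSE),
                       fs, paste0("ch", seq_len(n_ch)))
}

steady <- function(x) { # interior samples, away from filter edges
  n <- ncol(x$data)
  x$data[1, floor(n * 0.3):floor(n * 0.7)]
}

test_that("the broadband filter passes, stops and removes DC as designed", {
  rec10 <- sine_recording(10)
  out10 <- bandpass(rec10, 0.5, 30)
  expect_lt(abs(max(abs(steady(out10))) - 1), 0.01) # passband amplitude
  # zero-phase: no shift of a 10 Hz sine (phase < 1 degree ~ 0.28 samples)
  cc <- stats::ccf(steady(out10), steady(rec10), lag.max = 3, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  reg <- stats::lm(steady(out10) ~ steady(rec10) - 1)
  expect_gt(unname(stats::coef(reg)), 0.99)

  # 50 Hz attenuation matches the designed magnitude response within 2%
  rec50 <- sine_recording(50)
  out50 <- bandpass(rec50, 0.5, 30)
  measured <- max(abs(steady(out50)))
  expect_lt(measured, 0.1) # > 90% attenuation
  hp <- signal::butter(4, 0.5 / 500, "high")
  lp <- signal::butter(4, 30 / 500, "low")
  h <- function(flt, f) { # transfer function at f Hz, fs = 1000
    z <- exp(-1i * 2 * pi * f / 1000 * (seq_along(flt$b) - 1))
    sum(flt$b * z) / sum(flt$a * exp(-1i * 2 * pi * f / 1000 * (seq_along(flt$a) - 1)))
  }
  designed <- Mod(h(hp, 50) * h(lp, 50))^2 # squared: forward-backward pass
  expect_lt(abs(measured - designed), 0.02 * max(designed, measured) + 5e-4)

  # DC is removed
  recdc <- continuous_recording(matrix(1, 1, 5000), 1000, "ch1")
  expect_lt(mean(abs(steady(bandpass(recdc, 0.5, 30)))), 0.01)
  expect_error(bandpass(rec10, 0.5, 600), "Nyquist|fs/2")
})

test_that("mastoid re-referencing subtracts the reference mean", {
  withr::local_seed(1)
  x <- matrix(rnorm(5 * 100), 5)
  x[4, ] <- 0; x[5, ] <- 0 # TP9 = TP10 = 0
  rec <- continuous_recording(x, 1000, c("Cz", "C3", "C4", "TP9", "TP10"))
  expect_equal(rereference(rec)$data, rec$data, ignore_attr = TRUE)
  # a common-mode constant is rejected entirely
  recc <- continuous_recording(matrix(3, 4, 50), 1000,
                               c("Cz", "C3", "TP9", "TP10"))
  expect_equal(max(abs(rereference(recc)$data)), 0)
  # idempotence
  rec2 <- continuous_recording(matrix(rnorm(4 * 100), 4), 1000,
                               c("Cz", "C3", "TP9", "TP10"))
  once <- rereference(rec2)
  expect_equal(rereference(once)$data, once$data)
  expect_match(once$reference_label, "TP9")
  expect_error(rereference(rec2, c("A1", "A2")), "A1")
})

test_that("epoching honours the window convention and baseline", {
  # constant recording -> all-zero epochs after baseline correction
  rec <- continuous_recording(matrix(7, 2, 4000), 1000, c("Cz", "C3"))
  ev <- tibble::tibble(onset_ms = c(500, 1500), duration_ms = 150,
                       kind = "target", site = "left", block = 1,
                       trial = 2:3, label = "left_attended")
  eps <- epoch_recording(rec, ev)
  expect_equal(dim(eps$data), c(2, 2, 1201)) # -200..1000 ms at 1 kHz
  expect_equal(max(abs(eps$data)), 0)
  expect_equal(epoch_times(eps)[1], -200)
  expect_equal(tail(epoch_times(eps), 1), 1000)
  # epochs that do not fit are dropped, with an exact count
  ev2 <- rbind(ev, tibble::tibble(onset_ms = 3900, duration_ms = 150,
                                  kind = "target", site = "left", block = 1,
                                  trial = 4, label = "left_attended"))
  expect_warning(eps2 <- epoch_recording(rec, ev2), "dropped 1 of 3")
  expect_equal(dim(eps2$data)[1], 2)
})

test_that("a full run yields one epoch per target event", {
  run <- study_run()
  expect_equal(dim(run$epochs$data)[1], 96)
  expect_equal(sort(unique(run$epochs$labels)),
               c("left_attended", "right_attended"))
})

test_that("zero-phase filtering does not move a planted peak", {
  tmpl <- make_p300_template(350, 300, 10, 1000, 800)
  x <- matrix(0, 1, 6000)
  x[1, 2001:2800] <- tmpl
  rec <- continuous_recording(x, 1000, "Cz")
  ev <- tibble::tibble(onset_ms = 2000, duration_ms = 150, kind = "target",
                       site = "left", block = 1, trial = 2,
                       label = "left_attended")
  eps <- epoch_recording(bandpass(rec, 0.5, 30), ev)
  times <- epoch_times(eps)
  peak <- times[which.max(eps$data[1, 1, ])]
  expect_lte(abs(peak - 350), 1)
})

test_that("planted blink components are found and removed", {
  cfg <- paradigm_config(inter_block_break = 1, trials_per_block = 6,
                         blocks_per_run = 2)
  sched <- generate_schedule(cfg, seed = 7)
  sim <- simulate_run(sched, generator_params(n_channels = 16, seed = 7,
                                              blink_rate = 15,
                                              blink_amplitude = 150,
                                              lateral_power_ratio = 1))
  expect_gt(length(sim$truth$blink_onset_samples), 0)
  clean <- suppressMessages(remove_eog(sim$recording))
  eog <- attr(clean, "eog")
  expect_gte(length(eog$flagged), 1)
  # frontal low-frequency variance drops by >= 80%
  lowvar <- function(r, ch) {
    f <- bandpass(r, 0.5, 3)
    stats::var(f$data[match(ch, f$channel_names), ])
  }
  expect_gte(1 - lowvar(clean, "Fp1") / lowvar(sim$recording, "Fp1"), 0.8)
  # a second pass finds nothing new
  clean2 <- suppressMessages(remove_eog(clean))
  expect_length(attr(clean2, "eog")$flagged, 0)
})

test_that("a blink-free recording passes through EOG removal unchanged", {
  cfg <- paradigm_config(inter_block_break = 1, trials_per_block = 6,
                         blocks_per_run = 2)
  sched <- generate_schedule(cfg, seed = 7)
  sim <- simulate_run(sched, generator_params(n_channels = 16, seed = 8,
                                              blink_rate = 0,
                                              lateral_power_ratio = 1))
  clean <- suppressMessages(remove_eog(sim$recording))
  expect_length(attr(clean, "eog")$flagged, 0)
  rel_rms <- sqrt(mean((clean$data - sim$recording$data)^2)) /
    sqrt(mean(sim$recording$data^2))
  expect_lt(rel_rms, 0.05)
  # too-short recordings are refused
  short <- continuous_recording(matrix(rnorm(16 * 1000), 16), 1000,
                                sim$recording$channel_names)
  expect_error(remove_eog(short), "30")
})
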