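test_that("the P300 template has its contracted peak and support", {
  w <- make_p300_template(350, 300, 5, 1000, 1000)
  expect_equal(which.max(w) - 1, 350) # 0-based peak sample
  expect_equal(max(w), 5)
  expect_true(all(w >= 0))
  expect_gt(sum(w), 0)
  expect_true(all(w[seq_len(200)] == 0)) # zero outside the support
  expect_equal(make_p300_template(350, 300, 0, 1000, 1000), rep(0, 1000))
  expect_error(make_p300_template(900, 300, 5, 1000, 1000), "support")
})

test_that("pink noise has the requested spectral slope", {
  fit_slope <- function(x, fs) {
    p <- welch_psd(x, fs, segment_len = 4096)
    sel <- p$freq >= 1 & p$freq <= 100
    unname(stats::coef(stats::lm(log10(psd) ~ log10(freq), data = p[sel, ]))[2])
  }
  pink <- make_pink_noise(1, 2^16, exponent = 1, scale = 1, seed = 5)
  white <- make_pink_noise(1, 2^16, exponent = 0, scale = 1, seed = 5)
  expect_lt(abs(-fit_slope(pink[1, ], 1000) - 1), 0.25)
  expect_lt(abs(fit_slope(white[1, ], 1000)), 0.2)
  expect_equal(make_pink_noise(3, 100, 1, scale = 0), matrix(0, 3, 100))
  expect_lt(abs(mean(pink)), 1e-10)
})

test_that("simulation is bit-reproducible from the seed", {
  cfg <- paradigm_config(inter_block_break = 1, trials_per_block = 3,
                         blocks_per_run = 2)
  sched <- generate_schedule(cfg, seed = 9)
  a <- simulate_run(sched, generator_params(seed = 9))
  b <- simulate_run(sched, generator_params(seed = 9))
  expect_identical(a$recording$data, b$recording$data)
  expect_error(simulate_run(structure(list(events = NULL), class = "stimulus_schedule"),
                            generator_params()))
})

test_that("a null generator yields no condition differences beyond noise", {
  # attend left everywhere: right-site targets become 'ignored'
  cfg <- paradigm_config(inter_block_break = 1, trials_per_block = 9,
                         blocks_per_run = 4)
  sched <- generate_schedule(cfg, seed = 21, attend_sides = rep("left", 4))
  sim <- simulate_run(sched, generator_params(seed = 21, p300_amplitude = 0,
                                              lateral_power_ratio = 1))
  ev <- schedule_to_events_table(sched)
  eps <- epoch_recording(sim$recording, ev[ev$kind == "target", ])
  att <- grand_average(eps, "left_attended", channels = "Cz")
  ign <- grand_average(eps, "ignored", channels = "Cz")
  # the two grand averages differ only by noise on the order of SE
  diff <- att$avg[1, ] - ign$avg[1, ]
  se <- sqrt(att$se[1, ]^2 + ign$se[1, ]^2)
  expect_lt(mean(abs(diff)), 3 * mean(se))
})

test_that("planted P300 structure is recoverable at high SNR", {
  # a P300-dominated run: large template, small noise, no lateral contrast
  sched <- generate_schedule(paradigm_config(inter_block_break = 1,
                                             blocks_per_run = 2), seed = 17)
  sim <- simulate_run(sched, generator_params(seed = 17, p300_amplitude = 20,
                                              noise_scale = 2,
                                              lateral_scale = 1,
                                              lateral_power_ratio = 1))
  ev <- schedule_to_events_table(sched)
  eps <- epoch_recording(sim$recording, ev[ev$kind == "target", ])
  post <- filter_epochs(eps, c("left_attended", "right_attended"))
  # latency within +/- 10 ms of the planted 350 ms at Cz
  ga <- grand_average(post, channels = "Cz")
  expect_lt(abs(ga$peaks$peak_latency_ms - 350), 10)
  # the grand-average spatial pattern at the peak matches the planted map
  full <- grand_average(post)
  peak_idx <- which.min(abs(full$times - ga$peaks$peak_latency_ms))
  expect_gte(stats::cor(full$avg[, peak_idx], sim$truth$p300_topography),
             0.95)
})

test_that("disturbance onsets carry no planted deflection", {
  # marker-trial disturbances in early slots sit far from any target, so
  # their average isolates the generator (periodic stimulus spacing makes
  # within-trial disturbances pick up neighbouring targets' P300 tails)
  run <- study_run()
  sev <- run$sched$events
  mark <- sev[sev$trial == 1 & sev$slot <= 4, ]
  mark$label <- "disturbance"
  eps <- suppressWarnings(epoch_recording(run$sim$recording, mark))
  ga <- grand_average(eps, channels = "Cz")
  pk_idx <- which(ga$times == ga$peaks$peak_latency_ms)
  expect_lt(abs(ga$peaks$peak_amplitude), 3 * ga$se[1, pk_idx])
})

test_that("class separability grows with the planted variance ratio", {
  cfg <- paradigm_config(inter_block_break = 1, trials_per_block = 8,
                         blocks_per_run = 4)
  sched <- generate_schedule(cfg, seed = 31)
  acc <- vapply(c(1, 2.5, 6), function(ratio) {
    sim <- simulate_run(sched, generator_params(seed = 31,
                                                lateral_power_ratio = ratio))
    ev <- schedule_to_events_table(sched)
    eps <- epoch_recording(sim$recording, ev[ev$kind == "target", ])
    post <- filter_epochs(eps, c("left_attended", "right_attended"),
                          window = c(0, 1000))
    crossval(bandpass(post, 4, 20), m = 3, k = 7, seed = 31)$mean
  }, 0)
  expect_true(all(diff(acc) >= -0.04)) # non-decreasing up to fold noise
  expect_gt(acc[3], acc[1])
})
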