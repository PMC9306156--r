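test_that("activation profile follows the two-trapezoid prescription", {
  p <- make_activation_profile(2048)
  expect_length(p$samples, 34816L)          # 17 s at 2048 Hz
  expect_equal(max(p$samples), 0.60)
  expect_equal(min(p$samples), 0)
  t <- (seq_along(p$samples) - 1) / 2048
  # plateaus: 4 s at 30% and 4 s at 60% of MVC
  expect_true(all(abs(p$samples[t >= 1 & t <= 5] - 0.30) < 1e-9))
  expect_true(all(abs(p$samples[t >= 12 & t <= 16] - 0.60) < 1e-9))
  expect_true(all(p$samples[t > 6 & t < 11] == 0))  # 5-s separation
  # 1-s linear ramps
  expect_equal(p$samples[t == 0.5], 0.15, tolerance = 1e-6)
})

test_that("channel RMS maps are flat at rest and wrist shifts move hot spots", {
  lay <- build_default_layout()
  cfg <- simulation_config()
  rest <- channel_rms_map(cfg, task_label("RE", "neutral"), lay)
  expect_equal(rest, rep(cfg$baseline_noise, 256))
  for (g in c("PG", "IP")) {
    pro <- channel_rms_map(cfg, task_label(g, "pronation"), lay)
    sup <- channel_rms_map(cfg, task_label(g, "supination"), lay)
    expect_false(which.max(pro) == which.max(sup))
  }
  # zero wrist shift collapses the three wrist conditions to one map
  cfg0 <- simulation_config(wrist_dcol = 0, wrist_dz_mm = 0)
  maps <- lapply(hdemg_wrists, function(w)
    channel_rms_map(cfg0, task_label("PG", w), lay))
  expect_equal(maps[[1]], maps[[2]])
  expect_equal(maps[[2]], maps[[3]])
  # very wide spatial spread flattens the map toward baseline + sum(amps)
  cfgw <- simulation_config(spatial_sigma = 1e6)
  mw <- channel_rms_map(cfgw, task_label("PG", "neutral"), lay)
  spots <- subset(cfgw$model, gesture == "PG")
  expect_equal(mw, rep(cfgw$baseline_noise +
                         sum(cfgw$snr * cfgw$baseline_noise * spots$rel_amp),
                       256),
               tolerance = 1e-3)
})

test_that("simulated tasks are seed-reproducible with the expected amplitudes", {
  fx <- task_fixture()
  rec2 <- simulate_task(fx$cfg, task_label("PG", "neutral"), fx$lay, seed = 12)
  expect_identical(fx$rec$signal, rec2$signal)

  # rest recording: all-channel mean RMS at the baseline within 10%
  re <- simulate_task(fx$cfg, task_label("RE", "neutral"), fx$lay, seed = 4)
  expect_equal(mean(sqrt(rowMeans(re$signal^2))), fx$cfg$baseline_noise,
               tolerance = 0.10)

  # plateau-2 / plateau-1 RMS ratio of the source-driven activity is the
  # 60%/30% target ratio; the baseline noise floor is removed in quadrature
  # and baseline-dominated channels are excluded, since their ratio is 1 by
  # construction.
  fs <- fx$cfg$fs
  b <- fx$cfg$baseline_noise
  p1 <- fx$rec$signal[, (1.5 * fs):(4.5 * fs)]
  p2 <- fx$rec$signal[, (12.5 * fs):(15.5 * fs)]
  rms1 <- sqrt(rowMeans(p1^2))
  rms2 <- sqrt(rowMeans(p2^2))
  active <- rms1 > 3 * b
  expect_gt(sum(active), 10)
  ratio <- sqrt(pmax(rms2[active]^2 - b^2, 0)) /
    sqrt(pmax(rms1[active]^2 - b^2, 0))
  expect_equal(mean(ratio), 2.0, tolerance = 0.1)

  # corrupted channels carry large-variance noise, not signal
  cfg_c <- simulation_config(corrupted = 82L)
  rec_c <- simulate_task(cfg_c, task_label("PG", "neutral"),
                         build_default_layout(corrupted = 82L), seed = 12)
  expect_equal(sqrt(mean(rec_c$signal[83, ]^2)),
               cfg_c$corrupted_gain * cfg_c$baseline_noise, tolerance = 0.05)
})

test_that("session protocol covers the 8 x 3 task grid in pseudorandom order", {
  p1 <- session_protocol(1)
  expect_equal(nrow(p1), 24L)
  combos <- paste(p1$gesture, p1$wrist)
  expect_length(unique(combos), 24L)
  expect_setequal(combos, paste(rep(hdemg_gestures, 3),
                                rep(hdemg_wrists, each = 8)))
  expect_identical(session_protocol(1), p1)
  p2 <- session_protocol(2)
  expect_setequal(paste(p2$gesture, p2$wrist), combos)
  expect_false(identical(p2$gesture, p1$gesture) &&
                 identical(p2$wrist, p1$wrist))
})

test_that("simulate_session stamps measured MVC values onto its recordings", {
  lay <- build_default_layout()
  cfg <- simulation_config()
  ses <- simulate_session(cfg, lay, seed = 5, tasks = 1:2)
  expect_length(ses$recordings, 2L)
  for (i in 1:2) {
    rec <- ses$recordings[[i]]
    expect_equal(dim(rec$signal), c(256L, 34816L))
    expect_true(is.finite(rec$mvc) && rec$mvc > 0)
  }
  # the stored MVC equals compute_mvc() on the seed-matched MVC recording
  plan <- hdemg:::session_seed_plan(5)
  lab <- ses$recordings[[1]]$label
  i <- which(plan$mvc$gesture == lab$gesture & plan$mvc$wrist == lab$wrist)
  mvc_rec <- hdemg:::simulate_mvc_task(cfg, lab$gesture, lab$wrist, lay,
                                       plan$mvc$seed[i])
  expect_equal(ses$recordings[[1]]$mvc, compute_mvc(mvc_rec))
})
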