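test_that("volume waveform reproduces the breathing protocol", {
  # zero tidal volume: flat at FRC before the SVC
  tr0 <- volume_waveform(breathing_protocol(tidal_volume = 0))
  pre_svc <- tr0$volume_L[tr0$time_s < 12]
  expect_true(all(pre_svc == 0))
  # SVC excursion equals the configured vital capacity exactly
  tr <- volume_waveform(breathing_protocol(vital_capacity = 4))
  svc <- tr$volume_L[tr$time_s >= 12]
  expect_equal(max(svc) - min(svc), 4.0)
  # three tidal local maxima before the SVC onset
  v <- tr$volume_L[tr$time_s < 12]
  n_max <- sum(diff(sign(diff(v))) == -2)
  expect_equal(n_max, 3L)
  expect_error(breathing_protocol(tidal_period = 0), "must be > 0")
})

test_that("noiseless frames are constant while volume is constant", {
  mesh <- fix_mesh(1)
  phantom <- phantom_config(mesh)
  prot <- breathing_protocol(n_tidal = 2, tidal_volume = 0,
                             tidal_period = 1, svc_insp_s = 1,
                             svc_exp_s = 1, frame_rate = 10)
  sim <- simulate_sequence(phantom, prot, noise_model(0))
  flat <- which(sim$truth$volume == 0)
  expect_gt(length(flat), 5L)
  ref <- sim$sequence$frames[flat[1], ]
  for (i in flat) expect_equal(sim$sequence$frames[i, ], ref)
})

test_that("symmetric phantom ventilates both lungs identically", {
  mesh <- fix_mesh(1)
  phantom <- phantom_config(mesh, right_weight = 0.5)
  sig <- eitbench:::phantom_sigma(phantom, 2, 2)
  expect_equal(sort(sig[phantom$right_elems]),
               sort(sig[phantom$left_elems]))
})

test_that("lung conductivity loss tracks volume exactly (linear coupling)", {
  sim <- fix_sim06(1)
  phantom <- phantom_config(fix_mesh(1), right_weight = 0.6)
  lung <- c(phantom$right_elems, phantom$left_elems)
  swing <- vapply(seq_along(sim$truth$volume), function(i) {
    sig <- eitbench:::phantom_sigma(phantom, sim$truth$v_right[i],
                                    sim$truth$v_left[i])
    sum(phantom$sigma_lung_exp - sig[lung])
  }, numeric(1))
  expect_gt(stats::cor(sim$truth$volume, swing), 1 - 1e-12)
})

test_that("configured right fraction is recoverable from the conductivity swing", {
  phantom <- phantom_config(fix_mesh(1), right_weight = 0.6)
  areas <- element_areas(fix_mesh(1))
  sig <- eitbench:::phantom_sigma(phantom, 1, 1)
  dr <- sum((phantom$sigma_lung_exp - sig[phantom$right_elems]) *
              areas[phantom$right_elems]) / sum(areas[phantom$right_elems])
  dl <- sum((phantom$sigma_lung_exp - sig[phantom$left_elems]) *
              areas[phantom$left_elems]) / sum(areas[phantom$left_elems])
  expect_lt(abs(dr / (dr + dl) - 0.6), 1e-10)
})

test_that("an over-large swing is rejected with the offending frame named", {
  phantom <- phantom_config(fix_mesh(1), swing_per_L = 0.2)
  expect_error(simulate_sequence(phantom, breathing_protocol(),
                                 noise_model(0)),
               "frame [0-9]+")
})

test_that("seeded generation is reproducible and seeds differentiate noise", {
  phantom <- phantom_config(fix_mesh(1))
  prot <- breathing_protocol(n_tidal = 1, tidal_period = 2, svc_insp_s = 1,
                             svc_exp_s = 1, frame_rate = 10)
  s1 <- simulate_sequence(phantom, prot, noise_model(5e-4, seed = 11))
  s2 <- simulate_sequence(phantom, prot, noise_model(5e-4, seed = 11))
  s3 <- simulate_sequence(phantom, prot, noise_model(5e-4, seed = 12))
  expect_identical(s1$sequence$frames, s2$sequence$frames)
  expect_false(identical(s1$sequence$frames, s3$sequence$frames))
})

test_that("four-recording emulation shares the noiseless core", {
  phantom <- phantom_config(fix_mesh(1))
  prot <- breathing_protocol(n_tidal = 1, tidal_period = 2, svc_insp_s = 1,
                             svc_exp_s = 1, frame_rate = 10)
  recs <- emulate_two_devices(phantom, prot, seeds = c(21, 22, 23, 24))
  expect_named(recs, c("A1", "B1", "A2", "B2"))
  expect_identical(recs$A1$core$frames, recs$B2$core$frames)
  frames <- lapply(recs, function(r) r$sequence$frames)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(identical(frames[[i]], frames[[j]]))
  }
  expect_warning(
    emulate_two_devices(phantom, prot, seeds = c(21, 21, 23, 24)),
    "duplicate seeds")
})

test_that("paired recordings differ by sqrt(2) times the device noise", {
  phantom <- phantom_config(fix_mesh(1))
  prot <- breathing_protocol(n_tidal = 1, tidal_period = 2, svc_insp_s = 1,
                             svc_exp_s = 1, frame_rate = 50)
  recs <- emulate_two_devices(phantom, prot, seeds = c(31, 32, 33, 34))
  rel <- (recs$A1$sequence$frames - recs$A2$sequence$frames) /
    recs$A1$core$frames
  expect_equal(stats::sd(rel), sqrt(2) * 5e-4, tolerance = 0.1)
})

test_that("resistor-network recording has the documented nominal behaviour", {
  clean <- resistor_network_recording(10, 10, noise_model(0, 0))
  expect_true(all(clean$frames == 0.5))
  expect_equal(ncol(clean$frames), 16L)
  drifted <- resistor_network_recording(3600, 1, noise_model(0, 0.001))
  expect_equal(drifted$frames[nrow(drifted$frames), 1] /
                 drifted$frames[1, 1], 1.001)
  noisy <- resistor_network_recording(99.9, 10,
                                      noise_model(1e-3, 0, seed = 5))
  cv <- apply(noisy$frames, 2, function(v) stats::sd(v) / mean(v))
  expect_equal(unname(cv), rep(1e-3, 16), tolerance = 0.1)
})

test_that("frame and spirometry CSV round trips preserve the data", {
  rec <- resistor_network_recording(2, 5, noise_model(1e-3, 0, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_frames_csv(rec, path)
  back <- read_frames_csv(path)
  expect_equal(back$frames, rec$frames, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$timestamps, rec$timestamps)

  tr <- volume_waveform(breathing_protocol())
  sp <- withr::local_tempfile(fileext = ".csv")
  write_spirometry_csv(tr, sp)
  tr2 <- read_spirometry_csv(sp)
  expect_equal(tr2$volume_L, tr$volume_L, tolerance = 1e-12)
})
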