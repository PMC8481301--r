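test_that("breath detection counts sinusoid extrema and rejects flat curves", {
  t <- seq(0, 4, by = 0.01)
  for (k in c(2, 4)) {
    v <- sin(2 * pi * k * t / 4)
    seg <- detect_breaths(v)
    expect_length(seg$ends_insp, k)
    expect_true(length(seg$ends_exp) %in% c(k, k + 1L))
  }
  expect_error(detect_breaths(rep(1, 100)), "no breaths")
})

test_that("SVC segment brackets the generated maneuver within 2 frames", {
  sim <- fix_sim06(1)
  imgs <- predict(fix_greit(1), sim$sequence, reference = "auto")
  seg <- detect_breaths(global_curve(imgs)$value)
  expect_lte(abs(seg$svc["start"] - sim$truth$svc["start"]), 2)
  expect_lte(abs(seg$svc["peak"] - sim$truth$svc["peak"]), 2)
})

test_that("tidal image obeys the summation identity with the global curve", {
  sim <- fix_sim06(1)
  imgs <- predict(fix_greit(1), sim$sequence, reference = "auto")
  curve <- global_curve(imgs)
  seg <- detect_breaths(curve$value)
  i <- seg$ends_insp[1]; e <- seg$ends_exp[1]
  tv <- tidal_image(imgs, i, e)
  expect_equal(sum(tv), curve$value[i] - curve$value[e], tolerance = 1e-12)
  expect_true(all(tidal_image(imgs, i, i) == 0))
  expect_error(tidal_image(imgs, 10^6, e), "out of range")
})

test_that("noiseless symmetric phantom gives a left-right symmetric tidal image", {
  phantom <- phantom_config(fix_mesh(1), right_weight = 0.5)
  sim <- simulate_sequence(phantom, breathing_protocol(), noise_model(0))
  imgs <- predict(fix_greit(1), sim$sequence, reference = "auto")
  seg <- detect_breaths(global_curve(imgs)$value)
  tv <- unclass(tidal_image(imgs, seg$svc["peak"], seg$svc["start"]))
  mirrored <- tv[, rev(seq_len(ncol(tv)))]
  expect_lt(max(abs(tv - mirrored)) / max(abs(tv)), 1e-6)
})

test_that("volume normalization scales values and leaves shape indices alone", {
  expect_equal(attr(normalize_to_volume(1, 4000, 4000), "factor_mL_per_AU"), 1)
  expect_equal(as.numeric(normalize_to_volume(500, 4000, 5000)), 400)
  img <- matrix(stats::runif(1024), 32, 32)
  roi <- img > 0
  expect_identical(gi_index(img, roi),
                   gi_index(unclass(normalize_to_volume(img, 1234, 7)), roi))
  expect_error(normalize_to_volume(1, -1, 1), "must be > 0")
})

test_that("linearity returns r = 1 for an affine impedance-volume relation", {
  prot <- breathing_protocol()
  # spirometer sampled on the EIT grid so the affine relation is exact at
  # every compared point
  spiro <- volume_waveform(prot, sampling_rate = 50)
  tt <- seq(0, prot$duration, by = 1 / 50)
  curve <- data.frame(time_s = tt,
                      value = 2 + 3 * eitbench:::volume_at(prot, tt))
  seg <- detect_breaths(curve$value)
  lin <- linearity(curve, spiro, seg)
  expect_equal(lin$volume_impedance_r, 1.0, tolerance = 1e-9)
  # tidal TV = 3 * 0.5 L, SVC excursion = 3 * 4 L
  expect_equal(lin$tv_svc_ratio, 0.125, tolerance = 1e-6)
  bad <- spiro; bad$time_s <- bad$time_s + 1e5
  expect_error(linearity(curve, bad, seg), "overlap")
})

test_that("full-pipeline tidal/SVC ratio reflects the configured volumes", {
  sim <- fix_sim06(1)
  imgs <- predict(fix_greit(1), sim$sequence, reference = "auto")
  rep_ <- ventilation_report(imgs, sim$spirometry)
  expect_equal(rep_$tv_svc_ratio, 0.125, tolerance = 0.08)
  expect_gte(rep_$volume_impedance_r, 0.99)
})

test_that("lung ROI thresholding matches a brute-force oracle", {
  img <- matrix(0, 32, 32)
  img[10:15, 5:10] <- stats::runif(36, 0.5, 1)
  img[20:25, 20:28] <- stats::runif(54, 0.2, 0.9)
  roi <- lung_roi(img, 0.2)
  expect_identical(sum(roi), sum(img >= 0.2 * max(img)))
  # uniform positive image: everything in
  expect_true(all(lung_roi(matrix(1, 4, 4), 0.2)))
  hot <- matrix(0, 8, 8); hot[3, 3] <- 5
  expect_identical(which(lung_roi(hot, 0.2)), which(hot > 0))
  expect_error(lung_roi(matrix(0, 4, 4)), "no positive")
})

test_that("GI index matches hand-computed examples and is scale invariant", {
  img <- matrix(0, 32, 32); img[1, 1:4] <- c(1, 2, 3, 4)
  roi <- img > 0
  expect_equal(gi_index(img, roi), 0.4) # median 2.5: (1.5+.5+.5+1.5)/10
  expect_equal(gi_index(7 * img, roi), 0.4)
  img2 <- matrix(0, 32, 32); img2[1, 1:4] <- 5
  expect_equal(gi_index(img2, img2 > 0), 0)
})

test_that("GI grows when amplitude concentrates onto one pixel", {
  base <- matrix(0, 32, 32); base[5:8, 5:8] <- 1
  roi <- base > 0
  gis <- vapply(c(0, 0.3, 0.6), function(f) {
    img <- base
    img[roi] <- 1 - f
    img[5, 5] <- 1 - f + f * sum(roi)
    gi_index(img, roi)
  }, numeric(1))
  expect_true(all(diff(gis) > 0))
})

test_that("CoV matches centroid arithmetic", {
  sym <- matrix(1, 32, 32)
  expect_equal(center_of_ventilation(sym), 50)
  dorsal <- matrix(0, 32, 32); dorsal[32, ] <- 1
  expect_equal(center_of_ventilation(dorsal), 100 * 31.5 / 32)
  # two-row example: rows at y = 0.25 and 0.75 with weights 3 and 1
  two <- matrix(0, 2, 2); two[1, ] <- 3 / 2; two[2, ] <- 1 / 2
  expect_equal(center_of_ventilation(two), 37.5)
  expect_error(center_of_ventilation(matrix(0, 4, 4)), "non-positive")
})

test_that("regional fractions split at the image midlines", {
  sym <- matrix(1, 32, 32)
  expect_equal(unname(regional_fractions(sym)["right_fraction"]), 0.5)
  ventral <- matrix(0, 32, 32); ventral[1:16, ] <- 1
  expect_equal(unname(regional_fractions(ventral)["ventral_fraction"]), 1.0)
})

test_that("RVD-SD matches the two-pixel hand computation", {
  tt <- seq(0, 1, by = 0.025)
  ramp1 <- pmin(tt / 0.625, 1)               # crosses 0.4 at t = 0.25
  t0 <- 0.35 / 0.6                            # crosses 0.4 at t = 0.75
  ramp2 <- pmax(0, (tt - t0) / (1 - t0))
  frames <- lapply(seq_along(tt), function(i) {
    img <- matrix(0, 32, 32)
    img[5, 5] <- ramp1[i]; img[5, 6] <- ramp2[i]
    img
  })
  imgs <- make_images(frames, tt)
  seg <- structure(list(svc = c(start = 1L, peak = length(tt),
                                end = length(tt))),
                   class = "breath_segmentation")
  roi <- matrix(FALSE, 32, 32); roi[5, 5:6] <- TRUE
  out <- rvd_sd(imgs, seg, roi, threshold = 0.4)
  expect_equal(sort(attr(out, "rvd")), c(25, 75), tolerance = 1e-9)
  expect_equal(as.numeric(out), 25, tolerance = 1e-9) # population SD
  # identical time courses: zero spread
  frames_same <- lapply(seq_along(tt), function(i) {
    img <- matrix(0, 32, 32); img[5, 5:6] <- ramp1[i]; img
  })
  expect_equal(as.numeric(rvd_sd(make_images(frames_same, tt), seg, roi)), 0)
})

test_that("shape indices are invariant under global positive scaling", {
  sim <- fix_sim06(1)
  imgs <- predict(fix_greit(1), sim$sequence, reference = "auto")
  rep1 <- ventilation_report(imgs, sim$spirometry)
  scaled <- imgs; scaled$images <- 13 * imgs$images
  rep2 <- ventilation_report(scaled, sim$spirometry)
  for (f in c("GI", "CoV", "RVD_SD", "right_fraction", "ventral_fraction",
              "tv_svc_ratio", "volume_impedance_r")) {
    expect_equal(rep1[[f]], rep2[[f]], tolerance = 1e-9)
  }
  expect_equal(rep2$TV, 13 * rep1$TV, tolerance = 1e-9)
})
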