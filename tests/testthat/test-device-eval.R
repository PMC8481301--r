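test_that("paired TOST declares equivalence for truly equivalent devices", {
  set.seed(42)
  a <- stats::rnorm(50, mean = 10, sd = 0.1)
  b <- a + stats::rnorm(50, sd = 0.1)
  expect_lt(tost_equivalence(a, b, margin = 1)$p_value, 0.05)
})

test_that("TOST p-value is 0.5 with the mean difference at the margin", {
  d <- c(rep(-0.3, 100), rep(0.3, 100)) # mean 0, sd ~0.3
  a <- d + 1 # mean difference exactly 1
  res <- tost_equivalence(a, rep(0, 200), margin = 1)
  expect_equal(res$p_value, 0.5, tolerance = 1e-12)
})

test_that("TOST input validation and degenerate cases behave", {
  expect_error(tost_equivalence(1:5, 1:5 + 0.1, margin = 0), "> 0")
  expect_error(tost_equivalence(1:2, 1:2, margin = 1), "n >= 3")
  res <- tost_equivalence(c(1, 1, 1), c(1, 1, 1), margin = 0.5)
  expect_true(res$degenerate)
  expect_lt(res$p_value, 1e-300)
})

test_that("Bland-Altman summary matches hand computation", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  ba <- bland_altman(c(-2, 0, 2), c(0, 0, 0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 2)
  expect_equal(unname(ba$loa), c(-3.92, 3.92))
  # translation invariance
  ba2 <- bland_altman(c(-2, 0, 2) + 100, c(0, 0, 0) + 100)
  expect_equal(ba2$bias, ba$bias)
  expect_equal(ba2$loa, ba$loa)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("repeatability variability is the percent difference over the mean", {
  r <- repeatability_variability(9, 11)
  expect_equal(r$pct, 20)
  r2 <- repeatability_variability(c(9, 5), c(11, 5))
  expect_equal(r2$pct, c(20, 0))
  # scale invariance and symmetry
  expect_equal(repeatability_variability(27, 33)$pct, 20)
  expect_equal(repeatability_variability(11, 9)$pct, 20)
  rz <- repeatability_variability(c(1, 0), c(3, 0))
  expect_equal(rz$n_missing, 1L)
  expect_equal(rz$mean, 100)
})

test_that("TOST power matches a Monte-Carlo oracle", {
  margin <- 0.5
  # spec-scale configuration: equivalent devices, sd at the margin
  p_closed <- posthoc_power(50, 0.05, 0, margin, margin)
  mc <- function(n, diff, sd, margin, reps = 10000) {
    set.seed(99)
    mean(vapply(seq_len(reps), function(i) {
      d <- stats::rnorm(n, diff, sd)
      tost_equivalence(d, rep(0, n), margin)$p_value < 0.05
    }, logical(1)))
  }
  expect_equal(p_closed, mc(50, 0, margin, margin), tolerance = 0.01)
  # an interior-power configuration exercises the approximation harder
  p2 <- posthoc_power(20, 0.05, 0.1, 0.6, margin)
  expect_equal(p2, mc(20, 0.1, 0.6, margin), tolerance = 0.02)
})

test_that("TOST power limits and monotonicity hold", {
  expect_equal(posthoc_power(20, 0.05, 0, 1, margin = 1e6), 1,
               tolerance = 1e-6)
  p_small <- posthoc_power(3, 0.05, 0.1, 1, 1)
  p_large <- posthoc_power(50, 0.05, 0.1, 1, 1)
  expect_gt(p_large, p_small)
  expect_error(posthoc_power(20, 1.5, 0, 1, 1), "alpha")
})

test_that("identically-seeded device B reproduces device A exactly", {
  phantom <- phantom_config(fix_mesh(1))
  prot <- breathing_protocol(n_tidal = 1, tidal_period = 2, svc_insp_s = 1,
                             svc_exp_s = 1, frame_rate = 10)
  recs <- suppressWarnings(
    emulate_two_devices(phantom, prot, seeds = c(41, 41, 42, 42)))
  expect_identical(recs$A1$sequence$frames, recs$B1$sequence$frames)
  expect_identical(recs$A2$sequence$frames, recs$B2$sequence$frames)
})

test_that("a small synthetic study runs end to end with tidy bookkeeping", {
  st <- run_study(n_subjects = 5, model = fix_greit(1), seed = 17,
                  margins = c(right_fraction = 0.1))
  expect_equal(nrow(st$measures), 5 * 2 * 2)
  expect_length(st$failures, 0)
  # equivalent devices at a clinically meaningful margin
  expect_lt(st$agreement$right_fraction$tost$p_value, 0.05)
  expect_lt(abs(st$agreement$right_fraction$bland_altman$bias), 0.02)
  # repeatability summaries exist per device and index
  expect_named(st$repeatability, c("A", "B"))
  expect_gte(min(vapply(st$repeatability$A, function(r) r$mean,
                        numeric(1))), 0)
})
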