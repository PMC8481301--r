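#' Paired two-one-sided-tests (TOST) equivalence test
#'
#' Tests equivalence of paired device measurements: with differences
#' `d = a - b`, two one-sided t-tests of the mean of `d` against the
#' margins -margin and +margin are run and the larger one-sided p-value
#' reported. p < 0.05 declares the devices equivalent within the margin.
#'
#' @param a,b Paired measurement vectors (same subjects, same index).
#' @param margin Equivalence margin (> 0), same units as the data.
#' @return List with `p_value`, `mean_diff`, `sd_diff`, `margin`, `n`, and
#'   a `degenerate` flag set when the differences have zero variance (the
#'   p-value is then reported at the machine floor if the mean lies inside
#'   the margin).
#' @examples
#' tost_equivalence(rnorm(30), rnorm(30), margin = 1)$p_value
#' @export
tost_equivalence <- function(a, b, margin) {
  check_number(margin, "margin", positive = TRUE)
  if (length(a) != length(b)) stop_param("`a` and `b` differ in length")
  d <- a - b
  n <- length(d)
  if (n < 3L) stop_param("need n >= 3 pairs (got %d)", n)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    p <- if (abs(m) < margin) .Machine$double.xmin else 1
    return(list(p_value = p, mean_diff = m, sd_diff = 0, margin = margin,
                n = n, degenerate = TRUE))
  }
  se <- s / sqrt(n); df <- n - 1L
  p_lower <- stats::pt((m + margin) / se, df, lower.tail = FALSE)
  p_upper <- stats::pt((m - margin) / se, df, lower.tail = TRUE)
  list(p_value = max(p_lower, p_upper), mean_diff = m, sd_diff = s,
       margin = margin, n = n, degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of `a - b`) and 95% limits of agreement
#' (bias +/- 1.96 x SD of the differences, sample SD with n-1), together
#' with the (mean, difference) pairs for plotting.
#'
#' @param a,b Paired measurement vectors.
#' @return Object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa` (lower, upper), `pairs` data frame.
#' @examples
#' ba <- bland_altman(c(1, 3, 5), c(3, 3, 3))
#' ba$loa
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_param("`a` and `b` differ in length")
  if (length(a) < 2L) stop_param("need n >= 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 pairs = data.frame(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, LoA [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa[1L], x$loa[2L], nrow(x$pairs)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$pairs$mean, x$pairs$diff, xlab = "mean of devices",
       ylab = "difference (A - B)", ...)
  graphics::abline(h = c(x$bias, x$loa), lty = c(1, 2, 2),
                   col = c("black", "red3", "red3"))
  invisible(x)
}

#' Same-device repeatability variability
#'
#' Per-subject variability of two repeated measurements from the same
#' device: `100 * |m1 - m2| / ((m1 + m2) / 2)` percent, summarized as
#' mean +/- SD across subjects. Subjects with `m1 + m2 = 0` are recorded
#' as missing and excluded from the summary.
#'
#' @param m1,m2 Repeated measurement vectors.
#' @return Object of class `repeatability_record`: list with `pct`
#'   (per-subject percentages, `NA` where undefined), `mean`, `sd`,
#'   `n_missing`.
#' @export
repeatability_variability <- function(m1, m2) {
  if (length(m1) != length(m2)) stop_param("`m1` and `m2` differ in length")
  avg <- (m1 + m2) / 2
  pct <- ifelse(avg == 0, NA_real_, 100 * abs(m1 - m2) / avg)
  structure(list(pct = pct, mean = mean(pct, na.rm = TRUE),
                 sd = stats::sd(pct[!is.na(pct)]),
                 n_missing = sum(is.na(pct))),
            class = "repeatability_record")
}

#' @export
print.repeatability_record <- function(x, ...) {
  cat(sprintf("repeatability variability: %.1f ± %.1f %%", x$mean, x$sd))
  if (x$n_missing > 0) cat(sprintf(" (%d missing)", x$n_missing))
  cat("\n")
  invisible(x)
}

#' Post-hoc power of the paired TOST
#'
#' Power of the paired equivalence test at an observed effect and
#' standard deviation, by the standard noncentral-t approximation
#' (difference of the two one-sided noncentral-t rejection probabilities,
#' floored at 0).
#'
#' @param n Number of pairs (>= 3).
#' @param alpha One-sided significance level in (0, 1).
#' @param observed_mean_diff Observed mean paired difference.
#' @param observed_sd Observed SD of the paired differences (> 0).
#' @param margin Equivalence margin (> 0).
#' @return Estimated power in [0, 1].
#' @export
posthoc_power <- function(n, alpha, observed_mean_diff, observed_sd,
                          margin) {
  if (n < 3) stop_param("need n >= 3")
  if (alpha <= 0 || alpha >= 1) stop_param("`alpha` must lie in (0, 1)")
  check_number(observed_sd, "observed_sd", positive = TRUE)
  check_number(margin, "margin", positive = TRUE)
  se <- observed_sd / sqrt(n)
  df <- n - 1
  tc <- stats::qt(1 - alpha, df)
  pow <- stats::pt(-tc, df, ncp = (observed_mean_diff - margin) / se) -
    stats::pt(tc, df, ncp = (observed_mean_diff + margin) / se)
  max(0, min(1, pow))
}

#' Run a full synthetic device-comparison study
#'
#' Emulates the study design end to end: for each synthetic subject a
#' phantom is drawn from mild parameter priors, four recordings are
#' simulated in the measurement order device A, device B, device A,
#' device B (one shared noiseless forward core, independent noise), each
#' recording is reconstructed with one shared GREIT model and reduced to
#' its ventilation indices; the devices are then compared per index with
#' Bland-Altman summaries and paired TOST, and same-device repeatability
#' is summarized per device.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param mesh Shared forward mesh (default refinement 1, kept coarse so a
#'   study of 10 subjects runs in seconds).
#' @param protocol Breathing protocol (default short: 2 tidal breaths then
#'   a 3+3 s SVC at 20 Hz).
#' @param noise_a,noise_b Device noise models.
#' @param margins Named vector of per-index equivalence margins; indices
#'   not named default to `0.2 * SD` of the device-B values.
#' @param right_weight_range Uniform prior for the subjects' right-lung
#'   ventilation weight.
#' @param model A fitted `greit` model to reuse, or `NULL` to train one.
#' @param seed Master seed.
#' @return Object of class `eit_device_study`: list with `measures` (one
#'   row per subject x device x repetition), `agreement` (per-index
#'   Bland-Altman + TOST), `repeatability` (per device x index),
#'   `failures`, and metadata (including the pairing and margin policy).
#' @export
run_study <- function(n_subjects = 10,
                      mesh = build_thorax_mesh("circle", 1),
                      protocol = breathing_protocol(n_tidal = 2,
                                                    tidal_period = 3,
                                                    svc_insp_s = 3,
                                                    svc_exp_s = 3,
                                                    frame_rate = 20),
                      noise_a = noise_model(), noise_b = noise_model(),
                      margins = NULL,
                      right_weight_range = c(0.45, 0.55),
                      model = NULL, seed = 1L) {
  stim <- adjacent_protocol()
  em <- electrode_model()
  if (is.null(model)) {
    sigma0 <- rep(0.48, nrow(mesh$elements))
    jac <- compute_jacobian(mesh, sigma0, stim, em)
    model <- greit(jac, noise_level = max(noise_a$noise_rel,
                                          noise_b$noise_rel, 1e-6))
  }
  indices <- c("TV", "tv_svc_ratio", "volume_impedance_r",
               "right_fraction", "ventral_fraction", "GI", "CoV", "RVD_SD")
  rows <- list(); failures <- list()
  with_seed(seed, {
    subject_w <- stats::runif(n_subjects, right_weight_range[1L],
                              right_weight_range[2L])
    noise_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                     4L * n_subjects), ncol = 4L)
  })
  for (s in seq_len(n_subjects)) {
    res <- try({
      phantom <- phantom_config(mesh, right_weight = subject_w[s])
      recs <- emulate_two_devices(phantom, protocol,
                                  seeds = noise_seeds[s, ],
                                  noise_a = noise_a, noise_b = noise_b,
                                  stim = stim, electrodes = em)
      lapply(names(recs), function(lab) {
        r <- recs[[lab]]
        imgs <- predict(model, r$sequence, reference = "auto")
        rep_ <- ventilation_report(imgs, r$spirometry)
        data.frame(subject = s, device = substr(lab, 1L, 1L),
                   repetition = as.integer(substr(lab, 2L, 2L)),
                   as.data.frame(rep_[indices]))
      })
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures[[length(failures) + 1L]] <-
        list(subject = s, message = attr(res, "condition")$message)
    } else {
      rows <- c(rows, res)
    }
  }
  measures <- do.call(rbind, rows)
  if (is.null(measures) || nrow(measures) == 0L) {
    stop_param("all subjects failed; first error: %s",
               failures[[1L]]$message)
  }

  # agreement: repetition 1 of device A vs repetition 1 of device B
  a1 <- measures[measures$device == "A" & measures$repetition == 1L, ]
  b1 <- measures[measures$device == "B" & measures$repetition == 1L, ]
  common <- intersect(a1$subject, b1$subject)
  a1 <- a1[match(common, a1$subject), ]
  b1 <- b1[match(common, b1$subject), ]
  agreement <- lapply(indices, function(ix) {
    mrg <- if (!is.null(margins) && ix %in% names(margins)) {
      margins[[ix]]
    } else {
      0.2 * stats::sd(measures[measures$device == "B", ix])
    }
    if (!is.finite(mrg) || mrg <= 0) mrg <- NA_real_
    ba <- bland_altman(a1[[ix]], b1[[ix]])
    tost <- if (is.na(mrg)) NULL else tost_equivalence(a1[[ix]], b1[[ix]], mrg)
    list(index = ix, bland_altman = ba, tost = tost, margin = mrg)
  })
  names(agreement) <- indices

  repeatability <- list()
  for (dev in c("A", "B")) {
    r1 <- measures[measures$device == dev & measures$repetition == 1L, ]
    r2 <- measures[measures$device == dev & measures$repetition == 2L, ]
    common <- intersect(r1$subject, r2$subject)
    r1 <- r1[match(common, r1$subject), ]
    r2 <- r2[match(common, r2$subject), ]
    repeatability[[dev]] <- lapply(indices, function(ix) {
      repeatability_variability(r1[[ix]], r2[[ix]])
    })
    names(repeatability[[dev]]) <- indices
  }

  structure(list(
    measures = measures, agreement = agreement,
    repeatability = repeatability, failures = failures, model = model,
    meta = list(n_subjects = n_subjects, seed = seed,
                pairing = "paired TOST on repetition-1 device differences",
                margin_policy = "0.2 x SD of device-B values unless supplied")
  ), class = "eit_device_study")
}

#' @export
print.eit_device_study <- function(x, ...) {
  cat(sprintf("Synthetic device-comparison study: %d subjects, %d rows",
              x$meta$n_subjects, nrow(x$measures)))
  if (length(x$failures) > 0) {
    cat(sprintf(" (%d subjects failed)", length(x$failures)))
  }
  cat("\n\nAgreement (device A vs B, repetition 1):\n")
  for (ag in x$agreement) {
    p <- if (is.null(ag$tost)) NA_real_ else ag$tost$p_value
    cat(sprintf("  %-20s bias %+.4g  LoA [%.4g, %.4g]  TOST p %.3g (margin %.3g)\n",
                ag$index, ag$bland_altman$bias, ag$bland_altman$loa[1L],
                ag$bland_altman$loa[2L], p, ag$margin))
  }
  cat("\nRepeatability variability (mean ± SD %):\n")
  for (dev in names(x$repeatability)) {
    for (ix in names(x$repeatability[[dev]])) {
      r <- x$repeatability[[dev]][[ix]]
      cat(sprintf("  device %s %-20s %.1f ± %.1f\n", dev, ix,
                  r$mean, r$sd))
    }
  }
  invisible(x)
}

#' @export
summary.eit_device_study <- function(object, ...) {
  print(object, ...)
}
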