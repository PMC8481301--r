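#' Global impedance curve of an image sequence
#'
#' Per-frame sum of all in-mask pixel values — the global relative
#' impedance signal whose tidal swings and SVC excursion drive breath
#' segmentation.
#'
#' @param images An `eit_images` object.
#' @return Data frame with `time_s` and `value` (AU).
#' @export
global_curve <- function(images) {
  v <- apply(images$images, 3L, sum)
  data.frame(time_s = images$timestamps, value = v)
}

#' Segment breaths and locate the SVC maneuver on a global curve
#'
#' Detects alternating end-expiration minima and end-inspiration maxima by
#' prominence-filtered extremum detection (oscillations smaller than
#' `prominence_frac` of the curve's full excursion are removed), then
#' takes the trough-to-peak excursion of maximum amplitude as the SVC
#' inspiration.
#'
#' @param curve Numeric vector, or the data frame from [global_curve()].
#' @param prominence_frac Minimum extremum prominence as a fraction of the
#'   global excursion.
#' @return Object of class `breath_segmentation`: list with `ends_exp`,
#'   `ends_insp` (frame indices), and `svc = c(start, peak, end)`.
#' @export
detect_breaths <- function(curve, prominence_frac = 0.1) {
  values <- if (is.data.frame(curve)) curve$value else as.numeric(curve)
  rng <- max(values) - min(values)
  if (rng == 0) stop_param("no breaths detected: curve is flat")
  thr <- prominence_frac * rng

  # candidate alternating extrema, endpoints included
  d <- diff(values)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  turn <- which(diff(s) != 0) + 1L
  ext <- unique(c(1L, turn, length(values)))
  # prune small oscillations: repeatedly drop the adjacent extremum pair
  # with the smallest swing until all swings exceed the threshold
  repeat {
    if (length(ext) <= 2L) break
    amp <- abs(diff(values[ext]))
    k <- which.min(amp)
    if (amp[k] >= thr) break
    drop <- if (k == 1L) 2L else if (k == length(amp)) k else c(k, k + 1L)
    ext <- ext[-drop]
    ext <- dedupe_extrema(ext, values)
  }
  if (length(ext) < 2L) stop_param("no breaths detected")

  vals <- values[ext]
  is_max <- logical(length(ext))
  for (i in seq_along(ext)) {
    lo <- if (i > 1L) vals[i - 1L] else vals[i + 1L]
    is_max[i] <- vals[i] > lo
  }
  # endpoints are only half extrema: a recording that ends mid-slope must
  # not contribute a spurious end-inspiration (minima are kept — the
  # breathing protocol starts and ends at end-expiration)
  report <- is_max
  report[c(1L, length(ext))] <- FALSE
  ends_insp <- ext[report]
  ends_exp <- ext[!is_max]

  # SVC = largest trough-to-peak rise among consecutive extrema
  rises <- which(!is_max[-length(ext)] & is_max[-1L])
  if (length(rises) == 0L) stop_param("no breaths detected")
  amp <- vals[rises + 1L] - vals[rises]
  k <- rises[which.max(amp)]
  svc_start <- ext[k]; svc_peak <- ext[k + 1L]
  svc_end <- if (k + 2L <= length(ext)) ext[k + 2L] else length(values)
  structure(list(ends_exp = ends_exp, ends_insp = ends_insp,
                 svc = c(start = svc_start, peak = svc_peak,
                         end = svc_end)),
            class = "breath_segmentation")
}

# forward-fill NAs (plateau handling in slope signs)
zoo_locf <- function(x) {
  if (is.na(x[1L])) x[1L] <- x[which(!is.na(x))[1L]]
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  x[idx]
}

# after removing points, adjacent extrema of the same type can remain;
# keep the more extreme representative
dedupe_extrema <- function(ext, values) {
  if (length(ext) < 3L) return(ext)
  keep <- rep(TRUE, length(ext))
  i <- 2L
  while (i < length(ext)) {
    a <- values[ext[i]] - values[ext[i - 1L]]
    b <- values[ext[i + 1L]] - values[ext[i]]
    if (sign(a) == sign(b)) keep[i] <- FALSE
    i <- i + 1L
  }
  ext[keep]
}

#' Tidal variation image of one breath
#'
#' Pixelwise difference between the end-inspiration and end-expiration
#' frames of a breath.
#'
#' @param images An `eit_images`.
#' @param end_insp,end_exp Frame indices.
#' @return 32 x 32 matrix (class `tidal_image`), masked pixels zero.
#' @export
tidal_image <- function(images, end_insp, end_exp) {
  n_fr <- dim(images$images)[3L]
  if (end_insp < 1L || end_insp > n_fr || end_exp < 1L || end_exp > n_fr) {
    stop_param("frame index out of range (1..%d)", n_fr)
  }
  structure(images$images[, , end_insp] - images$images[, , end_exp],
            mask = images$mask, class = c("tidal_image", "matrix"))
}

#' Scale impedance quantities to spirometric SVC volume
#'
#' Impedance values are normalized to the corresponding SVC volume in
#' millilitres: the scale factor is `svc_volume_mL / dZ_svc` (mL per AU).
#' Ratios and the distribution indices (GI, CoV, RVD) are invariant under
#' this scaling.
#'
#' @param x Tidal image, index value or vector of impedance quantities
#'   (AU).
#' @param svc_volume_mL SVC volume in millilitres (> 0).
#' @param dZ_svc SVC impedance excursion in AU (> 0).
#' @return `x` scaled to mL-equivalents, with the factor in attribute
#'   `"factor_mL_per_AU"`.
#' @export
normalize_to_volume <- function(x, svc_volume_mL, dZ_svc) {
  check_number(svc_volume_mL, "svc_volume_mL", positive = TRUE)
  check_number(dZ_svc, "dZ_svc", positive = TRUE)
  f <- svc_volume_mL / dZ_svc
  out <- x * f
  attr(out, "factor_mL_per_AU") <- f
  out
}

#' Volume-impedance linearity during the SVC
#'
#' Interpolates the spirometry volume linearly onto the EIT timestamps of
#' the SVC segment, computes the Pearson correlation with the global
#' impedance curve there, and the ratio of mean tidal variation to the
#' SVC impedance excursion.
#'
#' @param curve Data frame from [global_curve()].
#' @param spiro A `spirometry_trace`.
#' @param seg A `breath_segmentation`.
#' @param scope `"svc"` (default) computes the correlation over the SVC
#'   segment only; `"all"` over the whole overlapping recording.
#' @return List with `tv_svc_ratio`, `volume_impedance_r`, `dZ_svc`,
#'   `mean_tv`.
#' @export
linearity <- function(curve, spiro, seg, scope = c("svc", "all")) {
  scope <- match.arg(scope)
  idx <- if (scope == "svc") seq(seg$svc["start"], seg$svc["end"]) else
    seq_along(curve$time_s)
  tt <- curve$time_s[idx]
  if (max(spiro$time_s) < min(tt) || min(spiro$time_s) > max(tt)) {
    stop_param("spirometry trace does not overlap the analysed segment")
  }
  vol <- stats::approx(spiro$time_s, spiro$volume_L, xout = tt,
                       rule = 2)$y
  r <- stats::cor(vol, curve$value[idx])
  dz_svc <- curve$value[seg$svc["peak"]] - curve$value[seg$svc["start"]]
  # mean tidal variation over complete pre-SVC breaths: each
  # end-inspiration before the SVC paired with the preceding end-expiration
  tv <- tidal_swings(curve$value, seg)
  list(tv_svc_ratio = mean(tv) / dz_svc, volume_impedance_r = r,
       dZ_svc = dz_svc, mean_tv = mean(tv))
}

tidal_swings <- function(values, seg) {
  peaks <- seg$ends_insp[seg$ends_insp < seg$svc["start"]]
  vapply(peaks, function(p) {
    troughs <- seg$ends_exp[seg$ends_exp < p]
    if (length(troughs) == 0L) return(NA_real_)
    values[p] - values[max(troughs)]
  }, numeric(1)) |> stats::na.omit() |> as.numeric()
}

#' Functional lung region of interest
#'
#' Pixels whose tidal variation reaches `threshold_fraction` of the image
#' maximum — the standard functional-lung ROI used by the GI, CoV and RVD
#' definitions.
#'
#' @param tv A `tidal_image` (or plain matrix).
#' @param threshold_fraction Threshold in (0, 1); default 0.2.
#' @return Logical matrix (class `lung_roi`), subset of the domain mask.
#' @export
lung_roi <- function(tv, threshold_fraction = 0.2) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop_param("`threshold_fraction` must lie in (0, 1)")
  }
  m <- max(tv)
  if (m <= 0) stop_param("tidal image has no positive amplitude")
  roi <- unclass(tv) >= threshold_fraction * m
  structure(roi, threshold_fraction = threshold_fraction,
            class = c("lung_roi", "matrix"))
}

#' Global inhomogeneity (GI) index
#'
#' `GI = sum_p |TV_p - median(TV_ROI)| / sum_p TV_p` over ROI pixels:
#' 0 for perfectly homogeneous ventilation, growing with spatial
#' heterogeneity. Scale-invariant.
#'
#' @param tv A `tidal_image`.
#' @param roi A `lung_roi` (defaults to the 20% ROI of `tv`).
#' @return GI value (>= 0).
#' @examples
#' img <- matrix(0, 32, 32); img[1, 1:4] <- c(1, 2, 3, 4)
#' gi_index(img, img > 0) # (1.5+0.5+0.5+1.5)/10
#' @export
gi_index <- function(tv, roi = lung_roi(tv)) {
  v <- unclass(tv)[unclass(roi)]
  if (length(v) == 0L) stop_param("empty ROI")
  tot <- sum(v)
  if (tot <= 0) stop_param("non-positive total tidal variation in ROI")
  sum(abs(v - stats::median(v))) / tot
}

#' Center of ventilation (CoV) along the ventral-dorsal axis
#'
#' Amplitude-weighted centroid of the tidal image along the
#' ventral-to-dorsal axis, as a percentage of the chest extent: 0% at the
#' ventral edge, 100% at the dorsal edge, 50% for a ventral-dorsal
#' symmetric distribution.
#'
#' @param tv A `tidal_image`.
#' @return CoV in percent.
#' @export
center_of_ventilation <- function(tv) {
  tvm <- unclass(tv)
  tot <- sum(tvm)
  if (tot <= 0) stop_param("non-positive total tidal variation")
  n <- nrow(tvm)
  y <- (seq_len(n) - 0.5) / n # row centres, 0 = ventral edge
  100 * sum(rowSums(tvm) * y) / tot
}

#' Right/left and ventral/dorsal ventilation fractions
#'
#' Splits the tidal image at the vertical and horizontal midlines
#' (columns 1-16 = subject right, rows 1-16 = ventral) and reports the
#' fraction of total tidal variation in the right and ventral halves.
#'
#' @param tv A `tidal_image`.
#' @return Named vector `c(right_fraction, ventral_fraction)`.
#' @export
regional_fractions <- function(tv) {
  tvm <- unclass(tv)
  tot <- sum(tvm)
  if (tot <= 0) stop_param("non-positive total tidal variation")
  h <- nrow(tvm) %/% 2L
  c(right_fraction = sum(tvm[, seq_len(h)]) / tot,
    ventral_fraction = sum(tvm[seq_len(h), ]) / tot)
}

#' Standard deviation of regional ventilation delay (RVD-SD)
#'
#' For every ROI pixel, the time at which its impedance change (relative
#' to the SVC inspiration start) first reaches `threshold` of its maximal
#' inspiratory change is found by linear interpolation between frames and
#' expressed as a percentage of the global inspiration time. RVD-SD is the
#' population standard deviation of these percentages over the ROI; the
#' slow-flow SVC inspiration serves as the low-flow maneuver the delay
#' definition assumes. Pixels that never cross the threshold are excluded
#' and counted in the `n_excluded` attribute.
#'
#' @param images An `eit_images`.
#' @param seg A `breath_segmentation` (its `svc` start/peak bound the
#'   inspiration).
#' @param roi A `lung_roi`.
#' @param threshold Per-pixel threshold fraction (default 0.4).
#' @return RVD-SD in percent, with attributes `rvd` (per-pixel values) and
#'   `n_excluded`.
#' @export
rvd_sd <- function(images, seg, roi, threshold = 0.4) {
  i0 <- seg$svc["start"]; i1 <- seg$svc["peak"]
  if (i1 - i0 + 1L < 3L) stop_param("SVC inspiration spans < 3 frames")
  tt <- images$timestamps[i0:i1]
  t_tot <- tt[length(tt)] - tt[1L]
  mask_idx <- which(unclass(roi))
  flat <- matrix(images$images[, , i0:i1],
                 nrow = prod(dim(images$images)[1:2]))
  sig <- flat[mask_idx, , drop = FALSE]
  sig <- sig - sig[, 1L]
  rvd <- rep(NA_real_, length(mask_idx))
  for (p in seq_along(mask_idx)) {
    s <- sig[p, ]
    mx <- max(s)
    if (mx <= 0) next
    thr <- threshold * mx
    k <- which(s >= thr)[1L]
    if (k == 1L) {
      tc <- tt[1L]
    } else {
      tc <- tt[k - 1L] + (tt[k] - tt[k - 1L]) *
        (thr - s[k - 1L]) / (s[k] - s[k - 1L])
    }
    rvd[p] <- 100 * (tc - tt[1L]) / t_tot
  }
  ok <- !is.na(rvd)
  if (!any(ok)) stop_param("no ROI pixel crosses the RVD threshold")
  out <- stats::sd(rvd[ok]) * sqrt((sum(ok) - 1) / sum(ok)) # population SD
  attr(out, "rvd") <- rvd[ok]
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Full ventilation-index report for one recording
#'
#' Runs the complete index pipeline on a reconstructed image sequence:
#' breath segmentation on the global curve, mean tidal-variation image
#' over the pre-SVC breaths, SVC normalization against spirometry,
#' linearity, regional fractions, GI, CoV and RVD-SD.
#'
#' @param images An `eit_images`.
#' @param spiro A `spirometry_trace` (optional; without it the
#'   volume-linked quantities are `NA`).
#' @param roi_threshold Functional-lung ROI threshold fraction.
#' @param rvd_threshold RVD per-pixel threshold fraction.
#' @param scope Correlation scope, see [linearity()].
#' @return Object of class `ventilation_report`: a list of the indices
#'   plus the segmentation and tidal image.
#' @export
ventilation_report <- function(images, spiro = NULL, roi_threshold = 0.2,
                               rvd_threshold = 0.4,
                               scope = c("svc", "all")) {
  curve <- global_curve(images)
  seg <- detect_breaths(curve$value)
  peaks <- seg$ends_insp[seg$ends_insp < seg$svc["start"]]
  if (length(peaks) == 0L) {
    stop_param("no complete tidal breath precedes the SVC")
  }
  tvs <- lapply(peaks, function(p) {
    troughs <- seg$ends_exp[seg$ends_exp < p]
    tidal_image(images, p, max(troughs))
  })
  tv <- Reduce(`+`, tvs) / length(tvs)
  tv <- structure(tv, mask = images$mask, class = c("tidal_image", "matrix"))
  roi <- lung_roi(tv, roi_threshold)
  fr <- regional_fractions(tv)
  dz_svc <- curve$value[seg$svc["peak"]] - curve$value[seg$svc["start"]]

  lin <- list(tv_svc_ratio = NA_real_, volume_impedance_r = NA_real_)
  svc_volume_mL <- NA_real_
  tv_mL <- NA_real_
  if (!is.null(spiro)) {
    lin <- linearity(curve, spiro, seg, scope = match.arg(scope))
    svc_volume_mL <- 1000 * (max(spiro$volume_L) - min(spiro$volume_L))
    tv_mL <- as.numeric(normalize_to_volume(sum(tv), svc_volume_mL, dz_svc))
  }
  rv <- rvd_sd(images, seg, roi, rvd_threshold)

  structure(list(
    TV = sum(tv), TV_mL = tv_mL, dZ_svc = dz_svc,
    svc_volume_mL = svc_volume_mL,
    tv_svc_ratio = lin$tv_svc_ratio,
    volume_impedance_r = lin$volume_impedance_r,
    right_fraction = unname(fr["right_fraction"]),
    ventral_fraction = unname(fr["ventral_fraction"]),
    GI = gi_index(tv, roi), CoV = center_of_ventilation(tv),
    RVD_SD = as.numeric(rv), rvd_excluded = attr(rv, "n_excluded"),
    segmentation = seg, tidal_image = tv, roi = roi
  ), class = "ventilation_report")
}

#' @export
print.ventilation_report <- function(x, ...) {
  cat("Ventilation indices\n")
  cat(sprintf("  TV                 %.4g AU", x$TV))
  if (!is.na(x$TV_mL)) cat(sprintf("  (%.0f mL-equivalent)", x$TV_mL))
  cat("\n")
  cat(sprintf("  dZ SVC             %.4g AU (SVC %.0f mL)\n", x$dZ_svc,
              x$svc_volume_mL))
  cat(sprintf("  TV / dZ_SVC        %.4g\n", x$tv_svc_ratio))
  cat(sprintf("  volume-impedance r %.4f\n", x$volume_impedance_r))
  cat(sprintf("  right fraction     %.3f\n", x$right_fraction))
  cat(sprintf("  ventral fraction   %.3f\n", x$ventral_fraction))
  cat(sprintf("  GI                 %.3f\n", x$GI))
  cat(sprintf("  CoV                %.1f %%\n", x$CoV))
  cat(sprintf("  RVD-SD             %.2f %% (%d pixels excluded)\n",
              x$RVD_SD, x$rvd_excluded))
  invisible(x)
}

#' Write ventilation reports as one CSV row per recording
#'
#' @param reports Named list of `ventilation_report` objects; names encode
#'   subject/device/repetition.
#' @param path File path.
#' @return The data frame written, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  cols <- c("TV", "TV_mL", "dZ_svc", "svc_volume_mL", "tv_svc_ratio",
            "volume_impedance_r", "right_fraction", "ventral_fraction",
            "GI", "CoV", "RVD_SD")
  d <- do.call(rbind, lapply(reports, function(r) {
    as.data.frame(r[cols])
  }))
  d <- cbind(recording = names(reports), d)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
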