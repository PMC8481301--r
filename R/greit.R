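#' 32x32 reconstruction pixel grid with in-domain mask
#'
#' Pixel centres cover the bounding square [-1, 1]^2; pixels whose centre
#' lies inside the domain ellipse form the mask. Images are stored
#' ventral-up: row 1 is the ventral edge, column 1 the subject's right.
#'
#' @param a,b Domain semi-axes (lateral, ventral-dorsal).
#' @param n Grid side length (GREIT standard: 32).
#' @return List with `n`, `mask` (n x n logical), `px` (coordinates of
#'   masked pixel centres, in mask order), `xc`, `yc` (centre coordinate
#'   vectors by column / row).
#' @export
pixel_grid <- function(a = 1, b = 1, n = 32) {
  xc <- -1 + (seq_len(n) - 0.5) * 2 / n        # columns: right -> left
  yr <- 1 - (seq_len(n) - 0.5) * 2 / n         # rows: ventral -> dorsal
  X <- matrix(xc, n, n, byrow = TRUE)
  Y <- matrix(yr, n, n)
  mask <- (X / a)^2 + (Y / b)^2 <= 1
  list(n = n, mask = mask, px = cbind(x = X[mask], y = Y[mask]),
       xc = xc, yr = yr)
}

#' Normalized voltage-difference data for time-difference imaging
#'
#' `dv_m = (v_m - v_ref,m) / v_ref,m` per channel, relative to a chosen
#' reference frame.
#'
#' @param seq An `eit_sequence` (or a frames matrix).
#' @param reference_frame Index of the reference frame.
#' @return Object of class `eit_diff_data`: list with `dv` (n_frames x
#'   n_channels), `reference_frame`, `timestamps`.
#' @examples
#' fr <- matrix(1:12 / 10, 3, 4)
#' normalize_difference(fr, 1)$dv[1, ]
#' @export
normalize_difference <- function(seq, reference_frame = 1L) {
  frames <- if (inherits(seq, "eit_sequence")) seq$frames else as.matrix(seq)
  ts <- if (inherits(seq, "eit_sequence")) seq$timestamps else
    seq_len(nrow(frames))
  if (reference_frame < 1L || reference_frame > nrow(frames)) {
    stop_param("reference_frame %d out of range", reference_frame)
  }
  vref <- frames[reference_frame, ]
  zero <- which(vref == 0)
  if (length(zero) > 0) {
    stop_param("reference frame has zero voltage in channel %d", zero[1L])
  }
  dv <- sweep(sweep(frames, 2L, vref, "-"), 2L, vref, "/")
  structure(list(dv = dv, reference_frame = as.integer(reference_frame),
                 timestamps = ts), class = "eit_diff_data")
}

#' Train a GREIT reconstruction matrix
#'
#' Fits the linear map `R` from normalized difference data to a masked
#' 32x32 pixel image by the GREIT recipe: small conductivity-decrease
#' targets are placed on a uniform in-domain grid, their difference data
#' `y_t` simulated through the Jacobian, and `R` chosen to minimize
#' `sum_t || xd_t - R y_t ||^2 + lambda^2 || R Sigma_n^{1/2} ||_F^2`,
#' i.e. `R = Xd Y' (Y Y' + lambda^2 Sigma_n)^{-1}`, with the desired image
#' `xd_t` a uniform disk of unit pixel sum around each target. The
#' regularization weight `lambda` is calibrated by a deterministic
#' monotone 1-D search so that the achieved noise figure (measurement SNR
#' over image SNR for the central training target) matches
#' `noise_figure` within 0.1%.
#'
#' @param jacobian An `eit_jacobian` from [compute_jacobian()] at the
#'   homogeneous training background.
#' @param n_targets Number of training targets (>= 64), taken as an evenly
#'   spaced subset of the in-domain candidate grid; `NULL` keeps all
#'   candidates (default grid: 32 x 32 centres, ~800 in-domain).
#' @param target_radius Radius of the conductivity target blob, as a
#'   fraction of the domain radius (0 < r < 0.5).
#' @param desired_radius Radius of the desired reconstructed disk,
#'   fraction of domain radius.
#' @param noise_figure Target noise figure (> 0).
#' @param noise_level Assumed per-channel relative measurement noise used
#'   in `Sigma_n` (diagonal).
#' @param grid_n Pixel grid side length.
#' @param keep_training Keep the training matrices `Y`, `Xd` in the
#'   returned object (needed for cross-checks; a few MB).
#' @return Object of class `greit`: list with the reconstruction matrix
#'   `R` (n_masked_pixels x 208), `lambda`, `nf` (achieved), `nf_target`,
#'   `grid`, and training metadata. Use [predict.greit()] to reconstruct.
#' @export
greit <- function(jacobian, n_targets = NULL, target_radius = 0.08,
                  desired_radius = 0.1, noise_figure = 0.5,
                  noise_level = 5e-4, grid_n = 32, keep_training = TRUE) {
  stopifnot(inherits(jacobian, "eit_jacobian"))
  if (target_radius <= 0 || target_radius >= 0.5) {
    stop_param("`target_radius` must lie in (0, 0.5)")
  }
  check_number(noise_figure, "noise_figure", positive = TRUE)
  mesh <- jacobian$mesh
  grid <- pixel_grid(mesh$a, mesh$b, grid_n)

  # candidate target centres: in-domain pixel centres where the blob fits
  rad_norm <- sqrt((grid$px[, 1L] / mesh$a)^2 + (grid$px[, 2L] / mesh$b)^2)
  cand <- which(rad_norm <= 1 - target_radius)
  if (!is.null(n_targets)) {
    if (n_targets < 64) stop_param("`n_targets` must be >= 64")
    if (n_targets < length(cand)) {
      cand <- cand[unique(round(seq(1, length(cand),
                                    length.out = n_targets)))]
    }
  }
  centers <- grid$px[cand, , drop = FALSE]
  n_t <- nrow(centers)

  ctr <- element_centroids(mesh)
  m <- nrow(mesh$elements)
  # conductivity-decrease indicator per target (nearest element fallback)
  ti <- tj <- integer(0)
  for (t in seq_len(n_t)) {
    d2 <- (ctr[, 1L] - centers[t, 1L])^2 + (ctr[, 2L] - centers[t, 2L])^2
    e <- which(d2 <= target_radius^2)
    if (length(e) == 0L) e <- which.min(d2)
    ti <- c(ti, e); tj <- c(tj, rep(t, length(e)))
  }
  D <- Matrix::sparseMatrix(i = ti, j = tj, x = 1, dims = c(m, n_t))
  # normalized difference data of a conductivity *decrease* (lung
  # inflation sign): positive image amplitude for inspiration
  Y <- as.matrix(-(jacobian$J %*% D) / jacobian$v0)

  # desired images: uniform disk, unit pixel sum
  n_px <- nrow(grid$px)
  Xd <- matrix(0, n_px, n_t)
  for (t in seq_len(n_t)) {
    d2 <- (grid$px[, 1L] - centers[t, 1L])^2 +
      (grid$px[, 2L] - centers[t, 2L])^2
    inside <- d2 <= desired_radius^2
    if (!any(inside)) inside <- d2 == min(d2)
    Xd[inside, t] <- 1 / sum(inside)
  }

  sig_n <- rep(sqrt(2) * noise_level, nrow(Y)) # difference of two noisy frames
  YYt <- tcrossprod(Y)
  XYt <- tcrossprod(Xd, Y)
  central <- which.min(rowSums(centers^2))
  y_s <- Y[, central]

  R_of <- function(lam) {
    A <- YYt + diag(lam^2 * sig_n^2, nrow(YYt))
    t(solve(A, t(XYt)))
  }
  nf_of <- function(lam) {
    R <- R_of(lam)
    x_s <- as.vector(R %*% y_s)
    x_n <- sqrt(rowSums(sweep(R, 2L, sig_n, "*")^2))
    (mean(abs(y_s)) / mean(sig_n)) / (mean(abs(x_s)) / mean(x_n))
  }
  # NF decreases monotonically in lambda; root-find in log10(lambda)
  # relative to the scale where data and regularization terms balance.
  # Reciprocity makes measurement pairs coincide, so Y Y' is rank
  # deficient and the unregularized limit is singular: the lower bracket
  # is raised until the system is solvable.
  lam0 <- sqrt(mean(diag(YYt)) / mean(sig_n^2))
  f <- function(l) log(nf_of(lam0 * 10^l)) - log(noise_figure)
  lo <- -5; hi <- 5
  flo <- NULL
  while (lo < hi) {
    flo <- try(f(lo), silent = TRUE)
    if (!inherits(flo, "try-error") && is.finite(flo)) break
    lo <- lo + 1
  }
  fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop_param(paste0("noise-figure calibration failed to bracket the ",
                      "target: NF(%.3g)=%.3g, NF(%.3g)=%.3g, target %.3g"),
               lam0 * 10^lo, exp(flo) * noise_figure,
               lam0 * 10^hi, exp(fhi) * noise_figure, noise_figure)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  lambda <- lam0 * 10^root$root
  R <- R_of(lambda)
  nf <- nf_of(lambda)

  structure(list(
    R = R, lambda = lambda, nf = nf, nf_target = noise_figure,
    grid = grid, mesh = mesh, centers = centers,
    target_radius = target_radius, desired_radius = desired_radius,
    noise_level = noise_level,
    training = if (keep_training) list(Y = Y, Xd = Xd, sig_n = sig_n)
  ), class = "greit")
}

#' @export
print.greit <- function(x, ...) {
  cat(sprintf(paste0(
    "GREIT reconstruction model\n  %d x %d pixel grid, %d in-mask pixels\n",
    "  %d training targets (blob radius %.2g, desired radius %.2g)\n",
    "  lambda = %.4g, noise figure %.4g (target %.4g)\n"),
    x$grid$n, x$grid$n, nrow(x$grid$px), nrow(x$centers),
    x$target_radius, x$desired_radius, x$lambda, x$nf, x$nf_target))
  invisible(x)
}

#' Reconstruct a time-difference image sequence
#'
#' Applies the trained linear map frame by frame: `x = R dv`. If raw
#' frames are supplied, they are first converted to normalized difference
#' data against `reference`; `reference = "auto"` detects the first
#' end-expiration frame from a provisional reconstruction (falling back
#' to frame 1).
#'
#' @param object A `greit` model.
#' @param newdata An `eit_diff_data`, an `eit_sequence`, or a frames
#'   matrix.
#' @param reference Reference frame index, or `"auto"`.
#' @param ... Unused.
#' @return Object of class `eit_images`: list with `images` (n x n x
#'   n_frames array, masked-out pixels zero), `timestamps`, `mask`.
#' @export
predict.greit <- function(object, newdata, reference = 1L, ...) {
  if (!inherits(newdata, "eit_diff_data")) {
    if (identical(reference, "auto")) {
      prov <- predict(object, newdata, reference = 1L)
      gc <- global_curve(prov)
      reference <- first_end_expiration(gc$value)
    }
    newdata <- normalize_difference(newdata, reference)
  }
  dv <- newdata$dv
  if (ncol(dv) != ncol(object$R)) {
    stop_param("difference data has %d channels, model expects %d",
               ncol(dv), ncol(object$R))
  }
  Xp <- object$R %*% t(dv) # n_px x n_frames
  n <- object$grid$n
  n_fr <- ncol(Xp)
  images <- array(0, dim = c(n, n, n_fr))
  mask_idx <- which(object$grid$mask)
  flat <- matrix(0, n * n, n_fr)
  flat[mask_idx, ] <- as.matrix(Xp)
  images <- array(flat, dim = c(n, n, n_fr))
  structure(list(images = images, timestamps = newdata$timestamps,
                 mask = object$grid$mask,
                 reference_frame = newdata$reference_frame),
            class = "eit_images")
}

# first end-expiration (first prominent local minimum) of a global curve;
# falls back to frame 1 when detection fails
first_end_expiration <- function(values) {
  seg <- try(detect_breaths(values), silent = TRUE)
  if (inherits(seg, "try-error") || length(seg$ends_exp) == 0L) {
    return(1L)
  }
  seg$ends_exp[1L]
}

#' @export
print.eit_images <- function(x, ...) {
  cat(sprintf("EIT image sequence: %d frames of %d x %d (%d in-mask pixels)\n",
              dim(x$images)[3L], dim(x$images)[1L], dim(x$images)[2L],
              sum(x$mask)))
  invisible(x)
}

#' @export
plot.eit_images <- function(x, frame = dim(x$images)[3L], ...) {
  img <- x$images[, , frame]
  # image() draws row 1 at the bottom; flip so ventral (row 1) is on top
  graphics::image(t(img[rev(seq_len(nrow(img))), ]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, asp = 1, ...)
  graphics::title(sprintf("frame %d (ventral up, right on left)", frame))
  invisible(x)
}

#' @export
plot.greit <- function(x, target = NULL, ...) {
  if (is.null(x$training)) stop_param("model was trained with keep_training = FALSE")
  if (is.null(target)) target <- which.min(rowSums(x$centers^2))
  rec <- as.vector(x$R %*% x$training$Y[, target])
  n <- x$grid$n
  img <- matrix(0, n, n)
  img[x$grid$mask] <- rec
  graphics::image(t(img[rev(seq_len(n)), ]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, asp = 1, ...)
  graphics::title(sprintf("point-spread, target %d", target))
  invisible(x)
}
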