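#' Two-lung breathing thorax phantom
#'
#' Defines the ground-truth conductivity model behind the synthetic data:
#' a homogeneous background with two elliptical lung regions whose
#' conductivity is coupled linearly to lung volume,
#' `sigma(t) = sigma_exp - k * w_region * V(t)`,
#' where `V(t)` is volume above FRC (litres), `k` the conductivity swing
#' per litre, and `w_region` the regional ventilation weight (right + left
#' = 1). Air entering the lung lowers its conductivity, so `k > 0` makes
#' conductivity fall on inspiration. Optional per-lung first-order lag
#' time constants delay each lung's volume signal, injecting known
#' regional ventilation delay for RVD testing.
#'
#' The mesh orientation convention puts the subject's right lung at x < 0
#' (see [build_thorax_mesh()]).
#'
#' @param mesh An `eit_mesh`.
#' @param sigma_background Background (non-lung) conductivity, S/m.
#' @param sigma_lung_exp Lung conductivity at end-expiration, S/m.
#' @param swing_per_L Conductivity decrease per litre of regional volume
#'   (S/m per L, > 0).
#' @param right_weight Fraction of ventilation going to the right lung,
#'   in (0, 1); left weight is `1 - right_weight`.
#' @param lung_centers 2 x 2 matrix of (right; left) lung ellipse centres.
#' @param lung_axes 2 x 2 matrix of (right; left) lung semi-axes.
#' @param tau_right,tau_left First-order lag time constants (s) of the
#'   regional volume signals; 0 = no delay.
#' @param dorsal_weight Optional ventral-dorsal skew in (0, 1): fraction of
#'   each lung's swing assigned to its dorsal half (0.5 = uniform).
#' @return Object of class `eit_phantom`; carries the per-element lung
#'   masks (`right_elems`, `left_elems`).
#' @export
phantom_config <- function(mesh,
                           sigma_background = 0.48,
                           sigma_lung_exp = 0.24,
                           swing_per_L = 0.02,
                           right_weight = 0.5,
                           lung_centers = rbind(c(-0.45, -0.05),
                                                c(0.45, -0.05)),
                           lung_axes = rbind(c(0.32, 0.45),
                                             c(0.32, 0.45)),
                           tau_right = 0, tau_left = 0,
                           dorsal_weight = 0.5) {
  check_number(sigma_background, "sigma_background", positive = TRUE)
  check_number(sigma_lung_exp, "sigma_lung_exp", positive = TRUE)
  check_number(swing_per_L, "swing_per_L", positive = TRUE)
  check_number(right_weight, "right_weight")
  if (right_weight <= 0 || right_weight >= 1) {
    stop_param("`right_weight` must lie strictly in (0, 1)")
  }
  check_number(tau_right, "tau_right", nonneg = TRUE)
  check_number(tau_left, "tau_left", nonneg = TRUE)
  if (dorsal_weight <= 0 || dorsal_weight >= 1) {
    stop_param("`dorsal_weight` must lie strictly in (0, 1)")
  }
  ctr <- element_centroids(mesh)
  in_ellipse <- function(k) {
    ((ctr[, 1L] - lung_centers[k, 1L]) / lung_axes[k, 1L])^2 +
      ((ctr[, 2L] - lung_centers[k, 2L]) / lung_axes[k, 2L])^2 <= 1
  }
  right_elems <- which(in_ellipse(1L))
  left_elems <- which(in_ellipse(2L))
  if (length(intersect(right_elems, left_elems)) > 0) {
    stop_param("lung ellipses overlap")
  }
  if (length(right_elems) == 0 || length(left_elems) == 0) {
    stop_param("a lung ellipse contains no mesh elements")
  }
  # lung ellipses must sit inside the domain
  nd <- mesh$nodes[unique(as.vector(mesh$elements[c(right_elems, left_elems), ])), ,
                   drop = FALSE]
  if (any((nd[, 1L] / mesh$a)^2 + (nd[, 2L] / mesh$b)^2 > 1 + 1e-9)) {
    stop_param("lung ellipses extend outside the domain")
  }
  structure(list(
    mesh = mesh, sigma_background = sigma_background,
    sigma_lung_exp = sigma_lung_exp, swing_per_L = swing_per_L,
    right_weight = right_weight, lung_centers = lung_centers,
    lung_axes = lung_axes, tau_right = tau_right, tau_left = tau_left,
    dorsal_weight = dorsal_weight,
    right_elems = right_elems, left_elems = left_elems
  ), class = "eit_phantom")
}

#' @export
print.eit_phantom <- function(x, ...) {
  cat(sprintf(paste0(
    "EIT breathing phantom: bg %.3g S/m, lung(exp) %.3g S/m, ",
    "swing %.3g S/m/L\n  right weight %.2f, lags (R %.2gs, L %.2gs), ",
    "%d + %d lung elements\n"),
    x$sigma_background, x$sigma_lung_exp, x$swing_per_L, x$right_weight,
    x$tau_right, x$tau_left, length(x$right_elems), length(x$left_elems)))
  invisible(x)
}

# first-order lag of a sampled signal; tau = 0 returns the input
lag_signal <- function(v, dt, tau) {
  if (tau <= 0) return(v)
  out <- numeric(length(v))
  out[1L] <- v[1L]
  a <- dt / (tau + dt)
  for (i in 2:length(v)) out[i] <- out[i - 1L] + a * (v[i] - out[i - 1L])
  out
}

# per-element conductivity for regional volumes (litres above FRC)
phantom_sigma <- function(phantom, v_right, v_left) {
  p <- phantom
  sigma <- rep(p$sigma_background, nrow(p$mesh$elements))
  ctr <- element_centroids(p$mesh)
  sw_r <- regional_swing_weights(p, p$right_elems, 1L, ctr)
  sw_l <- regional_swing_weights(p, p$left_elems, 2L, ctr)
  sigma[p$right_elems] <- p$sigma_lung_exp -
    p$swing_per_L * p$right_weight * v_right * sw_r
  sigma[p$left_elems] <- p$sigma_lung_exp -
    p$swing_per_L * (1 - p$right_weight) * v_left * sw_l
  sigma
}

# unit-mean multiplicative weights implementing the ventral-dorsal skew
regional_swing_weights <- function(phantom, elems, lung, ctr) {
  w <- rep(1, length(elems))
  if (phantom$dorsal_weight != 0.5) {
    dorsal <- ctr[elems, 2L] < phantom$lung_centers[lung, 2L]
    w[dorsal] <- 2 * phantom$dorsal_weight
    w[!dorsal] <- 2 * (1 - phantom$dorsal_weight)
  }
  w
}
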