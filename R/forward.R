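#' Adjacent-drive stimulation protocol
#'
#' The 16-electrode adjacent (neighbouring) pattern: current is driven
#' through each of the 16 adjacent electrode pairs in turn, and for every
#' drive the voltage is measured across each adjacent pair that shares no
#' electrode with the drive pair, giving 16 x 13 = 208 measurements per
#' frame.
#'
#' @param current Drive current amplitude in amperes (device default 5 mA).
#' @param frequency Carrier frequency in Hz; metadata only, the quasi-static
#'   forward model does not use it.
#' @return An object of class `eit_protocol` with `drive_pairs` (16 x 2),
#'   `meas` (per-drive list of 13 x 2 measurement pairs), `index` (208 x 4
#'   bookkeeping matrix: drive, meas pattern, electrode +, electrode -),
#'   `current`, `frequency`.
#' @export
adjacent_protocol <- function(current = 5e-3, frequency = 1e5) {
  check_number(current, "current", positive = TRUE)
  nxt <- function(k) k %% 16L + 1L
  drive_pairs <- cbind(1:16, nxt(1:16))
  meas <- vector("list", 16L)
  idx <- NULL
  for (d in 1:16) {
    keep <- vapply(1:16, function(m) {
      length(intersect(c(m, nxt(m)), drive_pairs[d, ])) == 0L
    }, logical(1))
    mm <- cbind((1:16)[keep], nxt((1:16)[keep]))
    meas[[d]] <- mm
    idx <- rbind(idx, cbind(d, (1:16)[keep], mm))
  }
  colnames(idx) <- c("drive", "meas", "el_pos", "el_neg")
  structure(list(drive_pairs = drive_pairs, meas = meas, index = idx,
                 n_meas = nrow(idx), current = current,
                 frequency = frequency),
            class = "eit_protocol")
}

#' Complete-electrode contact model
#'
#' @param contact_impedance Effective contact impedance in ohm-metre
#'   (2D complete-electrode model units), uniform across electrodes. The
#'   default 1e-3 is small relative to the tissue impedance scale, so the
#'   forward map is Ohmic (inverse in conductivity) to well below 1%.
#' @param point_electrodes If `TRUE`, currents are injected at single
#'   boundary nodes (the node nearest each electrode centre) instead of
#'   through the complete-electrode boundary condition. Test-only fallback
#'   used to compare against the analytic homogeneous-disk solution.
#' @return An object of class `eit_electrode_model`.
#' @export
electrode_model <- function(contact_impedance = 1e-3,
                            point_electrodes = FALSE) {
  check_number(contact_impedance, "contact_impedance", positive = TRUE)
  structure(list(contact_impedance = contact_impedance,
                 point_electrodes = isTRUE(point_electrodes)),
            class = "eit_electrode_model")
}

# Precompute everything that does not depend on sigma: stiffness triplet
# pattern (per-element coefficients), electrode boundary terms, measurement
# extraction, and P1 gradient operators. The constant-potential null space
# is removed by grounding node 1 (the mesh centre); all measurements are
# electrode-pair differences, so the choice of ground is immaterial.
fem_precompute <- function(mesh, protocol, electrodes) {
  nodes <- mesh$nodes; el <- mesh$elements
  n_nodes <- nrow(nodes); m <- nrow(el)
  x <- matrix(nodes[el, 1L], m, 3L)
  y <- matrix(nodes[el, 2L], m, 3L)
  area <- tri_signed_areas(nodes, el) # positive by construction
  # P1 basis gradients: grad phi_i = (b_i, c_i)
  b <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L]) /
    (2 * area)
  cc <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L]) /
    (2 * area)

  ii <- jj <- ee <- integer(9L * m); coef <- numeric(9L * m)
  k <- 0L
  for (i in 1:3) {
    for (j in 1:3) {
      idx <- k * m + seq_len(m)
      ii[idx] <- el[, i]; jj[idx] <- el[, j]; ee[idx] <- seq_len(m)
      coef[idx] <- area * (b[, i] * b[, j] + cc[, i] * cc[, j])
      k <- k + 1L
    }
  }

  L <- length(mesh$electrodes)
  ndof_full <- n_nodes + L
  elec_dofs_full <- n_nodes + seq_len(L)

  e_i <- e_j <- integer(0); e_x <- numeric(0)
  if (!electrodes$point_electrodes) {
    z <- electrodes$contact_impedance
    for (l in seq_len(L)) {
      for (edge in mesh$electrodes[[l]]) {
        p <- mesh$boundary_edges[edge, 1L]
        q <- mesh$boundary_edges[edge, 2L]
        le <- sqrt(sum((nodes[p, ] - nodes[q, ])^2))
        e_i <- c(e_i, p, q, p, q, p, elec_dofs_full[l], q, elec_dofs_full[l],
                 elec_dofs_full[l])
        e_j <- c(e_j, p, q, q, p, elec_dofs_full[l], p, elec_dofs_full[l], q,
                 elec_dofs_full[l])
        e_x <- c(e_x, le / (3 * z), le / (3 * z), le / (6 * z), le / (6 * z),
                 -le / (2 * z), -le / (2 * z), -le / (2 * z), -le / (2 * z),
                 le / z)
      }
    }
    inject_nodes <- NULL
  } else {
    # point mode: electrode dof tied to its centre boundary node by a stiff
    # penalty link so the same dof layout and extraction applies
    penal <- 1e8
    inject_nodes <- integer(L)
    for (l in seq_len(L)) {
      edges <- mesh$boundary_edges[mesh$electrodes[[l]], , drop = FALSE]
      cand <- unique(as.vector(edges))
      ctr <- colMeans(nodes[cand, , drop = FALSE])
      inject_nodes[l] <- cand[which.min((nodes[cand, 1L] - ctr[1L])^2 +
                                          (nodes[cand, 2L] - ctr[2L])^2)]
      p <- inject_nodes[l]
      e_i <- c(e_i, p, elec_dofs_full[l], p, elec_dofs_full[l])
      e_j <- c(e_j, p, p, elec_dofs_full[l], elec_dofs_full[l])
      e_x <- c(e_x, penal, -penal, -penal, penal)
    }
  }

  # ground node 1: drop its row/column, remap dof k -> k-1
  keep <- ii != 1L & jj != 1L
  ii <- ii[keep] - 1L; jj <- jj[keep] - 1L
  ee <- ee[keep]; coef <- coef[keep]
  keep_e <- e_i != 1L & e_j != 1L
  e_i <- e_i[keep_e] - 1L; e_j <- e_j[keep_e] - 1L; e_x <- e_x[keep_e]
  ndof <- ndof_full - 1L
  elec_dofs <- elec_dofs_full - 1L

  # current patterns: one column per adjacent pair (used both as drives and
  # as measurement adjoint fields)
  B <- matrix(0, ndof, 16L)
  for (d in 1:16) {
    pr <- protocol$drive_pairs[d, ]
    B[elec_dofs[pr[1L]], d] <- protocol$current
    B[elec_dofs[pr[2L]], d] <- -protocol$current
  }

  gi <- rep(seq_len(m), 3L)
  Gx <- Matrix::sparseMatrix(i = gi, j = as.vector(el), x = as.vector(b),
                             dims = c(m, n_nodes))
  Gy <- Matrix::sparseMatrix(i = gi, j = as.vector(el), x = as.vector(cc),
                             dims = c(m, n_nodes))

  list(mesh = mesh, protocol = protocol, electrodes = electrodes,
       ii = ii, jj = jj, ee = ee, coef = coef,
       e_i = e_i, e_j = e_j, e_x = e_x,
       ndof = ndof, elec_dofs = elec_dofs, n_nodes = n_nodes,
       area = area, B = B, Gx = Gx, Gy = Gy,
       inject_nodes = inject_nodes)
}

fem_assemble <- function(pre, sigma) {
  Matrix::sparseMatrix(i = c(pre$ii, pre$e_i), j = c(pre$jj, pre$e_j),
                       x = c(pre$coef * sigma[pre$ee], pre$e_x),
                       dims = c(pre$ndof, pre$ndof))
}

# Solve all 16 adjacent current patterns; returns the ndof x 16 solution.
fem_solve_patterns <- function(pre, sigma) {
  A <- fem_assemble(pre, sigma)
  U <- try(Matrix::solve(A, pre$B), silent = TRUE)
  if (inherits(U, "try-error")) {
    stop_param("forward system is singular or ill-conditioned: %s",
               attr(U, "condition")$message)
  }
  as.matrix(U)
}

extract_measurements <- function(pre, U) {
  Uel <- U[pre$elec_dofs, , drop = FALSE] # 16 electrodes x 16 drives
  idx <- pre$protocol$index
  Uel[cbind(idx[, "el_pos"], idx[, "drive"])] -
    Uel[cbind(idx[, "el_neg"], idx[, "drive"])]
}

#' Solve the EIT forward problem for one frame
#'
#' Complete-electrode-model finite-element solve of the 2D conductivity
#' equation for every drive pattern of the protocol, returning the 208
#' adjacent-pair boundary voltages.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element conductivity vector (S/m, all > 0).
#' @param protocol An `eit_protocol` (default adjacent, 5 mA).
#' @param electrodes An `eit_electrode_model`.
#' @param pre Optional precomputed FEM structure from an earlier call
#'   (internal reuse; must match `mesh`/`protocol`/`electrodes`).
#' @return Numeric vector of 208 voltages (V), ordered drive-major.
#' @examples
#' mesh <- build_thorax_mesh("circle", 1)
#' v <- solve_forward(mesh, rep(1, nrow(mesh$elements)))
#' length(v)
#' @export
solve_forward <- function(mesh, sigma, protocol = adjacent_protocol(),
                          electrodes = electrode_model(), pre = NULL) {
  check_sigma(mesh, sigma)
  if (is.null(pre)) pre <- fem_precompute(mesh, protocol, electrodes)
  extract_measurements(pre, fem_solve_patterns(pre, sigma))
}

check_sigma <- function(mesh, sigma) {
  if (length(sigma) != nrow(mesh$elements)) {
    stop_param("sigma has %d values but the mesh has %d elements",
               length(sigma), nrow(mesh$elements))
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop_param("conductivity must be finite and strictly positive")
  }
  invisible(sigma)
}

#' Sensitivity (Jacobian) of the forward map at a baseline conductivity
#'
#' Computes the 208 x n_elements matrix `J[m, e] = d v_m / d sigma_e` at
#' `sigma0` by the adjoint method: for measurement (drive d, pattern m),
#' `J = -(area_e / I) * grad(u_d) . grad(u_m)` where `u_d`, `u_m` are the
#' fields of the drive and the measurement current pattern.
#'
#' @inheritParams solve_forward
#' @param sigma0 Baseline per-element conductivity (S/m).
#' @return An object of class `eit_jacobian`: list with `J` (208 x m),
#'   `v0` (baseline voltages), `sigma0`, and the mesh/protocol handles.
#' @export
compute_jacobian <- function(mesh, sigma0, protocol = adjacent_protocol(),
                             electrodes = electrode_model(), pre = NULL) {
  check_sigma(mesh, sigma0)
  if (is.null(pre)) pre <- fem_precompute(mesh, protocol, electrodes)
  U <- fem_solve_patterns(pre, sigma0)
  v0 <- extract_measurements(pre, U)
  # re-insert the grounded node (potential 0) for gradient evaluation
  Un <- rbind(0, U[seq_len(pre$n_nodes - 1L), , drop = FALSE])
  GX <- as.matrix(pre$Gx %*% Un)
  GY <- as.matrix(pre$Gy %*% Un)
  idx <- pre$protocol$index
  I0 <- pre$protocol$current
  J <- -(GX[, idx[, "drive"], drop = FALSE] * GX[, idx[, "meas"], drop = FALSE] +
           GY[, idx[, "drive"], drop = FALSE] * GY[, idx[, "meas"], drop = FALSE]) *
    pre$area / I0
  J <- t(J) # 208 x m
  structure(list(J = J, v0 = v0, sigma0 = sigma0, mesh = mesh,
                 protocol = protocol, electrodes = electrodes),
            class = "eit_jacobian")
}

#' Analytic adjacent-drive voltages on a homogeneous unit disk
#'
#' Closed-form boundary potential for point current injection on the unit
#' disk: a source/sink pair (+I at angle `ta`, -I at `tb`) produces
#' `u(z) = (I / (pi * sigma)) * log(|z - z_b| / |z - z_a|)`. Used as the
#' independent oracle for the finite-element solver in point-electrode
#' mode.
#'
#' @param protocol An `eit_protocol`.
#' @param sigma Homogeneous conductivity (S/m).
#' @param electrode_angles Angular positions (radians) of the 16 electrodes.
#' @return 208-vector of analytic voltages matching the protocol ordering.
#' @export
disk_analytic_voltages <- function(protocol, sigma = 1,
                                   electrode_angles =
                                     pi / 2 - (0:15) * pi / 8) {
  z <- cbind(cos(electrode_angles), sin(electrode_angles))
  I0 <- protocol$current
  pot <- function(a, b, p) { # potential at boundary point p
    (I0 / (pi * sigma)) *
      log(sqrt(sum((p - z[b, ])^2)) / sqrt(sum((p - z[a, ])^2)))
  }
  idx <- protocol$index
  vapply(seq_len(nrow(idx)), function(r) {
    d <- idx[r, "drive"]
    a <- protocol$drive_pairs[d, 1L]; b <- protocol$drive_pairs[d, 2L]
    pot(a, b, z[idx[r, "el_pos"], ]) - pot(a, b, z[idx[r, "el_neg"], ])
  }, numeric(1))
}
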