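#' Measurement noise and drift model
#'
#' Noise is multiplicative Gaussian per measurement (scale-relative, the
#' natural counterpart of the SNR definition used for bench QC:
#' relative level 5e-4 corresponds to 66 dB). Drift is a linear fractional
#' gain change over time.
#'
#' @param noise_rel Relative standard deviation of the multiplicative
#'   Gaussian noise (>= 0). Default 5e-4 (about 66 dB), comfortably inside
#'   the device-class SNR bound of 60 dB.
#' @param drift_per_hour Linear fractional gain change per hour.
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `eit_noise_model`.
#' @export
noise_model <- function(noise_rel = 5e-4, drift_per_hour = 0, seed = NULL) {
  check_number(noise_rel, "noise_rel", nonneg = TRUE)
  check_number(drift_per_hour, "drift_per_hour")
  structure(list(noise_rel = noise_rel, drift_per_hour = drift_per_hour,
                 seed = seed), class = "eit_noise_model")
}

new_eit_sequence <- function(frames, timestamps, protocol = NULL,
                             device = "A", seed = NULL) {
  stopifnot(nrow(frames) == length(timestamps), all(is.finite(frames)))
  structure(list(frames = frames, timestamps = timestamps,
                 protocol = protocol, device = device, seed = seed),
            class = "eit_sequence")
}

#' @export
print.eit_sequence <- function(x, ...) {
  cat(sprintf("EIT frame sequence: %d frames x %d channels, %.3g s, device %s\n",
              nrow(x$frames), ncol(x$frames), diff(range(x$timestamps)),
              x$device))
  invisible(x)
}

apply_noise <- function(frames, timestamps, noise) {
  with_seed(noise$seed, {
    out <- frames
    if (noise$noise_rel > 0) {
      out <- out * (1 + stats::rnorm(length(out), sd = noise$noise_rel))
    }
    if (noise$drift_per_hour != 0) {
      out <- out * (1 + noise$drift_per_hour * timestamps / 3600)
    }
    out
  })
}

# noiseless voltage frames for a phantom/protocol; shared by
# simulate_sequence and emulate_two_devices
simulate_core <- function(phantom, protocol, frame_rate,
                          stim = adjacent_protocol(),
                          electrodes = electrode_model()) {
  tt <- seq(0, protocol$duration, by = 1 / frame_rate)
  v_glob <- volume_at(protocol, tt)
  dt <- 1 / frame_rate
  v_right <- lag_signal(v_glob, dt, phantom$tau_right)
  v_left <- lag_signal(v_glob, dt, phantom$tau_left)
  # positivity check before any solve, naming the first offending frame
  min_sig <- pmin(
    phantom$sigma_lung_exp - phantom$swing_per_L * phantom$right_weight *
      v_right * max_swing_weight(phantom, 1L),
    phantom$sigma_lung_exp - phantom$swing_per_L *
      (1 - phantom$right_weight) * v_left * max_swing_weight(phantom, 2L))
  if (any(min_sig <= 0)) {
    stop_param("conductivity driven <= 0 at frame %d; reduce swing_per_L",
               which(min_sig <= 0)[1L])
  }
  pre <- fem_precompute(phantom$mesh, stim, electrodes)
  frames <- matrix(0, length(tt), stim$n_meas)
  for (i in seq_along(tt)) {
    sigma <- phantom_sigma(phantom, v_right[i], v_left[i])
    frames[i, ] <- extract_measurements(pre, fem_solve_patterns(pre, sigma))
  }
  # ground truth: frame indices bracketing the SVC maneuver
  t_tidal <- protocol$n_tidal * protocol$tidal_period
  svc <- c(start = which.min(abs(tt - t_tidal)),
           peak = which.min(abs(tt - (t_tidal + protocol$svc_insp_s))),
           end = length(tt))
  list(frames = frames, timestamps = tt, volume = v_glob,
       v_right = v_right, v_left = v_left, svc = svc, pre = pre)
}

max_swing_weight <- function(phantom, lung) {
  if (phantom$dorsal_weight == 0.5) 1 else 2 * max(phantom$dorsal_weight,
                                                   1 - phantom$dorsal_weight)
}

#' Simulate a breathing EIT recording with matched spirometry
#'
#' Runs the complete-electrode forward model frame by frame while the
#' phantom's lung conductivity follows the breathing protocol,
#' `sigma(t) = sigma_exp - k * w_region * V_region(t)`, applies
#' multiplicative Gaussian measurement noise, and returns the frame
#' sequence together with a spirometry trace sampled at its own rate and
#' the generator's ground truth.
#'
#' @param phantom An `eit_phantom`.
#' @param protocol A `breathing_protocol`.
#' @param noise An `eit_noise_model`.
#' @param spiro_rate Spirometer sampling rate, Hz.
#' @param device Device label stored in the sequence.
#' @param stim Stimulation protocol (`eit_protocol`).
#' @param electrodes Electrode model.
#' @param core Optional precomputed noiseless core from a previous call
#'   with the same phantom/protocol (reused by [emulate_two_devices()]).
#' @return List with `sequence` (`eit_sequence`), `spirometry`
#'   (`spirometry_trace`) and `truth` (list: `volume` per frame, regional
#'   volumes, `right_fraction`, `svc` frame indices, lung element sets).
#' @export
simulate_sequence <- function(phantom, protocol = breathing_protocol(),
                              noise = noise_model(), spiro_rate = 25,
                              device = "A",
                              stim = adjacent_protocol(),
                              electrodes = electrode_model(),
                              core = NULL) {
  if (is.null(core)) {
    core <- simulate_core(phantom, protocol, protocol$frame_rate, stim,
                          electrodes)
  }
  frames <- apply_noise(core$frames, core$timestamps, noise)
  seq <- new_eit_sequence(frames, core$timestamps, stim, device, noise$seed)
  truth <- list(volume = core$volume, v_right = core$v_right,
                v_left = core$v_left,
                right_fraction = phantom$right_weight,
                svc = core$svc, right_elems = phantom$right_elems,
                left_elems = phantom$left_elems)
  list(sequence = seq, spirometry = volume_waveform(protocol, spiro_rate),
       truth = truth, core = core)
}

#' Emulate the four-recording device-comparison sequence
#'
#' Reproduces the study's measurement sequence — device A, device B,
#' device A again, device B again on the same subject — as four frame
#' sequences sharing one noiseless forward simulation but carrying
#' independent noise realizations.
#'
#' @inheritParams simulate_sequence
#' @param seeds Four integer seeds (one per recording). Duplicated seeds
#'   produce identical noise and trigger a warning.
#' @param noise_a,noise_b Noise models for devices A and B (seed fields are
#'   overridden by `seeds`).
#' @return List of four elements as from [simulate_sequence()], named
#'   `A1`, `B1`, `A2`, `B2` in measurement order.
#' @export
emulate_two_devices <- function(phantom, protocol = breathing_protocol(),
                                seeds = c(1L, 2L, 3L, 4L),
                                noise_a = noise_model(),
                                noise_b = noise_model(),
                                spiro_rate = 25,
                                stim = adjacent_protocol(),
                                electrodes = electrode_model()) {
  if (length(seeds) != 4L) stop_param("`seeds` must hold four integers")
  if (anyDuplicated(seeds)) {
    warning("duplicate seeds: recordings will share a noise realization")
  }
  core <- simulate_core(phantom, protocol, protocol$frame_rate, stim,
                        electrodes)
  labels <- c("A1", "B1", "A2", "B2")
  models <- list(noise_a, noise_b, noise_a, noise_b)
  out <- lapply(1:4, function(i) {
    nm <- models[[i]]; nm$seed <- seeds[i]
    simulate_sequence(phantom, protocol, nm, spiro_rate,
                      device = substr(labels[i], 1, 1), stim, electrodes,
                      core = core)
  })
  names(out) <- labels
  out
}

#' Synthetic resistor-network bench recording
#'
#' Emulates the bench QC setup: the device drives a resistive network
#' (100 ohms between every channel pair) with 5 mA, so every measuring
#' pair sees a nominal constant 0.5 V; the recording adds multiplicative
#' noise and linear drift.
#'
#' @param duration_s Recording length in seconds (bench protocol: 1 hour).
#' @param frame_rate Frames per second.
#' @param noise An `eit_noise_model`.
#' @param n_channels Number of measurement channels (device: 16).
#' @param baseline_v Nominal per-channel voltage (V); 0.5 = 100 ohm x 5 mA.
#' @return An `eit_sequence` with `n_channels` columns.
#' @examples
#' rec <- resistor_network_recording(10, 10, noise_model(0, 0))
#' all(rec$frames == 0.5)
#' @export
resistor_network_recording <- function(duration_s = 3600, frame_rate = 50,
                                       noise = noise_model(),
                                       n_channels = 16,
                                       baseline_v = 0.5) {
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(frame_rate, "frame_rate", positive = TRUE)
  tt <- seq(0, duration_s, by = 1 / frame_rate)
  frames <- matrix(baseline_v, length(tt), n_channels)
  frames <- apply_noise(frames, tt, noise)
  new_eit_sequence(frames, tt, NULL, device = "bench", seed = noise$seed)
}

#' Write / read an EIT frame sequence as flat CSV
#'
#' One frame per row; first column `time_s`, remaining columns `ch001`,
#' `ch002`, ... in protocol order.
#'
#' @param seq An `eit_sequence`.
#' @param path File path.
#' @export
write_frames_csv <- function(seq, path) {
  d <- data.frame(time_s = seq$timestamps, seq$frames)
  names(d) <- c("time_s", sprintf("ch%03d", seq_len(ncol(seq$frames))))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path) {
  d <- utils::read.csv(path)
  if (names(d)[1L] != "time_s") stop_param("first column must be time_s")
  new_eit_sequence(as.matrix(d[, -1L, drop = FALSE]), d$time_s,
                   NULL, device = "file")
}
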