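#' Breathing protocol: tidal breaths followed by a slow vital capacity
#'
#' Describes the maneuver the study protocol prescribes: relaxed tidal
#' breathing at functional residual capacity (FRC) level, followed by one
#' slow vital capacity (SVC) excursion — a slow maximal inspiration and a
#' slow maximal expiration back to FRC.
#'
#' @param n_tidal Number of tidal breaths before the SVC.
#' @param tidal_volume Tidal volume in litres.
#' @param tidal_period Tidal breath period in seconds.
#' @param vital_capacity SVC volume in litres.
#' @param svc_insp_s,svc_exp_s SVC inspiration / expiration durations (s).
#' @param frame_rate EIT frame rate in Hz (device setting 50 Hz).
#' @return Object of class `breathing_protocol`.
#' @export
breathing_protocol <- function(n_tidal = 3, tidal_volume = 0.5,
                               tidal_period = 4, vital_capacity = 4,
                               svc_insp_s = 4, svc_exp_s = 4,
                               frame_rate = 50) {
  check_number(n_tidal, "n_tidal", nonneg = TRUE)
  check_number(tidal_volume, "tidal_volume", nonneg = TRUE)
  check_number(tidal_period, "tidal_period", positive = TRUE)
  check_number(vital_capacity, "vital_capacity", positive = TRUE)
  check_number(svc_insp_s, "svc_insp_s", positive = TRUE)
  check_number(svc_exp_s, "svc_exp_s", positive = TRUE)
  check_number(frame_rate, "frame_rate", positive = TRUE)
  structure(list(n_tidal = as.integer(n_tidal), tidal_volume = tidal_volume,
                 tidal_period = tidal_period,
                 vital_capacity = vital_capacity, svc_insp_s = svc_insp_s,
                 svc_exp_s = svc_exp_s, frame_rate = frame_rate,
                 duration = n_tidal * tidal_period + svc_insp_s + svc_exp_s),
            class = "breathing_protocol")
}

# Continuous lung volume above FRC (litres) at time t for a protocol:
# sinusoidal tidal cycles, then a smooth monotone SVC inspiration and
# expiration (half-cosine ramps).
volume_at <- function(protocol, t) {
  p <- protocol
  t_tidal <- p$n_tidal * p$tidal_period
  t_peak <- t_tidal + p$svc_insp_s
  v <- numeric(length(t))
  i1 <- t < t_tidal
  v[i1] <- p$tidal_volume / 2 * (1 - cos(2 * pi * t[i1] / p$tidal_period))
  i2 <- t >= t_tidal & t < t_peak
  v[i2] <- p$vital_capacity / 2 *
    (1 - cos(pi * (t[i2] - t_tidal) / p$svc_insp_s))
  i3 <- t >= t_peak
  v[i3] <- p$vital_capacity / 2 *
    (1 + cos(pi * pmin((t[i3] - t_peak) / p$svc_exp_s, 1)))
  v
}

#' Spirometry volume trace for a breathing protocol
#'
#' Samples the protocol's lung-volume waveform at the spirometer's own
#' sampling rate (deliberately different from the EIT frame rate, so that
#' downstream volume-impedance comparisons must interpolate).
#'
#' @param protocol A `breathing_protocol`.
#' @param sampling_rate Spirometer sampling rate in Hz.
#' @return Object of class `spirometry_trace`: data frame with `time_s` and
#'   `volume_L` (relative to FRC).
#' @examples
#' tr <- volume_waveform(breathing_protocol(tidal_volume = 0))
#' all(tr$volume_L[tr$time_s < 12] == 0)
#' @export
volume_waveform <- function(protocol, sampling_rate = 25) {
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  t <- seq(0, protocol$duration, by = 1 / sampling_rate)
  structure(data.frame(time_s = t, volume_L = volume_at(protocol, t)),
            sampling_rate = sampling_rate,
            class = c("spirometry_trace", "data.frame"))
}

#' Write / read a spirometry trace as two-column CSV
#' @param trace A `spirometry_trace`.
#' @param path File path.
#' @export
write_spirometry_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              volume_L = trace$volume_L),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spirometry_csv
#' @export
read_spirometry_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "volume_L") %in% names(d))) {
    stop_param("spirometry CSV must have columns time_s, volume_L")
  }
  if (any(diff(d$time_s) <= 0)) {
    stop_param("spirometry timestamps must be strictly increasing")
  }
  structure(d[c("time_s", "volume_L")],
            class = c("spirometry_trace", "data.frame"))
}
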