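#' Per-channel signal-to-noise ratio of a voltage stream
#'
#' `SNR_i = -20 log10( sqrt( (1/(N-1)) sum (V_n - Vbar)^2 ) / |Vbar| )`
#' in dB — the sample standard deviation over the mean, with the N-1
#' divisor. The absolute value of the mean is used (the printed form
#' divides by the signed mean; negative mean voltages are
#' representation-dependent, so the magnitude is taken and a note logged
#' in the report metadata).
#'
#' @param v Numeric vector of >= 2 voltage samples of one channel.
#' @return SNR in dB; `Inf` with attribute `flag = "zero-variance"` for a
#'   constant stream.
#' @examples
#' channel_snr(c(1, 1 + 1e-3, 1 - 1e-3)) # 60 dB
#' @export
channel_snr <- function(v) {
  if (length(v) < 2L) stop_param("need at least 2 samples")
  m <- mean(v)
  if (m == 0) stop_param("zero mean voltage: SNR undefined")
  s <- stats::sd(v)
  if (s == 0) {
    return(structure(Inf, flag = "zero-variance"))
  }
  -20 * log10(s / abs(m))
}

#' Mean SNR over channels
#'
#' Arithmetic mean of the per-channel SNR values.
#'
#' @param snrs Numeric vector of per-channel SNRs (dB).
#' @return Mean SNR in dB.
#' @export
mean_snr <- function(snrs) {
  if (length(snrs) == 0L) stop_param("no channel SNR values supplied")
  mean(snrs)
}

#' Drift of a channel stream over a recording window
#'
#' `100 * |mean(last sub-window) - mean(first sub-window)| /
#' mean(first sub-window)` percent, using one-minute sub-window averages
#' (noise-robust, rather than instantaneous endpoint values).
#'
#' @param v Voltage samples of one channel.
#' @param timestamps Sample times (s).
#' @param window_s Evaluation window (s); the recording must span it.
#' @param sub_window_s Averaging sub-window at each end (s).
#' @return Drift in percent.
#' @export
drift_metric <- function(v, timestamps, window_s = 3600,
                         sub_window_s = 60) {
  span <- max(timestamps) - min(timestamps)
  if (span < window_s) {
    stop_param("recording spans %.3g s, shorter than the %.3g s window",
               span, window_s)
  }
  t0 <- min(timestamps)
  first <- v[timestamps <= t0 + sub_window_s]
  last <- v[timestamps >= t0 + window_s - sub_window_s &
              timestamps <= t0 + window_s]
  100 * abs(mean(last) - mean(first)) / mean(first)
}

#' Bench QC report for a recording
#'
#' Per-channel and mean SNR plus worst-channel drift for a (typically
#' resistor-network) frame sequence.
#'
#' @param seq An `eit_sequence`.
#' @param n_samples Number of samples per channel entering the SNR (the
#'   bench protocol uses N = 1000); `NULL` uses all frames.
#' @param window_s Drift window (s); `NULL` uses the full recording span.
#' @param sub_window_s Drift averaging sub-window (s).
#' @return Object of class `eit_qc_report`.
#' @export
qc_report <- function(seq, n_samples = NULL, window_s = NULL,
                      sub_window_s = 60) {
  frames <- seq$frames
  if (!is.null(n_samples)) {
    n_samples <- min(n_samples, nrow(frames))
    frames_snr <- frames[seq_len(n_samples), , drop = FALSE]
  } else {
    n_samples <- nrow(frames)
    frames_snr <- frames
  }
  snrs <- apply(frames_snr, 2L, channel_snr)
  if (is.null(window_s)) {
    window_s <- max(seq$timestamps) - min(seq$timestamps)
  }
  drift <- max(apply(seq$frames, 2L, drift_metric,
                     timestamps = seq$timestamps, window_s = window_s,
                     sub_window_s = min(sub_window_s, window_s / 4)))
  structure(list(
    channel_snr_db = snrs, mean_snr_db = mean_snr(snrs),
    min_snr_db = min(snrs), drift_pct = drift,
    n_samples = n_samples, window_s = window_s,
    notes = "SNR uses |mean|; sample SD with N-1 divisor"
  ), class = "eit_qc_report")
}

#' @export
print.eit_qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Bench QC report (N = %d samples/channel)\n",
    "  SNR: min %.2f dB, mean %.2f dB over %d channels\n",
    "  drift over %.3g s window: %.4f %%\n"),
    x$n_samples, x$min_snr_db, x$mean_snr_db, length(x$channel_snr_db),
    x$window_s, x$drift_pct))
  invisible(x)
}

#' Serialize a QC report to JSON-like text
#' @param x An `eit_qc_report`.
#' @param path File path.
#' @export
write_qc_report <- function(x, path) {
  lines <- c(
    "{",
    sprintf('  "n_samples": %d,', x$n_samples),
    sprintf('  "mean_snr_db": %.6f,', x$mean_snr_db),
    sprintf('  "min_snr_db": %.6f,', x$min_snr_db),
    sprintf('  "drift_pct": %.6f,', x$drift_pct),
    sprintf('  "channel_snr_db": [%s],',
            paste(sprintf("%.6f", x$channel_snr_db), collapse = ", ")),
    sprintf('  "notes": "%s"', x$notes),
    "}")
  writeLines(lines, path)
  invisible(path)
}
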