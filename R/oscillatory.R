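#' High-pass filter specification for oscillatory-potential isolation
#'
#' Oscillatory potentials (OPs) are the high-frequency wavelets riding on
#' the b-wave rising phase; they are isolated by removing the slow a/b-wave
#' energy with a high-pass filter cornered at 25 Hz. The realization is an
#' order-4 Butterworth applied forward and backward (zero-phase) over a
#' reflection-padded signal, so OP timing is preserved and edge transients
#' do not leak into the analysis window.
#'
#' @param cutoff_hz High-pass corner frequency (Hz, default 25).
#' @param order Butterworth order (integer >= 2) of the one-way filter; the
#'   zero-phase pass doubles the effective order.
#' @param zero_phase Apply forward-backward filtering (default `TRUE`).
#' @param op_window_ms Optional fixed `c(start, end)` window (ms, relative
#'   to flash onset) over which the OP RMS is computed. The default `NULL`
#'   anchors the window to each trace's own landmarks, a-trough to b-peak,
#'   which is where the OPs ride and is robust to latency shifts.
#' @return An object of class `erg_filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 25, order = 4, zero_phase = TRUE,
                        op_window_ms = NULL) {
  stopifnot(is.numeric(cutoff_hz), cutoff_hz > 0,
            is.numeric(order), order >= 2,
            is.logical(zero_phase))
  if (!is.null(op_window_ms)) {
    stopifnot(length(op_window_ms) == 2L, op_window_ms[1] < op_window_ms[2])
  }
  structure(list(cutoff_hz = cutoff_hz, family = "butterworth",
                 order = as.integer(order), zero_phase = zero_phase,
                 op_window_ms = op_window_ms),
            class = "erg_filter_spec")
}

# Butterworth coefficients for a trace's sampling rate.
hp_coefficients <- function(spec, fs) {
  if (spec$cutoff_hz >= fs / 2)
    stop(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)",
                 spec$cutoff_hz, fs / 2), call. = FALSE)
  signal::butter(spec$order, W = spec$cutoff_hz / (fs / 2), type = "high")
}

# Odd-symmetric reflection padding, then one- or two-pass filtering.
filter_padded <- function(x, ba, pad, zero_phase) {
  n <- length(x)
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2, by = -1)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad, by = -1)]
  xp <- c(head_pad, x, tail_pad)
  yp <- signal::filter(ba, xp)
  if (zero_phase) {
    yp <- rev(signal::filter(ba, rev(yp)))
  }
  yp[(pad + 1):(pad + n)]
}

#' Apply the OP high-pass filter to a trace
#'
#' Filters a trace on its own time grid. The realized frequency response of
#' the default specification rejects DC essentially completely and is flat
#' (gain > 0.99) from four times the corner upward, so OP-band energy
#' (~100-120 Hz in mouse) passes unattenuated while the a/b-wave energy is
#' removed. With `zero_phase = TRUE` a passband sinusoid's peak is shifted
#' by less than one sample.
#'
#' @param trace An `erg_trace`.
#' @param spec An [filter_spec()] object; the corner must lie below the
#'   trace's Nyquist frequency.
#' @return The filtered `erg_trace`.
#' @export
highpass <- function(trace, spec = filter_spec()) {
  stopifnot(inherits(trace, "erg_trace"), inherits(spec, "erg_filter_spec"))
  ba <- hp_coefficients(spec, trace$fs)
  pad <- ceiling(3 * trace$fs / spec$cutoff_hz / 2)
  if (length(trace$samples) <= pad + 1)
    stop(sprintf("trace too short to filter: need more than %d samples", pad + 1),
         call. = FALSE)
  out <- trace
  out$samples <- filter_padded(trace$samples, ba, pad, spec$zero_phase)
  out
}

#' Realized frequency response of the OP filter
#'
#' Gain magnitude of the filter as actually applied (squared for the
#' zero-phase forward-backward pass), evaluated from the transfer function.
#'
#' @param spec An [filter_spec()] object.
#' @param fs Sampling rate (Hz).
#' @param freqs_hz Frequencies at which to evaluate the gain.
#' @return Numeric vector of gains in \[0, 1\], one per frequency.
#' @export
filter_response <- function(spec, fs, freqs_hz) {
  ba <- hp_coefficients(spec, fs)
  w <- 2 * pi * freqs_hz / fs
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(ba$b * zz^-(seq_along(ba$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(ba$a * zz^-(seq_along(ba$a) - 1)), complex(1))
  g <- Mod(num / den)
  if (spec$zero_phase) g^2 else g
}

#' Score oscillatory potentials of a trace
#'
#' High-pass filters the raw trace, computes the root-mean-square of the
#' filtered signal over the OP window, and normalizes by the same trace's
#' b-wave amplitude. The normalized statistic `op_rms / b_amp` is invariant
#' under uniform rescaling of the voltage axis, which is what makes it
#' comparable across animals of different overall response size. For a
#' per-trace scalar normalizer, dividing the RMS by `b_amp` is identical to
#' normalizing the waveform first and then taking the RMS.
#'
#' @param raw The raw (unfiltered) `erg_trace`.
#' @param features An `erg_features` record for the same trace with
#'   `b_amp > 0`.
#' @param spec An [filter_spec()] object. With the default landmark window
#'   the RMS is taken from the a-trough to the b-peak of this trace.
#' @return The `erg_features` record with `op_rms` and `op_rms_norm` set.
#' @export
op_rms <- function(raw, features, spec = filter_spec()) {
  stopifnot(inherits(raw, "erg_trace"), inherits(features, "erg_features"),
            inherits(spec, "erg_filter_spec"))
  if (!is.finite(features$b_amp) || features$b_amp <= 0)
    stop("cannot normalize: b_amp must be strictly positive", call. = FALSE)
  filtered <- highpass(raw, spec)
  t <- trace_times(filtered)
  win <- if (is.null(spec$op_window_ms)) {
    c(features$a_implicit_ms, features$b_implicit_ms)
  } else {
    spec$op_window_ms
  }
  idx <- which(t >= win[1] & t <= win[2])
  if (!length(idx))
    stop("OP window contains no samples", call. = FALSE)
  if (win[1] < t[1] || win[2] > t[length(t)])
    stop("OP window extends outside the recorded epoch", call. = FALSE)
  rms <- sqrt(mean(filtered$samples[idx]^2))
  features$op_rms <- rms
  features$op_rms_norm <- rms / features$b_amp
  features
}
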