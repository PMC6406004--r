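#' Flash stimulus condition
#'
#' Describes a single flash stimulus: the adaptation state of the retina,
#' the flash strength, and where in the recorded epoch the flash occurs.
#'
#' @param adaptation `"scotopic"` (dark-adapted, rod-driven) or `"photopic"`
#'   (light-adapted, cone-driven).
#' @param intensity Flash strength in log10 cd.s/m^2. Stored on the log scale,
#'   matching the convention of log-spaced ERG flash series; converted to
#'   linear units before the Naka-Rushton intensity-response function is
#'   applied.
#' @param onset_ms Flash onset time measured from the first recorded sample
#'   (ms, >= 0). Samples before the onset form the pre-stimulus baseline.
#'
#' @return An object of class `erg_stimulus`.
#' @examples
#' stimulus_condition("scotopic", intensity = 0, onset_ms = 20)
#' @export
stimulus_condition <- function(adaptation = c("scotopic", "photopic"),
                               intensity = 0, onset_ms = 20) {
  adaptation <- match.arg(adaptation)
  stopifnot(is.numeric(intensity), length(intensity) == 1L, is.finite(intensity))
  if (!is.numeric(onset_ms) || length(onset_ms) != 1L || onset_ms < 0) {
    stop("`onset_ms` must be a single non-negative number", call. = FALSE)
  }
  structure(list(adaptation = adaptation, intensity = intensity,
                 onset_ms = onset_ms),
            class = "erg_stimulus")
}

#' Generative parameters for a synthetic ERG trace
#'
#' The synthetic waveform is an additive model of three components on a
#' millisecond time axis anchored at flash onset: a negative-going Gaussian
#' bump for the a-wave, a positive Gaussian bump for the b-wave, and a
#' Gaussian-windowed sinusoid for the oscillatory potentials (OPs), plus
#' additive white Gaussian noise. The a- and b-wave amplitudes are scaled
#' across flash intensities by a Naka-Rushton saturation function. Gaussian
#' bumps were chosen because their peak locations and values are known in
#' closed form, which makes the feature-extraction code testable against
#' exact ground truth.
#'
#' Default timing and frequency constants follow typical adult mouse ERG
#' physiology (a-trough near 15-25 ms, b-peak near 40-60 ms, OPs at roughly
#' 100-120 Hz); every value can be overridden.
#'
#' @param A_a a-wave peak magnitude at amplitude saturation (uV, >= 0).
#' @param t_a a-trough latency from flash onset (ms).
#' @param w_a a-component Gaussian width (ms, > 0).
#' @param A_b b-wave peak magnitude at saturation (uV, >= 0).
#' @param t_b b-peak latency (ms); must exceed `t_a`.
#' @param w_b b-component Gaussian width (ms, > 0).
#' @param A_op OP envelope amplitude (uV, >= 0). Not intensity-scaled.
#' @param f_op OP carrier frequency (Hz, > 25 so the OPs survive the 25 Hz
#'   high-pass filter).
#' @param t_op OP envelope center (ms), on the b-wave rising phase.
#' @param w_op OP envelope Gaussian width (ms, > 0).
#' @param sigma_noise Additive white-noise standard deviation (uV, >= 0).
#' @param R_max Naka-Rushton saturation gain (unitless multiplier applied to
#'   `A_a` and `A_b`; default 1).
#' @param I_50 Semi-saturation flash strength in linear cd.s/m^2 (> 0).
#' @param h Hill exponent of the intensity-response function (> 0).
#'
#' @return An object of class `erg_waveform_params`.
#' @seealso [synth_trace()], [naka_rushton()]
#' @export
waveform_params <- function(A_a = 150, t_a = 18, w_a = 7,
                            A_b = 300, t_b = 50, w_b = 18,
                            A_op = 30, f_op = 110, t_op = 32, w_op = 8,
                            sigma_noise = 4,
                            R_max = 1, I_50 = 0.1, h = 1) {
  p <- list(A_a = A_a, t_a = t_a, w_a = w_a,
            A_b = A_b, t_b = t_b, w_b = w_b,
            A_op = A_op, f_op = f_op, t_op = t_op, w_op = w_op,
            sigma_noise = sigma_noise, R_max = R_max, I_50 = I_50, h = h)
  bad <- !vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad)) {
    stop("non-numeric waveform parameter(s): ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  if (p$w_a <= 0 || p$w_b <= 0 || p$w_op <= 0)
    stop("component widths must be strictly positive", call. = FALSE)
  if (p$f_op <= 0) stop("`f_op` must be strictly positive", call. = FALSE)
  if (p$t_b <= p$t_a) stop("`t_b` must exceed `t_a`", call. = FALSE)
  if (p$A_a < 0 || p$A_b < 0 || p$A_op < 0 || p$sigma_noise < 0)
    stop("amplitudes and `sigma_noise` must be non-negative", call. = FALSE)
  if (p$R_max <= 0 || p$I_50 <= 0 || p$h <= 0)
    stop("`R_max`, `I_50` and `h` must be strictly positive", call. = FALSE)
  structure(p, class = "erg_waveform_params")
}

#' Unit Gaussian bump
#'
#' `exp(-(t - center)^2 / (2 * width^2))`: the shape function underlying the
#' a- and b-wave components and the OP envelope. Equals 1 at `t == center`
#' and decays symmetrically.
#'
#' @param t Time (ms); vectorized.
#' @param center Bump center (ms).
#' @param width Gaussian width (ms, > 0).
#' @return Shape values in (0, 1].
#' @examples
#' component_bump(40, center = 40, width = 5) # 1
#' component_bump(45, center = 40, width = 5) # exp(-0.5)
#' @export
component_bump <- function(t, center, width) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("`width` must be a single strictly positive number", call. = FALSE)
  exp(-((t - center)^2) / (2 * width^2))
}

#' Naka-Rushton intensity-response function
#'
#' The saturating hyperbolic relation standard in retinal physiology:
#' `R(I) = R_max * I^h / (I^h + I_50^h)`. Monotone nondecreasing in `I`
#' and bounded above by `R_max`; equals `R_max / 2` at `I == I_50`.
#'
#' @param I_linear Flash strength in linear units (>= 0); vectorized.
#' @param R_max Saturation amplitude (> 0).
#' @param I_50 Semi-saturation intensity (> 0).
#' @param h Hill exponent (> 0).
#' @return Response amplitude(s), same length as `I_linear`.
#' @examples
#' naka_rushton(0.1, R_max = 300, I_50 = 0.1, h = 1) # 150
#' @export
naka_rushton <- function(I_linear, R_max, I_50, h) {
  if (any(!is.finite(I_linear)) || any(I_linear < 0))
    stop("`I_linear` must be finite and non-negative", call. = FALSE)
  if (R_max <= 0 || I_50 <= 0 || h <= 0)
    stop("`R_max`, `I_50` and `h` must be strictly positive", call. = FALSE)
  Ih <- I_linear^h
  R_max * Ih / (Ih + I_50^h)
}

# Intensity-scaled (a, b) amplitudes for a stimulus; intensity is log10.
scaled_amplitudes <- function(params, stimulus) {
  I_lin <- 10^stimulus$intensity
  s <- naka_rushton(I_lin, params$R_max, params$I_50, params$h)
  list(A_a = params$A_a * s, A_b = params$A_b * s)
}

# Deterministic (noiseless) waveform value at time t (ms from flash onset).
# Vectorized over t; negative t (pre-stimulus) gives 0.
noiseless_waveform <- function(t, params, stimulus) {
  amps <- scaled_amplitudes(params, stimulus)
  y <- -amps$A_a * component_bump(t, params$t_a, params$w_a) +
    amps$A_b * component_bump(t, params$t_b, params$w_b) +
    params$A_op * component_bump(t, params$t_op, params$w_op) *
      sin(2 * pi * params$f_op * (t - params$t_op) / 1000)
  y[t < 0] <- 0
  y
}

#' Construct an ERG trace object
#'
#' A trace is a uniformly sampled voltage time series with its stimulus and
#' subject metadata. The time of sample `i` relative to flash onset is
#' `t0_ms + (i - 1) * 1000 / fs`; `t0_ms` must be negative enough to leave at
#' least 10 pre-stimulus samples for baseline estimation.
#'
#' @param samples Voltage samples (uV); all finite.
#' @param fs Sampling rate (Hz).
#' @param stimulus An [stimulus_condition()] object; `t0_ms` is derived from
#'   its `onset_ms` as `-onset_ms`.
#' @param subject_id Opaque subject identifier.
#' @param eye `"left"` or `"right"`.
#' @return An object of class `erg_trace` with fields `subject_id`, `eye`,
#'   `stimulus`, `fs`, `t0_ms`, `samples`.
#' @export
erg_trace <- function(samples, fs, stimulus, subject_id = "s1",
                      eye = c("left", "right")) {
  eye <- match.arg(eye)
  if (!inherits(stimulus, "erg_stimulus"))
    stop("`stimulus` must be an `erg_stimulus` object", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite numeric", call. = FALSE)
  t0_ms <- -stimulus$onset_ms
  n_pre <- sum(t0_ms + (seq_along(samples) - 1) * 1000 / fs < 0)
  if (n_pre < 10L)
    stop("trace must contain at least 10 pre-stimulus samples", call. = FALSE)
  duration_ms <- (length(samples) - 1) * 1000 / fs
  if (stimulus$onset_ms > duration_ms)
    stop("flash onset lies outside the recorded epoch", call. = FALSE)
  structure(list(subject_id = subject_id, eye = eye, stimulus = stimulus,
                 fs = fs, t0_ms = t0_ms, samples = as.numeric(samples)),
            class = "erg_trace")
}

#' Time axis of a trace
#'
#' @param trace An `erg_trace`.
#' @return Sample times in ms relative to flash onset (onset at 0).
#' @export
trace_times <- function(trace) {
  trace$t0_ms + (seq_along(trace$samples) - 1) * 1000 / trace$fs
}

#' @export
print.erg_trace <- function(x, ...) {
  cat(sprintf(
    "<erg_trace> subject %s (%s eye), %s flash %.2f log cd.s/m^2\n",
    x$subject_id, x$eye, x$stimulus$adaptation, x$stimulus$intensity))
  cat(sprintf("  %d samples at %g Hz, t = [%.1f, %.1f] ms re onset\n",
              length(x$samples), x$fs, x$t0_ms,
              max(trace_times(x))))
  invisible(x)
}

#' Simulate a single synthetic ERG trace
#'
#' Evaluates the additive waveform model on a uniform sample grid and adds
#' white Gaussian noise. Before flash onset the signal is pure noise around
#' zero; after onset it is the sum of the intensity-scaled a- and b-wave
#' bumps and the Gaussian-windowed OP sinusoid. Generation is driven by R's
#' RNG, so wrapping the call in `set.seed()` (or passing `seed`) makes the
#' trace reproducible bit for bit.
#'
#' @param params An [waveform_params()] object.
#' @param stimulus An [stimulus_condition()] object.
#' @param fs Sampling rate (Hz); must exceed `4 * f_op` for a comfortable
#'   Nyquist margin.
#' @param duration_ms Total epoch length (ms); must cover `t_b + 3 * w_b`
#'   past flash onset so the b-wave is fully contained.
#' @param subject_id,eye Metadata carried into the trace.
#' @param seed Optional integer; when given, the RNG state is set locally
#'   (and restored on exit) so the call is self-contained and repeatable.
#' @return An `erg_trace`.
#' @examples
#' tr <- synth_trace(waveform_params(sigma_noise = 0),
#'                   stimulus_condition("scotopic", 0))
#' range(tr$samples)
#' @export
synth_trace <- function(params, stimulus, fs = 2000, duration_ms = 180,
                        subject_id = "s1", eye = "left", seed = NULL) {
  stopifnot(inherits(params, "erg_waveform_params"),
            inherits(stimulus, "erg_stimulus"))
  if (fs <= 4 * params$f_op)
    stop(sprintf("`fs` = %g violates the Nyquist margin: need fs > 4 * f_op = %g",
                 fs, 4 * params$f_op), call. = FALSE)
  if (duration_ms - stimulus$onset_ms < params$t_b + 3 * params$w_b)
    stop("epoch too short: post-onset span must cover t_b + 3 * w_b",
         call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- floor(duration_ms * fs / 1000) + 1L
  t <- -stimulus$onset_ms + (seq_len(n) - 1) * 1000 / fs
  y <- noiseless_waveform(t, params, stimulus)
  if (params$sigma_noise > 0) y <- y + rnorm(n, 0, params$sigma_noise)
  erg_trace(y, fs, stimulus, subject_id = subject_id, eye = eye)
}
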