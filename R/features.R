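#' Average repeated sweeps of the same stimulus
#'
#' Pointwise arithmetic mean of several traces recorded under an identical
#' stimulus and time grid. Feature extraction operates on averaged traces,
#' matching standard ERG practice.
#'
#' @param traces A non-empty list of `erg_trace` objects sharing `fs`,
#'   `t0_ms`, length and stimulus.
#' @return A single `erg_trace` with metadata carried over from the first.
#' @export
average_traces <- function(traces) {
  if (!is.list(traces) || length(traces) == 0)
    stop("`traces` must be a non-empty list", call. = FALSE)
  ref <- traces[[1]]
  for (tr in traces) {
    stopifnot(inherits(tr, "erg_trace"))
    if (tr$fs != ref$fs || tr$t0_ms != ref$t0_ms ||
        length(tr$samples) != length(ref$samples) ||
        !identical(tr$stimulus, ref$stimulus)) {
      stop("incompatible traces: fs, t0_ms, length and stimulus must match",
           call. = FALSE)
    }
  }
  out <- ref
  out$samples <- rowMeans(vapply(traces, `[[`, numeric(length(ref$samples)),
                                 "samples"))
  out
}

#' Search windows and conventions for a/b-wave extraction
#'
#' @param a_window_ms Post-onset window (ms) searched for the a-trough;
#'   defaults to 0-50 ms, wide enough for any mouse a-wave.
#' @param b_window_end_ms End of the b-peak search (ms post onset); the
#'   search always starts at the a-trough. `Inf` means end of record.
#' @param b_amp_mode `"trough_to_peak"` (a-trough to b-peak, the dominant
#'   ERG convention, default) or `"baseline_to_peak"`.
#' @return An object of class `erg_feature_windows`.
#' @export
feature_windows <- function(a_window_ms = c(0, 50), b_window_end_ms = Inf,
                            b_amp_mode = c("trough_to_peak", "baseline_to_peak")) {
  b_amp_mode <- match.arg(b_amp_mode)
  stopifnot(length(a_window_ms) == 2L, a_window_ms[1] < a_window_ms[2],
            a_window_ms[1] >= 0)
  structure(list(a_window_ms = a_window_ms, b_window_end_ms = b_window_end_ms,
                 b_amp_mode = b_amp_mode),
            class = "erg_feature_windows")
}

#' Extract a-wave and b-wave features from an averaged trace
#'
#' Implements point-picking on the averaged trace: the a-wave peak is the
#' most negative point of the trace within the a-search window, and the
#' b-wave peak is the most positive point after the a-trough, without
#' subtracting oscillatory potentials first. The pre-stimulus mean serves as
#' baseline. Amplitude conventions: `a_amp` is the baseline-to-trough
#' magnitude; `b_amp` is trough-to-peak by default (see
#' [feature_windows()]). Implicit times are reported on the sample grid (no
#' sub-sample interpolation); ties at equal extreme values resolve to the
#' earliest sample.
#'
#' @param trace An averaged `erg_trace` with pre-stimulus samples.
#' @param windows An [feature_windows()] object.
#' @return An object of class `erg_features`: a list with `subject_id`,
#'   `stimulus`, `a_amp`, `a_implicit_ms`, `b_amp`, `b_implicit_ms`,
#'   `baseline_uV`, `op_rms` and `op_rms_norm` (both `NA` until
#'   [op_rms()] fills them), and `provenance` (character vector of
#'   warnings, e.g. a trough landing on a window boundary).
#' @export
extract_ab_features <- function(trace, windows = feature_windows()) {
  stopifnot(inherits(trace, "erg_trace"),
            inherits(windows, "erg_feature_windows"))
  t <- trace_times(trace)
  y <- trace$samples
  pre <- t < 0
  if (!any(pre)) stop("trace has no pre-stimulus samples", call. = FALSE)
  if (max(y) == min(y))
    stop("degenerate trace: all samples identical", call. = FALSE)
  baseline <- mean(y[pre])

  a_idx <- which(t >= windows$a_window_ms[1] & t <= windows$a_window_ms[2])
  if (!length(a_idx)) stop("a-search window contains no samples", call. = FALSE)
  trough_rel <- which.min(y[a_idx])          # earliest min on ties
  trough_i <- a_idx[trough_rel]
  provenance <- character()
  if (trough_rel == 1L || trough_rel == length(a_idx))
    provenance <- c(provenance, "a-trough at search-window boundary")

  b_idx <- which(t > t[trough_i] & t <= windows$b_window_end_ms)
  if (!length(b_idx)) stop("no samples after the a-trough for the b-peak",
                           call. = FALSE)
  peak_i <- b_idx[which.max(y[b_idx])]
  if (peak_i == b_idx[length(b_idx)])
    provenance <- c(provenance, "b-peak at end of search range")

  a_amp <- baseline - y[trough_i]
  b_amp <- switch(windows$b_amp_mode,
                  trough_to_peak = y[peak_i] - y[trough_i],
                  baseline_to_peak = y[peak_i] - baseline)
  structure(list(subject_id = trace$subject_id, stimulus = trace$stimulus,
                 a_amp = a_amp, a_implicit_ms = t[trough_i],
                 b_amp = b_amp, b_implicit_ms = t[peak_i],
                 op_rms = NA_real_, op_rms_norm = NA_real_,
                 baseline_uV = baseline, provenance = provenance),
            class = "erg_features")
}

#' @export
print.erg_features <- function(x, ...) {
  cat(sprintf(
    "<erg_features> %s %s %.2f log cd.s/m^2: a %.1f uV @ %.1f ms, b %.1f uV @ %.1f ms",
    x$subject_id, x$stimulus$adaptation, x$stimulus$intensity,
    x$a_amp, x$a_implicit_ms, x$b_amp, x$b_implicit_ms))
  if (!is.na(x$op_rms))
    cat(sprintf(", OP RMS %.2f uV (norm %.4f)", x$op_rms, x$op_rms_norm))
  cat("\n")
  invisible(x)
}

#' Extract the full feature table from a simulated or loaded dataset
#'
#' Runs a/b-wave extraction and OP scoring over every trace of a dataset and
#' returns the long-format feature table, one row per subject x adaptation x
#' intensity.
#'
#' @param dataset An `erg_dataset` (from [simulate_study()] or
#'   [load_dataset()]).
#' @param windows An [feature_windows()] object.
#' @param filter An [filter_spec()] object for OP isolation.
#' @return A data frame with columns `subject_id`, `genotype`, `treatment`,
#'   `adaptation`, `intensity`, `a_amp`, `a_implicit_ms`, `b_amp`,
#'   `b_implicit_ms`, `op_rms`, `op_rms_norm`.
#' @export
extract_features <- function(dataset, windows = feature_windows(),
                             filter = filter_spec()) {
  stopifnot(inherits(dataset, "erg_dataset"))
  meta <- unique(dataset$subjects[, c("subject_id", "genotype", "treatment")])
  rows <- lapply(dataset$traces, function(tr) {
    f <- extract_ab_features(tr, windows)
    f <- op_rms(tr, f, filter)
    data.frame(subject_id = tr$subject_id,
               adaptation = tr$stimulus$adaptation,
               intensity = tr$stimulus$intensity,
               a_amp = f$a_amp, a_implicit_ms = f$a_implicit_ms,
               b_amp = f$b_amp, b_implicit_ms = f$b_implicit_ms,
               op_rms = f$op_rms, op_rms_norm = f$op_rms_norm)
  })
  out <- do.call(rbind, rows)
  out <- merge(meta, out, by = "subject_id", sort = FALSE)
  out <- out[order(out$subject_id, out$adaptation, out$intensity), ]
  rownames(out) <- NULL
  out[, c("subject_id", "genotype", "treatment", "adaptation", "intensity",
          "a_amp", "a_implicit_ms", "b_amp", "b_implicit_ms",
          "op_rms", "op_rms_norm")]
}
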