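make_trace <- function(samples, fs = 2000, adaptation = "scotopic",
                       intensity = 0, onset_ms = 20) {
  erg_trace(samples, fs,
            stimulus_condition(adaptation, intensity, onset_ms = onset_ms))
}

test_that("trace averaging is the pointwise mean with strict compatibility", {
  tr <- synth_trace(waveform_params(), stimulus_condition("scotopic", 0),
                    seed = 3)
  avg <- average_traces(list(tr, tr, tr))
  expect_identical(avg$samples, tr$samples)
  neg <- tr; neg$samples <- -tr$samples
  expect_equal(average_traces(list(tr, neg))$samples,
               rep(0, length(tr$samples)))
  other <- synth_trace(waveform_params(), stimulus_condition("scotopic", 0),
                       fs = 1000, seed = 3)
  expect_error(average_traces(list(tr, other)), "incompatible")
  diff_stim <- synth_trace(waveform_params(), stimulus_condition("scotopic", 1),
                           seed = 3)
  expect_error(average_traces(list(tr, diff_stim)), "incompatible")
  expect_error(average_traces(list()), "non-empty")
})

test_that("noiseless extraction matches the fine-grid generator truth", {
  p <- waveform_params(A_op = 0, sigma_noise = 0)
  for (I in c(-2, -1, 0, 1)) {
    stim <- stimulus_condition("scotopic", I)
    tr <- synth_trace(p, stim)
    f <- extract_ab_features(tr)
    truth <- fine_grid_truth(p, stim)
    expect_lt(abs(f$a_amp - truth$a_amp) / truth$a_amp, 0.01)
    expect_lt(abs(f$b_amp - truth$b_amp) / truth$b_amp, 0.01)
    expect_lte(abs(f$a_implicit_ms - truth$a_t), 1000 / tr$fs)
    expect_lte(abs(f$b_implicit_ms - truth$b_t), 1000 / tr$fs)
  }
})

test_that("degenerate and malformed traces are rejected", {
  expect_error(extract_ab_features(make_trace(rep(0, 400))), "degenerate")
  expect_error(extract_ab_features(make_trace(rep(2.5, 400))), "degenerate")
})

test_that("amplitudes scale with the trace; implicit times do not", {
  tr <- synth_trace(waveform_params(sigma_noise = 0),
                    stimulus_condition("scotopic", 0))
  f1 <- extract_ab_features(tr)
  sc <- tr; sc$samples <- 4 * tr$samples
  f2 <- extract_ab_features(sc)
  expect_equal(f2$a_amp, 4 * f1$a_amp, tolerance = 1e-12)
  expect_equal(f2$b_amp, 4 * f1$b_amp, tolerance = 1e-12)
  expect_identical(f2$a_implicit_ms, f1$a_implicit_ms)
  expect_identical(f2$b_implicit_ms, f1$b_implicit_ms)
})

test_that("amplitudes are invariant to a DC offset (baseline subtraction)", {
  tr <- synth_trace(waveform_params(sigma_noise = 0),
                    stimulus_condition("scotopic", 0))
  f1 <- extract_ab_features(tr)
  shifted <- tr; shifted$samples <- tr$samples + 250
  f2 <- extract_ab_features(shifted)
  expect_equal(f2$a_amp, f1$a_amp, tolerance = 1e-9)
  # b_amp is trough-to-peak, offset-free by construction
  expect_equal(f2$b_amp, f1$b_amp, tolerance = 1e-9)
  expect_equal(f2$baseline_uV, f1$baseline_uV + 250, tolerance = 1e-9)
})

test_that("extraction error vanishes as component separation grows", {
  errs <- sapply(c(3, 5, 8), function(sep) {
    w <- 8
    p <- waveform_params(t_a = 20, w_a = w, t_b = 20 + sep * w, w_b = w,
                         A_op = 0, sigma_noise = 0)
    stim <- stimulus_condition("scotopic", 1)
    tr <- synth_trace(p, stim, duration_ms = 260)
    f <- extract_ab_features(tr, feature_windows(a_window_ms = c(0, 40)))
    amps <- ergkit:::scaled_amplitudes(p, stim)
    abs(f$a_amp - amps$A_a) / amps$A_a
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("ties at the extreme resolve to the earliest sample", {
  y <- rep(0, 100)
  y[60] <- y[70] <- -5   # two equal troughs
  y[80] <- y[90] <- 7    # two equal peaks
  y[1:20] <- 0
  tr <- make_trace(y, fs = 1000, onset_ms = 20)
  f <- extract_ab_features(tr)
  expect_equal(f$a_implicit_ms, (60 - 1) - 20)
  expect_equal(f$b_implicit_ms, (80 - 1) - 20)
})

test_that("boundary troughs are flagged in provenance", {
  p <- waveform_params(A_op = 0, sigma_noise = 0)
  tr <- synth_trace(p, stimulus_condition("scotopic", 0))
  f <- extract_ab_features(tr, feature_windows(a_window_ms = c(0, 10)))
  expect_true(any(grepl("boundary", f$provenance)))
})

test_that("the dataset feature table has the documented schema", {
  d <- study_design(genotypes = c("WT", "KO"), treatments = "STZ",
                    n_per_group = 2, seed = 8)
  sim <- simulate_study(d, effect_model(), waveform_params())
  feats <- extract_features(sim)
  expect_identical(names(feats),
                   c("subject_id", "genotype", "treatment", "adaptation",
                     "intensity", "a_amp", "a_implicit_ms", "b_amp",
                     "b_implicit_ms", "op_rms", "op_rms_norm"))
  expect_equal(nrow(feats), 4 * 9)
  expect_true(all(feats$a_implicit_ms < feats$b_implicit_ms))
  expect_true(all(is.finite(feats$op_rms_norm)))
})
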