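# Shared fixtures and independent oracles used across the suite.

# Evaluate the noiseless generative waveform on an arbitrary (fine) time
# grid and apply the same peak definitions as the extractor: a-trough =
# most negative point in the a-window, b-peak = most positive point after
# the a-trough, amplitudes baseline(=0)-to-trough and trough-to-peak.
fine_grid_truth <- function(params, stimulus, a_window = c(0, 50),
                            t_max = 160, dt = 0.001) {
  tt <- seq(0, t_max, by = dt)
  y <- ergkit:::noiseless_waveform(tt, params, stimulus)
  aw <- tt >= a_window[1] & tt <= a_window[2]
  i_a <- which(aw)[which.min(y[aw])]
  bw <- tt > tt[i_a]
  i_b <- which(bw)[which.max(y[bw])]
  list(a_amp = -y[i_a], a_t = tt[i_a],
       b_amp = y[i_b] - y[i_a], b_t = tt[i_b])
}

# Brute-force split-plot sum-of-squares oracle: nothing but explicit loops
# over observations and plain arithmetic means, independent of the
# vectorized implementation.
oracle_splitplot <- function(df, response = "y", between = "group",
                             within = "intensity", subject = "subject_id") {
  y <- df[[response]]
  g <- as.character(df[[between]])
  w <- as.character(df[[within]])
  s <- as.character(df[[subject]])
  groups <- sort(unique(g)); levels_w <- sort(unique(w))
  subjects <- sort(unique(s))
  G <- length(groups); k <- length(levels_w); N <- length(subjects)
  grand <- sum(y) / length(y)

  mean_of <- function(idx) sum(y[idx]) / length(which(idx))
  subj_mean <- sapply(subjects, function(ss) mean_of(s == ss))
  subj_grp <- sapply(subjects, function(ss) unique(g[s == ss]))
  grp_mean <- sapply(groups, function(gg) {
    mean(subj_mean[subj_grp == gg])
  })
  n_g <- sapply(groups, function(gg) sum(subj_grp == gg))
  cell_mean <- matrix(NA_real_, G, k, dimnames = list(groups, levels_w))
  for (gg in groups) for (ww in levels_w)
    cell_mean[gg, ww] <- mean_of(g == gg & w == ww)
  int_mean <- sapply(levels_w, function(ww) mean_of(w == ww))

  ss_group <- 0; ss_subj <- 0; ss_int <- 0; ss_inter <- 0; ss_res <- 0
  for (gg in groups)
    ss_group <- ss_group + k * n_g[[gg]] * (grp_mean[[gg]] - grand)^2
  for (ss_i in seq_along(subjects))
    ss_subj <- ss_subj +
      k * (subj_mean[ss_i] - grp_mean[[subj_grp[ss_i]]])^2
  for (ww in levels_w) ss_int <- ss_int + N * (int_mean[[ww]] - grand)^2
  for (gg in groups) for (ww in levels_w)
    ss_inter <- ss_inter + n_g[[gg]] *
      (cell_mean[gg, ww] - grp_mean[[gg]] - int_mean[[ww]] + grand)^2
  for (i in seq_along(y))
    ss_res <- ss_res + (y[i] - subj_mean[[s[i]]] -
                          cell_mean[g[i], w[i]] + grp_mean[[g[i]]])^2

  df_v <- as.integer(c(G - 1, N - G, k - 1, (G - 1) * (k - 1),
                       (N - G) * (k - 1)))
  SS <- c(ss_group, ss_subj, ss_int, ss_inter, ss_res)
  MS <- SS / df_v
  Fv <- c(MS[1] / MS[2], NA, MS[3] / MS[5], MS[4] / MS[5], NA)
  p <- c(pf(Fv[1], df_v[1], df_v[2], lower.tail = FALSE), NA,
         pf(Fv[3], df_v[3], df_v[5], lower.tail = FALSE),
         pf(Fv[4], df_v[4], df_v[5], lower.tail = FALSE), NA)
  list(SS = unname(SS), df = df_v, F = unname(Fv), p = unname(p))
}

# Random balanced split-plot dataset generator for oracle comparisons.
# `group_sd` adds a true group shift (0 gives null data with subject
# effects only).
random_splitplot <- function(G = 2, n = 3, k = 2, seed = 1, group_sd = 1) {
  set.seed(seed)
  subjects <- paste0("s", seq_len(G * n))
  d <- expand.grid(subject_id = subjects, intensity = paste0("I", seq_len(k)),
                   stringsAsFactors = FALSE)
  grp <- rep(paste0("g", seq_len(G)), each = n)
  d$group <- grp[match(d$subject_id, subjects)]
  d$y <- rnorm(nrow(d)) +
    rep(group_sd * rnorm(G), each = n)[match(d$subject_id, subjects)] +
    rnorm(G * n)[match(d$subject_id, subjects)]
  d
}

# Features record constructed directly, for OP-scoring tests that supply
# b_amp and landmarks by hand.
manual_features <- function(b_amp = 1, a_ms = 0, b_ms = 100,
                            subject_id = "s1") {
  structure(list(subject_id = subject_id, stimulus = NULL,
                 a_amp = NA_real_, a_implicit_ms = a_ms,
                 b_amp = b_amp, b_implicit_ms = b_ms,
                 op_rms = NA_real_, op_rms_norm = NA_real_,
                 baseline_uV = 0, provenance = character()),
            class = "erg_features")
}
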