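#' Two-way mixed (split-plot) ANOVA
#'
#' Fits the classic split-plot decomposition for a design with one
#' between-subjects factor (group) and one within-subjects factor (flash
#' intensity), subjects nested in groups and observed at every intensity.
#' The total sum of squares is partitioned into two strata:
#'
#' * between subjects: group main effect, tested against subjects-within-
#'   groups;
#' * within subjects: intensity main effect and the group x intensity
#'   interaction, both tested against the within-subjects residual.
#'
#' Unbalanced group sizes are handled by the weighted-means stratum
#' decomposition (group means weighted by group size), which for complete
#' within-subject data is orthogonal, so main effects are not contaminated
#' by the interaction. No sphericity correction is applied by default;
#' Greenhouse-Geisser adjustment of the within-stratum tests is available
#' via `gg_correction = TRUE`.
#'
#' The sum-of-squares partition identity (stratum SS add to the total SS)
#' and the degrees-of-freedom identity (df add to N*k - 1) are asserted on
#' every fit.
#'
#' @param data Long-format data frame, one row per subject x intensity.
#' @param response Name of the response column.
#' @param between Name of the group column.
#' @param within Name of the intensity (repeated) column.
#' @param subject Name of the subject-identifier column.
#' @param drop_incomplete Drop subjects missing any intensity level
#'   (listwise removal) instead of raising an error. Default `FALSE`.
#' @param gg_correction Apply the Greenhouse-Geisser epsilon to the
#'   within-stratum degrees of freedom. Default `FALSE`.
#' @return An object of class `erg_anova`: a list with `table` (data frame
#'   with columns `effect`, `SS`, `df`, `MS`, `F`, `p`), `epsilon_gg`,
#'   and the bookkeeping needed by [bonferroni_posthoc()].
#' @examples
#' d <- expand.grid(subject_id = paste0("s", 1:6), intensity = 1:3)
#' d$group <- rep(c("A", "B"), each = 3)[match(d$subject_id, paste0("s", 1:6))]
#' set.seed(1); d$y <- rnorm(nrow(d))
#' mixed_anova(d, "y")$table
#' @export
mixed_anova <- function(data, response, between = "group",
                        within = "intensity", subject = "subject_id",
                        drop_incomplete = FALSE, gg_correction = FALSE) {
  cols <- c(response, between, within, subject)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  y <- data[[response]]
  if (any(!is.finite(y))) stop("response contains non-finite values", call. = FALSE)
  g <- as.character(data[[between]])
  w <- as.character(data[[within]])
  s <- as.character(data[[subject]])

  # completeness: every subject at every within level, exactly once
  levels_w <- sort(unique(w))
  k <- length(levels_w)
  tab <- table(s, w)
  complete <- rownames(tab)[apply(tab == 1, 1, all)]
  if (length(complete) < length(unique(s))) {
    if (!drop_incomplete) {
      bad <- setdiff(unique(s), complete)
      stop("incomplete data: subject(s) missing intensity levels: ",
           paste(bad, collapse = ", "),
           " (set drop_incomplete = TRUE for listwise removal)", call. = FALSE)
    }
    keep <- s %in% complete
    y <- y[keep]; g <- g[keep]; w <- w[keep]; s <- s[keep]
  }
  subj_group <- tapply(g, s, function(x) unique(x))
  if (any(lengths(subj_group) != 1))
    stop("each subject must belong to exactly one group", call. = FALSE)
  groups <- sort(unique(g))
  G <- length(groups)
  if (G < 2) stop("need at least 2 groups", call. = FALSE)
  if (k < 2) stop("need at least 2 within-subject levels", call. = FALSE)
  n_g <- table(factor(unlist(subj_group), levels = groups))
  if (any(n_g < 2))
    stop("insufficient replication: every group needs >= 2 subjects",
         call. = FALSE)
  N <- sum(n_g)

  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  if (ss_total == 0)
    stop("degenerate data: all response values identical", call. = FALSE)

  subj_mean <- tapply(y, s, mean)                       # per-subject means
  grp_of_subj <- unlist(subj_group)[names(subj_mean)]
  grp_mean <- tapply(subj_mean, grp_of_subj, mean)[groups]
  cell_mean <- tapply(y, list(factor(g, groups), factor(w, levels_w)), mean)
  # intensity means weighted by group size (= plain means over subjects)
  int_mean <- as.numeric(n_g %*% cell_mean) / N

  ss_group <- k * sum(n_g * (grp_mean - grand)^2)
  ss_subj <- k * sum((subj_mean - grp_mean[grp_of_subj])^2)
  ss_within_lvl <- N * sum((int_mean - grand)^2)
  inter_dev <- sweep(sweep(cell_mean, 1, grp_mean, "-"), 2, int_mean - grand, "-")
  ss_inter <- sum(n_g * rowSums(inter_dev^2))
  fit_cell <- cell_mean[cbind(match(g, groups), match(w, levels_w))]
  ss_resid <- sum((y - subj_mean[s] - fit_cell + grp_mean[g])^2)

  df <- as.integer(c(G - 1, N - G, k - 1, (G - 1) * (k - 1), (N - G) * (k - 1)))
  SS <- unname(c(ss_group, ss_subj, ss_within_lvl, ss_inter, ss_resid))
  # partition and df identities, asserted on every accepted input
  stopifnot(abs(sum(SS) - ss_total) <= 1e-8 * max(ss_total, 1),
            sum(df) == N * k - 1)
  MS <- SS / df
  Fv <- unname(c(MS[1] / MS[2], NA, MS[3] / MS[5], MS[4] / MS[5], NA))

  eps <- 1
  if (gg_correction) eps <- gg_epsilon(y, g, w, s, groups, levels_w, cell_mean)
  p <- c(pf(Fv[1], df[1], df[2], lower.tail = FALSE), NA,
         pf(Fv[3], eps * df[3], eps * df[5], lower.tail = FALSE),
         pf(Fv[4], eps * df[4], eps * df[5], lower.tail = FALSE), NA)

  table <- data.frame(
    effect = c(between, paste0("subjects within ", between),
               within, paste(between, within, sep = " x "), "residual"),
    stratum = c("between", "between", "within", "within", "within"),
    SS = SS, df = df, MS = MS, F = Fv, p = p)
  structure(list(table = table, epsilon_gg = eps,
                 response = response, between = between, within = within,
                 subject = subject,
                 groups = groups, levels = levels_w,
                 n_per_group = as.numeric(n_g), cell_means = cell_mean,
                 ss_subj = ss_subj, df_subj = N - G,
                 ss_resid = ss_resid, df_resid = (N - G) * (k - 1)),
            class = "erg_anova")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# subject x intensity response matrix.
gg_epsilon <- function(y, g, w, s, groups, levels_w, cell_mean) {
  subj <- sort(unique(s))
  Y <- matrix(NA_real_, length(subj), length(levels_w),
              dimnames = list(subj, levels_w))
  Y[cbind(match(s, subj), match(w, levels_w))] <- y
  # center each subject's row by its group's cell means, then pool
  grp_of <- tapply(g, s, unique)[subj]
  Yc <- Y - cell_mean[match(grp_of, groups), , drop = FALSE]
  S <- crossprod(Yc) / (nrow(Yc) - length(groups))
  k <- ncol(S)
  # epsilon = (sum lambda)^2 / ((k-1) * sum lambda^2) of the double-centered
  # covariance (eigenvalues of the orthonormal-contrast covariance)
  Sc <- sweep(sweep(S, 1, rowMeans(S), "-"), 2, colMeans(S), "-") + mean(S)
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  min(1, max(eps, 1 / (k - 1)))
}

#' @export
print.erg_anova <- function(x, ...) {
  cat(sprintf("Two-way mixed ANOVA: %s ~ %s (between) x %s (within)\n",
              x$response, x$between, x$within))
  tab <- x$table
  tab$stars <- ifelse(is.na(tab$p), "", significance_stars(tab$p))
  print(format(tab, digits = 4), row.names = FALSE)
  if (x$epsilon_gg < 1)
    cat(sprintf("Greenhouse-Geisser epsilon = %.3f applied to within-stratum tests\n",
                x$epsilon_gg))
  invisible(x)
}

#' Asterisk ladder for p-values
#'
#' The conventional figure-legend ladder: `*` P < 0.05, `**` P < 0.01,
#' `***` P < 0.001, `^` P < 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of markers ("" when P >= 0.05).
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[!is.na(p) & p < 0.0001] <- "^"
  out[is.na(p)] <- NA_character_
  out
}

#' Bonferroni post-hoc pairwise comparisons at each intensity
#'
#' Simple-effect comparisons between groups at every intensity level,
#' following the split-plot fit. Because a between-group difference at a
#' fixed intensity mixes between- and within-subject variance, the error
#' term pools the two strata:
#' `MS_pooled = (SS_subjects + SS_residual) / (df_subjects + df_residual)`,
#' with the pooled df. Each comparison's t statistic is
#' `diff / sqrt(MS_pooled * (1/n1 + 1/n2))`, and raw p-values are
#' Bonferroni-adjusted by `m = (number of pairs) x (number of intensities)`.
#'
#' @param anova An `erg_anova` object from [mixed_anova()].
#' @param reference Optional group label: compare every other group to this
#'   reference only (as when figure asterisks mark differences versus a
#'   control genotype). Default `NULL` compares all pairs.
#' @return A data frame of class `erg_posthoc` with columns `group1`,
#'   `group2`, `level`, `diff`, `se`, `t`, `df`, `p_raw`, `p_adjusted`,
#'   `m_comparisons`, `stars`.
#' @export
bonferroni_posthoc <- function(anova, reference = NULL) {
  stopifnot(inherits(anova, "erg_anova"))
  groups <- anova$groups
  if (!is.null(reference) && !reference %in% groups)
    stop("reference group not present: ", reference, call. = FALSE)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  if (!is.null(reference)) {
    pairs <- lapply(setdiff(groups, reference),
                    function(gg) c(gg, reference))
  }
  ms_pooled <- (anova$ss_subj + anova$ss_resid) /
    (anova$df_subj + anova$df_resid)
  df_pooled <- anova$df_subj + anova$df_resid
  n <- setNames(anova$n_per_group, groups)
  m <- length(pairs) * length(anova$levels)
  rows <- list()
  for (lev in anova$levels) {
    for (pr in pairs) {
      d <- anova$cell_means[pr[1], lev] - anova$cell_means[pr[2], lev]
      se <- sqrt(ms_pooled * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
      tv <- d / se
      p_raw <- 2 * pt(-abs(tv), df_pooled)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = pr[1], group2 = pr[2], level = lev,
        diff = d, se = se, t = tv, df = df_pooled,
        p_raw = p_raw, p_adjusted = min(1, m * p_raw), m_comparisons = m)
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p_adjusted)
  class(out) <- c("erg_posthoc", "data.frame")
  out
}

#' Two-sample unpaired t-test (pooled variance)
#'
#' Classic Student t-test with pooled variance and
#' `df = n1 + n2 - 2`, as used for single-endpoint group comparisons
#' (e.g. endpoint glycemia).
#'
#' @param x,y Numeric samples, each with at least 2 values.
#' @param tails 2 (default) or 1. The one-tailed p is for the observed
#'   direction of the difference.
#' @return A list of class `erg_ttest`: `statistic`, `df`, `p`, `tails`,
#'   `estimate` (mean of `x` minus mean of `y`).
#' @export
ttest_unpaired <- function(x, y, tails = 2) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  stopifnot(tails %in% c(1, 2))
  if (var(x) == 0 && var(y) == 0 && mean(x) == mean(y)) {
    res <- list(statistic = 0, df = length(x) + length(y) - 2, p = 1)
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  p <- if (tails == 1) res$p / 2 else res$p
  structure(list(statistic = res$statistic, df = res$df, p = p,
                 tails = tails, estimate = mean(x) - mean(y)),
            class = "erg_ttest")
}

#' @export
print.erg_ttest <- function(x, ...) {
  cat(sprintf("%d-tailed unpaired t-test: t(%g) = %.4f, p = %.4g, diff = %.4g\n",
              x$tails, x$df, x$statistic, x$p, x$estimate))
  invisible(x)
}

#' Monte Carlo operating characteristics of the full pipeline
#'
#' Repeatedly simulates a study under the given design and effect model,
#' runs feature extraction and the split-plot ANOVA on every endpoint
#' (scotopic/photopic x a-wave amplitude, b-wave amplitude, normalized OP
#' RMS), and reports the fraction of replicates in which the group main
#' effect is significant at `alpha`. Under the null effect model this
#' estimates the type-I error rate; under a non-null model, power.
#'
#' @param design An [study_design()]; its `seed` anchors the replicate
#'   seed sequence unless `seeds` is given.
#' @param effects An [effect_model()].
#' @param params An [waveform_params()].
#' @param n_reps Number of Monte Carlo replicates (>= 1; >= 100 recommended
#'   for stable estimates).
#' @param alpha Significance level (default 0.05).
#' @param seeds Optional integer vector of length `n_reps`, one RNG seed
#'   per replicate.
#' @param windows,filter Extraction settings passed to [extract_features()].
#' @return A data frame with one row per endpoint: `adaptation`,
#'   `response`, `n_reps`, `n_reject`, `rate` and its binomial standard
#'   error `se`.
#' @export
operating_characteristics <- function(design, effects = effect_model(),
                                      params = waveform_params(),
                                      n_reps = 100, alpha = 0.05,
                                      seeds = NULL,
                                      windows = feature_windows(),
                                      filter = filter_spec()) {
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("`n_reps` must be a positive integer", call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (is.null(seeds)) seeds <- design$seed + seq_len(n_reps) - 1L
  stopifnot(length(seeds) == n_reps)
  responses <- c("a_amp", "b_amp", "op_rms_norm")
  adaptations <- c("scotopic", "photopic")
  reject <- array(0L, dim = c(2, 3),
                  dimnames = list(adaptations, responses))
  for (r in seq_len(n_reps)) {
    design$seed <- as.integer(seeds[r])
    sim <- simulate_study(design, effects, params)
    feats <- extract_features(sim, windows, filter)
    feats$group <- paste(feats$genotype, feats$treatment, sep = ":")
    for (ad in adaptations) {
      sub <- feats[feats$adaptation == ad, ]
      if (!nrow(sub)) next
      for (resp in responses) {
        fit <- mixed_anova(sub, resp, between = "group",
                           within = "intensity", subject = "subject_id")
        p <- fit$table$p[1]
        if (is.finite(p) && p < alpha) reject[ad, resp] <- reject[ad, resp] + 1L
      }
    }
  }
  out <- expand.grid(adaptation = adaptations, response = responses,
                     stringsAsFactors = FALSE)
  out$n_reps <- n_reps
  out$n_reject <- reject[cbind(out$adaptation, out$response)]
  out$rate <- out$n_reject / n_reps
  out$se <- sqrt(out$rate * (1 - out$rate) / n_reps)
  out
}
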