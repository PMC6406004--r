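test_that("split-plot decomposition matches the brute-force oracle", {
  # 100 random balanced instances of varying shape
  for (i in 1:100) {
    G <- 2 + i %% 3; n <- 3 + i %% 4; k <- 2 + i %% 5
    d <- random_splitplot(G = G, n = n, k = k, seed = i)
    fit <- mixed_anova(d, "y")
    orc <- oracle_splitplot(d)
    expect_equal(fit$table$SS, orc$SS, tolerance = 1e-8)
    expect_identical(fit$table$df, orc$df)
    expect_equal(fit$table$F, orc$F, tolerance = 1e-8)
    expect_equal(fit$table$p, orc$p, tolerance = 1e-6)
    # in-table identities
    expect_equal(sum(fit$table$SS), sum((d$y - mean(d$y))^2),
                 tolerance = 1e-10)
    expect_equal(sum(fit$table$df), nrow(d) - 1)
  }
})

test_that("split-plot decomposition matches the oracle on unbalanced groups", {
  for (i in 1:20) {
    d <- random_splitplot(G = 3, n = 5, k = 4, seed = 1000 + i)
    # drop two subjects from the first group, one from the second
    drop <- c("s1", "s2", "s6")
    d <- d[!d$subject_id %in% drop, ]
    fit <- mixed_anova(d, "y")
    orc <- oracle_splitplot(d)
    expect_equal(fit$table$SS, orc$SS, tolerance = 1e-8)
    expect_equal(fit$table$F, orc$F, tolerance = 1e-8)
    expect_equal(sum(fit$table$SS), sum((d$y - mean(d$y))^2),
                 tolerance = 1e-10)
  }
})

test_that("split-plot fit agrees with aov error strata on balanced data", {
  d <- random_splitplot(G = 3, n = 4, k = 3, seed = 42)
  fit <- mixed_anova(d, "y")
  a <- summary(stats::aov(y ~ group * intensity + Error(subject_id), data = d))
  between <- a[["Error: subject_id"]][[1]]
  within <- a[["Error: Within"]][[1]]
  expect_equal(fit$table$SS[1:2], between[["Sum Sq"]], tolerance = 1e-10)
  expect_equal(fit$table$SS[3:5], within[["Sum Sq"]], tolerance = 1e-10)
  expect_equal(fit$table$F[1], between[["F value"]][1], tolerance = 1e-10)
  expect_equal(fit$table$p[3:4], within[["Pr(>F)"]][1:2], tolerance = 1e-10)
})

test_that("the ANOVA is invariant to adding a constant to the response", {
  d <- random_splitplot(G = 2, n = 4, k = 3, seed = 9)
  f1 <- mixed_anova(d, "y")
  d$y <- d$y + 1000
  f2 <- mixed_anova(d, "y")
  expect_equal(f1$table$SS, f2$table$SS, tolerance = 1e-6)
  expect_equal(f1$table$p, f2$table$p, tolerance = 1e-8)
})

test_that("degenerate, incomplete and under-replicated data are rejected", {
  d <- random_splitplot(G = 2, n = 3, k = 2, seed = 2)
  dd <- d; dd$y <- 5
  expect_error(mixed_anova(dd, "y"), "degenerate")
  di <- d[-1, ]
  expect_error(mixed_anova(di, "y"), "incomplete")
  # listwise removal drops the offending subject only
  fit <- mixed_anova(di, "y", drop_incomplete = TRUE)
  expect_equal(sum(fit$table$df) + 1, nrow(d) - 2)
  dr <- d[d$subject_id != "s1" | d$group != "g1", ]
  dr <- dr[!(dr$subject_id %in% c("s3", "s5")), ]
  expect_error(mixed_anova(dr, "y"), "replication")
})

test_that("group main-effect p-values are uniform under the null", {
  pvals <- sapply(1:500, function(i) {
    d <- random_splitplot(G = 2, n = 8, k = 5, seed = 20000 + i,
                          group_sd = 0)
    mixed_anova(d, "y")$table$p[1]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
  expect_true(abs(mean(pvals < 0.05) - 0.05) < 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("Bonferroni post-hoc follows the pooled-stratum formula", {
  d <- random_splitplot(G = 4, n = 5, k = 5, seed = 31)
  fit <- mixed_anova(d, "y")
  ph <- bonferroni_posthoc(fit)
  expect_equal(nrow(ph), choose(4, 2) * 5)
  expect_true(all(ph$m_comparisons == choose(4, 2) * 5))
  expect_equal(ph$p_adjusted, pmin(1, ph$m_comparisons * ph$p_raw))
  expect_true(all(ph$p_adjusted >= ph$p_raw))
  # t recomputed from cell means and the pooled error stratum
  ms_pooled <- (fit$table$SS[2] + fit$table$SS[5]) /
    (fit$table$df[2] + fit$table$df[5])
  r1 <- ph[1, ]
  d1 <- fit$cell_means[r1$group1, as.character(r1$level)] -
    fit$cell_means[r1$group2, as.character(r1$level)]
  expect_equal(r1$t, d1 / sqrt(ms_pooled * (1 / 5 + 1 / 5)), tolerance = 1e-12)
  expect_equal(r1$df, fit$table$df[2] + fit$table$df[5])
  # reference mode
  phr <- bonferroni_posthoc(fit, reference = "g1")
  expect_equal(nrow(phr), 3 * 5)
  expect_true(all(phr$group2 == "g1"))
  expect_error(bonferroni_posthoc(fit, reference = "zz"), "reference")
})

test_that("identical groups give null post-hoc comparisons", {
  base <- random_splitplot(G = 1, n = 4, k = 3, seed = 3)
  base$group <- NULL
  d2 <- rbind(transform(base, group = "gA",
                        subject_id = paste0(subject_id, "A")),
              transform(base, group = "gB",
                        subject_id = paste0(subject_id, "B")))
  fit <- mixed_anova(d2, "y")
  ph <- bonferroni_posthoc(fit)
  expect_true(all(abs(ph$t) < 1e-10))
  expect_true(all(ph$p_adjusted == 1))
})

test_that("Bonferroni adjustment is monotone in the comparison count", {
  # the adjusted p of one fixed raw p grows with m and caps at 1: checked
  # through the public interface by refitting with more within levels
  d3 <- random_splitplot(G = 2, n = 4, k = 3, seed = 77)
  d6 <- random_splitplot(G = 2, n = 4, k = 6, seed = 77)
  ph3 <- bonferroni_posthoc(mixed_anova(d3, "y"))
  ph6 <- bonferroni_posthoc(mixed_anova(d6, "y"))
  expect_equal(unique(ph3$m_comparisons), 3)
  expect_equal(unique(ph6$m_comparisons), 6)
  expect_equal(ph3$p_adjusted, pmin(1, 3 * ph3$p_raw))
  expect_equal(ph6$p_adjusted, pmin(1, 6 * ph6$p_raw))
})

test_that("unpaired t-test matches the closed-form pooled-variance oracle", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- ttest_unpaired(x, y)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), 4)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # symmetry and identical samples
  swap <- ttest_unpaired(y, x)
  expect_equal(swap$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)
  same <- ttest_unpaired(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(ttest_unpaired(1, y), "at least 2")
})

test_that("operating_characteristics validates inputs and orders effects", {
  d <- study_design(genotypes = c("a", "b"), treatments = "STZ",
                    n_per_group = 4,
                    scotopic_intensities = c(-1, 0),
                    photopic_intensities = c(0, 0.5),
                    weeks_post_induction = 1, seed = 60)
  expect_error(operating_characteristics(d, n_reps = 0), "n_reps")
  eff <- effect_model(data.frame(group = "b:STZ", adaptation = "scotopic",
                                 component = "op", factor = 0.4))
  oc <- operating_characteristics(d, eff, waveform_params(), n_reps = 25)
  sc_op <- oc$rate[oc$adaptation == "scotopic" & oc$response == "op_rms_norm"]
  ph_op <- oc$rate[oc$adaptation == "photopic" & oc$response == "op_rms_norm"]
  expect_gt(sc_op, ph_op)
  expect_true(all(oc$n_reps == 25))
  expect_equal(oc$rate, oc$n_reject / 25)
})
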