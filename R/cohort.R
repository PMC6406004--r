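#' Study design for a synthetic ERG cohort
#'
#' Defines the group structure of a genotype-by-treatment study and the
#' flash intensity series recorded for every animal, mirroring the layout of
#' a streptozotocin (STZ) hyperglycemia experiment: each genotype crossed
#' with STZ or vehicle, glycemia and body weight tracked weekly, and full
#' scotopic and photopic intensity series recorded at the endpoint.
#'
#' A "group" is a genotype-treatment combination, keyed as
#' `"<genotype>:<treatment>"`. `n_per_group` may be a single integer
#' (applied to every group) or a named vector keyed that way.
#'
#' @param genotypes Character vector of genotype labels.
#' @param treatments Character vector, subset of `c("STZ", "vehicle")`.
#' @param n_per_group Integer count per group, or a named integer vector
#'   keyed `"<genotype>:<treatment>"`; all counts >= 1.
#' @param scotopic_intensities,photopic_intensities Strictly increasing
#'   flash series in log10 cd.s/m^2.
#' @param weeks_post_induction Number of weekly glycemia/weight follow-ups
#'   after the induction week.
#' @param seed Integer RNG seed; mandatory for a reproducible cohort.
#' @return An object of class `erg_study_design`.
#' @examples
#' study_design(genotypes = c("WT", "KO"), treatments = "STZ",
#'              n_per_group = 7, seed = 1)
#' @export
study_design <- function(genotypes = c("WT", "KO"),
                         treatments = c("STZ", "vehicle"),
                         n_per_group = 8,
                         scotopic_intensities = c(-3, -2, -1, 0, 1),
                         photopic_intensities = c(-1, -0.5, 0, 0.5),
                         weeks_post_induction = 6,
                         seed = 1) {
  stopifnot(is.character(genotypes), length(genotypes) >= 1)
  if (!all(treatments %in% c("STZ", "vehicle")) || length(treatments) < 1)
    stop("`treatments` must be a non-empty subset of c(\"STZ\", \"vehicle\")",
         call. = FALSE)
  groups <- as.vector(outer(genotypes, treatments, paste, sep = ":"))
  if (is.null(names(n_per_group))) {
    stopifnot(length(n_per_group) == 1L)
    n_per_group <- setNames(rep(as.integer(n_per_group), length(groups)), groups)
  } else {
    missing_g <- setdiff(groups, names(n_per_group))
    if (length(missing_g))
      stop("`n_per_group` missing groups: ", paste(missing_g, collapse = ", "),
           call. = FALSE)
    n_per_group <- setNames(as.integer(n_per_group[groups]), groups)
  }
  if (any(n_per_group < 1L)) stop("all group sizes must be >= 1", call. = FALSE)
  for (ii in list(scotopic_intensities, photopic_intensities)) {
    if (length(ii) && any(diff(ii) <= 0))
      stop("intensity series must be strictly increasing", call. = FALSE)
  }
  if (is.null(seed) || !is.numeric(seed))
    stop("`seed` is mandatory", call. = FALSE)
  structure(list(genotypes = genotypes, treatments = treatments,
                 groups = groups, n_per_group = n_per_group,
                 scotopic_intensities = scotopic_intensities,
                 photopic_intensities = photopic_intensities,
                 weeks_post_induction = as.integer(weeks_post_induction),
                 seed = as.integer(seed)),
            class = "erg_study_design")
}

#' Multiplicative group-effect model
#'
#' Encodes how experimental groups deviate from the shared waveform model.
#' Amplitude multipliers act on a single waveform component (`"a"`, `"b"`,
#' or `"op"`) in a single adaptation state for a single group, so e.g. a
#' scotopic-OP-only deficit in one group is expressed as one row with
#' `factor < 1`. The null model (no rows, all factors implicitly 1)
#' generates exchangeable groups.
#'
#' @param multipliers A data frame with columns `group`, `adaptation`
#'   (`"scotopic"`/`"photopic"`), `component` (`"a"`/`"b"`/`"op"`) and
#'   `factor` (> 0); or `NULL` for the null model.
#' @param glucose_shift Named numeric, mean blood-glucose elevation (mg/dL)
#'   added after the induction week per treatment.
#' @param between_subject_cv Coefficient of variation of the lognormal
#'   subject-level amplitude scale shared across all of a subject's traces.
#'   This shared scale induces the within-subject correlation that the
#'   split-plot ANOVA's error strata model; 0 disables it.
#' @return An object of class `erg_effect_model`.
#' @examples
#' effect_model(data.frame(group = "DKO:STZ", adaptation = "scotopic",
#'                         component = "op", factor = 0.7))
#' @export
effect_model <- function(multipliers = NULL,
                         glucose_shift = c(STZ = 300, vehicle = 0),
                         between_subject_cv = 0.2) {
  if (is.null(multipliers)) {
    multipliers <- data.frame(group = character(), adaptation = character(),
                              component = character(), factor = numeric())
  }
  req <- c("group", "adaptation", "component", "factor")
  if (!all(req %in% names(multipliers)))
    stop("`multipliers` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(multipliers)) {
    stopifnot(all(multipliers$adaptation %in% c("scotopic", "photopic")),
              all(multipliers$component %in% c("a", "b", "op")))
    if (any(multipliers$factor <= 0))
      stop("amplitude multipliers must be strictly positive", call. = FALSE)
  }
  stopifnot(is.numeric(between_subject_cv), between_subject_cv >= 0)
  if (is.null(names(glucose_shift)))
    stop("`glucose_shift` must be named by treatment", call. = FALSE)
  structure(list(multipliers = multipliers, glucose_shift = glucose_shift,
                 between_subject_cv = between_subject_cv),
            class = "erg_effect_model")
}

# Multiplier for one (group, adaptation, component); 1 when unspecified.
effect_multiplier <- function(effects, group, adaptation, component) {
  m <- effects$multipliers
  hit <- m$group == group & m$adaptation == adaptation & m$component == component
  if (!any(hit)) 1 else prod(m$factor[hit])
}

# Weekly glycemia and weight trajectories. Baseline glucose ~ N(150, 15);
# the treatment shift applies from week 1 (post-induction) on. Weight starts
# ~ N(20, 1.5) g; STZ blunts the weekly gain.
simulate_vitals <- function(treatment, weeks, glucose_shift) {
  shift <- if (treatment %in% names(glucose_shift)) glucose_shift[[treatment]] else 0
  baseline <- rnorm(1, 150, 15)
  glu <- c(baseline,
           baseline + shift + rnorm(weeks, 0, 30))
  gain <- if (identical(treatment, "STZ")) 0.05 else 0.25
  w0 <- rnorm(1, 20, 1.5)
  wt <- w0 + gain * (0:weeks) + c(0, rnorm(weeks, 0, 0.3))
  list(glucose = pmax(glu, 40), weight = pmax(wt, 10))
}

#' Simulate a full synthetic ERG study
#'
#' Draws a cohort according to the design, gives each subject a lognormal
#' amplitude scale (shared across all of that subject's traces), applies the
#' group-specific multiplicative effects to the targeted waveform
#' components, and generates one averaged trace per subject x adaptation x
#' intensity. Weekly glucose and weight series are simulated alongside.
#' The whole dataset is a deterministic function of `design$seed`.
#'
#' @param design An [study_design()] object.
#' @param effects An [effect_model()] object.
#' @param params An [waveform_params()] object shared by all subjects.
#' @param fs,duration_ms Sampling rate and epoch length passed to the trace
#'   generator.
#' @return An object of class `erg_dataset`: a list with `subjects` (one row
#'   per subject x week: `subject_id`, `genotype`, `treatment`, `group`,
#'   `subject_scale`, `week`, `glucose_mg_dl`, `weight_g`) and `traces`
#'   (list of `erg_trace`).
#' @examples
#' d <- study_design(genotypes = c("WT", "KO"), n_per_group = 2, seed = 42)
#' sim <- simulate_study(d, effect_model(), waveform_params())
#' length(sim$traces)
#' @export
simulate_study <- function(design, effects = effect_model(),
                           params = waveform_params(),
                           fs = 2000, duration_ms = 180) {
  stopifnot(inherits(design, "erg_study_design"),
            inherits(effects, "erg_effect_model"),
            inherits(params, "erg_waveform_params"))
  if (nrow(effects$multipliers)) {
    unknown <- setdiff(effects$multipliers$group, design$groups)
    if (length(unknown))
      stop("effect model refers to unknown group(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(design$seed)

  cv <- effects$between_subject_cv
  sdlog <- sqrt(log(1 + cv^2))
  weeks <- design$weeks_post_induction

  subj_rows <- list()
  traces <- list()
  sid <- 0L
  for (grp in design$groups) {
    parts <- strsplit(grp, ":", fixed = TRUE)[[1]]
    genotype <- parts[1]; treatment <- parts[2]
    mult <- list(
      scotopic = c(a = effect_multiplier(effects, grp, "scotopic", "a"),
                   b = effect_multiplier(effects, grp, "scotopic", "b"),
                   op = effect_multiplier(effects, grp, "scotopic", "op")),
      photopic = c(a = effect_multiplier(effects, grp, "photopic", "a"),
                   b = effect_multiplier(effects, grp, "photopic", "b"),
                   op = effect_multiplier(effects, grp, "photopic", "op")))
    for (k in seq_len(design$n_per_group[[grp]])) {
      sid <- sid + 1L
      subject_id <- sprintf("m%03d", sid)
      scale <- if (cv > 0) rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
      vit <- simulate_vitals(treatment, weeks, effects$glucose_shift)
      subj_rows[[sid]] <- data.frame(
        subject_id = subject_id, genotype = genotype, treatment = treatment,
        group = grp, subject_scale = scale, week = 0:weeks,
        glucose_mg_dl = vit$glucose, weight_g = vit$weight)
      for (adaptation in c("scotopic", "photopic")) {
        intensities <- if (adaptation == "scotopic") design$scotopic_intensities
                       else design$photopic_intensities
        m <- mult[[adaptation]]
        p_subj <- params
        p_subj$A_a <- params$A_a * scale * m[["a"]]
        p_subj$A_b <- params$A_b * scale * m[["b"]]
        p_subj$A_op <- params$A_op * scale * m[["op"]]
        for (I in intensities) {
          stim <- stimulus_condition(adaptation, intensity = I)
          traces[[length(traces) + 1L]] <-
            synth_trace(p_subj, stim, fs = fs, duration_ms = duration_ms,
                        subject_id = subject_id)
        }
      }
    }
  }
  structure(list(subjects = do.call(rbind, subj_rows), traces = traces,
                 design = design),
            class = "erg_dataset")
}

#' @export
print.erg_dataset <- function(x, ...) {
  n_subj <- length(unique(x$subjects$subject_id))
  cat(sprintf("<erg_dataset> %d subjects, %d traces, groups: %s\n",
              n_subj, length(x$traces),
              paste(unique(x$subjects$group), collapse = ", ")))
  invisible(x)
}
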