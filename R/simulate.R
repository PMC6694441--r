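#' Configuration for the synthetic tau-PET cohort generator
#'
#' The defaults emulate the study conditions the analysis assumes: four
#' biomarker groups of sizes 103/34/44/44 with Table-1-like demographics,
#' block-modular inter-regional covariance induced by shared latent factors
#' (one factor per lobar community of the AAL-90 atlas), age/sex/global-uptake
#' confounds, a planted mean elevation in bilateral
#' parahippocampal/fusiform/temporal regions and the left amygdala for the
#' `A4+T+` group, a positive FAQ-uptake coupling in that same group, and a CSF
#' total-tau coupling to the left olfactory and right parahippocampal regions.
#'
#' Covariance is induced through shared latent module factors rather than a
#' target matrix, which guarantees a positive semi-definite covariance for any
#' admissible configuration: a region in community c is
#' `sqrt(rb)*h + sqrt(rw - rb)*f_c + sqrt(1 - rw)*e`, giving within-module
#' correlation `rw` and between-module correlation `rb` for the stochastic
#' part (before confounds).
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param age_mean,age_sd Per-group age distribution (years).
#' @param male_fraction,mci_fraction,abeta_pos_fraction Per-group composition
#'   fractions; realized counts are exact (`round(n * fraction)`).
#' @param faq_mean,faq_sd Per-group FAQ baselines (score points).
#' @param mmse_mean,mmse_sd Per-group MMSE distribution.
#' @param module_assignment Named integer vector mapping each atlas region to
#'   a community index; defaults to the lobar communities of [aal90_atlas()].
#' @param within_module_r,between_module_r Target Pearson correlation of the
#'   stochastic component within and between communities; require
#'   `|r| < 1` and `within_module_r > between_module_r >= 0`.
#' @param effect_regions Regions receiving a planted group mean elevation.
#' @param effect_group Group receiving the elevation.
#' @param effect_size Standardized mean shift (in units of the stochastic SD).
#' @param faq_group Group whose FAQ is coupled to uptake in `effect_regions`.
#' @param faq_coupling FAQ points per uptake unit (0 disables the coupling).
#' @param faq_resid_sd Residual FAQ noise SD in the coupled group.
#' @param csf_regions Regions coupled to CSF total-tau in `csf_group`.
#' @param csf_group Group with the CSF-uptake coupling.
#' @param csf_coupling CSF ng/L per standardized uptake unit.
#' @param noise_sd SD of the stochastic (latent + noise) part, uptake units.
#' @param baseline Mean uptake level (arbitrary positive tracer units).
#' @param confound_slopes Named vector `c(age=, sex=, global=)`: uptake units
#'   per year of age, per sex code, and per SD of the subject-level global
#'   factor.
#' @param seed Optional RNG seed for reproducibility.
#' @return A validated object of class `sim_config`.
#' @export
simulation_config <- function(group_sizes = c("A4-T-" = 103L, "A4+T+" = 34L,
                                              "A4+T-" = 44L, "A4-T+" = 44L),
                              age_mean = c(77.8, 76.7, 75.7, 79.1),
                              age_sd = c(6.5, 7.1, 7.1, 7.0),
                              male_fraction = c(61, 16, 20, 19) /
                                c(103, 34, 44, 44),
                              mci_fraction = c(54, 16, 18, 21) /
                                c(103, 34, 44, 44),
                              abeta_pos_fraction = c(90, 30, 37, 38) /
                                c(103, 34, 44, 44),
                              faq_mean = c(1.68, 4.352, 1.85, 1.98),
                              faq_sd = c(4.24, 6.75, 5.01, 5.55),
                              mmse_mean = c(27.76, 28.33, 28.42, 28.70),
                              mmse_sd = c(1.87, 1.55, 1.41, 1.35),
                              module_assignment = default_module_assignment(),
                              within_module_r = 0.5,
                              between_module_r = 0.15,
                              effect_regions = default_effect_regions(),
                              effect_group = "A4+T+",
                              effect_size = 1.0,
                              faq_group = "A4+T+",
                              faq_coupling = 30,
                              faq_resid_sd = 6,
                              csf_regions = c("Olfactory_L",
                                              "ParaHippocampal_R"),
                              csf_group = "A4+T+",
                              csf_coupling = 50,
                              noise_sd = 0.15,
                              baseline = 1.2,
                              confound_slopes = c(age = 0.01, sex = 0.05,
                                                  global = 0.1),
                              seed = NULL) {
  per_group <- function(x) {
    x <- rep_len(x, length(group_sizes))
    names(x) <- names(group_sizes)
    x
  }
  cfg <- structure(list(
    group_sizes = group_sizes,
    age_mean = per_group(age_mean), age_sd = per_group(age_sd),
    male_fraction = per_group(male_fraction),
    mci_fraction = per_group(mci_fraction),
    abeta_pos_fraction = per_group(abeta_pos_fraction),
    faq_mean = per_group(faq_mean), faq_sd = per_group(faq_sd),
    mmse_mean = per_group(mmse_mean), mmse_sd = per_group(mmse_sd),
    module_assignment = module_assignment,
    within_module_r = within_module_r,
    between_module_r = between_module_r,
    effect_regions = effect_regions, effect_group = effect_group,
    effect_size = effect_size,
    faq_group = faq_group, faq_coupling = faq_coupling,
    faq_resid_sd = faq_resid_sd,
    csf_regions = csf_regions, csf_group = csf_group,
    csf_coupling = csf_coupling,
    noise_sd = noise_sd, baseline = baseline,
    confound_slopes = confound_slopes, seed = seed), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default community assignment: lobar blocks of the AAL-90 atlas
#' @return Named integer vector (region -> community index).
#' @export
default_module_assignment <- function() {
  atlas <- aal90_atlas()
  f <- factor(atlas$lobe)
  stats::setNames(as.integer(f), atlas$name)
}

#' Default planted effect regions (temporal/limbic elevation)
#' @return Character vector of region labels.
#' @export
default_effect_regions <- function() {
  c("ParaHippocampal_L", "ParaHippocampal_R", "Amygdala_L",
    "Fusiform_L", "Fusiform_R", "Temporal_Sup_R",
    "Temporal_Mid_L", "Temporal_Mid_R", "Temporal_Inf_L", "Temporal_Inf_R")
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$group_sizes <= 0)) stop("group sizes must be positive",
                                      call. = FALSE)
  if (is.null(names(cfg$group_sizes)) ||
      !all(names(cfg$group_sizes) %in% group_levels()))
    stop("group_sizes must be named by study group labels", call. = FALSE)
  rw <- cfg$within_module_r; rb <- cfg$between_module_r
  if (abs(rw) >= 1 || abs(rb) >= 1)
    stop("module correlations must have absolute value < 1", call. = FALSE)
  if (rw <= rb)
    stop("within_module_r must exceed between_module_r for a detectable ",
         "planted structure", call. = FALSE)
  if (rb < 0) stop("between_module_r must be >= 0", call. = FALSE)
  regions <- names(cfg$module_assignment)
  if (is.null(regions) || anyDuplicated(regions))
    stop("module_assignment must be uniquely named by region", call. = FALSE)
  bad <- setdiff(c(cfg$effect_regions, cfg$csf_regions), regions)
  if (length(bad)) stop("unknown region(s) in config: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  for (g in c(cfg$effect_group, cfg$faq_group, cfg$csf_group))
    if (!g %in% group_levels()) stop("unknown group label: ", g, call. = FALSE)
  invisible(cfg)
}

# exact count split of n into k "successes", randomly ordered
exact_binary <- function(n, fraction) {
  k <- round(n * fraction)
  sample(rep(c(1L, 0L), c(k, n - k)))
}

#' Generate a synthetic cohort with planted structure
#'
#' Regional uptake is the sum of a baseline, linear age/sex/global confound
#' terms, a group mean elevation in the configured effect regions, and a
#' correlated stochastic part built from shared latent module factors (see
#' [simulation_config()]). FAQ in the coupled group is
#' `baseline + faq_coupling * mean(uptake over effect regions) + noise`,
#' integer-clipped to the instrument range 0-30; CSF total-tau in the coupled
#' group tracks the configured regions and is clamped to the side of the 320
#' ng/L cut-off implied by each group's `T+`/`T-` suffix.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list with elements `cohort` (a `tau_cohort`) and `truth` (the
#'   planted module partition, effect regions/group, and coupling slopes).
#' @export
generate_cohort <- function(config = simulation_config()) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  atlas <- aal90_atlas()
  regions <- atlas$name
  stopifnot(identical(sort(names(config$module_assignment)), sort(regions)))
  mod <- config$module_assignment[regions]
  n_mod <- length(unique(mod))
  groups <- names(config$group_sizes)
  n_total <- sum(config$group_sizes)

  rw <- config$within_module_r; rb <- config$between_module_r
  load_shared <- sqrt(rb)
  load_module <- sqrt(rw - rb)
  load_noise <- sqrt(1 - rw)

  subj_list <- list()
  val_list <- list()
  for (g in groups) {
    n <- config$group_sizes[[g]]
    age <- stats::rnorm(n, config$age_mean[[g]], config$age_sd[[g]])
    sex <- exact_binary(n, config$male_fraction[[g]])
    diagnosis <- ifelse(exact_binary(n, config$mci_fraction[[g]]) == 1L,
                        "MCI", "NC")
    abeta <- ifelse(exact_binary(n, config$abeta_pos_fraction[[g]]) == 1L,
                    "positive", "negative")
    mmse <- round(stats::rnorm(n, config$mmse_mean[[g]], config$mmse_sd[[g]]))

    h <- stats::rnorm(n)                       # shared factor (all regions)
    f <- matrix(stats::rnorm(n * n_mod), n)    # one factor per community
    e <- matrix(stats::rnorm(n * length(regions)), n)
    z <- load_shared * h + load_module * f[, mod, drop = FALSE] +
      load_noise * e

    u <- stats::rnorm(n)                       # global-uptake confound
    vals <- config$baseline +
      config$confound_slopes[["age"]] * (age - mean(config$age_mean)) +
      config$confound_slopes[["sex"]] * sex +
      config$confound_slopes[["global"]] * u +
      config$noise_sd * z
    if (g == config$effect_group && length(config$effect_regions))
      vals[, match(config$effect_regions, regions)] <-
        vals[, match(config$effect_regions, regions)] +
        config$effect_size * config$noise_sd

    if (g == config$faq_group && config$faq_coupling != 0 &&
        length(config$effect_regions)) {
      drive <- rowMeans(vals[, match(config$effect_regions, regions),
                             drop = FALSE])
      faq <- config$faq_mean[[g]] +
        config$faq_coupling * (drive - mean(drive)) +
        stats::rnorm(n, 0, config$faq_resid_sd)
    } else {
      faq <- stats::rnorm(n, config$faq_mean[[g]], config$faq_sd[[g]])
    }
    faq <- pmin(30L, pmax(0L, as.integer(round(faq))))

    tau_abnormal <- grepl("T\\+$", g)
    csf <- if (tau_abnormal) stats::rnorm(n, 430, 70) else
      stats::rnorm(n, 240, 40)
    if (g == config$csf_group && config$csf_coupling != 0) {
      drive <- rowMeans(vals[, match(config$csf_regions, regions),
                             drop = FALSE])
      csf <- csf + config$csf_coupling * (drive - mean(drive)) /
        stats::sd(drive)
    }
    csf <- if (tau_abnormal) pmax(csf, CSF_TTAU_CUTOFF) else
      pmin(csf, CSF_TTAU_CUTOFF - 1)

    subj_list[[g]] <- data.frame(
      id = character(n), group = g, age = age, sex = sex,
      diagnosis = diagnosis, faq = faq, mmse = mmse,
      csf_ttau = round(csf, 1), abeta_status = abeta,
      stringsAsFactors = FALSE)
    val_list[[g]] <- vals
  }
  subjects <- do.call(rbind, subj_list)
  subjects$id <- sprintf("S%04d", seq_len(n_total))
  rownames(subjects) <- NULL
  values <- do.call(rbind, val_list)
  dimnames(values) <- list(subjects$id, regions)

  truth <- list(modules = mod,
                effect_regions = config$effect_regions,
                effect_group = config$effect_group,
                effect_size = config$effect_size,
                faq_group = config$faq_group,
                faq_coupling = config$faq_coupling,
                csf_regions = config$csf_regions,
                csf_group = config$csf_group)
  list(cohort = tau_cohort(values, subjects, atlas), truth = truth)
}

#' Sample a pair of exchangeable groups under the null
#'
#' Draws two groups of equal size from the identical generative process (no
#' planted effects, identical demographics), so any between-group statistic is
#' exchangeable by construction. Used to calibrate the permutation machinery.
#'
#' @param config Base configuration; its module structure, confounds and noise
#'   scale are kept, all group-specific effects are zeroed.
#' @param n_per_group Subjects per group (minimum 10).
#' @param labels Two group labels to assign (default the two tau-normal ones).
#' @param seed Optional RNG seed.
#' @return A `tau_cohort` with two exchangeable groups.
#' @export
sample_null_pair <- function(config = simulation_config(),
                             n_per_group = 20L,
                             labels = c("A4-T-", "A4+T-"),
                             seed = NULL) {
  if (n_per_group < 10L) stop("n_per_group must be at least 10", call. = FALSE)
  stopifnot(length(labels) == 2L, !anyDuplicated(labels))
  sizes <- stats::setNames(rep(as.integer(n_per_group), 2L), labels)
  cfg <- simulation_config(
    group_sizes = sizes,
    age_mean = rep(77, 2), age_sd = rep(7, 2),
    male_fraction = rep(0.5, 2), mci_fraction = rep(0.5, 2),
    abeta_pos_fraction = rep(0.8, 2),
    faq_mean = rep(2, 2), faq_sd = rep(4, 2),
    mmse_mean = rep(28, 2), mmse_sd = rep(1.6, 2),
    module_assignment = config$module_assignment,
    within_module_r = config$within_module_r,
    between_module_r = config$between_module_r,
    effect_regions = character(0), effect_size = 0,
    faq_coupling = 0, csf_coupling = 0,
    noise_sd = config$noise_sd, baseline = config$baseline,
    confound_slopes = config$confound_slopes,
    seed = seed)
  generate_cohort(cfg)$cohort
}
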