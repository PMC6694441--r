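#' Per-region one-way ANOVA across study groups
#'
#' ROI-level analog of a voxel-wise group comparison: for every region a
#' one-way ANOVA (equal-variance F test) across the groups present, with
#' Benjamini-Hochberg FDR across the regions. With `adjust_covariates = TRUE`
#' the values are first residualized for age, sex and whole-brain mean uptake
#' on the pooled cohort (group structure untouched).
#'
#' @param cohort A `tau_cohort` with >= 2 groups of >= 2 subjects each.
#' @param adjust_covariates Residualize for confounds before testing?
#' @param fdr_q FDR rate across regions (default 0.05).
#' @return Data frame with one row per region: `F`, `p`, `p_adj`,
#'   `significant`, `degenerate` (zero within-group variance everywhere,
#'   excluded from FDR) and one `mean_<group>` column per group.
#' @export
anova_regions <- function(cohort, adjust_covariates = FALSE, fdr_q = 0.05) {
  validate_cohort(cohort)
  g <- factor(as.character(cohort$subjects$group),
              levels = intersect(group_levels(),
                                 unique(cohort$subjects$group)))
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need at least 2 groups with at least 2 subjects each",
         call. = FALSE)
  vals <- cohort$values
  if (adjust_covariates) {
    s <- cohort$subjects
    vals <- residualize(vals, s$age, s$sex, rowMeans(vals))
  }
  regions <- colnames(vals)
  fit_one <- function(y) {
    within_var <- tapply(y, g, stats::var)
    if (all(within_var == 0, na.rm = TRUE))
      return(c(F = NA_real_, p = NA_real_))
    ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
    c(F = unname(ow$statistic), p = unname(ow$p.value))
  }
  stats_mat <- t(vapply(regions, function(r) fit_one(vals[, r]), numeric(2)))
  degenerate <- is.na(stats_mat[, "p"])
  adj <- rep(NA_real_, length(regions))
  sig <- rep(FALSE, length(regions))
  if (any(!degenerate)) {
    fdr <- fdr_bh(stats_mat[!degenerate, "p"], q = fdr_q)
    adj[!degenerate] <- fdr$adjusted
    sig[!degenerate] <- fdr$rejected
  }
  means <- sapply(levels(g), function(lvl)
    colMeans(vals[g == lvl, , drop = FALSE]))
  out <- data.frame(region = regions, F = stats_mat[, "F"],
                    p = stats_mat[, "p"], p_adj = adj, significant = sig,
                    degenerate = degenerate, row.names = NULL)
  colnames(means) <- paste0("mean_", levels(g))
  cbind(out, means)
}

#' Post-hoc two-sample contrasts against a reference group
#'
#' For each non-reference group, a pooled-variance two-sample t test per
#' region against the reference, restricted to the regions found significant
#' by [anova_regions()] (or to an explicit region set), with BH-FDR within
#' each comparison.
#'
#' @param cohort A `tau_cohort`.
#' @param reference_group Reference group label (default `"A4-T-"`).
#' @param regions Regions to test; default the ANOVA-significant set.
#' @param adjust_covariates Passed to [anova_regions()] when `regions` is
#'   derived from it; also applied to the contrast values.
#' @param fdr_q FDR rate within each comparison (default 0.05).
#' @return Named list (one element per comparison group) of data frames with
#'   columns `region`, `t`, `df`, `p`, `p_adj`, `significant`,
#'   `mean_group`, `mean_reference`.
#' @export
posthoc_contrasts <- function(cohort, reference_group = "A4-T-",
                              regions = NULL, adjust_covariates = FALSE,
                              fdr_q = 0.05) {
  validate_cohort(cohort)
  g <- as.character(cohort$subjects$group)
  if (!reference_group %in% g)
    stop("reference group ", reference_group, " not present", call. = FALSE)
  if (is.null(regions)) {
    aov_res <- anova_regions(cohort, adjust_covariates = adjust_covariates,
                             fdr_q = fdr_q)
    regions <- aov_res$region[aov_res$significant]
  }
  vals <- cohort$values
  if (adjust_covariates) {
    s <- cohort$subjects
    vals <- residualize(vals, s$age, s$sex, rowMeans(vals))
  }
  others <- setdiff(intersect(group_levels(), unique(g)), reference_group)
  ref_idx <- g == reference_group
  out <- lapply(others, function(grp) {
    idx <- g == grp
    if (length(regions) == 0L)
      return(data.frame(region = character(0), t = numeric(0),
                        df = numeric(0), p = numeric(0), p_adj = numeric(0),
                        significant = logical(0), mean_group = numeric(0),
                        mean_reference = numeric(0)))
    res <- t(vapply(regions, function(r) {
      tt <- stats::t.test(vals[idx, r], vals[ref_idx, r], var.equal = TRUE)
      c(t = unname(tt$statistic), df = unname(tt$parameter),
        p = unname(tt$p.value))
    }, numeric(3)))
    fdr <- fdr_bh(res[, "p"], q = fdr_q)
    data.frame(region = regions, t = res[, "t"], df = res[, "df"],
               p = res[, "p"], p_adj = fdr$adjusted,
               significant = fdr$rejected,
               mean_group = colMeans(vals[idx, regions, drop = FALSE]),
               mean_reference = colMeans(vals[ref_idx, regions,
                                              drop = FALSE]),
               row.names = NULL)
  })
  names(out) <- others
  out
}

#' Correlate regional uptake with a clinical score within one group
#'
#' Pearson correlation (two-tailed) between each masked region's uptake and a
#' per-subject score (e.g. FAQ) within a single group. Subjects with a
#' missing score are dropped pairwise with a message.
#'
#' @param cohort A `tau_cohort`.
#' @param regions Character vector of regions to test (the mask).
#' @param score_field Name of the metadata column holding the score
#'   (default `"faq"`).
#' @param group Group label to restrict to.
#' @return Data frame with columns `region`, `r`, `p`, `n`.
#' @export
correlate_with_score <- function(cohort, regions, score_field = "faq",
                                 group) {
  validate_cohort(cohort)
  idx <- as.character(cohort$subjects$group) == group
  score <- cohort$subjects[[score_field]][idx]
  if (is.null(score)) stop("no metadata field '", score_field, "'",
                           call. = FALSE)
  keep <- !is.na(score)
  if (sum(!keep) > 0)
    message("dropping ", sum(!keep), " subject(s) with missing ",
            score_field)
  score <- score[keep]
  if (length(score) < 3L)
    stop("need at least 3 subjects with a non-missing score", call. = FALSE)
  if (stats::sd(score) == 0)
    stop("score '", score_field, "' is constant in group ", group,
         call. = FALSE)
  vals <- cohort$values[idx, , drop = FALSE][keep, , drop = FALSE]
  res <- t(vapply(regions, function(r) {
    ct <- stats::cor.test(vals[, r], score)
    c(r = unname(ct$estimate), p = unname(ct$p.value))
  }, numeric(2)))
  data.frame(region = regions, r = res[, "r"], p = res[, "p"],
             n = length(score), row.names = NULL)
}

#' Correlate CSF total-tau with regional and global uptake within one group
#'
#' Per-region Pearson correlation between CSF total-tau and regional uptake,
#' plus a global correlation against the whole-brain mean uptake (reported as
#' region `"global_mean"`).
#'
#' @param cohort A `tau_cohort`.
#' @param group Group label to restrict to (>= 3 subjects with CSF values).
#' @return Data frame with columns `region`, `r`, `p`, `n`; the last row is
#'   the global-mean correlation.
#' @export
correlate_csf_pet <- function(cohort, group) {
  validate_cohort(cohort)
  idx <- as.character(cohort$subjects$group) == group
  csf <- cohort$subjects$csf_ttau[idx]
  if (is.null(csf)) stop("no csf_ttau metadata", call. = FALSE)
  keep <- !is.na(csf)
  if (sum(!keep) > 0)
    message("dropping ", sum(!keep), " subject(s) with missing CSF T-Tau")
  csf <- csf[keep]
  if (length(csf) < 3L)
    stop("need at least 3 subjects with CSF T-Tau", call. = FALSE)
  if (stats::sd(csf) == 0)
    stop("CSF T-Tau is constant in group ", group, call. = FALSE)
  vals <- cohort$values[idx, , drop = FALSE][keep, , drop = FALSE]
  regions <- colnames(vals)
  res <- t(vapply(regions, function(r) {
    ct <- stats::cor.test(vals[, r], csf)
    c(r = unname(ct$estimate), p = unname(ct$p.value))
  }, numeric(2)))
  gl <- stats::cor.test(rowMeans(vals), csf)
  data.frame(region = c(regions, "global_mean"),
             r = c(res[, "r"], unname(gl$estimate)),
             p = c(res[, "p"], unname(gl$p.value)),
             n = length(csf), row.names = NULL)
}
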