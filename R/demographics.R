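#' Pearson chi-square test on a 2x2 count table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with one
#' degree of freedom, the convention under which the demographic-table
#' p-values of the study design reproduce.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `statistic` (chi-square), `df` (1) and `p` (two-tailed).
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    zero_r <- which(rowSums(table) == 0)
    zero_c <- which(colSums(table) == 0)
    stop("degenerate margin: ",
         paste(c(if (length(zero_r)) paste("row", zero_r),
                 if (length(zero_c)) paste("column", zero_c)),
               collapse = ", "), call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = 1L, p = unname(res$p.value))
}

#' Pooled two-sample t test from summary statistics
#'
#' Equal-variance two-sample t test computed from group means, standard
#' deviations and sizes (as printed in a demographics table), with
#' `df = n_a + n_b - 2`. Reproduces the raw-data pooled t test exactly.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A (`sd_a >= 0`,
#'   `n_a >= 2`).
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return List with `t`, `df` and two-tailed `p`.
#' @export
t_test_from_summaries <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(sd_a >= 0, sd_b >= 0, n_a >= 2, n_b >= 2, n_a + n_b >= 4)
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  df <- n_a + n_b - 2
  if (sp2 == 0) {
    if (mean_a == mean_b) {
      warning("both standard deviations zero with equal means; t = 0",
              call. = FALSE)
      return(list(t = 0, df = df, p = 1))
    }
    return(list(t = sign(mean_a - mean_b) * Inf, df = df, p = 0))
  }
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

count_pair <- function(x, positive) {
  c(sum(x == positive, na.rm = TRUE), sum(x != positive & !is.na(x)))
}

#' Demographic comparison table for a cohort
#'
#' Per-group summaries (mean (SD) for continuous variables, positive:negative
#' counts for categorical ones) plus pairwise test p-values of every
#' non-reference group against the reference: uncorrected chi-square for
#' categorical splits, pooled t for continuous variables. A variable missing
#' for an entire group is marked unavailable.
#'
#' @param cohort A `tau_cohort`.
#' @param reference_group Reference group label (default `"A4-T-"`).
#' @return Data frame with one row per variable, one summary column per group
#'   and one `p_vs_<group>` column per comparison.
#' @export
demographics_table <- function(cohort, reference_group = "A4-T-") {
  validate_cohort(cohort)
  s <- cohort$subjects
  g <- as.character(s$group)
  if (!reference_group %in% g)
    stop("reference group ", reference_group, " not present", call. = FALSE)
  groups <- intersect(group_levels(), unique(g))
  others <- setdiff(groups, reference_group)

  cont_vars <- c(age = "age", FAQ = "faq", MMSE = "mmse")
  cat_vars <- list(
    "Sex (male:female)" = list(field = "sex", positive = 1),
    "CSF-Abeta (positive:negative)" = list(field = "abeta_status",
                                           positive = "positive"),
    "MCI:NC" = list(field = "diagnosis", positive = "MCI"))

  fmt_p <- function(p) formatC(p, digits = 3, format = "g")
  rows <- list()
  rows[["N"]] <- c(vapply(groups, function(grp) as.character(sum(g == grp)),
                          character(1)),
                   stats::setNames(rep("", length(others)),
                                   paste0("p_vs_", others)))
  for (lab in names(cat_vars)) {
    fld <- cat_vars[[lab]]$field
    pos <- cat_vars[[lab]]$positive
    if (is.null(s[[fld]])) next
    cells <- vapply(groups, function(grp) {
      x <- s[[fld]][g == grp]
      if (all(is.na(x))) return("unavailable")
      paste(count_pair(x, pos), collapse = ":")
    }, character(1))
    ps <- vapply(others, function(grp) {
      xa <- s[[fld]][g == reference_group]; xb <- s[[fld]][g == grp]
      if (all(is.na(xa)) || all(is.na(xb))) return("unavailable")
      tab <- rbind(count_pair(xa, pos), count_pair(xb, pos))
      fmt_p(chi_square_2x2(tab)$p)
    }, character(1))
    rows[[lab]] <- c(cells, stats::setNames(ps, paste0("p_vs_", others)))
  }
  for (lab in names(cont_vars)) {
    fld <- cont_vars[[lab]]
    if (is.null(s[[fld]])) next
    cells <- vapply(groups, function(grp) {
      x <- s[[fld]][g == grp]
      x <- x[!is.na(x)]
      if (!length(x)) return("unavailable")
      sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
    }, character(1))
    ps <- vapply(others, function(grp) {
      xa <- s[[fld]][g == reference_group]; xb <- s[[fld]][g == grp]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(xa) < 2 || length(xb) < 2) return("unavailable")
      fmt_p(t_test_from_summaries(mean(xa), stats::sd(xa), length(xa),
                                  mean(xb), stats::sd(xb), length(xb))$p)
    }, character(1))
    rows[[lab]] <- c(cells, stats::setNames(ps, paste0("p_vs_", others)))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(out) <- c(groups, paste0("p_vs_", others))
  cbind(variable = rownames(out), out, row.names = NULL)
}
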