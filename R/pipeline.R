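#' Configuration of a full analysis run
#'
#' Defaults follow the study conventions: a sparsity grid from 8 to 30
#' percent in steps of 1, nodal analysis at the fixed sparsity 8 percent,
#' 5000 permutations, alpha and FDR rate 0.05.
#'
#' @param reference_group Reference group for all comparisons.
#' @param grid Strictly increasing sparsity grid within (0, 1].
#' @param s_fixed Fixed sparsity for nodal analysis.
#' @param n_perm Permutations per test (>= 100).
#' @param alpha Significance level.
#' @param fdr_q FDR rate.
#' @param adjust_covariates Adjust the regional ANOVA/contrasts for age, sex
#'   and global uptake (default `TRUE`, mirroring the network
#'   residualization).
#' @param seed Integer seed; expanded into independent per-stage seeds.
#' @param out_dir Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(reference_group = "A4-T-",
                       grid = seq(0.08, 0.30, by = 0.01),
                       s_fixed = 0.08, n_perm = 5000L, alpha = 0.05,
                       fdr_q = 0.05, adjust_covariates = TRUE, seed = 1L,
                       out_dir = "results/run") {
  if (any(diff(grid) <= 0) || any(grid <= 0 | grid > 1))
    stop("grid must be strictly increasing within (0, 1]", call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  structure(list(reference_group = reference_group, grid = grid,
                 s_fixed = s_fixed, n_perm = as.integer(n_perm),
                 alpha = alpha, fdr_q = fdr_q,
                 adjust_covariates = isTRUE(adjust_covariates),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# independent per-stage seeds derived from the run seed (kept under 2^31)
stage_seed <- function(config, offset) (config$seed * 1000L + offset) %% 2147483647L

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

write_csv_out <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full covariance-network analysis
#'
#' Sequences every stage on a cohort: demographics table, per-group
#' correlation networks and global metric curves over the sparsity grid,
#' global permutation tests (cp/lp/q) and nodal permutation tests
#' (betweenness/degree, at the fixed sparsity) of each non-reference group
#' against the reference, regional ANOVA with post-hoc contrasts, FAQ
#' correlations over the ANOVA-significant mask, and CSF-PET correlations.
#' All outputs are delimited text under `config$out_dir`; a JSON manifest
#' records the configuration, seed and an MD5 hash of every file. A stage
#' failure aborts with the stage name; outputs already written are preserved.
#'
#' @param cohort A validated `tau_cohort`.
#' @param config A `run_config`.
#' @return Invisibly, the manifest as a list.
#' @export
run_full_pipeline <- function(cohort, config = run_config()) {
  validate_cohort(cohort)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- "init"
  on_fail <- function(e) stop("pipeline failed in stage '", stage, "': ",
                              conditionMessage(e), call. = FALSE)
  tryCatch({
    groups <- intersect(group_levels(), unique(cohort$subjects$group))
    others <- setdiff(groups, config$reference_group)
    safe <- function(x) gsub("\\+", "p", gsub("-", "m", x))

    stage <- "demographics"
    log_stage(stage, "comparing ", length(others), " group(s) vs ",
              config$reference_group)
    demo <- demographics_table(cohort, config$reference_group)
    outputs <- c(outputs, write_csv_out(
      demo, file.path(config$out_dir, "demographics.csv")))

    stage <- "networks"
    by_group <- split_by_group(cohort)
    nets <- lapply(by_group, group_network)
    for (grp in groups) {
      R <- nets[[grp]]$R
      df <- data.frame(region = rownames(R), R, check.names = FALSE)
      outputs <- c(outputs, write_csv_out(
        df, file.path(config$out_dir,
                      paste0("correlation_", safe(grp), ".csv"))))
    }
    log_stage(stage, "built ", length(nets), " group network(s)")

    stage <- "metric_curves"
    curves <- do.call(rbind, lapply(groups, function(grp) {
      do.call(rbind, lapply(config$grid, function(S) {
        gm <- global_metrics(binarize_at_sparsity(nets[[grp]], S))
        data.frame(group = grp, sparsity = S, metric = c("cp", "lp", "q"),
                   value = c(gm$cp, gm$lp, gm$q))
      }))
    }))
    outputs <- c(outputs, write_csv_out(
      curves, file.path(config$out_dir, "metric_curves.csv")))

    stage <- "global_permutation"
    k <- 0L
    perm_global <- do.call(rbind, lapply(others, function(grp) {
      do.call(rbind, lapply(c("cp", "lp", "q"), function(mt) {
        k <<- k + 1L
        res <- permutation_test_global(
          cohort, grp, config$reference_group, metric = mt,
          grid = config$grid, n_perm = config$n_perm, alpha = config$alpha,
          seed = stage_seed(config, k))
        log_stage(stage, grp, " ", mt, ": ", sum(res$significant),
                  " significant sparsity/ies (redraws=",
                  attr(res, "redraws"), ")")
        cbind(comparison = grp, as.data.frame(res))
      }))
    }))
    outputs <- c(outputs, write_csv_out(
      perm_global, file.path(config$out_dir, "permutation_global.csv")))

    stage <- "nodal_permutation"
    # nodal sparsity: as configured, raised if needed to the smallest grid
    # sparsity at which every group's network keeps all regions connected
    s_nodal <- max(config$s_fixed,
                   max(vapply(nets, min_connected_sparsity, numeric(1))))
    if (s_nodal > config$s_fixed)
      log_stage(stage, "raising nodal sparsity from ", config$s_fixed,
                " to ", s_nodal, " to keep all regions connected")
    perm_nodal <- do.call(rbind, lapply(others, function(grp) {
      do.call(rbind, lapply(c("bc", "degree"), function(mt) {
        k <<- k + 1L
        res <- permutation_test_nodal(
          cohort, grp, config$reference_group, metric = mt,
          s_fixed = s_nodal, n_perm = config$n_perm,
          alpha = config$alpha, fdr_q = config$fdr_q,
          seed = stage_seed(config, k))
        log_stage(stage, grp, " ", mt, ": ", sum(res$significant),
                  " significant region(s)")
        cbind(comparison = grp, metric = mt, res)
      }))
    }))
    outputs <- c(outputs, write_csv_out(
      perm_nodal, file.path(config$out_dir, "permutation_nodal.csv")))

    stage <- "regional_anova"
    aov_res <- anova_regions(cohort,
                             adjust_covariates = config$adjust_covariates,
                             fdr_q = config$fdr_q)
    outputs <- c(outputs, write_csv_out(
      aov_res, file.path(config$out_dir, "regional_anova.csv")))
    mask <- aov_res$region[aov_res$significant]
    log_stage(stage, length(mask), " significant region(s)")
    contr <- posthoc_contrasts(cohort, config$reference_group,
                               regions = mask,
                               adjust_covariates = config$adjust_covariates,
                               fdr_q = config$fdr_q)
    contr_df <- do.call(rbind, lapply(names(contr), function(grp)
      if (nrow(contr[[grp]])) cbind(comparison = grp, contr[[grp]]) else
        NULL))
    if (is.null(contr_df))
      contr_df <- data.frame(comparison = character(0), region = character(0))
    outputs <- c(outputs, write_csv_out(
      contr_df, file.path(config$out_dir, "posthoc_contrasts.csv")))

    stage <- "correlations"
    faq_df <- do.call(rbind, lapply(others, function(grp) {
      if (length(mask) == 0L) return(NULL)
      cbind(comparison = grp,
            correlate_with_score(cohort, mask, "faq", grp))
    }))
    if (is.null(faq_df))
      faq_df <- data.frame(comparison = character(0), region = character(0))
    outputs <- c(outputs, write_csv_out(
      faq_df, file.path(config$out_dir, "faq_correlations.csv")))
    csf_df <- do.call(rbind, lapply(groups, function(grp)
      cbind(group = grp, correlate_csf_pet(cohort, grp))))
    outputs <- c(outputs, write_csv_out(
      csf_df, file.path(config$out_dir, "csf_pet_correlations.csv")))

    stage <- "manifest"
    manifest <- list(
      config = unclass(config),
      s_nodal = s_nodal,
      groups = groups,
      n_subjects = n_subjects(cohort),
      outputs = lapply(stats::setNames(outputs, basename(outputs)),
                       function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("done", length(outputs), " output file(s) in ", config$out_dir)
    invisible(manifest)
  }, error = on_fail)
}

#' Human-readable summary of a completed run
#'
#' Reads the manifest of a [run_full_pipeline()] output directory and
#' summarizes the significant sparsities per global metric, significant nodes,
#' significant regions and score correlations per comparison. Findings absent
#' in a section are reported as explicit "none" entries; missing output files
#' are listed but not fatal.
#'
#' @param run_dir Path to a pipeline output directory.
#' @return Character vector of report lines (also printed).
#' @export
report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest found at ", manifest_path, call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c(paste0("Analysis run in ", run_dir),
             paste0("  subjects: ", manifest$n_subjects,
                    "; groups: ", paste(unlist(manifest$groups),
                                        collapse = ", ")),
             paste0("  seed: ", manifest$config$seed,
                    "; n_perm: ", manifest$config$n_perm))
  missing <- character(0)
  get_out <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) {
      missing <<- c(missing, name)
      return(NULL)
    }
    utils::read.csv(p, stringsAsFactors = FALSE)
  }

  pg <- get_out("permutation_global.csv")
  lines <- c(lines, "Global network properties (permutation, per sparsity):")
  if (!is.null(pg) && nrow(pg)) {
    for (cmp in unique(pg$comparison)) for (mt in unique(pg$metric)) {
      sub <- pg[pg$comparison == cmp & pg$metric == mt & pg$significant, ]
      lines <- c(lines, paste0("  ", cmp, " vs reference, ", mt, ": ",
                               if (nrow(sub)) paste(sub$sparsity,
                                                    collapse = ", ")
                               else "none"))
    }
  } else lines <- c(lines, "  none")

  pn <- get_out("permutation_nodal.csv")
  lines <- c(lines, "Nodal properties (fixed sparsity, FDR):")
  if (!is.null(pn) && nrow(pn)) {
    for (cmp in unique(pn$comparison)) for (mt in unique(pn$metric)) {
      sub <- pn[pn$comparison == cmp & pn$metric == mt & pn$significant, ]
      lines <- c(lines, paste0("  ", cmp, " vs reference, ", mt, ": ",
                               if (nrow(sub)) paste(sub$region,
                                                    collapse = ", ")
                               else "none"))
    }
  } else lines <- c(lines, "  none")

  av <- get_out("regional_anova.csv")
  lines <- c(lines, "Regional ANOVA (FDR):")
  sig <- if (!is.null(av)) av$region[av$significant] else character(0)
  lines <- c(lines, paste0("  ", if (length(sig)) paste(sig, collapse = ", ")
                           else "none"))

  fq <- get_out("faq_correlations.csv")
  lines <- c(lines, "FAQ correlations (within significant mask):")
  if (!is.null(fq) && nrow(fq)) {
    for (cmp in unique(fq$comparison)) {
      sub <- fq[fq$comparison == cmp & fq$p < 0.05, ]
      lines <- c(lines, paste0("  ", cmp, ": ",
                               if (nrow(sub)) paste0(sub$region, " (r=",
                                                     round(sub$r, 2), ")",
                                                     collapse = ", ")
                               else "none"))
    }
  } else lines <- c(lines, "  none")

  if (length(missing))
    lines <- c(lines, paste0("Missing outputs: ",
                             paste(missing, collapse = ", ")))
  cat(lines, sep = "\n")
  invisible(lines)
}
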