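#' Construct a tau cohort object
#'
#' A cohort bundles the subject-by-region uptake matrix with per-subject
#' metadata and the region atlas. All downstream analyses consume this
#' container.
#'
#' @param values Numeric matrix, one row per subject, one column per atlas
#'   region (columns named by region, rows named by subject id).
#' @param subjects Data frame of per-subject metadata with at least columns
#'   `id` and `group`; optional columns `age`, `sex` (0 = female, 1 = male),
#'   `diagnosis` (`"MCI"`/`"NC"`), `faq` (0-30), `mmse`, `csf_ttau` (ng/L),
#'   `abeta_status` (`"positive"`/`"negative"`).
#' @param atlas Region atlas data frame as returned by [aal90_atlas()].
#' @return An object of class `tau_cohort`.
#' @export
tau_cohort <- function(values, subjects, atlas = aal90_atlas()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- as.character(subjects$id)
  obj <- structure(list(values = values, subjects = subjects, atlas = atlas),
                   class = "tau_cohort")
  validate_cohort(obj)
  obj
}

#' Validate a tau cohort
#'
#' Enforces the container invariants: matching row/subject counts, unique
#' subject ids, finite values, region columns matching the atlas, bounded FAQ
#' scores, non-negative CSF total-tau, and (when both fields are present)
#' consistency of the group's `T+`/`T-` suffix with the 320 ng/L cut-off.
#'
#' @param cohort A `tau_cohort`.
#' @return The cohort, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "tau_cohort"))
  v <- cohort$values
  s <- cohort$subjects
  if (nrow(v) != nrow(s))
    stop("value matrix has ", nrow(v), " rows but metadata has ", nrow(s),
         " subjects", call. = FALSE)
  if (anyDuplicated(s$id))
    stop("duplicated subject ids: ",
         paste(unique(s$id[duplicated(s$id)]), collapse = ", "), call. = FALSE)
  if (nrow(v) > 0 && !all(is.finite(v)))
    stop("non-finite values in the uptake matrix", call. = FALSE)
  if (!identical(colnames(v), cohort$atlas$name))
    stop("value columns do not match the atlas regions in order", call. = FALSE)
  bad_group <- setdiff(unique(as.character(s$group)), group_levels())
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  if (!is.null(s$faq)) {
    f <- s$faq[!is.na(s$faq)]
    if (length(f) && (any(f < 0) || any(f > 30)))
      stop("FAQ scores must lie in [0, 30]", call. = FALSE)
  }
  if (!is.null(s$csf_ttau)) {
    ct <- s$csf_ttau[!is.na(s$csf_ttau)]
    if (length(ct) && any(ct < 0))
      stop("CSF T-Tau must be non-negative", call. = FALSE)
    has <- !is.na(s$csf_ttau) & !is.na(s$group)
    if (any(has)) {
      tau_pos <- grepl("T\\+$", as.character(s$group[has]))
      abn <- s$csf_ttau[has] >= CSF_TTAU_CUTOFF
      if (any(tau_pos != abn))
        stop("group T+/T- suffix inconsistent with CSF T-Tau vs the ",
             CSF_TTAU_CUTOFF, " ng/L cut-off for subject(s): ",
             paste(utils::head(s$id[has][tau_pos != abn], 5), collapse = ", "),
             call. = FALSE)
    }
  }
  invisible(cohort)
}

#' @export
print.tau_cohort <- function(x, ...) {
  cat("<tau_cohort> ", nrow(x$values), " subjects x ", ncol(x$values),
      " regions\n", sep = "")
  if (nrow(x$subjects) > 0)
    print(table(factor(x$subjects$group, levels = group_levels())))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `tau_cohort`.
#' @return Integer subject count.
#' @export
n_subjects <- function(cohort) nrow(cohort$values)

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a cohort from delimited text files
#'
#' The values file holds one row per subject: column 1 the subject id, the
#' remaining columns one per atlas region (header row of region names). The
#' metadata file is keyed by subject id. Both files may be comma- or
#' tab-delimited (detected from the header line). Subjects present in only one
#' of the two files are dropped with a warning.
#'
#' @param values_path Path to the subject-by-region values table.
#' @param metadata_path Path to the subject metadata table.
#' @param atlas Region atlas; defaults to [aal90_atlas()].
#' @return A validated `tau_cohort`.
#' @export
read_cohort <- function(values_path, metadata_path, atlas = aal90_atlas()) {
  for (p in c(values_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  vals <- utils::read.table(values_path, header = TRUE,
                            sep = detect_sep(values_path),
                            colClasses = "character", check.names = FALSE,
                            stringsAsFactors = FALSE)
  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = detect_sep(metadata_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  region_cols <- colnames(vals)[-1L]
  dup <- unique(region_cols[duplicated(region_cols)])
  if (length(dup))
    stop("duplicated region column(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  missing_r <- setdiff(atlas$name, region_cols)
  extra_r <- setdiff(region_cols, atlas$name)
  if (length(missing_r) || length(extra_r))
    stop("value file regions do not match the atlas; missing: ",
         paste(utils::head(missing_r, 3), collapse = ", "),
         if (length(missing_r) > 3) ", ..." else "",
         "; unexpected: ",
         paste(utils::head(extra_r, 3), collapse = ", "),
         if (length(extra_r) > 3) ", ..." else "", call. = FALSE)

  ids_v <- vals[[1L]]
  num <- suppressWarnings(
    vapply(atlas$name, function(r) as.numeric(vals[[r]]), numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1L,
                                      dimnames = list(NULL, atlas$name))
  bad <- which(is.na(num) & !is.na(as.matrix(vals[atlas$name])), arr.ind = TRUE)
  if (nrow(vals) > 0 && length(bad)) {
    bad <- matrix(bad, ncol = 2L)
    stop("non-numeric value at row ", bad[1, 1], " (subject ",
         ids_v[bad[1, 1]], "), column ", atlas$name[bad[1, 2]], call. = FALSE)
  }
  if (anyDuplicated(ids_v))
    stop("duplicated subject id(s) in values file: ",
         paste(unique(ids_v[duplicated(ids_v)]), collapse = ", "),
         call. = FALSE)
  if (!"id" %in% colnames(meta))
    stop("metadata file must contain an 'id' column", call. = FALSE)
  meta$id <- as.character(meta$id)

  common <- intersect(ids_v, meta$id)
  dropped <- union(setdiff(ids_v, meta$id), setdiff(meta$id, ids_v))
  if (length(dropped))
    warning("dropping ", length(dropped),
            " subject(s) present in only one file: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  keep_v <- match(common, ids_v)
  values <- matrix(num[keep_v, , drop = FALSE], ncol = nrow(atlas),
                   dimnames = list(common, atlas$name))
  subjects <- meta[match(common, meta$id), , drop = FALSE]
  rownames(subjects) <- NULL
  tau_cohort(values, subjects, atlas)
}

#' Write a cohort to delimited text files
#'
#' Writes `values.csv` (subject id + one column per region, values printed at
#' 10 significant digits) and `metadata.csv` into `out_dir`. Reading the files
#' back with [read_cohort()] reproduces the cohort exactly at that text
#' precision; a second write of the re-read cohort is byte-identical.
#'
#' @param cohort A validated `tau_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of the two file paths (values, metadata).
#' @export
write_cohort <- function(cohort, out_dir) {
  validate_cohort(cohort)
  if (nrow(cohort$values) > 0 && !all(is.finite(cohort$values)))
    stop("refusing to write non-finite values", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir,
                                 call. = FALSE)
  values_path <- file.path(out_dir, "values.csv")
  meta_path <- file.path(out_dir, "metadata.csv")
  txt <- matrix(sprintf("%.10g", cohort$values), nrow = nrow(cohort$values),
                ncol = ncol(cohort$values),
                dimnames = list(NULL, colnames(cohort$values)))
  header <- paste(c("id", colnames(cohort$values)), collapse = ",")
  body <- if (nrow(txt) > 0)
    paste(rownames(cohort$values), apply(txt, 1L, paste, collapse = ","),
          sep = ",")
  else character(0)
  writeLines(c(header, body), values_path)
  utils::write.table(cohort$subjects, meta_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  c(values = values_path, metadata = meta_path)
}

#' Split a cohort by study group
#'
#' Partitions the cohort into one sub-cohort per group label present. The
#' partition is disjoint and exhaustive; per-group sizes are attached as the
#' `"sizes"` attribute.
#'
#' @param cohort A `tau_cohort`; every subject must carry a group label.
#' @return Named list of `tau_cohort` objects, one per group, in
#'   [group_levels()] order.
#' @export
split_by_group <- function(cohort) {
  validate_cohort(cohort)
  g <- as.character(cohort$subjects$group)
  if (any(is.na(g)))
    stop("subjects without a group label: ",
         paste(cohort$subjects$id[is.na(g)], collapse = ", "), call. = FALSE)
  present <- group_levels()[group_levels() %in% g]
  out <- lapply(present, function(lvl) {
    idx <- which(g == lvl)
    subjects <- cohort$subjects[idx, , drop = FALSE]
    rownames(subjects) <- NULL
    tau_cohort(cohort$values[idx, , drop = FALSE], subjects, cohort$atlas)
  })
  names(out) <- present
  attr(out, "sizes") <- vapply(out, n_subjects, integer(1))
  out
}
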