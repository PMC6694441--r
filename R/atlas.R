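#' The 90-region AAL parcellation used by all networks
#'
#' Returns the automated anatomical labeling (AAL) atlas restricted to its 90
#' cerebral regions (45 per hemisphere), in the fixed order shared by every
#' matrix produced by this package. Each region carries a hemisphere tag and a
#' coarse lobar label; the lobar labels define the default community structure
#' planted by the synthetic-cohort generator.
#'
#' @return A data frame with columns `name`, `hemisphere` (`"L"`/`"R"`) and
#'   `lobe`, with 90 rows in canonical order.
#' @export
#' @examples
#' atlas <- aal90_atlas()
#' nrow(atlas)
aal90_atlas <- function() {
  path <- system.file("extdata", "aal90_regions.tsv", package = "taucovnet",
                      mustWork = TRUE)
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(atlas) == 90L, !anyDuplicated(atlas$name))
  atlas
}

#' Region labels of the AAL-90 atlas
#'
#' @return Character vector of the 90 region names in canonical order.
#' @export
aal90_regions <- function() aal90_atlas()$name

#' The four biomarker-defined study groups
#'
#' Subjects are classified by APOE epsilon-4 carriership (`A4+`/`A4-`) and CSF
#' total-tau status (`T+` abnormal, i.e. >= 320 ng/L; `T-` normal). The first
#' level, `A4-T-`, is the reference group for all comparisons.
#'
#' @return Character vector of the four group labels.
#' @export
group_levels <- function() c("A4-T-", "A4+T+", "A4+T-", "A4-T+")

# CSF total-tau abnormality cut-off (ng/L)
CSF_TTAU_CUTOFF <- 320
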