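#' Reference cohort tabulations
#'
#' Loads the bundled tabulations of a published 234-patient lung
#' brain-metastasis cohort (a 10-year regional neuropathology series):
#' the neuroanatomical site-overlap patient-count matrix, the
#' immunostain-refined subtype-by-site lesion table with per-subtype
#' patient counts, and the biomarker-by-subtype and biomarker-by-site
#' tables for EGFR, PD-L1 and RAS. These fixtures let every downstream
#' statistic (overlap semantics, the simplified 252-lesion exact test,
#' the PD-L1-by-site tests and the all-pairs decompositions) be
#' reproduced without any patient-level data.
#'
#' Note an internal inconsistency carried over faithfully from the
#' source tabulations: the biomarker overview reports 65 adequate EGFR
#' results while the EGFR-by-site table's adequate row sums to 71
#' (patients with multi-site lesions contribute one count per site in
#' the site tables, which accounts for part, but not all, of such
#' differences). Each table here reproduces its own printed counts; no
#' attempt is made to reconcile them.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{overlap}{7 x 7 symmetric site-overlap patient-count matrix.}
#'     \item{lesions}{4 x 6 subtype-by-site lesion
#'       \code{\link{contingency_table}} (columns: five named sites plus
#'       \code{"unknown/other"}).}
#'     \item{patients}{Named per-subtype patient counts.}
#'     \item{biomarker_subtype}{Named list of status-by-subtype
#'       \code{contingency_table}s (\code{egfr}, \code{pdl1},
#'       \code{ras}).}
#'     \item{biomarker_site}{Named list of status-by-site
#'       \code{contingency_table}s.}
#'   }
#' @examples
#' ref <- reference_cohort()
#' sum(simplify_table(ref$lesions, "unknown/other"))  # 252 lesions
#' @export
reference_cohort <- function() {
  dir <- system.file("extdata", "reference_cohort", package = "bmetlung")
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)

  t1 <- rd("table1_overlap.csv")
  overlap <- as.matrix(t1[, -1L])
  rownames(overlap) <- t1$site
  storage.mode(overlap) <- "integer"

  t2 <- rd("table2_subtype_site.csv")
  lesions <- as.matrix(t2[, setdiff(names(t2), c("subtype", "patients"))])
  rownames(lesions) <- t2$subtype
  patients <- stats::setNames(as.integer(t2$patients), t2$subtype)

  long_split <- function(df) {
    out <- lapply(split(df, df$marker), function(d) {
      m <- as.matrix(d[, setdiff(names(d), c("marker", "status"))])
      rownames(m) <- d$status
      contingency_table(m)
    })
    out[unique(df$marker)]
  }

  list(overlap = overlap,
       lesions = contingency_table(lesions),
       patients = patients,
       biomarker_subtype = long_split(rd("table4_biomarker_subtype.csv")),
       biomarker_site = long_split(rd("table5_biomarker_site.csv")))
}
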