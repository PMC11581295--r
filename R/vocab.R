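#' Closed label vocabularies
#'
#' All classifier outputs are drawn from closed vocabularies: six mutually
#' exclusive diagnostic categories (ordered from least to most specific --
#' the hierarchy used to resolve reports matching several category
#' patterns), seven neuroanatomical site codes (five lobes/cerebellum plus
#' \code{"other"} for non-lobar locations and \code{"unknown"} when no
#' location keyword matches), lung-cancer subtypes, immunostain names and
#' lung biomarker names.
#'
#' @format Character vectors of labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
bm_categories <- function() {
  c("unclassified", "brain cardiovascular disease", "miscellaneous lesions",
    "other brain lesions", "probable metastasis", "primary brain tumour")
}

#' @rdname vocabularies
#' @export
bm_sites <- function() {
  c("frontal", "parietal", "temporal", "occipital", "cerebellum",
    "other", "unknown")
}

#' @rdname vocabularies
#' @export
bm_named_sites <- function() bm_sites()[1:5]

#' @rdname vocabularies
#' @export
bm_subtypes <- function() {
  c("AC", "SCC", "SCLC", "NSCLC-NOS", "other", "not-applicable")
}

#' @rdname vocabularies
#' @export
bm_stains <- function() c("TTF-1", "p63", "p40", "neuroendocrine")

#' @rdname vocabularies
#' @export
bm_markers <- function() {
  c("egfr", "alk_ihc", "alk_fish", "pdl1", "ras", "braf_v600", "ros1")
}

# primary sites the lexicon can emit; "multiple/ambiguous" is assigned when
# two distinct organ keywords fire, "unknown" when none does.
bm_primary_sites <- function() {
  c("lung", "breast", "melanoma", "colorectal", "kidney",
    "unknown", "multiple/ambiguous", "not-applicable")
}

TRI_STATE <- c("positive", "negative", "not-done")

PDL1_BINS <- c("negative", "low-positive", "positive", "not-done")
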