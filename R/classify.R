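#' @useDynLib bmetlung, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# --- text normalisation ----------------------------------------------------

# Lowercase, collapse whitespace. Hyphens are kept: stems such as "tempor"
# must still match inside hyphenated dual-site forms ("temporo-parietal").
normalize_text <- function(text) {
  text <- tolower(text)
  text <- gsub("[ \t]+", " ", text)
  trimws(text)
}

# Sentence units for negation scoping: split on period, semicolon, newline.
split_sentences <- function(text) {
  s <- unlist(strsplit(text, "[.;\n]+"))
  s <- trimws(s)
  s[nzchar(s)]
}

# Minimal same-sentence negation rule: a diagnosis/site keyword inside a
# sentence carrying a negation cue is ignored. Cues are deliberately
# narrow so that stain result sentences ("p63: negative") are untouched.
NEGATION_CUE <- "\\bno\\b|negative for|without|free of|\\bnot? evidence\\b"

affirmed_sentences <- function(text) {
  s <- split_sentences(normalize_text(text))
  s[!grepl(NEGATION_CUE, s, perl = TRUE)]
}

# highest-priority label among rules of one axis matching any sentence
match_axis <- function(sentences, lexicon, axis) {
  rules <- lexicon[lexicon$axis == axis, , drop = FALSE]
  if (nrow(rules) == 0L || length(sentences) == 0L) return(character(0))
  hit <- vapply(rules$pattern, function(p)
    any(grepl(p, sentences, perl = TRUE)), logical(1))
  rules$label[hit]  # rules are stored sorted by decreasing priority
}

# --- diagnosis classification ---------------------------------------------

#' Classify a pathology report by diagnosis
#'
#' Assigns exactly one diagnostic category from the six-level hierarchy
#' (unclassified, brain cardiovascular disease, miscellaneous lesions,
#' other brain lesions, probable metastasis, primary brain tumour), a
#' primary site for probable metastases, and -- for lung metastases -- a
#' lung-cancer subtype. Subtype assignment honours the supersession
#' hierarchy: the specific patterns for small cell, adenocarcinoma and
#' squamous cell carcinoma each supersede the generic non-small cell
#' pattern, so "non-small cell carcinoma, favour adenocarcinoma" is
#' classified as adenocarcinoma, and a report matching only the generic
#' pattern becomes NSCLC-NOS.
#'
#' Keywords inside a sentence carrying a negation cue ("no ...",
#' "negative for ...") are ignored. If two distinct organ keywords fire,
#' the primary site is labelled \code{"multiple/ambiguous"} (such cases
#' are excluded from the single-primary lung cohort downstream).
#'
#' @param text Report text (non-empty string).
#' @param lexicon A match lexicon, see [default_lexicon()].
#' @return A list with elements \code{category}, \code{subtype},
#'   \code{primary_site}.
#' @examples
#' lex <- default_lexicon()
#' classify_diagnosis(
#'   "Metastatic non-small cell carcinoma, favour adenocarcinoma,
#'    consistent with lung primary.", lex)
#' @export
classify_diagnosis <- function(text, lexicon = default_lexicon()) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("report text must be a non-empty string")
  sent <- affirmed_sentences(text)

  cats <- match_axis(sent, lexicon, "category")
  category <- if (length(cats)) cats[[1L]] else "unclassified"

  primary_site <- "not-applicable"
  subtype <- "not-applicable"
  if (category == "probable metastasis") {
    organs <- unique(match_axis(sent, lexicon, "primary_site"))
    primary_site <- if (length(organs) == 0L) "unknown"
      else if (length(organs) > 1L) "multiple/ambiguous"
      else organs
    if (identical(primary_site, "lung")) {
      subs <- match_axis(sent, lexicon, "subtype")
      subtype <- if (length(subs)) subs[[1L]] else "other"
    }
  }
  list(category = category, subtype = subtype, primary_site = primary_site)
}

#' Code the neuroanatomical locations mentioned in a report
#'
#' Returns the set of all site codes whose keyword stems match the report
#' (negated sentences excluded). Stem matching makes hyphenated dual-site
#' phrasings map to both sites: "temporo-parietal" yields
#' \{temporal, parietal\}. Repeated mentions of one site deduplicate. When
#' no location keyword matches the fallback is \code{"unknown"}; unknown
#' never co-occurs with a named site.
#'
#' @inheritParams classify_diagnosis
#' @return Character vector of site codes (a set).
#' @examples
#' code_locations("Temporo-parietal lesion, resection.")
#' @export
code_locations <- function(text, lexicon = default_lexicon()) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("report text must be a non-empty string")
  sent <- affirmed_sentences(text)
  sites <- unique(match_axis(sent, lexicon, "location"))
  if (length(sites) == 0L) sites <- "unknown"
  sites
}

# --- corpus-level classification ------------------------------------------

#' Classify a report corpus
#'
#' Runs [classify_diagnosis()], [code_locations()], [parse_stain()],
#' [parse_biomarkers()] and [refine_subtype()] over each report of a
#' corpus and returns one labelled row per case.
#'
#' @param reports Data frame with columns \code{case_id},
#'   \code{patient_id}, \code{accession_year}, \code{report_text}
#'   (as produced by [generate_corpus()] or read with [read_corpus()]).
#' @param lexicon A match lexicon.
#' @return Data frame of case labels, one row per report, with columns
#'   \code{category}, \code{primary_site}, \code{subtype_reported},
#'   \code{subtype_refined}, \code{site_set} (pipe-delimited),
#'   per-stain tri-states and per-marker statuses.
#' @export
classify_corpus <- function(reports, lexicon = default_lexicon()) {
  stopifnot(all(c("case_id", "patient_id", "accession_year",
                  "report_text") %in% names(reports)))
  n <- nrow(reports)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    text <- reports$report_text[[i]]
    dx <- classify_diagnosis(text, lexicon)
    sites <- code_locations(text, lexicon)
    ttf1 <- parse_stain(text, "TTF-1")
    p63  <- parse_stain(text, "p63")
    p40  <- parse_stain(text, "p40")
    ne   <- parse_stain(text, "neuroendocrine")
    bio  <- parse_biomarkers(text)
    rows[[i]] <- data.frame(
      case_id = reports$case_id[[i]],
      patient_id = reports$patient_id[[i]],
      accession_year = reports$accession_year[[i]],
      category = dx$category,
      primary_site = dx$primary_site,
      subtype_reported = dx$subtype,
      subtype_refined = refine_subtype(dx$subtype, ttf1, p63),
      site_set = paste(sites, collapse = "|"),
      ttf1 = ttf1, p63 = p63, p40 = p40, neuroendocrine = ne,
      egfr = bio$egfr, alk_ihc = bio$alk_ihc, alk_fish = bio$alk_fish,
      ras = bio$ras, braf_v600 = bio$braf_v600, ros1 = bio$ros1,
      pdl1_tps = if (is.null(bio$pdl1_tps)) NA_real_ else bio$pdl1_tps,
      pdl1_bin = bio$pdl1_bin,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- audit against generator ground truth ---------------------------------

#' Audit classifier output against ground truth
#'
#' Compares predicted case labels with the generator's truth records,
#' axis by axis, and returns exact-match accuracies. Site sets are
#' compared as sets (order-insensitive). The mismatch rows are attached
#' as an attribute for inspection.
#'
#' @param predicted Labels data frame from [classify_corpus()].
#' @param truth Truth data frame from [generate_corpus()].
#' @param axes Label columns to compare.
#' @return Data frame with columns \code{axis}, \code{n}, \code{correct},
#'   \code{accuracy}; attribute \code{"mismatches"} holds a data frame of
#'   disagreeing case ids per axis.
#' @export
audit_agreement <- function(predicted, truth,
                            axes = c("category", "primary_site",
                                     "subtype_reported", "subtype_refined",
                                     "site_set")) {
  if (nrow(predicted) != nrow(truth))
    stop("predicted and truth differ in length")
  ord_p <- order(predicted$case_id)
  ord_t <- order(truth$case_id)
  predicted <- predicted[ord_p, , drop = FALSE]
  truth <- truth[ord_t, , drop = FALSE]
  if (!identical(as.character(predicted$case_id),
                 as.character(truth$case_id)))
    stop("case ids of predicted and truth do not align")

  canon_set <- function(x)
    vapply(strsplit(x, "|", fixed = TRUE),
           function(s) paste(sort(unique(s)), collapse = "|"), "")
  res <- vector("list", length(axes))
  mism <- list()
  for (k in seq_along(axes)) {
    ax <- axes[[k]]
    tc <- if (ax %in% names(truth)) ax else paste0("true_", ax)
    if (!tc %in% names(truth)) stop("truth lacks column for axis ", ax)
    pv <- as.character(predicted[[ax]])
    tv <- as.character(truth[[tc]])
    if (ax == "site_set") { pv <- canon_set(pv); tv <- canon_set(tv) }
    ok <- pv == tv
    res[[k]] <- data.frame(axis = ax, n = length(ok),
                           correct = sum(ok),
                           accuracy = mean(ok))
    if (any(!ok))
      mism[[ax]] <- data.frame(case_id = predicted$case_id[!ok],
                               axis = ax, predicted = pv[!ok],
                               truth = tv[!ok])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "mismatches") <-
    if (length(mism)) do.call(rbind, c(mism, make.row.names = FALSE))
    else NULL
  out
}
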