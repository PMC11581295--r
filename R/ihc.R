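# Immunostain extraction and immunostain-driven subtype refinement.

STAIN_PATTERNS <- c(
  "TTF-1" = "ttf ?-? ?1",
  "p63" = "\\bp63\\b",
  "p40" = "\\bp40\\b",
  "neuroendocrine" = "synaptophysin|chromogranin|cd ?56|neuroendocrine"
)

#' Extract an immunostain result from report text
#'
#' Scans the report sentence by sentence for the stain name and returns a
#' tri-state: \code{"positive"} or \code{"negative"} when an unambiguous
#' result sentence exists, \code{"not-done"} otherwise (including "not
#' performed" phrasings and sentences that mention the stain with both
#' polarity words).
#'
#' @param text Report text.
#' @param stain_name One of \code{"TTF-1"}, \code{"p63"}, \code{"p40"},
#'   \code{"neuroendocrine"}.
#' @return \code{"positive"}, \code{"negative"} or \code{"not-done"}.
#' @examples
#' parse_stain("TTF-1: positive. p63: negative.", "TTF-1")
#' parse_stain("TTF-1 and p63 were not performed.", "p63")
#' @export
parse_stain <- function(text, stain_name) {
  stain_name <- match.arg(stain_name, names(STAIN_PATTERNS))
  pat <- STAIN_PATTERNS[[stain_name]]
  sent <- split_sentences(normalize_text(text))
  sent <- sent[grepl(pat, sent, perl = TRUE)]
  for (s in sent) {
    if (grepl("not (performed|done|available)|pending", s, perl = TRUE))
      return("not-done")
    not_pos <- grepl("not positive", s, perl = TRUE)
    pos <- grepl("positive|immunoreactive", s, perl = TRUE) && !not_pos
    neg <- grepl("negative|non-?reactive", s, perl = TRUE) || not_pos
    if (pos && neg) next  # ambiguous sentence, look further
    if (pos) return("positive")
    if (neg) return("negative")
  }
  "not-done"
}

#' Refine a reported lung-cancer subtype with TTF-1 / p63 immunostains
#'
#' Applies the immunostain reclassification rules to reports signed out as
#' generic non-small cell carcinoma: TTF-1 positive with p63 not positive
#' (negative or not performed) is re-classified as adenocarcinoma; TTF-1
#' negative with p63 positive as squamous cell carcinoma; a case meeting
#' neither rule stays NSCLC-NOS. All other reported subtypes pass through
#' unchanged, so the function is idempotent, and an unstained case
#' (TTF-1 not done) never reclassifies.
#'
#' The p63 side of the adenocarcinoma rule deliberately reads "NOT
#' positive" rather than "negative": p63 was performed in only a minority
#' of cases, and treating an absent p63 as non-positive is the only
#' reading under which a large share of generic NSCLC can be resolved by
#' TTF-1 alone.
#'
#' @param reported_subtype Subtype from the report
#'   (one of [bm_subtypes()]).
#' @param ttf1,p63 Tri-states from [parse_stain()].
#' @return The refined subtype.
#' @examples
#' refine_subtype("NSCLC-NOS", "positive", "not-done")  # "AC"
#' refine_subtype("NSCLC-NOS", "negative", "positive")  # "SCC"
#' refine_subtype("SCLC", "positive", "negative")       # unchanged
#' @export
refine_subtype <- function(reported_subtype, ttf1, p63) {
  stopifnot(length(reported_subtype) == length(ttf1),
            length(ttf1) == length(p63))
  bad <- !reported_subtype %in% bm_subtypes()
  if (any(bad))
    stop("unknown subtype: ", paste(unique(reported_subtype[bad]),
                                    collapse = ", "))
  out <- reported_subtype
  nos <- reported_subtype == "NSCLC-NOS"
  out[nos & ttf1 == "positive" & p63 %in% c("negative", "not-done")] <- "AC"
  out[nos & ttf1 == "negative" & p63 == "positive"] <- "SCC"
  out
}

#' Bin a PD-L1 tumour proportion score
#'
#' Pure binning function: TPS < 1\% is negative, 1--49\% low positive,
#' 50\% or more positive. \code{NA} maps to \code{"not-done"}.
#'
#' @param tps Numeric vector of tumour proportion scores (percent,
#'   0--100), possibly \code{NA}.
#' @return Character vector of bins.
#' @examples
#' bin_pdl1(c(0.9, 1, 49.9, 50, NA))
#' @export
bin_pdl1 <- function(tps) {
  if (any(!is.na(tps) & (tps < 0 | tps > 100)))
    stop("TPS must lie in [0, 100]")
  out <- rep("not-done", length(tps))
  out[!is.na(tps) & tps < 1] <- "negative"
  out[!is.na(tps) & tps >= 1 & tps < 50] <- "low-positive"
  out[!is.na(tps) & tps >= 50] <- "positive"
  out
}

MARKER_PATTERNS <- c(
  egfr = "\\begfr\\b",
  alk_ihc = "alk (ihc|immuno)",
  alk_fish = "alk fish|alk by fluorescence",
  ras = "\\bk?ras\\b",
  braf_v600 = "\\bbraf\\b",
  ros1 = "\\bros ?-? ?1\\b"
)

marker_status <- function(sentences, pattern) {
  sent <- sentences[grepl(pattern, sentences, perl = TRUE)]
  for (s in sent) {
    if (grepl("not (performed|done|available)|pending|insufficient", s))
      return("not-done")
    if (grepl("negative|not detected|wild ?-?type|no .*(mutation|rearrangement|fusion)",
              s, perl = TRUE))
      return("negative")
    if (grepl("positive|detected|identified|rearranged|mutat", s, perl = TRUE))
      return("positive")
  }
  "not-done"
}

#' Parse lung biomarker statuses from report text
#'
#' Extracts the lung biomarker panel (EGFR, ALK by immunostaining, ALK by
#' FISH, RAS, BRAF V600, ROS-1, PD-L1) from the report. The PD-L1 tumour
#' proportion score is parsed as a percentage and binned with
#' [bin_pdl1()]; a malformed TPS (non-numeric or above 100) raises a
#' warning and leaves PD-L1 not-done.
#'
#' @param text Report text (non-empty).
#' @return A list (biomarker profile): per-marker statuses, plus
#'   \code{pdl1_tps} (numeric or \code{NULL}) and \code{pdl1_bin}.
#' @examples
#' parse_biomarkers("EGFR mutation: negative. PD-L1 TPS 60%.")
#' @export
parse_biomarkers <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("report text must be a non-empty string")
  sent <- split_sentences(normalize_text(text))
  prof <- lapply(MARKER_PATTERNS, function(p) marker_status(sent, p))
  names(prof) <- names(MARKER_PATTERNS)

  tps <- NULL
  m <- regmatches(sent, regexpr(
    "pd ?-? ?l1[^0-9<]*(tps[^0-9<]*)?(<\\s*1|[0-9]+(\\.[0-9]+)?)\\s*%",
    sent, perl = TRUE))
  m <- m[lengths(m) > 0 | nzchar(m)]
  m <- m[nzchar(m)]
  if (length(m)) {
    raw <- sub(".*?(<\\s*1|[0-9]+(\\.[0-9]+)?)\\s*%$", "\\1", m[[1L]],
               perl = TRUE)
    val <- if (grepl("<", raw)) 0 else suppressWarnings(as.numeric(raw))
    if (is.na(val) || val > 100) {
      warning("malformed PD-L1 TPS ('", raw, "'); leaving PD-L1 not-done")
    } else {
      tps <- val
    }
  }
  prof$pdl1_tps <- tps
  prof$pdl1_bin <- if (is.null(tps)) "not-done" else bin_pdl1(tps)
  # ALK for tabulation: IHC takes precedence over FISH when both present
  prof$alk <- if (prof$alk_ihc != "not-done") prof$alk_ihc else prof$alk_fish
  prof
}
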