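#' Match lexicon for the hierarchical string-matching classifier
#'
#' The classifier is driven by an ordered rule table (the "match lexicon"):
#' one rule per row with a match \code{axis} (\code{category},
#' \code{subtype}, \code{primary_site} or \code{location}), an integer
#' \code{priority} (unique within an axis; when several rules of one axis
#' fire on a report, the highest priority wins -- this is how
#' "adenocarcinoma" and "squamous cell carcinoma" supersede the generic
#' "non-small cell carcinoma" pattern), a case-insensitive \code{pattern}
#' (Perl regular expression applied to the normalised report text; plain
#' substrings and word stems such as \code{"cerebell"} are the common case)
#' and the \code{label} the rule emits.
#'
#' The lexicon ships as an editable plain-text resource
#' (\code{system.file("extdata", "lexicon.tsv", package = "bmetlung")})
#' rather than being hard-coded, so site-specific report idioms can be
#' added without touching code. For the \code{location} axis all matching
#' rules contribute (a report can name several sites); for the other axes
#' exactly one label is retained.
#'
#' @param path Path to a lexicon TSV with columns
#'   \code{axis}, \code{priority}, \code{pattern}, \code{label}.
#' @param lexicon A lexicon data frame, as returned by these functions.
#' @return A data frame of class \code{bm_lexicon}.
#' @examples
#' lex <- default_lexicon()
#' head(lex)
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "lexicon.tsv", package = "bmetlung")
  read_lexicon(path)
}

#' @rdname default_lexicon
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lex <- utils::read.delim(path, header = TRUE, sep = "\t",
                           quote = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  validate_lexicon(lex)
}

#' @rdname default_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  lexicon <- validate_lexicon(lexicon)
  utils::write.table(lexicon, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_lexicon <- function(lex) {
  need <- c("axis", "priority", "pattern", "label")
  if (!all(need %in% names(lex)))
    stop("lexicon must have columns: ", paste(need, collapse = ", "))
  axes <- c("category", "subtype", "primary_site", "location")
  bad <- setdiff(unique(lex$axis), axes)
  if (length(bad))
    stop("unknown lexicon axis: ", paste(bad, collapse = ", "))
  lex$priority <- as.integer(lex$priority)
  for (ax in unique(lex$axis)) {
    pr <- lex$priority[lex$axis == ax]
    if (anyDuplicated(pr))
      stop("priorities must be unique within axis '", ax, "'")
  }
  # labels must come from the closed vocabularies
  ok <- list(category = bm_categories(),
             subtype = bm_subtypes(),
             primary_site = bm_primary_sites(),
             location = bm_sites())
  for (ax in unique(lex$axis)) {
    bad <- setdiff(lex$label[lex$axis == ax], ok[[ax]])
    if (length(bad))
      stop("axis '", ax, "' emits labels outside the closed vocabulary: ",
           paste(bad, collapse = ", "))
  }
  lex <- lex[order(lex$axis, -lex$priority), , drop = FALSE]
  rownames(lex) <- NULL
  class(lex) <- c("bm_lexicon", "data.frame")
  lex
}
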