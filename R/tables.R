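# Patient-level cohort construction and the printed-style tabulations:
# first-case retention, the site-overlap matrix, subtype-by-site lesion
# and patient tables, conditional distributions, biomarker tables.

#' Labelled contingency table
#'
#' Light-weight container for a labelled r x c table of non-negative
#' integer counts, as fed to the exact tests. Margins are recomputed on
#' construction and after any manipulation, so they always equal the cell
#' sums.
#'
#' @param mat Numeric matrix of non-negative integers with dimnames.
#' @return An integer matrix of class \code{contingency_table}.
#' @examples
#' contingency_table(matrix(1:4, 2, dimnames = list(c("a", "b"), c("x", "y"))))
#' @export
contingency_table <- function(mat) {
  mat <- as.matrix(mat)
  if (any(is.na(mat)) || any(mat < 0) || any(mat != round(mat)))
    stop("contingency table cells must be non-negative integers")
  storage.mode(mat) <- "integer"
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("r", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  class(mat) <- c("contingency_table", class(mat))
  mat
}

#' @export
print.contingency_table <- function(x, ...) {
  y <- unclass(x)
  y <- rbind(cbind(y, Sum = rowSums(y)),
             Sum = c(colSums(y), sum(y)))
  print(y, ...)
  invisible(x)
}

#' Margins of a contingency table
#' @param x A \code{contingency_table} (or plain matrix).
#' @return List with \code{row}, \code{col}, \code{total}.
#' @export
table_margins <- function(x) {
  list(row = rowSums(x), col = colSums(x), total = sum(x))
}

#' Retain the first pathology case per patient
#'
#' Mirrors the cohort rule that in patients with several metastatic
#' pathology cases only the earliest case is analysed. Cases are ordered
#' within patient by \code{accession_year} and then by \code{case_id}
#' (accession order); the output has exactly one row per distinct
#' patient.
#'
#' @param cases Data frame with \code{patient_id}, \code{case_id} and
#'   \code{accession_year} columns.
#' @return The filtered data frame.
#' @export
first_case_per_patient <- function(cases) {
  need <- c("patient_id", "case_id", "accession_year")
  if (!all(need %in% names(cases)))
    stop("cases must carry columns: ", paste(need, collapse = ", "))
  if (any(is.na(cases$accession_year)))
    stop("missing ordering key (accession_year)")
  ord <- order(cases$patient_id, cases$accession_year, cases$case_id)
  cases <- cases[ord, , drop = FALSE]
  out <- cases[!duplicated(cases$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

split_sites <- function(site_set) strsplit(site_set, "|", fixed = TRUE)

#' Neuroanatomical site-overlap matrix
#'
#' Builds the symmetric 7 x 7 patient-count matrix over site codes:
#' cell (i, i) counts patients whose site set contains site i and cell
#' (i, j) patients whose set contains both i and j. [overlap_summary()]
#' derives the summary rows: Sum (row sums), Diagonal, Off-diagonal
#' (Sum - Diagonal), Pure (patients with exactly that single site) and
#' Mixed (patients with more than one site). When every patient carries
#' at most two sites the identity Pure = Diagonal - Off-diagonal holds,
#' which lets Pure and Mixed be recovered from the printed matrix alone.
#'
#' @param patients Data frame with a \code{site_set} column
#'   (pipe-delimited site codes), or a list of character site sets.
#' @return A 7 x 7 symmetric integer matrix of class
#'   \code{overlap_matrix}; attribute \code{"n_patients"}.
#' @examples
#' om <- overlap_matrix(list("frontal", "frontal", c("frontal", "parietal")))
#' overlap_summary(om)
#' @export
overlap_matrix <- function(patients) {
  sets <- if (is.data.frame(patients)) split_sites(patients$site_set)
          else lapply(patients, as.character)
  if (any(lengths(sets) == 0L) || any(vapply(sets, function(s)
      any(!nzchar(s)), logical(1))))
    stop("every patient must have a non-empty site set")
  sites <- bm_sites()
  bad <- setdiff(unique(unlist(sets)), sites)
  if (length(bad)) stop("unknown site codes: ", paste(bad, collapse = ", "))
  m <- matrix(0L, 7L, 7L, dimnames = list(sites, sites))
  for (s in sets) {
    s <- unique(s)
    for (a in s) for (b in s) m[a, b] <- m[a, b] + 1L
  }
  structure(m, class = c("overlap_matrix", class(m)),
            n_patients = length(sets),
            pure = vapply(sites, function(x)
              sum(vapply(sets, function(s) identical(unique(s), x),
                         logical(1))), 0L),
            mixed = sum(lengths(lapply(sets, unique)) > 1L))
}

#' @rdname overlap_matrix
#' @param x A site-overlap matrix: either an \code{overlap_matrix} or a
#'   plain symmetric patient-count matrix (e.g. typed in from a printed
#'   table), in which case Pure is derived via the two-site identity
#'   Pure = Diagonal - Off-diagonal and Mixed as patients minus total
#'   Pure.
#' @export
overlap_summary <- function(x) {
  m <- unclass(x)
  if (!isSymmetric(unname(m))) stop("overlap matrix must be symmetric")
  diag_ <- diag(m)
  sum_ <- rowSums(m)
  off <- sum_ - diag_
  if (!is.null(attr(x, "pure"))) {
    pure <- attr(x, "pure")
    mixed <- attr(x, "mixed")
    n <- attr(x, "n_patients")
  } else {
    pure <- diag_ - off   # exact when no patient has more than two sites
    n <- sum(diag_) - sum(off) / 2
    mixed <- n - sum(pure)
  }
  out <- data.frame(site = colnames(m), sum = sum_, diagonal = diag_,
                    off_diagonal = off, pure = as.integer(pure),
                    row.names = NULL, check.names = FALSE)
  attr(out, "mixed") <- as.integer(mixed)
  attr(out, "n_patients") <- as.integer(n)
  out
}

#' @export
print.overlap_matrix <- function(x, ...) {
  print(unclass(x)[,], ...)
  s <- overlap_summary(x)
  cat("Pure:", paste(s$pure, collapse = " "),
      " Mixed:", attr(s, "mixed"), "\n")
  invisible(x)
}

#' Lesion and patient tabulation by lung subtype and site
#'
#' Tabulates a lung-metastasis cohort the way the reference tables count:
#' a patient contributes one lesion per distinct named site
#' (frontal/parietal/temporal/occipital/cerebellum) in its site set;
#' patients whose set holds no named site contribute a single lesion to
#' the merged \code{"unknown/other"} column. Lesions therefore exceed
#' patients exactly when site sets overlap. Internal \code{"other"} and
#' \code{"unknown"} codes are kept separate upstream and merged only
#' here, at presentation.
#'
#' @param patients Data frame with \code{subtype_refined} (or
#'   \code{subtype}) and \code{site_set} columns; one row per patient.
#' @return List with \code{lesions} (4 x 6 \code{contingency_table}),
#'   \code{patients} (named patient counts per subtype) and
#'   \code{n_patients}.
#' @export
site_by_subtype <- function(patients) {
  sub_col <- if ("subtype_refined" %in% names(patients)) "subtype_refined"
             else "subtype"
  subs <- c("AC", "SCC", "SCLC", "NSCLC-NOS")
  cols <- c(bm_named_sites(), "unknown/other")
  m <- matrix(0L, 4L, 6L, dimnames = list(subs, cols))
  pat <- stats::setNames(integer(4L), subs)
  sets <- split_sites(patients$site_set)
  for (i in seq_len(nrow(patients))) {
    st <- patients[[sub_col]][[i]]
    if (!st %in% subs) next
    pat[st] <- pat[st] + 1L
    named <- intersect(unique(sets[[i]]), bm_named_sites())
    if (length(named) == 0L) {
      m[st, "unknown/other"] <- m[st, "unknown/other"] + 1L
    } else {
      m[st, named] <- m[st, named] + 1L
    }
  }
  list(lesions = contingency_table(m), patients = pat,
       n_patients = sum(pat))
}

#' Drop labelled columns from a contingency table
#'
#' Removes named columns (e.g. the \code{"unknown/other"} column when
#' simplifying a lesion table before exact testing) and recomputes the
#' margins.
#'
#' @param table A \code{contingency_table} or matrix.
#' @param drop_columns Character vector of column labels to remove; may
#'   be empty (identity).
#' @return The reduced \code{contingency_table}.
#' @export
simplify_table <- function(table, drop_columns = character(0)) {
  bad <- setdiff(drop_columns, colnames(table))
  if (length(bad)) stop("unknown column label: ", paste(bad, collapse = ", "))
  keep <- setdiff(colnames(table), drop_columns)
  if (length(keep) == 0L) stop("cannot drop all columns")
  contingency_table(unclass(table)[, keep, drop = FALSE])
}

#' Restrict a cohort to single-lesion patients at named sites
#'
#' Keeps patients whose site set is exactly one named site (drops
#' multi-site patients and those coded only unknown/other) -- the subset
#' used for the sensitivity re-analysis without overlapping location
#' codes.
#'
#' @param patients Data frame with a \code{site_set} column.
#' @return The filtered data frame.
#' @export
single_site_subset <- function(patients) {
  sets <- lapply(split_sites(patients$site_set), unique)
  keep <- vapply(sets, function(s)
    length(s) == 1L && s %in% bm_named_sites(), logical(1))
  out <- patients[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conditional (row- or column-wise) proportions
#'
#' Normalises each slice of the conditioning axis to sum to 1: condition
#' on \code{"col"} to ask "given the neuroanatomical site, how likely is
#' each subtype?", on \code{"row"} for the per-subtype distribution over
#' sites. Slices with a zero margin are returned as \code{NA}.
#'
#' @param table Contingency table or matrix.
#' @param condition_on \code{"row"} or \code{"col"}.
#' @return Numeric matrix of proportions.
#' @export
conditional_distributions <- function(table, condition_on = c("row", "col")) {
  condition_on <- match.arg(condition_on)
  m <- unclass(as.matrix(table))
  margin <- if (condition_on == "row") 1L else 2L
  p <- prop.table(m, margin)
  p[!is.finite(p)] <- NA_real_
  p
}

#' Biomarker-by-subtype and biomarker-by-site tables
#'
#' For each captured biomarker, tabulates patient counts by refined
#' subtype and -- with lesion semantics, one contribution per distinct
#' named site in the patient's site set -- by neuroanatomical site.
#' Patients coded only unknown/other are excluded from the site tables.
#' PD-L1 rows are negative / low-positive / positive; other markers
#' negative / positive. An "adequate" row (column sums) is what the
#' printed tables call the tested-with-result count.
#'
#' @param patients Lung-cohort data frame with biomarker status columns
#'   (\code{egfr}, \code{ras}, \code{pdl1_bin}, ...), a subtype column
#'   and \code{site_set}.
#' @param markers Which markers to tabulate; default the three analysed
#'   ones.
#' @return List with elements \code{by_subtype} and \code{by_site}, each
#'   a named list of \code{contingency_table}s (markers with no tested
#'   patient are dropped).
#' @export
biomarker_tables <- function(patients,
                             markers = c("egfr", "pdl1", "ras")) {
  sub_col <- if ("subtype_refined" %in% names(patients)) "subtype_refined"
             else "subtype"
  subs <- c("AC", "SCC", "NSCLC-NOS", "SCLC")
  sites <- bm_named_sites()
  sets <- lapply(split_sites(patients$site_set), unique)

  status_of <- function(marker) {
    if (marker == "pdl1") {
      if ("pdl1_bin" %in% names(patients)) patients$pdl1_bin
      else bin_pdl1(patients$pdl1_tps)
    } else if (marker == "alk") {
      ifelse(patients$alk_ihc != "not-done", patients$alk_ihc,
             patients$alk_fish)
    } else patients[[marker]]
  }

  by_subtype <- list(); by_site <- list()
  for (mk in markers) {
    st <- status_of(mk)
    lev <- if (mk == "pdl1") c("negative", "low-positive", "positive")
           else c("negative", "positive")
    done <- st %in% lev
    if (!any(done)) next
    ms <- matrix(0L, length(lev), 4L, dimnames = list(lev, subs))
    ml <- matrix(0L, length(lev), 5L, dimnames = list(lev, sites))
    for (i in which(done)) {
      s <- st[[i]]; ty <- patients[[sub_col]][[i]]
      if (ty %in% subs) ms[s, ty] <- ms[s, ty] + 1L
      named <- intersect(sets[[i]], sites)
      ml[s, named] <- ml[s, named] + 1L
    }
    by_subtype[[mk]] <- contingency_table(ms)
    by_site[[mk]] <- contingency_table(ml)
  }
  list(by_subtype = by_subtype, by_site = by_site)
}
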