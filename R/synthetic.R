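# Synthetic surgical-neuropathology report corpus with ground truth.
#
# The generator emulates the joint statistical structure of a regional
# 10-year brain-biopsy cohort: the diagnostic-category case mix, the lung
# fraction among metastases, the refined-subtype x neuroanatomical-site
# joint distribution of lung metastases, the multi-site overlap rate,
# immunostain availability, and year-banded biomarker availability. Every
# synthetic report is paired with a truth record so the downstream
# classifier, refinement rules and tabulations can be audited exactly.

TABLE2_JOINT <- local({
  m <- rbind(
    "AC"        = c(59, 31, 14, 21, 37, 2),
    "SCC"       = c( 8,  5,  5,  8,  1, 0),
    "SCLC"      = c( 6,  4,  0,  2, 17, 1),
    "NSCLC-NOS" = c(15,  8,  1,  4,  6, 0))
  colnames(m) <- c("frontal", "parietal", "temporal", "occipital",
                   "cerebellum", "unknown/other")
  m / sum(m)
})

#' Configuration of the synthetic report generator
#'
#' Builds and validates the parameter set that defines the simulated
#' cohort. The defaults are the study conditions the package is designed
#' around: a six-category diagnostic mix with a probable-metastasis rate
#' of 0.185 and an unclassifiable rate of 0.015; a lung fraction of
#' 234/511 among metastases with a known single primary; a lung
#' subtype-by-site joint distribution equal to the reference cohort's
#' lesion table proportions; a two-site overlap probability of 36/234 for
#' lung-metastasis patients; immunostain availability of 206/234 (TTF-1),
#' 46/234 (p63) and 5/234 (p40); and biomarker availability keyed to
#' accession-year bands (none before 2014, 69.6\% any-marker testing from
#' 2016 on).
#'
#' @param n_cases Number of reports to generate (positive integer).
#' @param category_mix Named probability vector over the six diagnostic
#'   categories ([bm_categories()]); must sum to 1 within 1e-9.
#' @param primary_site_mix Named probability vector over primary sites for
#'   metastases (includes \code{"unknown"}).
#' @param subtype_site_joint 4 x 6 probability matrix over refined lung
#'   subtype (AC, SCC, SCLC, NSCLC-NOS) by site (five named sites plus
#'   \code{"unknown/other"}); must sum to 1.
#' @param overlap_rate Probability that a lung-metastasis patient carries
#'   two site codes.
#' @param multi_case_rate Fraction of patients receiving a second case
#'   (exercises first-case-per-patient retention).
#' @param ihc_availability Named per-stain probabilities that a stain was
#'   performed (\code{ttf1}, \code{p63}, \code{p40},
#'   \code{neuroendocrine}).
#' @param reclass_rates Fractions of refined AC / SCC lung cases whose
#'   report nonetheless reads generic non-small cell carcinoma and whose
#'   refined label is recovered through the immunostain rules.
#' @param biomarker_config List with \code{any_rate_by_band} (any-marker
#'   testing probability for accession bands 2011-2013, 2014-2015,
#'   2016-2020), \code{adequacy} (per-marker adequate-result probability
#'   given any testing), \code{positivity} (per-marker positive rate given
#'   adequate), \code{pdl1_bin_mix} (negative / low-positive / positive
#'   mix given adequate PD-L1) and \code{alk_fish_extra} (probability an
#'   ALK-tested case also carries a FISH result).
#' @param lexical_noise Noise level in \[0, 1\] scaling three independent
#'   degradation channels: synonym/abbreviation substitution, negated
#'   distractor sentences, and hyphenated dual-site phrasings.
#' @param max_sites Maximum number of site codes per patient (default 2;
#'   see the methods vignette for why the overlap-matrix arithmetic
#'   identity requires 2).
#' @param seed Integer seed; a fixed seed yields a byte-identical corpus.
#' @return A validated list of class \code{bm_generator_config}.
#' @examples
#' cfg <- generator_config(n_cases = 50, seed = 1)
#' @export
generator_config <- function(n_cases = 1000,
                             category_mix = NULL,
                             primary_site_mix = NULL,
                             subtype_site_joint = TABLE2_JOINT,
                             overlap_rate = 36 / 234,
                             multi_case_rate = 27 / 511,
                             ihc_availability = c(ttf1 = 206 / 234,
                                                  p63 = 46 / 234,
                                                  p40 = 5 / 234,
                                                  neuroendocrine = 25 / 28),
                             reclass_rates = c(ac = 37 / 152, scc = 4 / 23),
                             biomarker_config = NULL,
                             lexical_noise = 0,
                             max_sites = 2,
                             seed = 1L) {
  if (is.null(category_mix))
    category_mix <- c("unclassified" = 0.015,
                      "brain cardiovascular disease" = 0.100,
                      "miscellaneous lesions" = 0.100,
                      "other brain lesions" = 0.200,
                      "probable metastasis" = 0.185,
                      "primary brain tumour" = 0.400)
  if (is.null(primary_site_mix)) {
    primary_site_mix <- c(lung = 234 / 511, breast = 0.16, melanoma = 0.12,
                          colorectal = 0.10, kidney = 0.08)
    primary_site_mix <- c(primary_site_mix,
                          unknown = 1 - sum(primary_site_mix))
  }
  if (is.null(biomarker_config))
    biomarker_config <- list(
      any_rate_by_band = c("2011-2013" = 0, "2014-2015" = 0.064,
                           "2016-2020" = 0.696),
      adequacy = c(egfr = 65 / 90, alk = 78 / 90, pdl1 = 79 / 90,
                   ras = 51 / 90, braf_v600 = 51 / 90, ros1 = 0.45),
      positivity = c(egfr = 8 / 65, alk = 1 / 78, ras = 23 / 51,
                     braf_v600 = 1 / 51, ros1 = 0.02),
      pdl1_bin_mix = c(negative = 27 / 79, "low-positive" = 15 / 79,
                       positive = 37 / 79),
      alk_fish_extra = 0.3)

  cfg <- list(n_cases = n_cases, category_mix = category_mix,
              primary_site_mix = primary_site_mix,
              subtype_site_joint = subtype_site_joint,
              overlap_rate = overlap_rate,
              multi_case_rate = multi_case_rate,
              ihc_availability = ihc_availability,
              reclass_rates = reclass_rates,
              biomarker_config = biomarker_config,
              lexical_noise = lexical_noise,
              max_sites = max_sites, seed = as.integer(seed))
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_cases) || length(cfg$n_cases) != 1L ||
      is.na(cfg$n_cases) || cfg$n_cases < 1)
    stop("configuration error in field 'n_cases': must be >= 1")
  cfg$n_cases <- as.integer(cfg$n_cases)
  check_prob <- function(p, field) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("configuration error in field '", field,
           "': probabilities must be non-negative and sum to 1")
  }
  if (!setequal(names(cfg$category_mix), bm_categories()))
    stop("configuration error in field 'category_mix': names must be the ",
         "six diagnostic categories")
  check_prob(cfg$category_mix, "category_mix")
  check_prob(cfg$primary_site_mix, "primary_site_mix")
  if (!is.matrix(cfg$subtype_site_joint) ||
      !all(dim(cfg$subtype_site_joint) == c(4L, 6L)))
    stop("configuration error in field 'subtype_site_joint': need 4 x 6 matrix")
  check_prob(c(cfg$subtype_site_joint), "subtype_site_joint")
  for (f in c("overlap_rate", "multi_case_rate", "lexical_noise")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("configuration error in field '", f, "': must lie in [0, 1]")
  }
  if (any(cfg$ihc_availability < 0 | cfg$ihc_availability > 1))
    stop("configuration error in field 'ihc_availability'")
  if (!cfg$max_sites %in% c(2L, 3L) && cfg$max_sites != 2 && cfg$max_sites != 3)
    stop("configuration error in field 'max_sites': must be 2 or 3")
  class(cfg) <- "bm_generator_config"
  cfg
}

# conditional stain-availability so that the corpus-wide availability
# matches the configured target despite reclassified cases forcing a
# stain to be present (see methods vignette).
stain_conditionals <- function(cfg) {
  p_sub <- rowSums(cfg$subtype_site_joint)
  ra <- cfg$reclass_rates[["ac"]]; rs <- cfg$reclass_rates[["scc"]]
  forced_t <- p_sub[["AC"]] * ra + p_sub[["SCC"]] * rs
  forced_p <- p_sub[["SCC"]] * rs
  clamp <- function(x) min(max(x, 0), 1)
  c(ttf1 = clamp((cfg$ihc_availability[["ttf1"]] - forced_t) / (1 - forced_t)),
    p63 = clamp((cfg$ihc_availability[["p63"]] - forced_p) / (1 - forced_p)))
}

year_band <- function(year) {
  ifelse(year <= 2013, "2011-2013",
         ifelse(year <= 2015, "2014-2015", "2016-2020"))
}

# generic site mix for specimens outside the lung-metastasis cohort
BACKGROUND_SITE_MIX <- c(frontal = 0.33, parietal = 0.19, temporal = 0.09,
                         occipital = 0.12, cerebellum = 0.22, other = 0.04,
                         unknown = 0.01)

sample1 <- function(x, prob = NULL) {
  x[sample.int(length(x), 1L, prob = prob)]
}

# --- single-case truth draw ------------------------------------------------

draw_truth_case <- function(cfg, cond) {
  category <- sample1(names(cfg$category_mix), prob = cfg$category_mix)
  primary <- "not-applicable"
  sub_rep <- "not-applicable"; sub_ref <- "not-applicable"
  ihc <- c(ttf1 = "not-done", p63 = "not-done", p40 = "not-done",
           neuroendocrine = "not-done")
  bio <- stats::setNames(rep("not-done", 7L),
                         c("egfr", "alk_ihc", "alk_fish", "ras",
                           "braf_v600", "ros1", "pdl1"))
  tps <- NA_real_

  if (category == "unclassified") {
    sites <- "unknown"
  } else if (category != "probable metastasis") {
    sites <- sample1(names(BACKGROUND_SITE_MIX), prob = BACKGROUND_SITE_MIX)
  } else {
    primary <- sample1(names(cfg$primary_site_mix),
                       prob = cfg$primary_site_mix)
    if (primary != "lung") {
      sites <- sample1(names(BACKGROUND_SITE_MIX), prob = BACKGROUND_SITE_MIX)
      if (primary != "melanoma") sub_rep <- "not-applicable"
    } else {
      # refined subtype x site cell from the configured joint
      J <- cfg$subtype_site_joint
      cell <- sample.int(length(J), 1L, prob = c(J))
      sub_ref <- rownames(J)[(cell - 1L) %% 4L + 1L]
      col <- colnames(J)[(cell - 1L) %/% 4L + 1L]
      s1 <- if (col == "unknown/other") {
        if (stats::runif(1) < 1 / 3) "unknown" else "other"
      } else col
      sites <- s1
      if (s1 != "unknown" && stats::runif(1) < cfg$overlap_rate) {
        row <- J[sub_ref, ]
        extra <- if (cfg$max_sites >= 3L && stats::runif(1) < 0.15) 2L else 1L
        pool <- setdiff(names(row), c(s1, "unknown/other"))
        w <- row[pool] + 1e-9
        sites <- c(s1, sample(pool, min(extra, length(pool)), prob = w))
        if (s1 == "other") sites <- unique(c("other", sites))
      }
      # reported subtype and immunostains consistent with the refinement
      ra <- cfg$reclass_rates[["ac"]]; rs <- cfg$reclass_rates[["scc"]]
      av <- cfg$ihc_availability
      if (sub_ref == "AC" && stats::runif(1) < ra) {
        sub_rep <- "NSCLC-NOS"
        ihc[["ttf1"]] <- "positive"
        ihc[["p63"]] <- if (stats::runif(1) < cond[["p63"]])
          "negative" else "not-done"
      } else if (sub_ref == "SCC" && stats::runif(1) < rs) {
        sub_rep <- "NSCLC-NOS"
        ihc[["ttf1"]] <- "negative"
        ihc[["p63"]] <- "positive"
      } else {
        sub_rep <- sub_ref
        if (stats::runif(1) < cond[["ttf1"]])
          ihc[["ttf1"]] <- switch(sub_rep,
            "AC" = if (stats::runif(1) < 0.88) "positive" else "negative",
            "SCC" = if (stats::runif(1) < 0.90) "negative" else "positive",
            "SCLC" = if (stats::runif(1) < 0.85) "positive" else "negative",
            "NSCLC-NOS" = "negative")
        if (stats::runif(1) < cond[["p63"]])
          ihc[["p63"]] <- switch(sub_rep,
            "AC" = "negative",
            "SCC" = "positive",
            "SCLC" = "negative",
            "NSCLC-NOS" = "negative")
      }
      if (stats::runif(1) < av[["p40"]])
        ihc[["p40"]] <- if (sub_ref == "SCC") "positive" else "negative"
      if (sub_rep == "SCLC" && stats::runif(1) < av[["neuroendocrine"]])
        ihc[["neuroendocrine"]] <- "positive"
    }
  }
  list(category = category, primary = primary, sub_rep = sub_rep,
       sub_ref = sub_ref, sites = sites, ihc = ihc, bio = bio, tps = tps)
}

draw_biomarkers <- function(cfg, year) {
  bc <- cfg$biomarker_config
  bio <- stats::setNames(rep("not-done", 7L),
                         c("egfr", "alk_ihc", "alk_fish", "ras",
                           "braf_v600", "ros1", "pdl1"))
  tps <- NA_real_
  if (stats::runif(1) < bc$any_rate_by_band[[year_band(year)]]) {
    for (m in c("egfr", "ras", "braf_v600", "ros1"))
      if (stats::runif(1) < bc$adequacy[[m]])
        bio[[m]] <- if (stats::runif(1) < bc$positivity[[m]])
          "positive" else "negative"
    if (stats::runif(1) < bc$adequacy[["alk"]]) {
      st <- if (stats::runif(1) < bc$positivity[["alk"]])
        "positive" else "negative"
      bio[["alk_ihc"]] <- st
      if (stats::runif(1) < bc$alk_fish_extra) bio[["alk_fish"]] <- st
    }
    if (stats::runif(1) < bc$adequacy[["pdl1"]]) {
      bin <- sample1(names(bc$pdl1_bin_mix), prob = bc$pdl1_bin_mix)
      tps <- switch(bin,
        negative = 0,
        "low-positive" = sample(1:49, 1L),
        positive = sample(50:100, 1L))
      bio[["pdl1"]] <- if (bin == "negative") "negative" else "positive"
    }
  }
  list(bio = bio, tps = tps)
}

#' Generate a synthetic report corpus with ground truth
#'
#' Draws \code{n_cases} cases from the configured cohort model, renders
#' each as free report text with [render_report()], and returns the
#' reports together with one truth record per case. A configurable
#' fraction of patients receives a second, later case so that
#' first-case-per-patient retention is exercised. The refined subtype in
#' each truth record is, by construction, exactly what
#' [refine_subtype()] yields from the truth immunostains, and at zero
#' lexical noise the rendered text contains exactly the canonical keyword
#' for every true label.
#'
#' @param config A [generator_config()].
#' @param lexicon Match lexicon used for canonical phrases.
#' @return A list with data frames \code{reports} (\code{case_id},
#'   \code{patient_id}, \code{accession_year}, \code{report_text}) and
#'   \code{truth} (\code{true_*} label columns, immunostain tri-states,
#'   biomarker statuses and PD-L1 TPS).
#' @examples
#' cc <- generate_corpus(generator_config(n_cases = 20, seed = 7))
#' cc$reports$report_text[1]
#' @export
generate_corpus <- function(config, lexicon = default_lexicon()) {
  config <- validate_generator_config(unclass(config))
  set.seed(config$seed)
  cond <- stain_conditionals(config)
  n <- config$n_cases

  truth_rows <- vector("list", n)
  report_rows <- vector("list", n)
  i <- 1L; pidx <- 0L
  while (i <= n) {
    pidx <- pidx + 1L
    year <- sample(2011:2020, 1L)
    tr <- draw_truth_case(config, cond)
    if (tr$primary == "lung") {
      bm <- draw_biomarkers(config, year)
      tr$bio <- bm$bio; tr$tps <- bm$tps
    }
    ncase <- if (stats::runif(1) < config$multi_case_rate && i < n) 2L else 1L
    for (k in seq_len(ncase)) {
      if (k == 2L) {
        year <- min(year + sample(0:2, 1L), 2020L)
        # second specimen: same tumour; site concordant three times in four
        if (stats::runif(1) > 0.75 && tr$primary == "lung" &&
            !identical(tr$sites, "unknown")) {
          row <- config$subtype_site_joint[tr$sub_ref, ]
          pool <- setdiff(names(row), "unknown/other")
          tr$sites <- sample1(pool, prob = row[pool] + 1e-9)
        }
      }
      truth_rows[[i]] <- data.frame(
        case_id = sprintf("C%05d", i),
        patient_id = sprintf("P%05d", pidx),
        accession_year = year,
        true_category = tr$category,
        true_primary_site = tr$primary,
        true_subtype_reported = tr$sub_rep,
        true_subtype_refined = tr$sub_ref,
        true_site_set = paste(tr$sites, collapse = "|"),
        ttf1 = tr$ihc[["ttf1"]], p63 = tr$ihc[["p63"]],
        p40 = tr$ihc[["p40"]],
        neuroendocrine = tr$ihc[["neuroendocrine"]],
        egfr = tr$bio[["egfr"]], alk_ihc = tr$bio[["alk_ihc"]],
        alk_fish = tr$bio[["alk_fish"]], ras = tr$bio[["ras"]],
        braf_v600 = tr$bio[["braf_v600"]], ros1 = tr$bio[["ros1"]],
        pdl1_tps = tr$tps,
        pdl1_bin = bin_pdl1(tr$tps),
        stringsAsFactors = FALSE)
      report_rows[[i]] <- data.frame(
        case_id = sprintf("C%05d", i),
        patient_id = sprintf("P%05d", pidx),
        accession_year = year,
        report_text = render_report(truth_rows[[i]], lexicon,
                                    noise = config$lexical_noise),
        stringsAsFactors = FALSE)
      i <- i + 1L
      if (i > n) break
    }
  }
  truth <- do.call(rbind, truth_rows)
  reports <- do.call(rbind, report_rows)
  rownames(truth) <- rownames(reports) <- NULL
  list(reports = reports, truth = truth)
}

# --- report rendering ------------------------------------------------------

SITE_PHRASES <- c(frontal = "frontal lobe", parietal = "parietal lobe",
                  temporal = "temporal lobe", occipital = "occipital lobe",
                  cerebellum = "cerebellar hemisphere",
                  other = "brainstem", unknown = "brain, site not specified")

HYPHEN_FORMS <- list(
  c("frontal", "parietal", "fronto-parietal region"),
  c("frontal", "temporal", "fronto-temporal region"),
  c("frontal", "occipital", "fronto-occipital region"),
  c("temporal", "parietal", "temporo-parietal region"),
  c("parietal", "occipital", "parieto-occipital region"),
  c("temporal", "occipital", "temporo-occipital region"))

SUBTYPE_PHRASES <- c("AC" = "adenocarcinoma",
                     "SCC" = "squamous cell carcinoma",
                     "SCLC" = "small cell carcinoma",
                     "NSCLC-NOS" = "non-small cell carcinoma")

CATEGORY_PHRASES <- list(
  "primary brain tumour" = c("Glioblastoma, IDH-wildtype.",
                             "Meningioma, WHO grade 1.",
                             "Schwannoma."),
  "brain cardiovascular disease" = c("Organizing hematoma.",
                                     "Subacute infarct.",
                                     "Arteriovenous malformation."),
  "other brain lesions" = c("Brain abscess with acute inflammation.",
                            "Demyelinating disease, active plaque.",
                            "Radiation necrosis."),
  "miscellaneous lesions" = c("Arachnoid cyst.", "Epidermoid cyst.",
                              "Lipoma."),
  "unclassified" = c("Minute fragments of tissue, see comment.",
                     "Scant material, descriptive diagnosis only."))

DISTRACTORS <- c("No evidence of meningioma.",
                 "Negative for small cell carcinoma.",
                 "Without evidence of involvement by lymphoma.")

PRIMARY_PHRASES <- c(lung = "lung", breast = "breast",
                     colorectal = "colorectal", kidney = "renal")

#' Render a truth record as free report text
#'
#' Produces the report text the classifier consumes. At noise 0 the text
#' contains exactly the canonical keyword for each true label: one site
#' phrase per site code, a diagnosis sentence, one sentence per performed
#' immunostain ("TTF-1: positive."), and a biomarker section. At positive
#' noise three degradation channels may fire, each with probability
#' proportional to the noise level: synonym/abbreviation substitution
#' (including forms the lexicon does not know), negated distractor
#' sentences, and hyphenated dual-site phrasings such as
#' "temporo-parietal".
#'
#' Draws come from the R random number stream, so rendering is
#' deterministic given the RNG state.
#'
#' @param truth One truth record (single-row data frame or list) as
#'   produced by [generate_corpus()].
#' @param lexicon Match lexicon (canonical keywords).
#' @param noise Noise level in \[0, 1\].
#' @return A single string.
#' @export
render_report <- function(truth, lexicon = default_lexicon(), noise = 0) {
  stopifnot(noise >= 0, noise <= 1)
  sites <- strsplit(truth$true_site_set, "|", fixed = TRUE)[[1L]]
  category <- truth$true_category

  # --- site header ---
  hyph <- NULL
  if (length(sites) == 2L && noise > 0 && stats::runif(1) < noise) {
    for (h in HYPHEN_FORMS)
      if (setequal(sites, h[1:2])) { hyph <- h[3]; break }
  }
  header <- if (!is.null(hyph)) {
    paste0("Brain, ", hyph, ", resection.")
  } else if (identical(sites, "unknown")) {
    "Brain, site not specified, resection."
  } else {
    paste0("Brain, ", paste(SITE_PHRASES[sites], collapse = " and "),
           ", resection.")
  }

  # --- diagnosis sentence ---
  dx <- if (category == "probable metastasis") {
    pr <- truth$true_primary_site
    if (pr == "melanoma") {
      "Metastatic melanoma."
    } else if (pr == "unknown") {
      "Metastatic carcinoma, primary site not determined."
    } else if (pr == "lung") {
      phrase <- SUBTYPE_PHRASES[[truth$true_subtype_reported]]
      organ <- "lung"
      if (noise > 0 && stats::runif(1) < 0.5 * noise) organ <- "pulmonary"
      if (noise > 0 && stats::runif(1) < 0.3 * noise &&
          truth$true_subtype_reported == "AC") phrase <- "adenoca"
      if (noise > 0 && stats::runif(1) < 0.2 * noise) {
        paste0("Metastatic ", phrase, ".")
      } else {
        paste0("Metastatic ", phrase, ", consistent with ", organ,
               " primary.")
      }
    } else {
      paste0("Metastatic carcinoma, consistent with ",
             PRIMARY_PHRASES[[pr]], " primary.")
    }
  } else {
    sample1(CATEGORY_PHRASES[[category]])
  }

  # --- immunostains ---
  ihc <- character(0)
  stain_label <- c(ttf1 = "TTF-1", p63 = "p63", p40 = "p40")
  for (s in names(stain_label))
    if (truth[[s]] != "not-done")
      ihc <- c(ihc, paste0(stain_label[[s]], ": ", truth[[s]], "."))
  if (truth$neuroendocrine != "not-done")
    ihc <- c(ihc, paste0("Synaptophysin: ", truth$neuroendocrine, "."))

  # --- biomarker section ---
  bio <- character(0)
  bio_label <- c(egfr = "EGFR mutation", alk_ihc = "ALK IHC",
                 alk_fish = "ALK FISH", ras = "KRAS",
                 braf_v600 = "BRAF V600", ros1 = "ROS-1")
  for (b in names(bio_label))
    if (truth[[b]] != "not-done")
      bio <- c(bio, paste0(bio_label[[b]], ": ", truth[[b]], "."))
  if (!is.na(truth$pdl1_tps))
    bio <- c(bio, paste0("PD-L1 TPS ", truth$pdl1_tps, "%."))

  extra <- character(0)
  if (noise > 0 && stats::runif(1) < noise)
    extra <- sample1(DISTRACTORS)

  paste(c(header, dx, ihc, bio, extra), collapse = " ")
}

# --- corpus I/O ------------------------------------------------------------

#' Read and write corpus / truth tables
#'
#' The corpus interchange format is plain tab-separated text with one row
#' per case: \code{case_id}, \code{patient_id}, \code{accession_year},
#' \code{report_text} (reports contain no tabs or newlines); the truth
#' table is a parallel TSV. Generator configurations round-trip through
#' YAML.
#'
#' @param x Data frame (corpus or truth) or a generator configuration.
#' @param path File path.
#' @name corpus_io
#' @export
write_corpus <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_corpus <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
}

#' @rdname corpus_io
#' @export
write_generator_config <- function(x, path) {
  y <- unclass(x)
  y$subtype_site_joint <- list(
    rows = rownames(x$subtype_site_joint),
    cols = colnames(x$subtype_site_joint),
    values = as.vector(x$subtype_site_joint))
  # named atomic vectors must become maps, or YAML drops the names
  for (f in c("category_mix", "primary_site_mix", "ihc_availability",
              "reclass_rates"))
    y[[f]] <- as.list(y[[f]])
  y$biomarker_config <- lapply(y$biomarker_config, function(v)
    if (is.numeric(v) && length(v) > 1L) as.list(v) else v)
  yaml::write_yaml(y, path, precision = 17L)  # doubles round-trip exactly
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  j <- y$subtype_site_joint
  m <- matrix(unlist(j$values), nrow = length(j$rows),
              dimnames = list(unlist(j$rows), unlist(j$cols)))
  y$subtype_site_joint <- m
  for (f in c("category_mix", "primary_site_mix", "ihc_availability",
              "reclass_rates"))
    y[[f]] <- unlist(y[[f]])
  bc <- y$biomarker_config
  for (f in c("any_rate_by_band", "adequacy", "positivity", "pdl1_bin_mix"))
    bc[[f]] <- unlist(bc[[f]])
  y$biomarker_config <- bc
  validate_generator_config(y)
}
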