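# End-to-end orchestration: generate -> classify -> refine -> first-case
# -> lung cohort -> tabulate -> exact tests -> heatmap inputs, with a
# reproducible manifest. Also a fixture-driven mode that computes all
# headline statistics directly from the bundled reference tables.

#' Run the full synthetic-cohort pipeline
#'
#' Generates a synthetic corpus, classifies it, refines subtypes with the
#' immunostain rules, retains the first case per patient, restricts to
#' probable lung metastases with a single primary, builds the overlap
#' matrix and the subtype-by-site / biomarker tables, and runs the exact
#' tests on the simplified lesion table. All tabular outputs are written
#' as plain text (TSV/CSV), statistics and the manifest as JSON; a rerun
#' with the same configuration reproduces every output byte-identically.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed); \code{NULL} to
#'   return results without writing.
#' @param lexicon Match lexicon.
#' @param stats_method \code{"auto"} (enumerate when feasible, otherwise
#'   Monte-Carlo), \code{"exact"} or \code{"mc"}.
#' @param stats_reps,stats_seed Monte-Carlo replicates and seed.
#' @param alpha Significance level recorded in the manifest.
#' @return Invisibly, a list with the per-stage objects
#'   (\code{corpus}, \code{labels}, \code{cohort}, \code{tables},
#'   \code{stats}) and the run \code{manifest} (per-stage record counts,
#'   seeds, configuration hash).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         lexicon = default_lexicon(),
                         stats_method = c("auto", "exact", "mc"),
                         stats_reps = 1e5, stats_seed = 1L,
                         alpha = 0.05) {
  stats_method <- match.arg(stats_method)
  corpus <- generate_corpus(config, lexicon)
  labels <- classify_corpus(corpus$reports, lexicon)

  patients <- first_case_per_patient(labels)
  mets <- patients[patients$category == "probable metastasis", ,
                   drop = FALSE]
  confirmed <- mets[!mets$primary_site %in% "multiple/ambiguous", ,
                    drop = FALSE]
  lung <- confirmed[confirmed$primary_site == "lung", , drop = FALSE]

  tables <- NULL; stats <- NULL; skip_reason <- NULL
  if (nrow(lung) > 0L) {
    sbs <- site_by_subtype(lung)
    simplified <- simplify_table(sbs$lesions, "unknown/other")
    tables <- list(
      overlap = overlap_matrix(lung),
      lesions = sbs$lesions,
      patients_by_subtype = sbs$patients,
      simplified = simplified,
      by_site_given_subtype = conditional_distributions(sbs$lesions, "row"),
      by_subtype_given_site = conditional_distributions(sbs$lesions, "col"),
      biomarkers = biomarker_tables(lung))
    live <- simplified[rowSums(simplified) > 0L,
                       colSums(simplified) > 0L, drop = FALSE]
    if (nrow(live) >= 2L && ncol(live) >= 2L) {
      global <- switch(stats_method,
        exact = fisher_rxc_exact(simplified),
        mc = fisher_rxc_mc(simplified, reps = stats_reps,
                           seed = stats_seed),
        auto = tryCatch(fisher_rxc_exact(simplified),
                        error = function(e)
                          fisher_rxc_mc(simplified, reps = stats_reps,
                                        seed = stats_seed)))
      pmat <- all_pairs_2x2(simplified)
      stats <- list(global_subtype_site = global,
                    pairwise_p = pmat,
                    pairwise_bins = matrix(as.character(bin_pvalue(pmat)),
                                           nrow(pmat),
                                           dimnames = dimnames(pmat)),
                    heatmap_order = heatmap_order(pmat))
    } else {
      skip_reason <- "simplified lesion table degenerate; stats skipped"
    }
  } else {
    skip_reason <- "no lung metastases in cohort; tables empty, stats skipped"
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bmetlung")),
    seed = config$seed,
    stats = list(method = stats_method, reps = stats_reps,
                 seed = stats_seed, alpha = alpha),
    config_hash = config_hash(config),
    counts = list(corpus = nrow(corpus$reports),
                  patients = nrow(patients),
                  probable_metastasis = nrow(mets),
                  confirmed_single_primary = nrow(confirmed),
                  lung = nrow(lung)),
    skipped = skip_reason)

  result <- list(corpus = corpus, labels = labels, cohort = lung,
                 tables = tables, stats = stats, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_generator_config(config, f)
  unname(tools::md5sum(f))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_corpus(result$corpus$reports, p("corpus.tsv"))
  write_corpus(result$corpus$truth, p("truth.tsv"))
  write_corpus(result$labels, p("labels.tsv"))
  if (!is.null(result$tables)) {
    wm <- function(m, f) utils::write.csv(as.data.frame(unclass(m)[,]),
                                          p(f), row.names = TRUE)
    wm(result$tables$overlap, "overlap_matrix.csv")
    wm(result$tables$lesions, "subtype_site_lesions.csv")
    wm(result$tables$simplified, "subtype_site_simplified.csv")
    sidecar <- list(
      lesions_margins = table_margins(result$tables$lesions),
      simplified_margins = table_margins(result$tables$simplified),
      patients_by_subtype = as.list(result$tables$patients_by_subtype),
      config_hash = result$manifest$config_hash,
      seed = result$manifest$seed)
    jsonlite::write_json(sidecar, p("tables_margins.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(result$stats)) {
    g <- result$stats$global_subtype_site
    jsonlite::write_json(
      list(global_subtype_site = unclass(g),
           n_pairwise = length(result$stats$pairwise_p)),
      p("stats.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(result$stats$pairwise_p),
                     p("pairwise_p.csv"), row.names = TRUE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Headline statistics from the bundled reference tables
#'
#' Fixture-driven analysis mode: recomputes every statistic derivable
#' from the bundled reference cohort tabulations, without touching the
#' synthetic generator. This separates validation of the inference
#' engine from validation of the text pipeline.
#'
#' Computed quantities: the overlap-matrix summary (Pure row and Mixed
#' count recovered from the printed matrix); the simplified 4 x 5 lesion
#' table (252 lesions in 20 cells) and its Freeman-Halton p-value by
#' fixed-margin Monte-Carlo; the all-pairs 2x2 decomposition (60
#' p-values) with colour bins and clustering order; the exact 3 x 5
#' PD-L1-by-site test; the PD-L1 negative-vs-positive 2x2 site
#' contrasts; and the biomarker-by-subtype tests with small cell
#' carcinoma excluded.
#'
#' @param mc_reps Monte-Carlo replicates for the 4 x 5 lesion table
#'   (too many margin-compatible tables for enumeration).
#' @param seed Seed for the Monte-Carlo sampler.
#' @return A list of results; see Details.
#' @export
run_reference_stats <- function(mc_reps = 1e6, seed = 1L) {
  ref <- reference_cohort()
  simplified <- simplify_table(ref$lesions, "unknown/other")

  global <- fisher_rxc_mc(simplified, reps = mc_reps, seed = seed)
  pmat <- all_pairs_2x2(simplified)

  pdl1_site <- ref$biomarker_site$pdl1
  pdl1_p <- fisher_rxc_exact(pdl1_site)

  # every negative-vs-positive 2x2 site contrast for PD-L1
  np <- pdl1_site[c("negative", "positive"), , drop = FALSE]
  contrasts <- all_pairs_2x2(np)

  drop_sclc <- function(tab) simplify_table(tab, "SCLC")
  subtype_tests <- lapply(ref$biomarker_subtype, function(tab)
    fisher_rxc_exact(drop_sclc(tab)))

  list(overlap_summary = overlap_summary(ref$overlap),
       simplified = simplified,
       global_subtype_site = global,
       pairwise_p = pmat,
       pairwise_bins = bin_pvalue(pmat),
       heatmap_order = heatmap_order(pmat),
       pdl1_site = pdl1_p,
       pdl1_site_contrasts = contrasts,
       biomarker_subtype_tests = subtype_tests)
}
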