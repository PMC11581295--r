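test_that("invalid generator configurations are rejected by field name", {
  expect_error(generator_config(n_cases = 0), "n_cases")
  bad_mix <- c("unclassified" = 0.5, "brain cardiovascular disease" = 0.2,
               "miscellaneous lesions" = 0.2, "other brain lesions" = 0.2,
               "probable metastasis" = 0.2, "primary brain tumour" = 0.2)
  expect_error(generator_config(n_cases = 10, category_mix = bad_mix),
               "category_mix")
  expect_error(generator_config(n_cases = 10, overlap_rate = 1.5),
               "overlap_rate")
  expect_error(generator_config(n_cases = 10,
                                subtype_site_joint = diag(4)),
               "subtype_site_joint")
})

test_that("a fixed seed yields a byte-identical corpus", {
  cfg <- generator_config(n_cases = 60, seed = 11)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  # and the serialised TSV is byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_corpus(c1$reports, f1); write_corpus(c2$reports, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("corpus size and truth pairing honour the configuration", {
  cfg <- generator_config(n_cases = 150, seed = 3, multi_case_rate = 0.2)
  cc <- generate_corpus(cfg)
  expect_equal(nrow(cc$reports), 150)
  expect_equal(nrow(cc$truth), 150)
  expect_identical(cc$reports$case_id, cc$truth$case_id)
  # a configurable fraction of patients carries more than one case
  expect_gt(sum(table(cc$truth$patient_id) > 1), 0)
  # site sets are never empty, unknown never joins a named site
  sets <- strsplit(cc$truth$true_site_set, "|", fixed = TRUE)
  expect_true(all(lengths(sets) >= 1))
  multi <- sets[lengths(sets) > 1]
  expect_false(any(vapply(multi, function(s) "unknown" %in% s, logical(1))))
})

test_that("refined truth subtype equals the refinement rules applied to truth stains", {
  cc <- generate_corpus(generator_config(n_cases = 500, seed = 5))
  tr <- cc$truth[cc$truth$true_primary_site == "lung", ]
  expect_gt(nrow(tr), 20)
  expect_identical(refine_subtype(tr$true_subtype_reported, tr$ttf1, tr$p63),
                   tr$true_subtype_refined)
})

test_that("generator marginals converge to configured values", {
  cfg <- generator_config(n_cases = 10000, seed = 1)
  cc <- generate_corpus(cfg)
  tr <- cc$truth
  se3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)

  # diagnostic category mix over all cases
  for (cat_ in names(cfg$category_mix)) {
    p0 <- cfg$category_mix[[cat_]]
    expect_lt(abs(mean(tr$true_category == cat_) - p0),
              se3(p0, nrow(tr)) + 1e-12)
  }
  # lung fraction among metastases
  mets <- tr[tr$true_category == "probable metastasis", ]
  p_lung <- cfg$primary_site_mix[["lung"]]
  expect_lt(abs(mean(mets$true_primary_site == "lung") - p_lung),
            se3(p_lung, nrow(mets)))
  # two-site overlap rate among lung patients
  lung <- mets[mets$true_primary_site == "lung", ]
  p_ov <- cfg$overlap_rate
  obs_ov <- mean(grepl("|", lung$true_site_set, fixed = TRUE))
  expect_lt(abs(obs_ov - p_ov), se3(p_ov, nrow(lung)))
  # refined subtype marginals against the joint's row sums
  p_sub <- rowSums(cfg$subtype_site_joint)
  for (s in names(p_sub))
    expect_lt(abs(mean(lung$true_subtype_refined == s) - p_sub[[s]]),
              se3(p_sub[[s]], nrow(lung)))
})

test_that("rendering is canonical at zero noise and may hyphenate at noise", {
  lex <- default_lexicon()
  tr <- data.frame(true_category = "probable metastasis",
                   true_primary_site = "lung",
                   true_subtype_reported = "SCLC",
                   true_subtype_refined = "SCLC",
                   true_site_set = "cerebellum",
                   ttf1 = "not-done", p63 = "not-done", p40 = "not-done",
                   neuroendocrine = "positive",
                   egfr = "not-done", alk_ihc = "not-done",
                   alk_fish = "not-done", ras = "not-done",
                   braf_v600 = "not-done", ros1 = "not-done",
                   pdl1_tps = NA_real_, pdl1_bin = "not-done")
  set.seed(1)
  txt <- render_report(tr, lex, noise = 0)
  expect_match(txt, "small cell carcinoma")
  expect_match(txt, "cerebell")
  expect_no_match(txt, "non-small cell")

  # same RNG state implies same text
  set.seed(42); a <- render_report(tr, lex, noise = 0.8)
  set.seed(42); b <- render_report(tr, lex, noise = 0.8)
  expect_identical(a, b)

  tr$true_site_set <- "temporal|parietal"
  hyph <- FALSE
  set.seed(2)
  for (i in 1:50) {
    t2 <- render_report(tr, lex, noise = 1)
    if (grepl("temporo-parietal", t2)) hyph <- TRUE
  }
  expect_true(hyph)
})

test_that("biomarker availability follows the accession-year bands", {
  cc <- generate_corpus(generator_config(n_cases = 6000, seed = 9))
  tr <- cc$truth
  lung <- tr[tr$true_primary_site == "lung", ]
  markers <- c("egfr", "alk_ihc", "ras", "braf_v600", "ros1", "pdl1_bin")
  any_tested <- rowSums(lung[, markers] != "not-done") > 0
  expect_equal(sum(any_tested & lung$accession_year <= 2013), 0)
  late <- lung$accession_year >= 2016
  expect_gt(mean(any_tested[late]), 0.55)
  expect_lt(mean(any_tested[late]), 0.85)
})

test_that("generator configuration round-trips through YAML", {
  cfg <- generator_config(n_cases = 25, seed = 4, lexical_noise = 0.3)
  f <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, f)
  cfg2 <- read_generator_config(f)
  unlink(f)
  expect_equal(cfg2$n_cases, cfg$n_cases)
  expect_equal(cfg2$category_mix, cfg$category_mix)
  expect_equal(cfg2$subtype_site_joint, cfg$subtype_site_joint,
               tolerance = 1e-12)
  expect_identical(generate_corpus(cfg2), generate_corpus(cfg))
})
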