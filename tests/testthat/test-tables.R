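test_that("first-case retention keeps the earliest case per patient", {
  cases <- data.frame(
    case_id = c("C2", "C1", "C3", "C4", "C5"),
    patient_id = c("P1", "P1", "P2", "P3", "P3"),
    accession_year = c(2015, 2013, 2016, 2018, 2018))
  out <- first_case_per_patient(cases)
  expect_equal(nrow(out), 3)
  expect_setequal(out$case_id, c("C1", "C3", "C4"))  # year, then case id
  # identity on single-case cohorts
  single <- cases[c(2, 3, 4), ]
  expect_equal(first_case_per_patient(single)$case_id, single$case_id)
  expect_error(first_case_per_patient(cases[, -3]), "accession_year")
})

test_that("overlap matrix counts pure and mixed patients by hand", {
  om <- overlap_matrix(list("frontal", "frontal", c("frontal", "parietal")))
  expect_equal(om["frontal", "frontal"], 3L)
  expect_equal(om["parietal", "parietal"], 1L)
  expect_equal(om["frontal", "parietal"], 1L)
  s <- overlap_summary(om)
  expect_equal(s$pure[s$site == "frontal"], 2L)
  expect_equal(s$pure[s$site == "parietal"], 0L)
  expect_equal(attr(s, "mixed"), 1L)
  expect_identical(unclass(om)[,], t(unclass(om)[,]))
  expect_error(overlap_matrix(list(character(0))), "non-empty")
})

test_that("pure and mixed rows are recoverable from a printed overlap matrix", {
  ref <- reference_cohort()
  s <- overlap_summary(ref$overlap)
  expect_equal(s$diagonal, c(88, 48, 20, 35, 61, 17, 1))
  expect_equal(s$off_diagonal, c(9, 17, 6, 13, 12, 15, 0))
  expect_equal(s$pure, c(79, 31, 14, 22, 49, 2, 1))
  expect_equal(attr(s, "mixed"), 36L)
  expect_equal(attr(s, "n_patients"), 234L)
})

test_that("overlap identity Pure = Diagonal - OffDiagonal holds for 2-site corpora", {
  cc <- generate_corpus(generator_config(n_cases = 2000, seed = 13))
  tr <- cc$truth[cc$truth$true_primary_site == "lung", ]
  tr <- first_case_per_patient(tr)
  om <- overlap_matrix(data.frame(site_set = tr$true_site_set))
  s <- overlap_summary(om)
  expect_equal(s$pure, s$diagonal - s$off_diagonal)
  expect_equal(sum(s$pure) + attr(s, "mixed"), nrow(tr))
})

test_that("lesion tabulation uses distinct named sites per patient", {
  pat <- data.frame(subtype_refined = c("AC", "SCLC", "AC"),
                    site_set = c("frontal|parietal", "cerebellum",
                                 "unknown"))
  sbs <- site_by_subtype(pat)
  expect_equal(sbs$lesions["AC", "frontal"], 1L)
  expect_equal(sbs$lesions["AC", "parietal"], 1L)
  expect_equal(sbs$lesions["AC", "unknown/other"], 1L)
  expect_equal(sum(sbs$lesions), 4L)       # 2 + 1 + 1 lesions
  expect_equal(sbs$patients[["AC"]], 2L)
  expect_equal(sbs$n_patients, 3L)
  # empty cohort tabulates to all-zero
  empty <- site_by_subtype(pat[0, ])
  expect_equal(sum(empty$lesions), 0L)
})

test_that("lesion counts are conserved and bounded by patients", {
  cc <- generate_corpus(generator_config(n_cases = 1500, seed = 17))
  tr <- first_case_per_patient(
    cc$truth[cc$truth$true_primary_site == "lung", ])
  names(tr)[names(tr) == "true_subtype_refined"] <- "subtype_refined"
  names(tr)[names(tr) == "true_site_set"] <- "site_set"
  sbs <- site_by_subtype(tr)
  sets <- strsplit(tr$site_set, "|", fixed = TRUE)
  expected_lesions <- sum(vapply(sets, function(s) {
    named <- intersect(unique(s), bm_named_sites())
    max(length(named), 1L)
  }, numeric(1)))
  expect_equal(sum(sbs$lesions), expected_lesions)
  expect_gte(sum(sbs$lesions), sbs$n_patients)
})

test_that("simplification drops labelled columns and recomputes margins", {
  ref <- reference_cohort()
  s <- simplify_table(ref$lesions, "unknown/other")
  expect_equal(dim(s), c(4L, 5L))
  expect_equal(sum(s), 252L)
  expect_equal(rowSums(s), rowSums(ref$lesions) -
                 ref$lesions[, "unknown/other"])
  expect_identical(simplify_table(ref$lesions, character(0)), ref$lesions)
  expect_error(simplify_table(ref$lesions, "no-such-column"), "unknown")
  expect_error(simplify_table(ref$lesions, colnames(ref$lesions)), "all")
})

test_that("single-site subset keeps exactly single named-site patients", {
  pat <- data.frame(site_set = c("frontal|parietal", "frontal", "unknown",
                                 "other", "cerebellum"))
  out <- single_site_subset(pat)
  expect_equal(out$site_set, c("frontal", "cerebellum"))
})

test_that("conditional distributions normalise each slice", {
  ref <- reference_cohort()
  p_site <- conditional_distributions(ref$lesions, "col")
  expect_equal(unname(colSums(p_site)), rep(1, 6))
  # given a cerebellar lesion, the adenocarcinoma share is 37/61
  expect_equal(p_site["AC", "cerebellum"], 37 / 61)
  p_sub <- conditional_distributions(ref$lesions, "row")
  expect_equal(unname(rowSums(p_sub)), rep(1, 4))
  # a zero margin yields missing proportions, not an error
  m <- matrix(c(1, 1, 0, 0), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_true(all(is.na(conditional_distributions(m, "col")[, "y"])))
  u <- matrix(rep(1, 4), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(unname(conditional_distributions(u, "row")),
               matrix(0.5, 2, 2))
})

test_that("biomarker tables follow lesion semantics and exclude unknown/other", {
  pat <- data.frame(
    subtype_refined = c("AC", "AC", "SCC"),
    site_set = c("frontal", "frontal|cerebellum", "unknown"),
    egfr = c("positive", "negative", "not-done"),
    ras = c("not-done", "not-done", "not-done"),
    pdl1_bin = c("not-done", "low-positive", "positive"))
  bt <- biomarker_tables(pat)
  expect_equal(bt$by_subtype$egfr["positive", "AC"], 1L)
  expect_equal(sum(bt$by_subtype$egfr), 2L)
  # second patient contributes one count per named site
  expect_equal(bt$by_site$egfr["negative", "frontal"], 1L)
  expect_equal(bt$by_site$egfr["negative", "cerebellum"], 1L)
  # unknown-only patient appears in subtype but not site tables
  expect_equal(sum(bt$by_subtype$pdl1), 2L)
  expect_equal(sum(bt$by_site$pdl1), 2L)
  # a marker with no tested patient is dropped
  expect_null(bt$by_subtype$ras)
})

test_that("contingency table validates counts and keeps margins consistent", {
  expect_error(contingency_table(matrix(c(1, -1, 2, 3), 2)), "non-negative")
  expect_error(contingency_table(matrix(c(0.5, 1, 2, 3), 2)), "integer")
  ct <- contingency_table(matrix(1:6, 2))
  mg <- table_margins(ct)
  expect_equal(mg$total, sum(1:6))
  expect_equal(unname(mg$row), c(9, 12))
})
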