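test_that("2x2 exact p equals brute-force enumeration and the reference implementation", {
  expect_equal(fisher_2x2(matrix(5, 2, 2))$p, 1)
  expect_error(fisher_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")

  set.seed(101)
  for (i in 1:40) {
    m <- random_table(2, 2, sample(4:30, 1))
    if (sum(m) == 0) next
    p <- fisher_2x2(m)$p
    expect_equal(p, brute_fisher_2x2(m), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("r x c enumeration matches brute force, the 2x2 special case, and is label-invariant", {
  set.seed(202)
  for (i in 1:10) {
    m <- random_table(3, 3, sample(8:22, 1))
    p <- fisher_rxc_exact(m)$p
    expect_equal(p, brute_fisher_rxc(m), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-6)
    # invariance under permutations and transpose
    expect_equal(fisher_rxc_exact(m[sample(3), sample(3)])$p, p,
                 tolerance = 1e-10)
    expect_equal(fisher_rxc_exact(t(m))$p, p, tolerance = 1e-10)
  }
  for (i in 1:15) {
    m <- random_table(2, 2, sample(5:25, 1))
    expect_equal(fisher_rxc_exact(m)$p, fisher_2x2(m)$p, tolerance = 1e-12)
  }
})

test_that("degenerate margins reduce cleanly", {
  m <- matrix(c(3, 0, 4, 0, 2, 0), 2)  # empty second row
  expect_equal(fisher_rxc_exact(m)$p,
               fisher_rxc_exact(m[1, , drop = FALSE])$p)
  expect_equal(fisher_rxc_exact(matrix(c(5, 3), 1))$p, 1)
})

test_that("enumeration refuses infeasible tables and directs to Monte-Carlo", {
  s <- ref_simplified()   # ~5.7e13 margin-compatible tables
  expect_error(fisher_rxc_exact(s), "fisher_rxc_mc")
  expect_error(fisher_rxc_exact(matrix(1:9, 3), max_tables = 2),
               "infeasible")
})

test_that("Monte-Carlo estimates agree with enumeration within 3 standard errors", {
  set.seed(303)
  fails <- 0
  for (i in 1:25) {
    m <- random_table(3, 3, sample(10:25, 1))
    ex <- fisher_rxc_exact(m)$p
    mc <- fisher_rxc_mc(m, reps = 4000, seed = i)
    if (abs(mc$p - ex) > 3 * mc$mc_se + 1 / 4001) fails <- fails + 1
  }
  expect_lte(fails, 2)
  # determinism under a fixed seed and the add-one guarantee
  m <- matrix(c(8, 1, 2, 9, 3, 3), 2)
  a <- fisher_rxc_mc(m, reps = 2000, seed = 7)
  b <- fisher_rxc_mc(m, reps = 2000, seed = 7)
  expect_identical(a$p, b$p)
  expect_gt(a$p, 0)
  expect_gt(a$mc_se, 0)
  expect_error(fisher_rxc_mc(m, reps = 10), "reps")
})

test_that("the exact test is conservative under the fixed-margin null", {
  set.seed(404)
  tabs <- stats::r2dtable(800, c(25, 25), c(30, 20))  # n = 50
  pv <- vapply(tabs, function(t) fisher_2x2(t)$p, numeric(1))
  rej <- mean(pv <= 0.05)
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 800))
})

test_that("all-pairs decomposition yields one labelled p per pair of rows and columns", {
  s <- ref_simplified()
  pm <- all_pairs_2x2(s)
  expect_equal(dim(pm), c(choose(4, 2), choose(5, 2)))
  expect_equal(length(pm), 60L)
  expect_true("AC-SCLC" %in% rownames(pm))
  expect_true("frontal-cerebellum" %in% colnames(pm))
  # reduction: a 2x2 input gives the single fisher_2x2 p
  m <- matrix(c(9, 5, 13, 0), 2)
  expect_equal(as.vector(all_pairs_2x2(m)), fisher_2x2(m)$p)
  # permuting rows permutes labels but not the multiset of p-values
  pm2 <- all_pairs_2x2(s[c(3, 1, 4, 2), ])
  expect_equal(sort(round(as.vector(pm2), 12)),
               sort(round(as.vector(pm), 12)))
})

test_that("p-value colour bins follow the half-open boundaries", {
  expect_equal(as.character(bin_pvalue(c(0, 0.03, 0.049999))),
               rep("red", 3))
  expect_equal(as.character(bin_pvalue(0.05)), "pink")
  expect_equal(as.character(bin_pvalue(0.1)), "white")
  expect_equal(as.character(bin_pvalue(0.2)), "light blue")
  expect_equal(as.character(bin_pvalue(c(0.4, 0.7, 1))),
               rep("dark blue", 3))
  expect_error(bin_pvalue(1.2), "0, 1")
  expect_error(bin_pvalue(-0.1), "0, 1")
})

test_that("heatmap ordering is deterministic and groups identical rows", {
  m <- matrix(c(0.1, 0.1, 0.9,
                0.9, 0.9, 0.1,
                0.1, 0.1, 0.9,
                0.5, 0.5, 0.5), 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), c("x", "y", "z")))
  ord <- heatmap_order(m)
  pos <- match(c(1, 3), ord$row_order)   # identical rows a and c adjacent
  expect_equal(abs(diff(pos)), 1)
  expect_identical(heatmap_order(m), ord)
  # permuting the input does not change the label sequence
  perm <- c(2, 4, 1, 3)
  ord2 <- heatmap_order(m[perm, ])
  expect_equal(rownames(m)[ord$row_order],
               rownames(m[perm, ])[ord2$row_order])
  # single-row matrices keep identity order
  expect_equal(heatmap_order(m[1, , drop = FALSE])$row_order, 1L)
  m[2, 2] <- NA
  expect_error(heatmap_order(m), "complete")
})
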