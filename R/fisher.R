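# Exact inference for labelled contingency tables: two-sided 2x2 Fisher
# test, Freeman-Halton exact r x c test by full enumeration, fixed-margin
# Monte-Carlo estimation, the all-pairs 2x2 decomposition, and p-value
# binning / clustering for heatmap figures.
#
# Two-sided convention throughout: probability ordering. The p-value is
# the null probability of all fixed-margin tables whose probability does
# not exceed that of the observed table, with a relative tie tolerance
# (default 1e-7) so that tables equal to the observed probability up to
# rounding are counted as ties.

exact_test_result <- function(p, method, ...) {
  structure(c(list(p = p, method = method), list(...)),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat("Exact test (", x$method, "): p = ", format(x$p, digits = 5), "\n",
      sep = "")
  if (!is.null(x$mc_se))
    cat("  Monte-Carlo: reps = ", x$mc_reps,
        ", se = ", format(x$mc_se, digits = 3), "\n", sep = "")
  if (!is.null(x$tables_enumerated))
    cat("  tables enumerated: ", format(x$tables_enumerated, big.mark = ","),
        "\n", sep = "")
  invisible(x)
}

check_count_matrix <- function(m, min_dim = 1L) {
  m <- unclass(as.matrix(m))
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("table entries must be non-negative integers")
  if (sum(m) < 1) stop("table total must be positive")
  storage.mode(m) <- "integer"
  m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value by probability ordering: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability is at most that of the observed table (up to a
#' relative tie tolerance).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param tol Relative tie tolerance for "as or more extreme".
#' @return An object of class \code{exact_test} with elements \code{p}
#'   and \code{method}.
#' @examples
#' fisher_2x2(matrix(c(9, 5, 13, 0), 2))
#' @export
fisher_2x2 <- function(table, tol = 1e-7) {
  m <- check_count_matrix(table)
  if (!all(dim(m) == 2L)) stop("fisher_2x2 needs a 2x2 table")
  n <- sum(m); r1 <- sum(m[1L, ]); c1 <- sum(m[, 1L])
  k <- max(0L, r1 + c1 - n):min(r1, c1)
  d <- stats::dhyper(k, c1, n - c1, r1)
  dobs <- stats::dhyper(m[1L, 1L], c1, n - c1, r1)
  p <- min(1, sum(d[d <= dobs * (1 + tol)]))
  exact_test_result(p, "exact-2x2")
}

#' Freeman-Halton exact test for an r x c table
#'
#' Generalises the Fisher exact test to r x c tables: the p-value is the
#' sum of multivariate-hypergeometric probabilities of all tables with
#' the observed margins that are no more probable than the observed one.
#' The full set of margin-compatible tables is enumerated in compiled
#' code (column-wise recursive composition with row-margin caps), after a
#' dynamic-programming pre-count guards feasibility: if more than
#' \code{max_tables} tables share the margins the function refuses and
#' directs the caller to [fisher_rxc_mc()]. Rows and columns with a zero
#' margin are dropped first; a table left with fewer than two rows or
#' columns is degenerate and returns p = 1. On a 2x2 input the result
#' equals [fisher_2x2()].
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param tol Relative tie tolerance.
#' @param max_tables Enumeration feasibility ceiling (number of
#'   margin-compatible tables; default 5e7).
#' @return An \code{exact_test} with \code{p}, \code{method} and
#'   \code{tables_enumerated}.
#' @examples
#' fisher_rxc_exact(matrix(c(3, 1, 2, 5, 4, 2), 2))
#' @export
fisher_rxc_exact <- function(table, tol = 1e-7, max_tables = 5e7) {
  m <- check_count_matrix(table)
  m <- m[rowSums(m) > 0L, colSums(m) > 0L, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    return(exact_test_result(1, "exact-rxc-enumeration",
                             tables_enumerated = 1))
  n_tab <- rxc_table_count(rowSums(m), colSums(m))
  if (n_tab > max_tables)
    stop("enumeration infeasible: ", format(n_tab, big.mark = ","),
         " tables share these margins (ceiling ",
         format(max_tables, big.mark = ","),
         "); use fisher_rxc_mc() instead")
  res <- rxc_exact_sum(m, tol, max_tables * 1.01)
  exact_test_result(res$p, "exact-rxc-enumeration",
                    tables_enumerated = res$tables)
}

#' Monte-Carlo Freeman-Halton test for large tables
#'
#' Estimates the probability-ordering p-value by sampling tables from
#' the null fixed-margin distribution with Patefield's sequential
#' conditional algorithm (base R's \code{r2dtable}) and applying the
#' add-one correction, \eqn{\hat p = (1 + \#\{P(T) \le P(obs)\}) /
#' (reps + 1)}, so the estimate is never zero. The binomial standard
#' error of the estimate is reported; a fixed seed reproduces the
#' estimate exactly.
#'
#' @inheritParams fisher_rxc_exact
#' @param reps Number of sampled tables (at least 1000).
#' @param seed Integer seed for the sampler.
#' @return An \code{exact_test} with \code{p}, \code{method},
#'   \code{mc_reps} and \code{mc_se}.
#' @examples
#' fisher_rxc_mc(matrix(c(3, 1, 2, 5, 4, 2), 2), reps = 2000, seed = 1)
#' @export
fisher_rxc_mc <- function(table, reps = 1e5, seed = 1L, tol = 1e-7) {
  m <- check_count_matrix(table)
  if (!is.numeric(reps) || length(reps) != 1L || is.na(reps) || reps < 1000)
    stop("reps must be a single number >= 1000")
  reps <- as.integer(reps)
  m <- m[rowSums(m) > 0L, colSums(m) > 0L, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    p <- 1
    return(exact_test_result(p, "monte-carlo", mc_reps = reps,
                             mc_se = 0))
  }
  set.seed(as.integer(seed))
  # P(T) <= P(obs) * (1 + tol)  <=>  sum lgamma(x+1) >= s_obs - log1p(tol)
  s_obs <- sum(lgamma(m + 1))
  thresh <- s_obs - log1p(tol)
  hits <- 0
  left <- reps
  rs <- rowSums(m); cs <- colSums(m)
  while (left > 0L) {
    chunk <- min(left, 20000L)
    tabs <- stats::r2dtable(chunk, rs, cs)
    s <- vapply(tabs, function(t) sum(lgamma(t + 1)), numeric(1))
    hits <- hits + sum(s >= thresh)
    left <- left - chunk
  }
  p <- (1 + hits) / (reps + 1)
  exact_test_result(p, "monte-carlo", mc_reps = reps,
                    mc_se = sqrt(p * (1 - p) / reps))
}

#' All-pairs 2x2 decomposition of an r x c table
#'
#' Constructs every 2x2 table obtained by choosing an unordered pair of
#' rows and an unordered pair of columns, and computes the two-sided
#' Fisher p-value for each. A 4 x 5 table yields choose(4,2) *
#' choose(5,2) = 60 p-values. The result is labelled by the pair names
#' ("AC-SCLC", "frontal-cerebellum", ...).
#'
#' @inheritParams fisher_rxc_exact
#' @return Numeric matrix of p-values, row pairs by column pairs.
#' @export
all_pairs_2x2 <- function(table, tol = 1e-7) {
  m <- check_count_matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least two rows and two columns")
  rp <- utils::combn(nrow(m), 2L)
  cp <- utils::combn(ncol(m), 2L)
  pm <- matrix(NA_real_, ncol(rp), ncol(cp))
  rownames(pm) <- apply(rp, 2L, function(i)
    paste(rownames(m)[i], collapse = "-"))
  colnames(pm) <- apply(cp, 2L, function(j)
    paste(colnames(m)[j], collapse = "-"))
  for (a in seq_len(ncol(rp)))
    for (b in seq_len(ncol(cp))) {
      sub <- m[rp[, a], cp[, b]]
      # an all-zero extraction carries no information
      pm[a, b] <- if (sum(sub) == 0L) 1 else fisher_2x2(sub, tol = tol)$p
    }
  pm
}

#' Bin p-values into heatmap colour categories
#'
#' Half-open bins: red for p in \[0, 0.05), pink \[0.05, 0.1), white
#' \[0.1, 0.2), light blue \[0.2, 0.4) and dark blue \[0.4, 1\].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Factor with levels red, pink, white, light blue, dark blue.
#' @examples
#' bin_pvalue(c(0.03, 0.05, 1))
#' @export
bin_pvalue <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  lab <- c("red", "pink", "white", "light blue", "dark blue")
  idx <- findInterval(p, c(0.05, 0.1, 0.2, 0.4)) + 1L
  factor(lab[idx], levels = lab)
}

#' Deterministic hierarchical ordering for p-value heatmaps
#'
#' Returns the leaf orders of complete-linkage hierarchical clustering
#' (Euclidean distance) of the rows and columns of a complete p-value
#' matrix. Rows and columns are pre-sorted by label so that the ordering
#' is invariant to the input permutation (ties in the linkage are broken
#' by label order); identical rows end up adjacent.
#'
#' @param pvalue_matrix Complete numeric matrix (no missing values).
#' @return List with integer vectors \code{row_order} and
#'   \code{col_order} (indices into the input).
#' @export
heatmap_order <- function(pvalue_matrix) {
  m <- as.matrix(pvalue_matrix)
  if (any(is.na(m))) stop("p-value matrix must be complete")
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  ord_axis <- function(x) {
    if (nrow(x) < 3L) return(seq_len(nrow(x)))
    srt <- order(rownames(x))
    h <- stats::hclust(stats::dist(x[srt, , drop = FALSE]),
                       method = "complete")
    srt[h$order]
  }
  list(row_order = ord_axis(m), col_order = ord_axis(t(m)))
}

#' Render a clustered p-value heatmap
#'
#' Draws the all-pairs p-value matrix as a clustered heatmap with the
#' five-bin colour scale of [bin_pvalue()]. Requires the \pkg{pheatmap}
#' package.
#'
#' @param pvalue_matrix Matrix of p-values (rows and columns labelled).
#' @param file Optional output file (png/pdf inferred from extension).
#' @return The \code{pheatmap} object, invisibly.
#' @export
plot_pvalue_heatmap <- function(pvalue_matrix, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_pvalue_heatmap requires the 'pheatmap' package")
  cols <- c("#d73027", "#fbb4b9", "#ffffff", "#abd9e9", "#2c7bb6")
  ph <- pheatmap::pheatmap(
    pvalue_matrix,
    breaks = c(0, 0.05, 0.1, 0.2, 0.4, 1),
    color = cols,
    clustering_method = "complete",
    display_numbers = TRUE, number_format = "%.3f",
    filename = if (is.null(file)) NA else file,
    silent = !is.null(file))
  invisible(ph)
}
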