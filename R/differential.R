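# Differential pathway activity between two sample groups: per-pathway
# t / Wilcoxon tests, Storey q-value FDR, direction summaries and
# cross-dataset t-score consistency.

# Run a two-group row-wise test over a matrix.  `testfun(x1, x2)` returns
# list(statistic, p.value).  Rows with <2 usable values in either group are
# skipped with a reason.
.row_group_test <- function(x, f, testfun, stat_name) {
  g1 <- names(f)[f == levels(f)[1L]]
  g2 <- names(f)[f == levels(f)[2L]]
  if (length(g1) < 2L || length(g2) < 2L)
    .stopf("both groups need at least 2 samples (found %d and %d)",
           length(g1), length(g2))
  rows <- lapply(rownames(x), function(pw) {
    x1 <- x[pw, g1]; x1 <- x1[!is.na(x1)]
    x2 <- x[pw, g2]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L)
      return(list(skip = sprintf("%s: fewer than 2 non-missing values in a group", pw)))
    res <- testfun(x1, x2)
    list(row = data.frame(pathway = pw,
                          mean_1 = mean(x1), mean_2 = mean(x2),
                          stat = unname(res$statistic), p = res$p.value,
                          stringsAsFactors = FALSE))
  })
  skipped <- unlist(lapply(rows, `[[`, "skip"))
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (is.null(tab) || !nrow(tab)) .stopf("no testable rows")
  names(tab)[names(tab) == "stat"] <- stat_name
  names(tab)[names(tab) == "mean_1"] <- paste0("mean_", levels(f)[1L])
  names(tab)[names(tab) == "mean_2"] <- paste0("mean_", levels(f)[2L])
  tab$direction <- ifelse(tab[[paste0("mean_", levels(f)[1L])]] >
                          tab[[paste0("mean_", levels(f)[2L])]], "up", "down")
  qv <- storey_qvalue(tab$p)
  tab$q <- as.numeric(qv)
  tab <- tab[order(tab$p), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "groups") <- levels(f)
  attr(tab, "pi0") <- attr(qv, "pi0")
  attr(tab, "skipped") <- skipped
  class(tab) <- c("differential_table", "data.frame")
  tab
}

#' Differential pathway activity by Welch t-test
#'
#' Compares each pathway's activity scores between two sample groups with a
#' two-sided Welch (unequal-variance) t-test, then attaches Storey q-values.
#' Direction `"up"` means higher mean activity in group 1 (the first level
#' of `groups`, or the first label encountered).  Pathways with Q < 0.01
#' are conventionally called differential (1% FDR).
#'
#' @param activity pathways x samples matrix from [activity_matrix()].
#' @param labels named character vector (or two-column data frame) of group
#'   labels.
#' @param groups optional length-2 character vector fixing group order.
#' @return a `differential_table` data frame sorted by P: pathway, group
#'   means, `t`, `p`, `q`, `direction`.
#' @export
t_test_pathways <- function(activity, labels, groups = NULL) {
  .check_matrix(activity, "activity matrix")
  f <- .align_labels(labels, colnames(activity), groups)
  .row_group_test(activity, f,
                  function(x1, x2) stats::t.test(x1, x2),
                  "t")
}

#' Differential pathway activity by Wilcoxon rank-sum test
#'
#' As [t_test_pathways()] but with the two-sided Wilcoxon (Mann-Whitney)
#' rank-sum test, the conventional choice for enrichment-score activity
#' whose distribution is bimodal rather than normal.
#'
#' @inheritParams t_test_pathways
#' @return a `differential_table` with statistic column `w`.
#' @export
wilcoxon_pathways <- function(activity, labels, groups = NULL) {
  .check_matrix(activity, "activity matrix")
  f <- .align_labels(labels, colnames(activity), groups)
  .row_group_test(activity, f,
                  function(x1, x2)
                    suppressWarnings(stats::wilcox.test(x1, x2)),
                  "w")
}

#' @export
print.differential_table <- function(x, n = 10L, ...) {
  g <- attr(x, "groups")
  cat(sprintf("Differential pathway table: %d pathways, groups %s vs %s (direction 'up' = higher in %s), pi0 = %.3f\n",
              nrow(x), g[1L], g[2L], g[1L], attr(x, "pi0")))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Storey q-values
#'
#' False-discovery-rate adjusted significance after Storey & Tibshirani:
#' the null proportion pi0 is estimated on the grid lambda = 0.05, 0.10,
#' ..., 0.95 as mean(p > lambda) / (1 - lambda), smoothed with a cubic
#' smoothing spline (3 df) and read off at lambda = 0.95, clipped to (0, 1].
#' q-values are then q_(i) = min over j >= i of pi0 m p_(j) / j, i.e. pi0
#' times the Benjamini-Hochberg adjustment, enforced monotone in P.
#'
#' @param p vector of p-values in [0, 1].
#' @param pi0 optional fixed null proportion; `pi0 = 1` reproduces
#'   Benjamini-Hochberg exactly.
#' @param lambda tuning grid for the pi0 smoother.
#' @return q-values in the order of `p`, with the estimated `pi0` attached
#'   as an attribute.
#' @export
storey_qvalue <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  if (anyNA(p) || any(p < 0 | p > 1))
    .stopf("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 2L) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)    # clip to (0, 1]
    }
  } else {
    if (!(pi0 > 0 && pi0 <= 1)) .stopf("pi0 must lie in (0, 1]")
  }
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(pi0 * m * p[o] / seq(m, 1L)))[order(o)]
  attr(q, "pi0") <- pi0
  q
}

#' Fraction of up-regulated genes per pathway
#'
#' Gene-level Welch t-tests (group 1 vs group 2) are computed once; each
#' pathway then reports (i) the fraction of its member genes with t > 0 and
#' (ii) the same fraction restricted to differentially expressed members
#' (gene-level P < `p_cut`).  A pathway dominated by one direction has
#' fractions near 1 (up) or 0 (down); fraction (ii) is `NA` when no member
#' passes `p_cut`.
#'
#' @param x expression matrix (standardized one-channel values or two-channel
#'   log-ratios), genes x samples.
#' @param labels sample group labels (two groups).
#' @param sets named list of gene sets restricted to the matrix.
#' @param p_cut gene-level significance cut for fraction (ii), default 0.001.
#' @param groups optional group order.
#' @return data frame: pathway, n_genes, frac_up_all, n_sig, frac_up_sig.
#' @export
fraction_upregulated <- function(x, labels, sets, p_cut = 0.001,
                                 groups = NULL) {
  .check_matrix(x)
  f <- .align_labels(labels, colnames(x), groups)
  gene_tab <- .row_group_test(x, f,
                              function(x1, x2) stats::t.test(x1, x2), "t")
  t_g <- stats::setNames(gene_tab$t, gene_tab$pathway)
  p_g <- stats::setNames(gene_tab$p, gene_tab$pathway)
  rows <- lapply(names(sets), function(pw) {
    g <- intersect(sets[[pw]], names(t_g))
    if (!length(g)) return(NULL)
    sig <- g[p_g[g] < p_cut]
    data.frame(pathway = pw,
               n_genes = length(g),
               frac_up_all = mean(t_g[g] > 0),
               n_sig = length(sig),
               frac_up_sig = if (length(sig)) mean(t_g[sig] > 0)
                             else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-dataset consistency of test statistics
#'
#' Pearson correlation of the per-entity statistics (pathway t-scores, or
#' gene t-scores) from two independent datasets over their shared universe.
#' Pathway-level statistics are expected to replicate better than gene-level
#' ones because they average out sample-specific gene perturbations.
#'
#' @param tableA,tableB `differential_table` data frames (or any data frame
#'   with a `pathway` column and the statistic column).
#' @param column statistic column name, default `"t"`.
#' @return Pearson correlation R of the two statistic vectors.
#' @export
tscore_consistency <- function(tableA, tableB, column = "t") {
  shared <- intersect(tableA$pathway, tableB$pathway)
  if (length(shared) < 3L)
    .stopf("fewer than 3 shared entities between the two tables")
  a <- tableA[[column]][match(shared, tableA$pathway)]
  b <- tableB[[column]][match(shared, tableB$pathway)]
  stats::cor(a, b)
}
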