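# Within-pathway gene co-expression: average pairwise Spearman correlation
# of member expression profiles across samples.

#' Within-pathway co-expression strength
#'
#' For each pathway, computes the Spearman correlation of every pair of
#' member gene expression profiles across samples and averages the
#' m(m-1)/2 coefficients; a positive mean indicates the pathway's genes tend
#' to be co-expressed.  Pairs are evaluated on pairwise-complete samples and
#' pairs with fewer than 3 complete samples are dropped from the mean.
#'
#' @param x expression matrix, genes x samples, at least 3 samples.
#' @param sets named list of gene sets restricted to the matrix.
#' @return data frame: pathway, mean_rho, n_pairs (pairs entering the mean),
#'   n_genes (mapped members); pathways with fewer than 2 mapped genes are
#'   skipped and listed in the `skipped` attribute.
#' @export
pathway_coexpression <- function(x, sets) {
  .check_matrix(x)
  if (ncol(x) < 3L) .stopf("need at least 3 samples")
  n_obs_base <- !is.na(x)
  skipped <- character()
  rows <- lapply(names(sets), function(pw) {
    g <- intersect(sets[[pw]], rownames(x))
    if (length(g) < 2L) {
      skipped <<- c(skipped,
                    sprintf("%s: fewer than 2 mapped genes", pw))
      return(NULL)
    }
    sub <- x[g, , drop = FALSE]
    C <- suppressWarnings(
      stats::cor(t(sub), method = "spearman",
                 use = "pairwise.complete.obs"))
    # pairwise complete sample counts
    obs <- n_obs_base[g, , drop = FALSE]
    n_pair <- obs %*% t(obs)
    up <- upper.tri(C)
    ok <- up & n_pair >= 3L & !is.na(C)
    vals <- C[ok]
    data.frame(pathway = pw,
               mean_rho = if (length(vals)) mean(vals) else NA_real_,
               n_pairs = length(vals),
               n_genes = length(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("no pathway with at least 2 mapped genes")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Compare co-expression strength between two conditions
#'
#' Paired t-test across the shared pathways of the per-pathway mean
#' correlations from two datasets/conditions; a positive t means stronger
#' within-pathway co-expression in `tableA`.
#'
#' @param tableA,tableB data frames from [pathway_coexpression()].
#' @return a `coupling_test` object (t, p, df, n_pairs = pathways compared,
#'   estimate = mean difference A - B).
#' @export
compare_coexpression <- function(tableA, tableB) {
  shared <- intersect(tableA$pathway, tableB$pathway)
  a <- tableA$mean_rho[match(shared, tableA$pathway)]
  b <- tableB$mean_rho[match(shared, tableB$pathway)]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) .stopf("fewer than 3 shared evaluable pathways")
  if (stats::sd(a - b) == 0) {
    res <- list(statistic = c(t = 0), p.value = 1,
                parameter = c(df = length(a) - 1L))
  } else {
    res <- stats::t.test(a, b, paired = TRUE)
  }
  structure(list(t = unname(res$statistic), p = res$p.value,
                 df = unname(res$parameter), n_pairs = length(a),
                 estimate = mean(a) - mean(b), mode = "coexpression",
                 test = "paired"),
            class = "coupling_test")
}
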