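# Pathway co-regulation: Spearman correlation of activity profiles with
# shared-gene exclusion, threshold networks, and coupling comparisons
# between conditions.

#' Correlation of two pathways' activity profiles, shared genes excluded
#'
#' Genes common to both sets would inflate the correlation of the two
#' AR-score profiles, so the intersection is removed first and the AR-scores
#' recomputed on the residual (unique) members across all samples; the
#' Spearman coefficient of the two residual profiles is returned.  A pair
#' whose residual set falls below `min_genes` mapped members is "not
#' evaluable" - distinct from a correlation of zero.
#'
#' @param setA,setB character vectors of member gene ids.
#' @param x standardized expression matrix, genes x samples.
#' @param min_genes minimum residual set size (default 5).
#' @return list with `rho` (Spearman coefficient or `NA`), `evaluable`,
#'   `reason` (`NULL` when evaluable) and `n_shared`.
#' @export
corr_pair_excluding_shared <- function(setA, setB, x, min_genes = 5L) {
  .check_matrix(x)
  R <- .rank_matrix(x)
  .corr_pair_ranks(R, setA, setB, min_genes, colSums(!is.na(R)))
}

# Same computation from a precomputed rank matrix (used by pathway_cor).
.corr_pair_ranks <- function(R, setA, setB, min_genes,
                             n_per = colSums(!is.na(R))) {
  shared <- intersect(setA, setB)
  resA <- setdiff(setA, shared)
  resB <- setdiff(setB, shared)
  genes <- rownames(R)
  nA <- sum(resA %in% genes)
  nB <- sum(resB %in% genes)
  if (nA < min_genes || nB < min_genes) {
    return(list(rho = NA_real_, evaluable = FALSE,
                reason = sprintf(
                  "residual set below min_genes after removing %d shared gene(s) (%d and %d left)",
                  length(shared), nA, nB),
                n_shared = length(shared)))
  }
  pa <- .ar_profile(R, resA, n_per)
  pb <- .ar_profile(R, resB, n_per)
  rho <- stats::cor(pa, pb, method = "spearman",
                    use = "pairwise.complete.obs")
  list(rho = rho, evaluable = TRUE, reason = NULL, n_shared = length(shared))
}

#' All-pairs pathway correlation matrix with shared-gene exclusion
#'
#' Evaluates every unordered pair of pathways (K(K-1)/2 pairs for K sets):
#' disjoint pairs use the sets' own AR-score profiles; overlapping pairs are
#' recomputed on residual sets after removing the shared genes.  Spearman
#' coefficients use mid-ranks for tied scores.
#'
#' @param sets named list of gene sets restricted to the matrix.
#' @param x standardized expression matrix.
#' @param min_genes minimum residual set size for a pair to be evaluable.
#' @return a `pathway_cor` object: list with `rho` (K x K symmetric matrix,
#'   diagonal 1, `NA` for non-evaluable pairs), `n_samples`, `n_pairs`,
#'   `sizes` (mapped set sizes), `not_evaluable` (data frame of pair,
#'   reason), `min_genes`.
#' @export
pathway_cor <- function(sets, x, min_genes = 5L) {
  .check_matrix(x)
  K <- length(sets)
  if (K < 2L) .stopf("need at least 2 pathways")
  nm <- names(sets)
  R <- .rank_matrix(x)
  n_per <- colSums(!is.na(R))
  A <- t(vapply(sets, function(s) .ar_profile(R, s, n_per), numeric(ncol(x))))
  rho <- suppressWarnings(
    stats::cor(t(A), method = "spearman", use = "pairwise.complete.obs"))
  dimnames(rho) <- list(nm, nm)
  ne <- list()
  # Recompute pairs with shared genes on residual sets (or mark not
  # evaluable); disjoint pairs already correct.
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      shared <- intersect(sets[[i]], sets[[j]])
      if (!length(shared)) next
      res <- .corr_pair_ranks(R, sets[[i]], sets[[j]], min_genes, n_per)
      rho[i, j] <- rho[j, i] <- res$rho
      if (!res$evaluable)
        ne[[length(ne) + 1L]] <- data.frame(pathway_a = nm[i],
                                            pathway_b = nm[j],
                                            reason = res$reason,
                                            stringsAsFactors = FALSE)
    }
  }
  diag(rho) <- 1
  structure(list(rho = rho,
                 n_samples = ncol(x),
                 n_pairs = K * (K - 1L) / 2L,
                 sizes = lengths(sets),
                 not_evaluable = if (length(ne)) do.call(rbind, ne)
                                 else data.frame(pathway_a = character(),
                                                 pathway_b = character(),
                                                 reason = character()),
                 min_genes = min_genes),
            class = "pathway_cor")
}

#' @export
print.pathway_cor <- function(x, ...) {
  cat(sprintf("Pathway correlation matrix: %d pathways, %d unordered pairs, %d samples\n",
              nrow(x$rho), x$n_pairs, x$n_samples))
  cat(sprintf("Shared-gene exclusion applied; %d pair(s) not evaluable (min_genes = %d)\n",
              nrow(x$not_evaluable), x$min_genes))
  invisible(x)
}

# Upper-triangle pair vector of a pathway_cor over a given pathway universe.
.pair_vector <- function(pc, universe) {
  r <- pc$rho[universe, universe, drop = FALSE]
  r[upper.tri(r)]
}

#' Threshold a correlation matrix into a co-regulation network
#'
#' Pathway pairs whose Spearman coefficient strictly exceeds `tau` in
#' absolute value are connected; positive edges link correlated pathways,
#' negative edges anti-correlated ones.  Isolated pathways are retained as
#' nodes, annotated with their gene count.
#'
#' @param pc a `pathway_cor` object.
#' @param tau correlation cut-off in (0, 1), default 0.75.
#' @return a `pathway_network` object: list with `nodes` (pathway, size),
#'   `edges` (pathway_a, pathway_b, rho, sign; `pathway_a < pathway_b`
#'   lexicographically) and `tau`.
#' @export
build_network <- function(pc, tau = 0.75) {
  stopifnot(inherits(pc, "pathway_cor"))
  if (!(tau > 0 && tau < 1)) .stopf("tau must be in (0, 1)")
  r <- pc$rho
  nm <- rownames(r)
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) > tau, arr.ind = TRUE)
  a <- nm[idx[, 1L]]
  b <- nm[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  rho <- r[idx]
  ord <- order(a, b)
  edges <- data.frame(pathway_a = a[ord], pathway_b = b[ord],
                      rho = rho[ord],
                      sign = ifelse(rho[ord] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(pathway = nm, size = unname(pc$sizes[nm]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, tau = tau),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("Pathway co-regulation network (|rho| > %g): %d nodes, %d edges (%d positive, %d negative)\n",
              x$tau, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Compare pathway-pair coupling between two conditions
#'
#' Tests whether pathway activity profiles are more strongly correlated in
#' one condition than another (e.g. normal vs tumor) by comparing the two
#' vectors of pairwise coefficients over the common pathway universe.  Pairs
#' not evaluable in either matrix are dropped pairwise.  The default
#' compares absolute coefficients with a paired t-test (the pairs are
#' matched entities across conditions); a positive t means stronger coupling
#' in `pcA`.
#'
#' @param pcA,pcB `pathway_cor` objects for the two conditions.
#' @param mode `"abs"` (coupling strength regardless of direction) or
#'   `"signed"`.
#' @param test `"paired"` or `"two_sample"` (Welch).
#' @return a `coupling_test` object: list with `t`, `p`, `df`, `n_pairs`,
#'   `estimate` (mean difference A - B), `mode`, `test`.
#' @export
compare_coupling <- function(pcA, pcB, mode = c("abs", "signed"),
                             test = c("paired", "two_sample")) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  stopifnot(inherits(pcA, "pathway_cor"), inherits(pcB, "pathway_cor"))
  universe <- intersect(rownames(pcA$rho), rownames(pcB$rho))
  if (length(universe) < 2L) .stopf("no common pathway universe")
  a <- .pair_vector(pcA, universe)
  b <- .pair_vector(pcB, universe)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L)
    .stopf("fewer than 3 common evaluable pathway pairs")
  if (mode == "abs") { a <- abs(a); b <- abs(b) }
  d <- a - b
  if (test == "paired" && stats::sd(d) == 0) {
    # degenerate but well-defined: identical coupling
    res <- list(statistic = c(t = 0), p.value = 1,
                parameter = c(df = length(d) - 1L))
  } else {
    res <- stats::t.test(a, b, paired = (test == "paired"))
  }
  structure(list(t = unname(res$statistic), p = res$p.value,
                 df = unname(res$parameter), n_pairs = length(a),
                 estimate = mean(a) - mean(b), mode = mode, test = test),
            class = "coupling_test")
}

#' @export
print.coupling_test <- function(x, ...) {
  cat(sprintf("Coupling comparison (%s coefficients, %s t-test) over %d pathway pairs\n",
              x$mode, x$test, x$n_pairs))
  cat(sprintf("  t = %.4g, df = %.4g, P = %.4g, mean difference = %.4g\n",
              x$t, x$df, x$p, x$estimate))
  invisible(x)
}
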