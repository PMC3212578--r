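# Per-sample pathway activity scores: the AR-score (normalized average rank),
# its absolute-value variant for two-channel log-ratios, and the KS-like
# enrichment score (ES) used as a comparator.

#' Rank the genes of one sample
#'
#' Mid-ranks (ties share the average of the ranks they span) over the
#' non-missing genes of one expression column.  The highest relative
#' expression receives rank n, so a larger average rank means higher
#' expression.  `mode = "absolute"` ranks `|value|`, which scores up- and
#' down-regulation jointly on log-ratio data instead of letting them cancel.
#'
#' @param values named numeric vector (one sample's expression).
#' @param mode `"signed"` or `"absolute"`.
#' @return named numeric vector of ranks over the non-missing genes; the
#'   rank sum always equals n(n+1)/2.
#' @export
rank_profile <- function(values, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  v <- values[!is.na(values)]
  if (length(v) < 2L)
    .stopf("rank_profile: need at least 2 non-missing values, got %d",
           length(v))
  rank(if (mode == "absolute") abs(v) else v, ties.method = "average")
}

#' AR-score of one gene set in one ranked sample
#'
#' The normalized average rank: the mean rank of the set's members divided by
#' the total number of ranked genes n, i.e. sum(r_i) / (m n) for the m
#' members present.  Values lie in (0, 1] (the upper boundary is attained
#' only by a single top-ranked gene); higher means the set's genes sit higher
#' in the sample's expression ranking, i.e. higher pathway activity.  Bounds
#' for a set of size m are [(m+1)/(2n), (2n-m+1)/(2n)].
#'
#' @param ranks named rank vector from [rank_profile()].
#' @param genes character vector of member gene ids.
#' @return the AR-score, or `NA` when no member is present in the ranking.
#' @export
ar_score <- function(ranks, genes) {
  present <- genes[genes %in% names(ranks)]
  if (!length(present)) return(NA_real_)
  mean(ranks[present]) / length(ranks)
}

#' KS-like enrichment score of one gene set in one ranked sample
#'
#' Walks the genes from highest to lowest relative expression; member hits
#' increment a running sum, misses decrement it, and the score is the running
#' sum at its maximum absolute deviation (signed; on a tie the earliest
#' extremum in the walk wins).  Unweighted steps are 1/m per hit and
#' 1/(n-m) per miss; weighted hit steps are |z_i| / sum of member |z|, with
#' `values` supplying z.  Values lie in [-1, 1]: +1 when all members occupy
#' the top m positions, -1 when they occupy the bottom m.
#'
#' @param ranks named rank vector from [rank_profile()].
#' @param genes member gene ids.
#' @param weighting `"unweighted"` (classic Kolmogorov-Smirnov statistic) or
#'   `"weighted"`.
#' @param values named expression values; required for `weighting =
#'   "weighted"`.
#' @return the enrichment score, or `NA` when no member is present.
#' @export
es_score <- function(ranks, genes,
                     weighting = c("unweighted", "weighted"),
                     values = NULL) {
  weighting <- match.arg(weighting)
  n <- length(ranks)
  hit <- names(ranks) %in% genes
  m <- sum(hit)
  if (m == 0L) return(NA_real_)
  if (m == n)
    .stopf("es_score undefined when the set covers all %d ranked genes", n)
  ord <- order(ranks, decreasing = TRUE)   # walk from highest expression down
  hit <- hit[ord]
  step <- numeric(n)
  if (weighting == "unweighted") {
    step[hit] <- 1 / m
  } else {
    if (is.null(values))
      .stopf("weighted es_score needs the expression values")
    w <- abs(values[names(ranks)])[ord]
    step[hit] <- w[hit] / sum(w[hit])
  }
  step[!hit] <- -1 / (n - m)
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

# Column-wise mid-rank matrix; NAs stay NA and are excluded from n.
.rank_matrix <- function(x, mode = "signed") {
  R <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2L)
      .stopf("sample '%s' has fewer than 2 non-missing values", colnames(x)[j])
    R[ok, j] <- rank(if (mode == "absolute") abs(v[ok]) else v[ok],
                     ties.method = "average")
  }
  R
}

# AR profile of one gene set across all samples, from a precomputed rank
# matrix; per-sample n is the effective (non-missing) gene count.
.ar_profile <- function(R, genes, n_per_sample = colSums(!is.na(R))) {
  idx <- rownames(R) %in% genes
  if (!any(idx)) return(rep(NA_real_, ncol(R)))
  sub <- R[idx, , drop = FALSE]
  m <- colSums(!is.na(sub))
  p <- colSums(sub, na.rm = TRUE) / (m * n_per_sample)
  p[m == 0L] <- NA_real_
  p
}

#' Pathway activity matrix
#'
#' Scores every (pathway, sample) pair of a standardized expression matrix:
#' AR-scores (`"AR"`), AR-scores on absolute values for two-channel
#' log-ratios (`"AR_abs"`), or KS-like enrichment scores (`"ES"`).  The
#' per-sample total gene count n is recomputed per column when missingness
#' differs between samples; cells whose pathway has no measurable member in
#' a sample propagate as `NA`.
#'
#' @param x numeric matrix, genes x samples (standardized for one-channel
#'   data; log-ratios can be scored directly).
#' @param sets named list of gene sets, already restricted to the matrix
#'   (see [restrict_to_matrix()]).
#' @param score_type `"AR"`, `"AR_abs"` or `"ES"`.
#' @param es_weighting passed to [es_score()] for `score_type = "ES"`.
#' @return pathways x samples numeric matrix with a `score_type` attribute.
#' @export
activity_matrix <- function(x, sets,
                            score_type = c("AR", "AR_abs", "ES"),
                            es_weighting = "unweighted") {
  .check_matrix(x)
  score_type <- match.arg(score_type)
  if (!length(sets)) .stopf("empty gene-set collection")
  mode <- if (score_type == "AR_abs") "absolute" else "signed"
  R <- .rank_matrix(x, mode)
  if (score_type == "ES") {
    A <- matrix(NA_real_, length(sets), ncol(x),
                dimnames = list(names(sets), colnames(x)))
    for (j in seq_len(ncol(x))) {
      v <- x[, j]
      r <- R[!is.na(v), j]
      for (k in seq_along(sets))
        A[k, j] <- es_score(r, sets[[k]], es_weighting, values = v[names(r)])
    }
  } else {
    n_per <- colSums(!is.na(R))
    A <- t(vapply(sets, function(s) .ar_profile(R, s, n_per),
                  numeric(ncol(x))))
    dimnames(A) <- list(names(sets), colnames(x))
  }
  attr(A, "score_type") <- score_type
  A
}
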