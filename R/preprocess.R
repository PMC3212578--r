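# Gene-wise standardization and gene-set/matrix alignment.

#' Gene-wise standardization of an expression matrix
#'
#' Converts absolute expression values into relative levels by subtracting
#' each gene's mean and dividing by its standard deviation across samples
#' (sample sd, denominator n-1).  Required for one-channel data before
#' rank-based scoring; two-channel log-ratios are already relative and can
#' skip this step.  Genes with zero variance (or fewer than two non-missing
#' values) carry no relative information and are dropped with a warning.
#'
#' @param x numeric matrix, genes x samples, at least two samples.
#' @return the standardized matrix; dropped gene ids are available in the
#'   `dropped` attribute.
#' @export
standardize_genewise <- function(x) {
  .check_matrix(x)
  if (ncol(x) < 2L)
    .stopf("relative levels undefined with a single sample")
  n_ok <- rowSums(!is.na(x))
  mu <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1L, stats::sd, na.rm = TRUE)
  drop <- n_ok < 2L | is.na(s) | s == 0
  if (any(drop))
    warning(sprintf("dropping %d gene(s) with zero variance or <2 values: %s",
                    sum(drop),
                    paste(utils::head(rownames(x)[drop], 5L), collapse = ", ")),
            call. = FALSE)
  z <- (x[!drop, , drop = FALSE] - mu[!drop]) / s[!drop]
  attr(z, "dropped") <- rownames(x)[drop]
  z
}

#' Restrict a gene-set collection to the genes present in a matrix
#'
#' Pathway genes absent from the measured platform cannot be ranked; each set
#' is intersected with the matrix rows and sets falling below `min_genes`
#' mapped members are excluded.
#'
#' @param sets named list of character vectors.
#' @param x expression matrix whose rownames define the measurable genes.
#' @param min_genes minimum mapped set size to keep a set (default 5).
#' @return list with elements `sets` (the restricted collection, original
#'   order preserved) and `report` (data frame: set, n_original, n_mapped,
#'   kept).
#' @export
restrict_to_matrix <- function(sets, x, min_genes = 5L) {
  genes <- rownames(x)
  mapped <- lapply(sets, function(s) s[s %in% genes])
  n_mapped <- lengths(mapped)
  if (all(n_mapped == 0L))
    .stopf(paste("no gene-set member maps to the matrix;",
                 "likely an identifier-namespace mismatch"))
  kept <- n_mapped >= min_genes
  report <- data.frame(set = names(sets),
                       n_original = lengths(sets),
                       n_mapped = n_mapped,
                       kept = kept,
                       row.names = NULL,
                       stringsAsFactors = FALSE)
  out <- mapped[kept]
  attr(out, "description") <- attr(sets, "description")[names(out)]
  list(sets = out, report = report)
}
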