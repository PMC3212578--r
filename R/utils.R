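# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tokens treated as missing when parsing expression tables (case-insensitive).
.na_tokens <- c("", "na", "nan", "null")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    .stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stopf("%s must have row (gene/pathway) and column (sample) names", what)
  invisible(x)
}

# Coerce sample labels (named vector or two-column data.frame) into a factor
# aligned with `sample_ids`; exactly two groups, level order = order of
# appearance unless `groups` fixes it.  Group 1 is the reference: "up" means
# higher in group 1.
.align_labels <- function(labels, sample_ids, groups = NULL) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L)
      .stopf("label table needs two columns: sample id, group")
    labels <- stats::setNames(as.character(labels[[2L]]),
                              as.character(labels[[1L]]))
  }
  if (is.null(names(labels)))
    .stopf("labels must be named by sample id (or be a two-column table)")
  unknown <- setdiff(names(labels), sample_ids)
  if (length(unknown))
    .stopf("labeled sample(s) not in the matrix: %s",
           paste(utils::head(unknown, 5L), collapse = ", "))
  labels <- labels[intersect(sample_ids, names(labels))]
  lev <- groups %||% unique(unname(labels))
  if (length(lev) != 2L)
    .stopf("exactly two group labels required, found: %s",
           paste(unique(labels), collapse = ", "))
  labels <- labels[labels %in% lev]
  f <- factor(unname(labels), levels = lev)
  names(f) <- names(labels)
  if (any(table(f) < 1L)) .stopf("a group has no samples")
  f
}

#' Bimodality coefficient of a sample
#'
#' Sarle's bimodality coefficient \eqn{b = (g_1^2 + 1) / (g_2 + 3 (n-1)^2 /
#' ((n-2)(n-3)))}, where \eqn{g_1} is the sample skewness and \eqn{g_2} the
#' sample excess kurtosis.  Values above 5/9 (the uniform distribution's
#' coefficient) suggest bimodality; a normal sample gives about 1/3.  Used to
#' contrast the near-normal distribution of AR-scores with the bimodal
#' distribution of enrichment scores.
#'
#' @param x numeric vector (missing values dropped), length at least 4.
#' @return the bimodality coefficient, a single number.
#' @export
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) .stopf("need at least 4 finite values")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}
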