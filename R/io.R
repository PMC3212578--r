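# Readers and writers for the file formats the pipeline touches.  No
# computation lives here.

#' Read a gene-set collection in GMT format
#'
#' One set per line, tab-separated: set name, description, then member gene
#' identifiers (Broad dialect).  Duplicate genes within a line are collapsed;
#' set order follows line order.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors (one per set), with a
#'   `description` attribute carrying the second GMT column.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    .stopf("GMT parse error at line %d: fewer than 3 tab-separated fields",
           which(keep)[bad[1L]])
  nm <- vapply(fields, `[[`, character(1L), 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup))
    .stopf("GMT format error: duplicate set name '%s'", dup[1L])
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    unique(g[nzchar(g)])
  })
  if (any(lengths(sets) == 0L))
    .stopf("GMT format error: set '%s' has no genes",
           nm[which(lengths(sets) == 0L)[1L]])
  names(sets) <- nm
  attr(sets, "description") <-
    stats::setNames(vapply(fields, `[[`, character(1L), 2L), nm)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors; an optional `description`
#'   attribute supplies the second column (defaults to the set name).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
}

.parse_numeric_cells <- function(chr, gene_ids, sample_ids, path) {
  low <- tolower(trimws(chr))
  vals <- suppressWarnings(as.numeric(chr))
  bad <- is.na(vals) & !(low %in% .na_tokens)
  if (any(bad)) {
    i <- which(bad)[1L]
    r <- (i - 1L) %% length(gene_ids) + 1L
    cc <- (i - 1L) %/% length(gene_ids) + 1L
    .stopf("parse error in %s: non-numeric value '%s' at gene '%s', sample '%s'",
           path, chr[i], gene_ids[r], sample_ids[cc])
  }
  matrix(vals, nrow = length(gene_ids),
         dimnames = list(gene_ids, sample_ids))
}

# Duplicate gene ids are collapsed by keeping the row with the highest mean
# (probe-collapse convention); the choice is reported via message().
.collapse_duplicates <- function(x) {
  if (!anyDuplicated(rownames(x))) return(x)
  means <- rowMeans(x, na.rm = TRUE)
  ord <- order(rownames(x), -means)
  x <- x[ord, , drop = FALSE]
  dup <- duplicated(rownames(x))
  message(sprintf("collapsed %d duplicated gene id(s), keeping highest-mean rows",
                  sum(dup)))
  x[!dup, , drop = FALSE]
}

#' Read a gene expression matrix
#'
#' Supports plain TSV (first column gene id, header row of sample ids) and
#' GCT 1.2 (`#1.2` version line, dimensions line, Name/Description columns).
#' Blank, `NA`, `NaN` and `null` tokens (case-insensitive) become missing
#' values; duplicated gene ids are collapsed to the highest-mean row.
#'
#' @param path input path.
#' @param format `"tsv"` or `"gct"`.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("expression file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "gct") {
    if (length(lines) < 3L || !startsWith(trimws(lines[1L]), "#1.2"))
      .stopf("GCT format error in %s: missing '#1.2' version line", path)
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]),
                                                 "[\t ]+")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      .stopf("GCT format error in %s: bad dimensions line", path)
    body <- lines[-(1:2)]
    hdr <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    rows <- strsplit(body[-1L], "\t", fixed = TRUE)
    if (length(rows) != dims[1L])
      .stopf("GCT format error in %s: dims line says %d rows, found %d",
             path, dims[1L], length(rows))
    if (length(hdr) - 2L != dims[2L])
      .stopf("GCT format error in %s: dims line says %d samples, found %d",
             path, dims[2L], length(hdr) - 2L)
    gene_ids <- vapply(rows, `[[`, character(1L), 1L)
    sample_ids <- hdr[-(1:2)]
    cells <- t(vapply(rows, function(r) r[-(1:2)],
                      character(length(sample_ids))))
    if (length(sample_ids) == 1L) cells <- matrix(cells, ncol = 1L)
    x <- .parse_numeric_cells(as.vector(cells), gene_ids, sample_ids, path)
  } else {
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    rows <- rows[vapply(rows, function(r) any(nzchar(r)), logical(1L))]
    sample_ids <- hdr[-1L]
    gene_ids <- vapply(rows, `[[`, character(1L), 1L)
    cells <- t(vapply(rows, function(r) {
      v <- r[-1L]
      length(v) <- length(sample_ids)   # right-pad short rows with NA
      v
    }, character(length(sample_ids))))
    if (length(sample_ids) == 1L) cells <- matrix(cells, ncol = 1L)
    x <- .parse_numeric_cells(as.vector(cells), gene_ids, sample_ids, path)
  }
  .collapse_duplicates(x)
}

# Write a matrix as TSV with a leading id column; `header` lines (already
# "#"-prefixed) are prepended.
.write_matrix_tsv <- function(x, path, id_col, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  writeLines(paste(c(id_col, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
}

#' Write a pathway activity matrix (pathways x samples) as TSV
#'
#' @param activity numeric matrix, pathways in rows.
#' @param path output path.
#' @param header optional character vector of `#`-prefixed comment lines.
#' @export
write_activity <- function(activity, path, header = character()) {
  .check_matrix(activity, "activity matrix")
  .write_matrix_tsv(activity, path, "pathway", header)
}

#' Read back a matrix written by [write_activity()]
#'
#' @param path TSV path; `#` comment lines are skipped.
#' @return numeric matrix.
#' @export
read_activity <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Read sample group labels
#'
#' Two-column TSV (sample id, group label), with or without a header line.
#'
#' @param path input path.
#' @return named character vector of group labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .stopf("label file %s needs two columns", path)
  if (tolower(df[1L, 1L]) %in% c("sample", "sample_id", "id"))
    df <- df[-1L, , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a generic data frame as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @param header optional `#`-prefixed comment lines.
#' @export
write_table <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pathway co-regulation network
#'
#' TSV output is an edge list (`pathway_a`, `pathway_b`, `rho`, `sign`) with
#' `pathway_a < pathway_b` lexicographically; GraphML output goes through
#' igraph and carries `rho`/`sign` edge attributes and node sizes.
#'
#' @param network a `pathway_network` from [build_network()].
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @param header optional `#`-prefixed comment lines (TSV only).
#' @export
write_network <- function(network, path, format = c("tsv", "graphml"),
                          header = character()) {
  format <- match.arg(format)
  stopifnot(inherits(network, "pathway_network"))
  if (format == "tsv") {
    write_table(network$edges, path, header)
  } else {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("pathway_a", "pathway_b", "rho", "sign")],
      directed = FALSE, vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
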