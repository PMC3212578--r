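# Shared fixtures and small independent oracles, all built in code.

# A tiny named expression matrix.
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force AR-score: mean rank of members / n, ranks computed afresh.
brute_ar <- function(values, members) {
  r <- rank(values, ties.method = "average")
  mean(r[members]) / length(values)
}

# Brute-force mean pairwise Spearman over a set of gene rows.
brute_coexpr <- function(x, genes) {
  pairs <- utils::combn(genes, 2)
  mean(apply(pairs, 2, function(p)
    stats::cor(x[p[1], ], x[p[2], ], method = "spearman")))
}

# Brute-force shared-gene-excluded pathway correlation: rebuilds residual
# sets, re-ranks every sample and rank-correlates the two profiles.
brute_pair_cor <- function(setA, setB, x) {
  shared <- intersect(setA, setB)
  ra <- setdiff(setA, shared)
  rb <- setdiff(setB, shared)
  prof <- function(s) apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    mean(r[s]) / length(r)
  })
  stats::cor(prof(ra), prof(rb), method = "spearman")
}

# Plain Rand index of two flat clusterings.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- (same_a == same_b)
  (sum(agree) - n) / (n * (n - 1))
}

# A standardized matrix from pure exchangeable noise.
noise_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  suppressWarnings(standardize_genewise(
    toy_matrix(matrix(rnorm(n_genes * n_samples), n_genes))))
}

# Generate, standardize and score one simulated dataset; returns the pieces
# most tests need.
sim_pipeline <- function(cfg, score_type = "AR") {
  sim <- simulate_expression(cfg)
  z <- suppressWarnings(standardize_genewise(sim$expression))
  r <- restrict_to_matrix(sim$sets, z)
  A <- activity_matrix(z, r$sets, score_type)
  list(sim = sim, z = z, sets = r$sets, activity = A)
}
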