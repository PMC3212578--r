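# Synthetic expression data with known pathway structure.  A Gaussian factor
# model: every pathway has a per-sample latent activity; a single global
# factor induces exchangeable correlation gamma between all pathway latents
# (pathway coupling); member genes load on their pathway's latent with
# within-pathway correlation rho_w; designated pathway pairs share a
# fraction of member genes to exercise shared-gene exclusion; differential
# pathways shift their members' mean expression in the second condition.

#' Configuration for the synthetic expression generator
#'
#' Conditions are named by `n_samples` (default a "normal" and a "tumor"
#' group); `rho_w` and `gamma` may be scalars or per-condition vectors.  The
#' tumor defaults emulate the attenuation seen in cancer data: roughly
#' halved within-pathway co-expression and strongly reduced inter-pathway
#' coupling, with the first `n_diff` pathways shifted up by `delta`
#' marginal-sd units in the second condition.  All latent and noise
#' components have unit variance, so `delta` is an effect size in gene-sd
#' units and the implied correlation structure is positive semi-definite
#' for any `rho_w`, `gamma` in [0, 1).
#'
#' @param n_genes total genes (members plus pure-noise background).
#' @param n_pathways number of gene sets.
#' @param size_range inclusive range of set sizes.
#' @param n_samples named integer vector: samples per condition.
#' @param rho_w within-pathway gene correlation per condition, in [0, 1).
#' @param gamma exchangeable correlation between pathway latent activities
#'   per condition, in [0, 1).
#' @param n_diff number of differential pathways (the first `n_diff`).
#' @param delta mean shift of differential-pathway member genes in the
#'   second condition, in marginal-sd units.
#' @param n_overlap_pairs number of pathway pairs sharing genes (taken from
#'   the end of the pathway list).
#' @param overlap_frac fraction of the second pathway's genes shared with
#'   its partner.
#' @param noise_sd overall expression scale.
#' @param baseline_mean,baseline_sd per-gene baseline intensity (constant
#'   across samples; removed by gene-wise standardization).
#' @param seed RNG seed; identical configs generate identical data.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 4000, n_pathways = 100,
                       size_range = c(10, 30),
                       n_samples = c(normal = 30, tumor = 30),
                       rho_w = c(normal = 0.3, tumor = 0.15),
                       gamma = c(normal = 0.6, tumor = 0.2),
                       n_diff = 10, delta = 1,
                       n_overlap_pairs = 5, overlap_frac = 0.25,
                       noise_sd = 1, baseline_mean = 8, baseline_sd = 2,
                       seed = 1) {
  conds <- names(n_samples) %||% paste0("g", seq_along(n_samples))
  names(n_samples) <- conds
  rec <- function(v) stats::setNames(rep_len(unname(v), length(conds)), conds)
  rho_w <- rec(rho_w); gamma <- rec(gamma)
  if (any(rho_w < 0 | rho_w >= 1) || any(gamma < 0 | gamma >= 1))
    .stopf("infeasible correlation structure: rho_w and gamma must lie in [0, 1)")
  if (!is.finite(delta)) .stopf("delta must be finite")
  if (any(n_samples < 1) || n_genes < 1 || n_pathways < 1 ||
      any(size_range < 1) || size_range[1] > size_range[2])
    .stopf("sizes must be positive and size_range non-decreasing")
  if (n_diff > n_pathways) .stopf("n_diff exceeds n_pathways")
  if (2 * n_overlap_pairs > n_pathways)
    .stopf("too many overlap pairs for n_pathways")
  if (!(overlap_frac >= 0 && overlap_frac < 1))
    .stopf("overlap_frac must lie in [0, 1)")
  structure(list(n_genes = n_genes, n_pathways = n_pathways,
                 size_range = size_range, n_samples = n_samples,
                 rho_w = rho_w, gamma = gamma, n_diff = n_diff,
                 delta = delta, n_overlap_pairs = n_overlap_pairs,
                 overlap_frac = overlap_frac, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = seed),
            class = "sim_config")
}

#' Generate a synthetic expression dataset
#'
#' Draws an expression matrix, gene-set collection and sample labels from
#' the factor model described in [sim_config()], together with a ground
#' truth record (differential pathways, overlap pairs, the coupling and
#' co-expression parameters per condition).
#'
#' @param config a `sim_config`.
#' @return list with `expression` (genes x samples), `sets` (named list),
#'   `labels` (named character vector), `truth` (list).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_pathways
  conds <- names(config$n_samples)
  # sample() would misread a scalar range, so draw offsets explicitly
  sizes <- config$size_range[1] - 1L +
    sample.int(config$size_range[2] - config$size_range[1] + 1L,
               K, replace = TRUE)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  pw_ids <- sprintf("pw%03d", seq_len(K))

  # Membership: overlap pairs occupy the tail of the pathway list so they do
  # not collide with the differential pathways at the head.
  overlap_pairs <- if (config$n_overlap_pairs > 0)
    cbind(a = K - 2 * seq_len(config$n_overlap_pairs) + 1L,
          b = K - 2 * seq_len(config$n_overlap_pairs) + 2L)
  else cbind(a = integer(), b = integer())
  sets <- vector("list", K)
  primary <- integer(config$n_genes)      # driving pathway per gene (0 = noise)
  ptr <- 0L
  take <- function(n) {
    if (ptr + n > config$n_genes)
      .stopf("n_genes too small for the requested pathway sizes")
    idx <- ptr + seq_len(n); ptr <<- ptr + n; idx
  }
  for (k in seq_len(K)) {
    partner <- overlap_pairs[overlap_pairs[, "b"] == k, "a"]
    if (length(partner)) {
      o <- round(config$overlap_frac * sizes[k])
      shared <- utils::head(sets[[partner]], o)
      fresh <- take(sizes[k] - length(shared))
      primary[fresh] <- k
      sets[[k]] <- c(shared, fresh)
    } else {
      idx <- take(sizes[k])
      primary[idx] <- k
      sets[[k]] <- idx
    }
  }
  names(sets) <- pw_ids

  p_total <- sum(config$n_samples)
  sample_ids <- unlist(lapply(conds, function(cc)
    sprintf("%s_%02d", cc, seq_len(config$n_samples[[cc]]))))
  labels <- stats::setNames(rep(conds, config$n_samples), sample_ids)

  Z <- matrix(NA_real_, config$n_genes, p_total,
              dimnames = list(gene_ids, sample_ids))
  diff_pw <- seq_len(config$n_diff)
  col0 <- 0L
  for (ci in seq_along(conds)) {
    cc <- conds[ci]
    p <- config$n_samples[[cc]]
    gam <- config$gamma[[cc]]
    rw <- config$rho_w[[cc]]
    gfac <- stats::rnorm(p)                              # global factor
    A <- sqrt(gam) * matrix(gfac, K, p, byrow = TRUE) +
         sqrt(1 - gam) * matrix(stats::rnorm(K * p), K, p)
    E <- matrix(stats::rnorm(config$n_genes * p), config$n_genes, p)
    block <- E                                           # background genes
    in_pw <- primary > 0L
    block[in_pw, ] <- sqrt(rw) * A[primary[in_pw], , drop = FALSE] +
                      sqrt(1 - rw) * E[in_pw, , drop = FALSE]
    if (ci == 2L && config$n_diff > 0) {
      shifted <- primary %in% diff_pw
      block[shifted, ] <- block[shifted, ] + config$delta
    }
    Z[, col0 + seq_len(p)] <- block
    col0 <- col0 + p
  }
  baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                           config$baseline_sd)
  expr <- config$noise_sd * Z + baseline
  sets_named <- lapply(sets, function(idx) gene_ids[idx])
  truth <- list(diff_pathways = pw_ids[diff_pw],
                delta = config$delta,
                gamma = config$gamma,
                rho_w = config$rho_w,
                overlap_pairs = data.frame(
                  pathway_a = pw_ids[overlap_pairs[, "a"]],
                  pathway_b = pw_ids[overlap_pairs[, "b"]],
                  stringsAsFactors = FALSE),
                coupling = "exchangeable: all pathway latents share correlation gamma",
                seed = config$seed)
  list(expression = expr, sets = sets_named, labels = labels, truth = truth)
}
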