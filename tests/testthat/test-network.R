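test_that("pair correlation is +/-1 for monotonically related disjoint profiles", {
  # AR profiles are within-sample relative ranks, so the fixture pins a
  # constant background ladder and slides both sets up it in lockstep:
  # set A sits at 10j + 0.5 in sample j, set B just above at 10j + 0.7,
  # so both AR profiles increase strictly in j
  p <- 12
  bg <- matrix(rep(1:120, p), 120, p)                      # constant ladder
  setA_vals <- matrix(rep(10 * (1:p) + 0.5, each = 6), 6, byrow = FALSE)
  setB_vals <- matrix(rep(10 * (1:p) + 0.7, each = 6), 6, byrow = FALSE)
  x <- toy_matrix(rbind(setA_vals, setB_vals, bg))
  setA <- rownames(x)[1:6]; setB <- rownames(x)[7:12]
  expect_equal(corr_pair_excluding_shared(setA, setB, x)$rho, 1)
  x2 <- x
  x2[7:12, ] <- matrix(rep(10 * (p:1) + 0.7, each = 6), 6)  # decreasing in j
  expect_equal(corr_pair_excluding_shared(setA, setB, x2)$rho, -1)
})

test_that("pair correlation is symmetric and flags empty residual sets", {
  set.seed(22)
  x <- toy_matrix(matrix(rnorm(300), 30))
  setA <- rownames(x)[1:8]
  setB <- rownames(x)[5:20]
  r1 <- corr_pair_excluding_shared(setA, setB, x)
  r2 <- corr_pair_excluding_shared(setB, setA, x)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$n_shared, 4L)

  sub <- corr_pair_excluding_shared(rownames(x)[1:5], rownames(x)[1:12], x)
  expect_false(sub$evaluable)        # residual of the subset is empty
  expect_true(is.na(sub$rho))
  expect_match(sub$reason, "min_genes")
})

test_that("shared-gene exclusion matches a from-scratch oracle and equals the naive value for disjoint sets", {
  set.seed(23)
  x <- toy_matrix(matrix(rnorm(40 * 10), 40))
  genes <- rownames(x)
  sets <- list(P1 = genes[1:7], P2 = genes[5:12], P3 = genes[13:20],
               P4 = genes[21:28], P5 = genes[26:35], P6 = genes[33:40])
  for (i in 1:5) for (j in (i + 1):6) {
    res <- corr_pair_excluding_shared(sets[[i]], sets[[j]], x)
    if (res$evaluable)
      expect_equal(res$rho, brute_pair_cor(sets[[i]], sets[[j]], x))
  }
  # disjoint pair: exclusion is a no-op relative to the naive profiles
  pc <- pathway_cor(sets[c("P3", "P4")], x)
  naive <- stats::cor(
    apply(x, 2, function(col) mean(rank(col)[genes[13:20]]) / 40),
    apply(x, 2, function(col) mean(rank(col)[genes[21:28]]) / 40),
    method = "spearman")
  expect_equal(pc$rho["P3", "P4"], naive)
})

test_that("all_pairs evaluates exactly K(K-1)/2 pairs and returns a valid matrix", {
  set.seed(24)
  x <- toy_matrix(matrix(rnorm(50 * 8), 50))
  mk <- function(k) stats::setNames(
    lapply(seq_len(k), function(i) rownames(x)[(5 * i - 4):(5 * i)]),
    sprintf("pw%d", seq_len(k)))
  expect_equal(pathway_cor(mk(2), x)$n_pairs, 1)
  expect_equal(pathway_cor(mk(5), x)$n_pairs, 10)
  pc <- pathway_cor(mk(5), x)
  expect_true(isSymmetric(pc$rho))
  expect_equal(unname(diag(pc$rho)), rep(1, 5))
  expect_true(all(abs(pc$rho) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("network threshold is a strict inequality and isolated nodes are kept", {
  rho <- diag(4)
  nm <- sprintf("pw%d", 1:4)
  dimnames(rho) <- list(nm, nm)
  rho["pw1", "pw2"] <- rho["pw2", "pw1"] <- 0.75     # exactly tau: no edge
  rho["pw3", "pw4"] <- rho["pw4", "pw3"] <- 0.8
  pc <- structure(list(rho = rho, n_samples = 20L, n_pairs = 6L,
                       sizes = stats::setNames(rep(10L, 4), nm),
                       not_evaluable = data.frame(), min_genes = 5L),
                  class = "pathway_cor")
  net <- build_network(pc, 0.75)
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$pathway_a, "pw3")
  expect_identical(net$edges$sign, "positive")
  expect_equal(nrow(net$nodes), 4L)                  # isolated nodes retained
  net_all <- build_network(pc, 0.9)
  expect_equal(nrow(net_all$edges), 0L)
  expect_equal(nrow(net_all$nodes), 4L)
  expect_error(build_network(pc, 1.5), "tau")
})

test_that("compare_coupling handles identical matrices, sign-only differences and attenuation", {
  set.seed(25)
  nm <- sprintf("pw%d", 1:25)                        # 300 pairs
  K <- length(nm)
  r <- matrix(runif(K * K, -0.9, 0.9), K)
  r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(nm, nm)
  mk <- function(m) structure(list(rho = m, n_samples = 50L,
                                   n_pairs = K * (K - 1) / 2,
                                   sizes = stats::setNames(rep(10L, K), nm),
                                   not_evaluable = data.frame(),
                                   min_genes = 5L),
                              class = "pathway_cor")
  pcA <- mk(r)
  expect_equal(compare_coupling(pcA, pcA)$t, 0)
  expect_equal(compare_coupling(pcA, pcA)$p, 1)

  neg <- mk(-r + 2 * diag(K))                        # same |rho|, signs flipped
  expect_equal(compare_coupling(pcA, neg, mode = "abs")$t, 0)

  att <- mk(r * 0.5 + 0.5 * diag(K))                 # attenuated by half
  ct <- compare_coupling(pcA, att, mode = "abs")
  expect_gt(ct$t, 0)
  expect_lt(ct$p, 0.01)
  expect_gte(ct$n_pairs, 200)
  # swapping the arguments negates the paired t exactly
  expect_equal(compare_coupling(att, pcA, mode = "abs")$t, -ct$t)
  expect_error(compare_coupling(mk(r[1:2, 1:2]), mk(r[1:2, 1:2])),
               "fewer than 3")
})

test_that("median coupled-pair correlation rises monotonically with gamma", {
  # pathway genes are kept a small fraction of the universe: ranking is a
  # within-sample relative measure, so coupling shared by most genes would
  # partly cancel out of the rank profiles
  med <- sapply(c(0, 0.3, 0.6, 0.9), function(g) {
    cfg <- sim_config(n_genes = 3000, n_pathways = 12,
                      n_samples = c(all = 120), rho_w = 0.7, gamma = g,
                      n_diff = 0, n_overlap_pairs = 0, seed = 31)
    pp <- sim_pipeline(cfg)
    pc <- pathway_cor(pp$sets, pp$z)
    median(abs(pc$rho[upper.tri(pc$rho)]))
  })
  expect_true(all(diff(med) > 0))
})
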