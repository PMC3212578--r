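make_activity <- function(g1_vals, g2_vals) {
  n1 <- length(g1_vals); n2 <- length(g2_vals)
  A <- toy_matrix(matrix(c(g1_vals, g2_vals), 1),
                  genes = "pw1",
                  samples = sprintf("s%d", seq_len(n1 + n2)))
  labels <- stats::setNames(rep(c("a", "b"), c(n1, n2)), colnames(A))
  list(A = A, labels = labels)
}

test_that("t-test table is null-calibrated on equal groups and finds planted shifts", {
  set.seed(41)
  d <- make_activity(rnorm(200, 0.5, 0.01), rnorm(200, 0.5, 0.01))
  dt <- t_test_pathways(d$A, d$labels)
  expect_lt(abs(dt$t[1]), 2.6)
  expect_gt(dt$p[1], 0.01)

  # near-complete separation: closed-form large t, tiny P
  set.seed(42)
  d2 <- make_activity(0.8 + rnorm(5, sd = 1e-3), 0.2 + rnorm(5, sd = 1e-3))
  dt2 <- t_test_pathways(d2$A, d2$labels)
  expect_gt(dt2$t[1], 0)
  expect_lt(dt2$p[1], 1e-6)
  expect_identical(dt2$direction[1], "up")
  # agreement with a direct t.test call on the same numbers
  ref <- stats::t.test(d2$A[1, 1:5], d2$A[1, 6:10])
  expect_equal(dt2$t[1], unname(ref$statistic))
  expect_equal(dt2$p[1], ref$p.value)
})

test_that("planted differential pathways are recovered at Q < 0.01", {
  cfg <- sim_config(n_pathways = 100, n_samples = c(normal = 30, tumor = 30),
                    n_diff = 10, delta = 1, n_overlap_pairs = 0, seed = 43)
  pp <- sim_pipeline(cfg)
  dt <- t_test_pathways(pp$activity, pp$sim$labels,
                        groups = c("tumor", "normal"))
  called <- dt$pathway[dt$q < 0.01]
  expect_gte(length(intersect(called, pp$sim$truth$diff_pathways)), 9)
  expect_lte(length(setdiff(called, pp$sim$truth$diff_pathways)), 2)
  # planted pathways are shifted up in tumors
  expect_true(all(dt$direction[dt$pathway %in% called[called %in%
    pp$sim$truth$diff_pathways]] == "up"))
})

test_that("direction labels flip exactly when the group order is swapped", {
  cfg <- sim_config(n_genes = 600, n_pathways = 20,
                    n_samples = c(normal = 10, tumor = 10),
                    n_diff = 4, delta = 1.5, n_overlap_pairs = 0, seed = 44)
  pp <- sim_pipeline(cfg)
  d1 <- t_test_pathways(pp$activity, pp$sim$labels,
                        groups = c("normal", "tumor"))
  d2 <- t_test_pathways(pp$activity, pp$sim$labels,
                        groups = c("tumor", "normal"))
  m <- match(d1$pathway, d2$pathway)
  expect_equal(d1$t, -d2$t[m])
  expect_identical(ifelse(d1$direction == "up", "down", "up"),
                   d2$direction[m])
})

test_that("Wilcoxon table reproduces the exact rank-sum P under complete separation", {
  d <- make_activity(c(0.9, 0.85, 0.8, 0.75, 0.7),
                     c(0.3, 0.25, 0.2, 0.15, 0.1))
  wt <- wilcoxon_pathways(d$A, d$labels)
  expect_equal(wt$p[1], 2 / choose(10, 5))           # exact enumeration
  expect_identical(wt$direction[1], "up")

  set.seed(45)
  dn <- make_activity(rnorm(100), rnorm(100))
  expect_gt(wilcoxon_pathways(dn$A, dn$labels)$p[1], 0.01)
})

test_that("Wilcoxon-on-ES and t-on-AR call concordant pathway sets on strong shifts", {
  cfg <- sim_config(n_genes = 2500, n_pathways = 50,
                    n_samples = c(normal = 30, tumor = 30),
                    n_diff = 10, delta = 2, n_overlap_pairs = 0, seed = 46)
  pp_ar <- sim_pipeline(cfg, "AR")
  es <- activity_matrix(pp_ar$z, pp_ar$sets, "ES")
  dt_ar <- t_test_pathways(pp_ar$activity, pp_ar$sim$labels,
                           groups = c("tumor", "normal"))
  dt_es <- wilcoxon_pathways(es, pp_ar$sim$labels,
                             groups = c("tumor", "normal"))
  call_ar <- dt_ar$pathway[dt_ar$q < 0.01]
  call_es <- dt_es$pathway[dt_es$q < 0.01]
  jaccard <- length(intersect(call_ar, call_es)) /
             length(union(call_ar, call_es))
  expect_gt(jaccard, 0.6)
})

test_that("Storey q-values: BH oracle at pi0 = 1, uniform-p pi0 in [0.85, 1], monotone", {
  set.seed(47)
  p <- runif(1000)
  expect_equal(as.numeric(storey_qvalue(p, pi0 = 1)),
               p.adjust(p, "BH"))
  q <- storey_qvalue(p)
  pi0 <- attr(q, "pi0")
  expect_gte(pi0, 0.85)
  expect_lte(pi0, 1)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))           # monotone in P
  expect_true(all(q >= 0 & q <= 1))
  # q >= pi0 * BH by construction
  expect_true(all(q - pi0 * p.adjust(p, "BH") >= -1e-12))

  expect_equal(as.numeric(storey_qvalue(rep(1, 20))), rep(1, 20))
  expect_error(storey_qvalue(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Storey pi0 drops below 1 when true effects are present", {
  set.seed(48)
  p <- c(runif(800), rbeta(200, 0.2, 8))             # 20% non-null
  q <- storey_qvalue(p)
  expect_lt(attr(q, "pi0"), 0.95)
  expect_lte(sum(q < 0.01), sum(p.adjust(p, "BH") < 0.01) + 50)
})

test_that("type-I error of pathway t-tests is nominal on independent-gene nulls", {
  cfg <- sim_config(n_pathways = 100, n_samples = c(a = 30, b = 30),
                    rho_w = 0, gamma = 0, n_diff = 0,
                    n_overlap_pairs = 0, seed = 49)
  pp <- sim_pipeline(cfg)
  dt <- t_test_pathways(pp$activity, pp$sim$labels)
  frac <- mean(dt$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 100) + 1e-9)
})

test_that("fraction_upregulated matches its definition on shifted and null designs", {
  set.seed(50)
  n <- 20
  x <- toy_matrix(matrix(rnorm(30 * n), 30))
  x[1:5, 11:20] <- x[1:5, 11:20] - 3                 # genes 1-5 up in group a
  labels <- stats::setNames(rep(c("a", "b"), each = 10), colnames(x))
  sets <- list(Up = rownames(x)[1:5], Null = rownames(x)[6:30])
  fu <- fraction_upregulated(x, labels, sets, p_cut = 0.001)
  expect_equal(fu$frac_up_all[fu$pathway == "Up"], 1)
  expect_equal(fu$frac_up_sig[fu$pathway == "Up"], 1)
  expect_lt(abs(fu$frac_up_all[fu$pathway == "Null"] - 0.5), 0.35)
  # vacuous filter: both fractions identical at p_cut = 1
  fu1 <- fraction_upregulated(x, labels, sets, p_cut = 1.0)
  expect_equal(fu1$frac_up_all, fu1$frac_up_sig)
  # no member passing the cut -> fraction (ii) missing
  fu0 <- fraction_upregulated(x, labels, sets["Null"], p_cut = 1e-12)
  expect_true(is.na(fu0$frac_up_sig))
})

test_that("t-score consistency is 1 for identical tables and -1 for negated ones", {
  tab <- data.frame(pathway = sprintf("pw%d", 1:10), t = rnorm(10))
  expect_equal(tscore_consistency(tab, tab), 1)
  neg <- tab; neg$t <- -neg$t
  expect_equal(tscore_consistency(tab, neg), -1)
  expect_error(tscore_consistency(tab[1:2, ], tab[1:2, ]), "fewer than 3")
})

test_that("pathway t-scores replicate across datasets better than gene t-scores", {
  run <- function(seed) {
    cfg <- sim_config(n_genes = 1500, n_pathways = 40,
                      n_samples = c(normal = 25, tumor = 25),
                      n_diff = 8, delta = 0.8, n_overlap_pairs = 0,
                      seed = seed)
    pp <- sim_pipeline(cfg)
    dt <- t_test_pathways(pp$activity, pp$sim$labels,
                          groups = c("tumor", "normal"))
    # gene-level t on the same data
    gt <- t_test_pathways(pp$z, pp$sim$labels, groups = c("tumor", "normal"))
    list(pw = dt, gene = gt)
  }
  a <- run(51); b <- run(52)                         # same truth, fresh noise
  r_pw <- tscore_consistency(a$pw, b$pw)
  r_gene <- tscore_consistency(a$gene, b$gene)
  expect_gt(r_pw, r_gene)
})
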