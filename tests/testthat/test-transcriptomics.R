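test_that("parcel summarization matches hand-computed means", {
  sp <- tiny_space(100, 7, 10)
  u <- rep(2, 100)
  expect_equal(parcellate_map(u, sp), rep(2, 10))

  # parcel-constant map: exact constants recovered
  v <- numeric(100)
  lh <- sp$structure == "cortex-L"
  v[lh] <- sp$parcel[lh] + 10
  expect_equal(parcellate_map(v, sp), 10 + 0:9)

  # random map against explicit per-parcel means
  set.seed(18)
  m <- rnorm(100)
  oracle <- vapply(0:9, function(p)
    mean(m[lh & !is.na(sp$parcel) & sp$parcel == p]), numeric(1))
  expect_lt(max(abs(parcellate_map(m, sp) - oracle)), 1e-12)
})

test_that("gene map correlations rank by brute-force sort", {
  sp <- tiny_space(100, 7, 10)
  set.seed(19)
  P <- 50
  ref <- rnorm(P)
  vals <- rbind(ref, -ref,
                matrix(rnorm(48 * P), 48))
  vals <- t(apply(vals, 1, function(x) (x - mean(x)) / sd(x)))
  ex <- expression_matrix(c("TARGET", "ANTI", sprintf("g%02d", 3:50)), vals)
  gm <- gene_map_correlations(ref, ex, targets = c("TARGET", "ANTI"))
  expect_equal(unname(gm$r["TARGET"]), 1, tolerance = 1e-12)
  expect_equal(unname(gm$percentile["TARGET"]), 100)
  expect_equal(unname(gm$percentile["ANTI"]), 0)
  # percentile equals the brute-force sort rank for every gene
  gm_all <- gene_map_correlations(ref, ex, targets = ex$genes)
  brute <- 100 * (rank(gm_all$r, ties.method = "min") - 1) /
    (length(gm_all$r) - 1)
  expect_equal(unname(gm_all$percentile), unname(brute))
  # correlations are affine-invariant in the parcel map
  gm2 <- gene_map_correlations(3 * ref + 7, ex, targets = "TARGET")
  expect_equal(gm2$r, gm$r, tolerance = 1e-12)
  # zero-variance gene is masked
  vals2 <- vals; vals2[5, ] <- 0
  ex2 <- expression_matrix(ex$genes, vals2)
  expect_true(is.na(gene_map_correlations(ref, ex2)$r[5]))
})

test_that("dependent-correlation comparison matches the reference", {
  expect_equal(compare_dependent_correlations(0.5, 0.5, 0.3, 100)$z, 0)
  expect_equal(compare_dependent_correlations(0.5, 0.5, 0.3, 100)$p, 1)
  # monotonicity in the gap
  z1 <- abs(compare_dependent_correlations(0.5, 0.4, 0.3, 100)$z)
  z2 <- abs(compare_dependent_correlations(0.6, 0.3, 0.3, 100)$z)
  expect_gt(z2, z1)
  # random grid of feasible correlation triples against the independently
  # coded oracle (triples sampled from actual trivariate data)
  set.seed(20)
  for (i in 1:50) {
    X <- matrix(rnorm(60), 20, 3) %*% matrix(runif(9, -1, 1), 3)
    R <- cor(X)
    n <- sample(10:500, 1)
    got <- compare_dependent_correlations(R[1, 3], R[2, 3], R[1, 2], n)$z
    expect_equal(got, steiger_oracle(R[1, 3], R[2, 3], R[1, 2], n),
                 tolerance = 1e-8)
  }
  expect_error(compare_dependent_correlations(1, 0.5, 0.3, 50),
               "degenerate")
  expect_error(compare_dependent_correlations(0.9, -0.9, 0.9, 50),
               "infeasible")
  # table helper applies the Bonferroni multiplier
  tab <- compare_dependent_correlations_table(
    data.frame(r_ag = c(0.5, 0.2), r_bg = c(0.1, 0.2),
               r_ab = c(0.3, 0.3)), n = 180)
  expect_equal(tab$p_bonferroni, pmin(1, 2 * tab$p_raw))
})

test_that("expression network summary localizes loaded genes", {
  sp <- tiny_space(100, 7, 10)
  P <- 10
  lh <- sp$structure == "cortex-L"
  parcel_net <- vapply(0:(P - 1), function(p) {
    m <- !is.na(sp$parcel) & sp$parcel == p
    names(sort(table(as.character(sp$network)[m]),
               decreasing = TRUE))[1]
  }, character(1))
  target_net <- "default"
  g0 <- ifelse(parcel_net == target_net, 2, -0.5)
  g0 <- (g0 - mean(g0)) / sd(g0)
  set.seed(21)
  g2 <- as.numeric(scale(rnorm(P)))
  g1 <- -g0 + rnorm(P, 0, 0.1)
  g1 <- (g1 - mean(g1)) / sd(g1)
  ex <- expression_matrix(c("HI", "ANTIHI", "RAND"), rbind(g0, g1, g2))
  su <- expression_network_summary(ex, sp)
  expect_equal(names(which.max(su$network_means["HI", ])), target_net)
  expect_lt(su$gene_cor["HI", "ANTIHI"], -0.9)
  expect_equal(diag(su$gene_cor), rep(1, 3), ignore_attr = TRUE)
})

test_that("optional permutation p-value separates real from null genes", {
  sp <- tiny_space(100, 7, 10)
  set.seed(22)
  ref <- rnorm(60)
  ex <- simulate_expression(sp, ref, n_genes = 50, r_target = 0.9,
                            seed = 4)
  gm <- gene_map_correlations(ref, ex,
                              targets = c("GENE_TARGET", "GENE_0010"),
                              n_perm = 200)
  expect_lt(gm$perm_p[["GENE_TARGET"]], 0.05)
  expect_gt(gm$perm_p[["GENE_0010"]], 0.05)
})
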