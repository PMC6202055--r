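test_that("TFCE matches a literal threshold-sum oracle", {
  skip_if_not_installed("igraph")
  set.seed(11)
  # 50-node ring
  ring <- tiny_space(50, 1, 4)
  stat <- rnorm(50)
  expect_lt(max(abs(tfce(stat, ring) -
                      tfce_oracle(stat, ring$edges))), 1e-9)
  # random sparse graph on 80 nodes
  n <- 80
  e <- unique(t(apply(matrix(sample(n, 240, TRUE), ncol = 2), 1, sort)))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  csr <- local({
    from <- c(e[, 1], e[, 2]); to <- c(e[, 2], e[, 1])
    o <- order(from, to)
    list(ptr = as.integer(c(0, cumsum(tabulate(from[o], n)))),
         idx = as.integer(to[o] - 1L))
  })
  stat2 <- rnorm(n, sd = 2)
  expect_lt(max(abs(tfce(stat2, csr) - tfce_oracle(stat2, e))), 1e-9)
})

test_that("TFCE is zero on zero maps and monotone under scaling", {
  ring <- tiny_space(60, 1, 4)
  expect_identical(tfce(numeric(60), ring), numeric(60))
  set.seed(12)
  stat <- rnorm(60)
  t1 <- tfce(stat, ring)
  t2 <- tfce(1.7 * stat, ring)
  expect_true(all(abs(t2) >= abs(t1) - 1e-12))
  expect_equal(sign(t1), sign(t2))
  expect_error(tfce(stat, ring, dh = -1), "dh")
})

test_that("paired contrast handles identity and detects injected effects", {
  sp <- tiny_space(100, 7, 5)
  set.seed(13)
  A <- matrix(rnorm(20 * 100), 20)
  cr0 <- paired_contrast(A, A, sp, n_perm = 200, seed = 1)
  expect_equal(cr0$z, rep(0, 100))
  expect_equal(sum(cr0$sig_mask_pos) + sum(cr0$sig_mask_neg), 0L)

  # 1-SD mean shift in 20 contiguous grayordinates: the region is detected
  # (a sizeable share of its grayordinates survives FWE correction) while
  # nothing outside its dilation is flagged
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    A <- matrix(rnorm(20 * 100), 20)
    B <- matrix(rnorm(20 * 100), 20)
    B[, 31:50] <- B[, 31:50] + 1
    cr <- paired_contrast(A, B, sp, n_perm = 300, seed = s)
    mean(cr$sig_mask_neg[31:50]) >= 0.35 &&
      !any(cr$sig_mask_neg[c(1:28, 53:100)])
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # determinism under a fixed seed
  cr1 <- paired_contrast(A, A + 0.1, sp, n_perm = 150, seed = 9)
  cr2 <- paired_contrast(A, A + 0.1, sp, n_perm = 150, seed = 9)
  expect_identical(cr1$fwe_p, cr2$fwe_p)
  expect_error(paired_contrast(A[1:3, ], A[1:3, ], sp, 200), "5 subjects")
})

test_that("condition main effect is null-calibrated and powered", {
  sp <- tiny_space(100, 7, 5)
  set.seed(14)
  same <- matrix(rnorm(12 * 100), 12)
  cr <- main_effect_contrast(list(same, same, same), sp, n_perm = 150,
                             seed = 2)
  expect_equal(cr$F, rep(0, 100))
  # effect in one condition only
  hits <- vapply(1:10, function(s) {
    set.seed(200 + s)
    m <- lapply(1:3, function(i) matrix(rnorm(20 * 100), 20))
    m[[2]][, 11:25] <- m[[2]][, 11:25] + 1
    cr <- main_effect_contrast(m, sp, n_perm = 300, seed = s)
    mean(cr$sig_mask_pos[11:25]) >= 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(main_effect_contrast(list(same, same, same[1:3, ]), sp, 200),
               "missing cell")
})

test_that("mask means and change-score correlation are exact", {
  maps <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(0, 0, 4, 4))
  expect_equal(mask_means(maps, c(TRUE, FALSE, TRUE, FALSE)),
               c(2, 6, 2))
  expect_equal(mask_means(maps, 2L), c(2, 6, 0))
  expect_error(mask_means(maps, rep(FALSE, 4)), "empty mask")

  x <- rnorm(100)
  expect_equal(change_score_correlation(x, x)$r, 1)
  y <- -x + rnorm(100, 0, 0.1)
  expect_lt(change_score_correlation(x, y)$r, -0.95)
  expect_error(change_score_correlation(x, rep(1, 100)), "zero variance")
})

test_that("spatial correlation equals the direct formula", {
  set.seed(15)
  a <- rnorm(500); b <- rnorm(500)
  expect_equal(spatial_correlation(a, b), cor(a, b), tolerance = 1e-12)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), -1)
  m <- c(rep(TRUE, 250), rep(FALSE, 250))
  expect_equal(spatial_correlation(a, b, m), cor(a[1:250], b[1:250]),
               tolerance = 1e-12)
  expect_error(spatial_correlation(a, b[1:10]), "mismatched")
})

test_that("rank conjunction equals brute-force set intersection", {
  set.seed(16)
  maps <- replicate(4, rnorm(200), simplify = FALSE)
  cj <- top_bottom_conjunction(maps, 0.10)
  k <- floor(0.10 * 200)
  brute <- function(decreasing) Reduce(intersect, lapply(maps, function(m)
    order(m, decreasing = decreasing)[seq_len(k)]))
  expect_setequal(which(cj$top), brute(TRUE))
  expect_setequal(which(cj$bottom), brute(FALSE))

  # identical maps: conjunction is that map's top/bottom decile
  same <- replicate(4, maps[[1]], simplify = FALSE)
  cjs <- top_bottom_conjunction(same, 0.10)
  expect_equal(sum(cjs$top), k)
  expect_equal(sum(cjs$bottom), k)
  expect_false(any(cjs$top & cjs$bottom))

  # disjoint top ranks: empty top conjunction
  m1 <- c(rep(1, 100), rep(0, 100))
  m2 <- c(rep(0, 100), rep(1, 100))
  cjd <- top_bottom_conjunction(list(m1 + seq(0, 1e-3, length.out = 200),
                                     m2 + seq(0, 1e-3, length.out = 200)),
                                0.10)
  expect_equal(sum(cjd$top), 0L)

  # deterministic tie-breaking by lower index
  tied <- list(c(rep(1, 25), rep(0, 25)), c(rep(1, 25), rep(0, 25)))
  cjt <- top_bottom_conjunction(tied, 0.10)
  expect_identical(which(cjt$top), 1:5)
  expect_identical(which(cjt$bottom), 26:30)
  # fully tied input degenerates with a warning, keeping sets disjoint
  expect_warning(cjd2 <- top_bottom_conjunction(list(rep(1, 50),
                                                     rep(1, 50)), 0.10),
                 "degenerate ties")
  expect_false(any(cjd2$top & cjd2$bottom))
  expect_error(top_bottom_conjunction(maps, 0.6), "fraction")
})

test_that("network means aggregate per label", {
  sp <- tiny_space(100, 7, 5)
  u <- rep(3.5, 100)
  nm <- network_means(u, sp)
  expect_true(all(nm == 3.5))
  v <- numeric(100)
  v[sp$network == "limbic"] <- 2
  nm2 <- network_means(v, sp)
  expect_equal(unname(nm2["limbic"]), 2)
  expect_true(all(nm2[setdiff(names(nm2), "limbic")] == 0))
  # hand-computed toy value
  w <- seq_len(100) / 10
  expect_equal(unname(nm2["visual"] * 0 + network_means(w, sp)["visual"]),
               mean(w[sp$network == "visual"]))
})

test_that("symptom correlations apply the Bonferroni rule", {
  set.seed(17)
  d <- matrix(rnorm(24 * 7), 24, 7,
              dimnames = list(NULL, paste0("n", 1:7)))
  sc <- d[, 3] * 2 + rnorm(24, 0, 0.1)
  tab <- symptom_correlations(d, sc)
  expect_equal(tab$p_bonferroni, pmin(1, 7 * tab$p_raw))
  expect_lt(tab$p_bonferroni[3], 0.05)
  expect_error(symptom_correlations(d, rep(1, 24)), "constant")
  # uncoupled scores: rarely significant after correction
  frac_sig <- mean(replicate(20, {
    any(symptom_correlations(matrix(rnorm(24 * 7), 24), rnorm(24))$
          p_bonferroni < 0.05)
  }))
  expect_lte(frac_sig, 0.2)
})
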