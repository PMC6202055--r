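test_that("fisher transform is exact, odd, and clipped", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "exceeds 1")
})

test_that("GBC matches the hand-computed duplicate-pair case", {
  # two perfectly correlated pairs, pairs mutually orthogonal sinusoids
  T <- 64
  t <- seq_len(T)
  s1 <- sin(2 * pi * 4 * t / T)
  s2 <- cos(2 * pi * 4 * t / T)
  bold <- cbind(s1, 2 * s1, s2, 3 * s2)
  g <- gbc_map(bold)
  expected <- (atanh(1 - 1e-7) + 0 + 0) / 3
  expect_equal(unname(g), rep(expected, 4), tolerance = 1e-10)

  # negating one series negates only its own GBC when other pairs are 0
  bold2 <- cbind(s1, s2, sin(2 * pi * 8 * t / T))
  g2 <- gbc_map(bold2)
  g2n <- gbc_map(cbind(-bold2[, 1], bold2[, -1]))
  expect_equal(g2n[1], -g2[1], tolerance = 1e-10)
  expect_equal(g2n[-1], g2[-1], tolerance = 1e-10)
})

test_that("blocked GBC equals the dense computation", {
  set.seed(5)
  bold <- matrix(rnorm(100 * 500), 100)
  dense <- {
    R <- cor(bold)
    Fz <- atanh(pmin(pmax(R, -(1 - 1e-7)), 1 - 1e-7))
    diag(Fz) <- 0
    rowSums(Fz) / 499
  }
  for (bs in c(7L, 64L, 512L, 1000L))
    expect_lt(max(abs(gbc_map(bold, block_size = bs) - dense)), 1e-10)
  # covariance method against dense cov
  Cv <- cov(bold); diag(Cv) <- 0
  expect_lt(max(abs(gbc_map(bold, method = "covariance") -
                      rowSums(Cv) / 499)), 1e-10)
})

test_that("GBC on independent noise is near zero and masks degeneracy", {
  set.seed(6)
  g <- gbc_map(matrix(rnorm(2000 * 50), 2000))
  expect_lt(mean(abs(g)), 0.01)
  bold <- matrix(rnorm(40 * 5), 40)
  bold[, 3] <- 2
  expect_warning(gm <- gbc_map(bold), "zero-variance")
  expect_true(is.nan(gm[3]))
  expect_true(all(is.finite(gm[-3])))
})

test_that("correlation GBC is affine-invariant, covariance GBC is not", {
  set.seed(7)
  bold <- matrix(rnorm(60 * 20), 60)
  scl <- runif(20, 0.5, 3)
  shifted <- sweep(sweep(bold, 2, scl, "*"), 2, runif(20, -5, 5), "+")
  expect_equal(gbc_map(shifted), gbc_map(bold), tolerance = 1e-10)
  expect_gt(max(abs(gbc_map(shifted, method = "covariance") -
                      gbc_map(bold, method = "covariance"))), 0.01)
})

test_that("seed maps match dense oracles and scale properties", {
  set.seed(8)
  bold <- matrix(rnorm(30 * 200), 30)
  seed_idx <- c(5L, 9L, 100L)
  s <- rowMeans(bold[, seed_idx])
  oracle <- atanh(pmin(pmax(as.numeric(cor(s, bold)), -(1 - 1e-7)),
                       1 - 1e-7))
  expect_lt(max(abs(seed_fc_map(bold, seed_idx) - oracle)), 1e-10)

  # single-grayordinate seed equals that row of the correlation matrix
  one <- seed_fc_map(bold, 5L)
  expect_lt(max(abs(one - atanh(pmin(pmax(cor(bold)[5, ], -(1 - 1e-7)),
                                     1 - 1e-7)))), 1e-10)
  expect_equal(one[5], atanh(1 - 1e-7))

  # doubling a target doubles covariance, leaves correlation unchanged
  bold2 <- bold
  bold2[, 20] <- 2 * bold2[, 20]
  expect_equal(seed_fc_map(bold2, seed_idx, method = "covariance")[20],
               2 * seed_fc_map(bold, seed_idx,
                               method = "covariance")[20],
               tolerance = 1e-10)
  expect_equal(seed_fc_map(bold2, seed_idx)[20],
               seed_fc_map(bold, seed_idx)[20], tolerance = 1e-10)
  expect_error(seed_fc_map(bold, integer(0)), "empty seed")
})

test_that("GS beta map recovers the injected topography", {
  sp <- tiny_space(300, 7, 10)
  set.seed(9)
  T <- 240
  g <- rnorm(T)
  w <- runif(300, 0.5, 1.5)
  bold <- tcrossprod(g, w) + matrix(rnorm(T * 300, 0, 0.1), T)
  b <- gs_beta_map(bold, sp)
  # betas recover w up to the mean gray-matter weight scale
  w_eff <- w / mean(w[gray_mask(sp)])
  expect_lt(sqrt(mean((b - w_eff)^2)), 0.1)

  # identical series everywhere: every beta is 1
  bold_same <- matrix(rep(rnorm(T), 300), T)
  expect_equal(gs_beta_map(bold_same, sp), rep(1, 300), tolerance = 1e-10)

  # adding a GS-orthogonal signal to a grayordinate outside the gray mask
  # (so the GS itself is untouched) leaves its beta unchanged
  gs <- rowMeans(bold[, gray_mask(sp)])
  orth <- residuals(lm(rnorm(T) ~ gs))
  k <- which(!gray_mask(sp))[1]
  bold3 <- bold
  bold3[, k] <- bold3[, k] + orth
  expect_lt(abs(gs_beta_map(bold3, sp)[k] - b[k]), 1e-10)
  expect_error(gs_beta_map(matrix(1, 40, 300), sp), "zero-variance")
})

test_that("variance summaries obey their closed forms", {
  sp <- tiny_space(300, 7, 10)
  set.seed(10)
  bold <- matrix(rnorm(240 * 300), 240)
  vs <- variance_summaries(bold, sp)
  expect_true(all(abs(vs$local_var - 1) < 0.4))
  expect_equal(mean(vs$local_var), 1, tolerance = 0.02)
  # variance of the mean of G iid unit-variance series ~ 1/G
  G_gm <- sum(gray_mask(sp))
  expect_equal(vs$gs_variance, 1 / G_gm, tolerance = 3 / G_gm)
  cst <- variance_summaries(matrix(5, 20, 300), sp)
  expect_true(all(cst$local_var == 0))
  expect_equal(cst$gs_variance, 0)
})
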