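test_that("high-pass filter has the required frequency response", {
  T <- 240L; tr <- 2.5
  t <- (seq_len(T) - 1) * tr
  amp_ratio <- function(f) {
    x <- matrix(sin(2 * pi * f * t))
    y <- highpass_filter(x, 0.008, tr = tr)
    # FFT amplitude at the probe frequency, output over input
    k <- round(f * T * tr) + 1L
    abs(fft(y[, 1]))[k] / abs(fft(x[, 1]))[k]
  }
  expect_gt(amp_ratio(0.05), 0.95)            # passband
  expect_gt(amp_ratio(4 * 0.008)^2, 0.9)      # power at 4x cutoff
  expect_lt(amp_ratio(0.002), 0.2)            # stopband
  expect_lt(amp_ratio(0.008 / 4)^2, 0.05)     # power at cutoff/4
  # constant series -> zeros (mean removal)
  expect_equal(highpass_filter(matrix(7, T, 2), 0.008, tr = tr),
               matrix(0, T, 2))
  expect_error(highpass_filter(matrix(rnorm(T)), 0.3, tr = tr), "Nyquist")
})

test_that("design matrix has the documented columns and drop rules", {
  run <- manual_run(T = 40)
  run$bold <- run$bold + rnorm(length(run$bold))
  run$motion <- matrix(rnorm(240), 40, 6)
  run$ventricle_ts <- rnorm(40)
  run$wm_ts <- rnorm(40)
  X <- build_design(run, include_gs = FALSE)
  expect_equal(ncol(X), 17L)  # 1 + 8 + 8
  expect_equal(colnames(X)[1:3], c("intercept", "ventricle", "wm"))
  gs <- rnorm(40)
  Xg <- build_design(run, include_gs = TRUE, gs = gs)
  expect_equal(ncol(Xg), 19L)
  expect_true(all(c("gs", "d_gs") %in% colnames(Xg)))
  # derivative columns are lagged differences with first element zero
  expect_equal(Xg[, "d_gs"], c(0, diff(gs)), ignore_attr = TRUE)
  # constant channel: both it and its (zero) derivative are dropped
  run$wm_ts <- rep(2, 40)
  expect_warning(Xc <- build_design(run, include_gs = FALSE),
                 "zero-variance")
  expect_equal(ncol(Xc), 15L)
  expect_false(any(c("wm", "d_wm") %in% colnames(Xc)))
  expect_error(build_design(run, include_gs = TRUE), "gs is required")
})

test_that("nuisance regression recovers betas and orthogonalizes", {
  set.seed(1)
  T <- 240L
  run <- manual_run(T = T, G = 3)
  run$motion <- matrix(rnorm(T * 6, 0, 0.01), T, 6)
  run$ventricle_ts <- rnorm(T)
  run$wm_ts <- rnorm(T)
  gs <- rnorm(T)
  run$bold[, 1] <- 2 * gs + rnorm(T, 0, 0.1)
  run$bold[, 2] <- rnorm(T)
  run$bold[, 3] <- rnorm(T)
  X <- build_design(run, include_gs = TRUE, gs = gs)
  fit <- regress_nuisance(run, X)
  expect_gte(fit$betas["gs", 1], 1.9)
  expect_lte(fit$betas["gs", 1], 2.1)
  # bold unrelated to the GS: its GS beta is near zero, residual ~ input
  expect_lt(abs(fit$betas["gs", 2]), 0.2)
  expect_gt(cor(fit$residual[, 2], run$bold[, 2]), 0.95)
  # residuals orthogonal to every regressor
  cors <- abs(cor(fit$residual, X[, -1]))
  expect_lt(max(cors), 1e-8)
  # rank-deficient designs are rejected with the offending column named
  Xbad <- cbind(X, dup = X[, "gs"])
  expect_error(regress_nuisance(run, Xbad), "collinear.*dup")
})

test_that("GSR is idempotent", {
  fx <- small_cohort(n_subjects = 1, n_gray = 100, T = 120, n_parcels = 5)
  run <- fx$cohort$runs[[1]]
  pp <- preprocess_run(run, fx$space, gsr = TRUE)
  # regressing the same GS against the GSR residuals yields zero betas
  gc_ <- pp$gs - mean(pp$gs)
  b2 <- as.numeric(crossprod(gc_, pp$fit$residual)) / sum(gc_^2)
  expect_lt(max(abs(b2)), 1e-8)
  # and the residual's own spatial mean is numerically annihilated
  expect_lt(max(abs(global_signal(pp$fit$residual, fx$space))), 1e-9)
})

test_that("scrubbing reproduces the hand-derived flag sets", {
  # single 0.6 mm translation step at frame 50: displacement exceeds the
  # 0.5 mm criterion at frame 50 only; dilation -1/+2 flags 49..52
  run <- manual_run(T = 240)
  run$motion[50:240, 1] <- 0.6
  mk <- scrub(run)
  expect_identical(which(mk$flagged), 49:52)
  expect_false(mk$subject_excluded)
  expect_equal(mk$fraction_flagged, 4 / 240)

  # rotation criterion: 0.012 rad * 50 mm = 0.6 mm arc length
  run2 <- manual_run(T = 240)
  run2$motion[100:240, 5] <- 0.012
  expect_identical(which(scrub(run2)$flagged), 99:102)

  # sub-threshold motion is not flagged
  run3 <- manual_run(T = 240)
  run3$motion[50:240, 1] <- 0.4
  expect_false(any(scrub(run3)$flagged))

  # DVARS criterion: a single-frame intensity burst against a gently
  # varying background
  set.seed(2)
  run4 <- manual_run(T = 240, G = 50)
  run4$bold <- run4$bold + matrix(rnorm(240 * 50, 0, 0.1), 240, 50)
  run4$bold[120, ] <- run4$bold[120, ] + 5
  mk4 <- scrub(run4)
  # the jump inflates DVARS entering (120) and leaving (121) the frame
  expect_true(all(c(119, 120, 121, 122, 123) %in% which(mk4$flagged)))
  expect_false(1 %in% which(mk4$flagged))

  # >50% flagged frames excludes the subject
  run5 <- manual_run(T = 240)
  run5$motion[seq(2, 240, by = 3), 1] <- 1   # spike every 3rd frame
  mk5 <- scrub(run5)
  expect_gt(mk5$fraction_flagged, 0.5)
  expect_true(mk5$subject_excluded)
})

test_that("frame censoring deletes rows and guards minimum length", {
  run <- manual_run(T = 240, G = 5)
  mask <- rep(FALSE, 240)
  expect_identical(apply_scrub(run$bold, mask), run$bold)
  mask[c(3, 50, 100, 200)] <- TRUE
  expect_equal(nrow(apply_scrub(run$bold, mask)), 236L)
  expect_error(apply_scrub(run$bold, rep(TRUE, 240)), "censoring")

  # censoring a handful of clean frames barely moves connectivity
  fx <- small_cohort(n_subjects = 1, n_gray = 60, T = 240, n_parcels = 4,
                     motion_spike_rate = 0, seed = 7)
  run2 <- fx$cohort$runs[[1]]
  mask10 <- rep(FALSE, 240)
  mask10[seq(11, 230, length.out = 10)] <- TRUE
  r_full <- cor(run2$bold)
  r_cens <- cor(apply_scrub(run2$bold, mask10))
  expect_lt(mean(abs(r_full - r_cens)), 0.02)
})

test_that("QA metrics quantify SNR and scrub burden", {
  set.seed(3)
  run <- manual_run(T = 2000, G = 10)
  run$bold <- run$bold + matrix(rnorm(20000, 0, 10), 2000, 10)
  mk <- scrub(run)
  qa <- qa_metrics(run, mk)
  expect_equal(mean(qa$snr_map), 10, tolerance = 0.5)
  run0 <- manual_run(T = 100, G = 2)
  mk0 <- scrub(run0)
  expect_warning(qa0 <- qa_metrics(run0, mk0), "zero-variance")
  expect_true(all(is.nan(qa0$snr_map)))
  expect_equal(qa0$percent_scrubbed, 0)

  # uncoupled QA metrics do not predict connectivity levels
  set.seed(4)
  pvals <- replicate(20, qa_fz_correlation(rnorm(24), rnorm(24))$p)
  expect_gte(mean(pvals > 0.05), 0.9)
})
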