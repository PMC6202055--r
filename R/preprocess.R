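# DCT-II basis on T frames, components k = 1..n_comp (no constant term);
# component k has frequency k / (2 T tr) Hz.  Columns are mutually
# orthogonal and orthogonal to the intercept.
dct_basis <- function(T, n_comp) {
  t <- seq_len(T) - 0.5
  outer(t, seq_len(n_comp), function(tt, k) cos(pi * k * tt / T))
}

#' High-pass filter a BOLD run
#'
#' Removes the temporal mean and all slow components below `cutoff_hz` by
#' regressing out a discrete-cosine basis spanning `[0, cutoff_hz]`.  The
#' DCT regression is exactly linear, composes cleanly with the nuisance GLM,
#' and has no IIR edge transients.  Frequencies well below the cutoff are
#' strongly attenuated while the passband is preserved.
#'
#' @param run a `bold_run`, or a plain T x G matrix (then `tr` is required).
#' @param cutoff_hz high-pass cutoff in Hz.
#' @param tr repetition time in seconds (taken from the run when given one).
#' @return an object of the same kind as the input with filtered BOLD
#'   (nuisance channels of a run are filtered identically).
#' @export
highpass_filter <- function(run, cutoff_hz = 0.008, tr = NULL) {
  is_run <- inherits(run, "bold_run")
  x <- if (is_run) run$bold else as.matrix(run)
  if (is_run) tr <- run$tr
  if (is.null(tr)) stop("tr is required when filtering a plain matrix")
  T <- nrow(x)
  if (T < 8L) stop("T must be >= 8")
  if (cutoff_hz >= 1 / (2 * tr)) stop("cutoff must be below Nyquist")
  filt <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    k_max <- floor(2 * T * tr * cutoff_hz)
    if (k_max >= 1L) {
      B <- dct_basis(T, k_max)
      m <- m - B %*% (crossprod(B, m) / colSums(B^2))
    }
    m
  }
  if (!is_run) return(filt(x))
  run$bold <- filt(x)
  run$ventricle_ts <- drop(filt(matrix(run$ventricle_ts)))
  run$wm_ts <- drop(filt(matrix(run$wm_ts)))
  run
}

#' Global signal of a run
#'
#' The spatial mean of the BOLD signal over the gray-matter mask (cortex
#' plus labelled subcortical gray), explicitly excluding the ventricle and
#' white-matter proxies.
#'
#' @param bold T x G matrix or `bold_run`.
#' @param space a `gray_space`.
#' @return length-T numeric vector.
#' @export
global_signal <- function(bold, space) {
  x <- if (inherits(bold, "bold_run")) bold$bold else bold
  if (ncol(x) != space$n_gray) stop("bold does not match the space")
  rowMeans(x[, gray_mask(space), drop = FALSE])
}

# first temporal difference with the first element set to 0
first_derivative <- function(x) {
  if (is.matrix(x)) rbind(0, diff(x)) else c(0, diff(x))
}

#' Build a nuisance design matrix
#'
#' Columns, in fixed order: intercept; ventricle signal; white-matter
#' signal; the six motion parameters; optionally the global signal; then the
#' first temporal derivative (backward difference, first element 0) of every
#' non-intercept column in the same order.  Zero-variance regressors other
#' than the intercept are dropped with a warning.
#'
#' @param run a `bold_run` (supplies ventricle/wm/motion channels).
#' @param include_gs include the global signal and its derivative.
#' @param gs length-T global signal vector; required iff `include_gs`.
#' @return numeric design matrix with named columns; 17 columns without GS,
#'   19 with.
#' @export
build_design <- function(run, include_gs = FALSE, gs = NULL) {
  T <- nrow(run$bold)
  if (include_gs && is.null(gs)) stop("gs is required when include_gs=TRUE")
  if (!include_gs && !is.null(gs)) stop("gs supplied but include_gs=FALSE")
  base <- cbind(ventricle = run$ventricle_ts, wm = run$wm_ts, run$motion)
  colnames(base) <- c("ventricle", "wm", paste0("motion", 1:6))
  if (include_gs) {
    if (length(gs) != T) stop("gs length does not match T")
    base <- cbind(base, gs = gs)
  }
  deriv <- first_derivative(base)
  colnames(deriv) <- paste0("d_", colnames(base))
  X <- cbind(intercept = rep(1, T), base, deriv)
  sds <- apply(X[, -1, drop = FALSE], 2, sd)
  drop_cols <- names(sds)[sds < .Machine$double.eps]
  if (length(drop_cols)) {
    warning("dropping zero-variance regressors: ",
            paste(drop_cols, collapse = ", "))
    X <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
  }
  X
}

#' Ordinary least-squares nuisance regression
#'
#' Fits every grayordinate's time series on the design by OLS and returns
#' betas and residuals.  The residual columns are orthogonal to every design
#' column by construction.
#'
#' @param run a `bold_run` or a T x G matrix.
#' @param design T x R design matrix (from [build_design()]).
#' @return a `nuisance_fit`: list with `names` (regressors), `design`,
#'   `betas` (R x G; rows named, including `gs` when present), `residual`
#'   (T x G).
#' @export
regress_nuisance <- function(run, design) {
  y <- if (inherits(run, "bold_run")) run$bold else as.matrix(run)
  T <- nrow(y)
  if (nrow(design) != T) stop("design rows do not match T")
  if (T <= ncol(design)) stop("T must exceed the number of regressors")
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[seq(qd$rank + 1L, ncol(design))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qd, y)
  resid <- y - design %*% betas
  rownames(betas) <- colnames(design)
  structure(list(names = colnames(design), design = design, betas = betas,
                 residual = resid), class = "nuisance_fit")
}

#' Motion/intensity scrubbing mask
#'
#' Flags frames by two criteria: (1) framewise displacement -- the sum over
#' the six rigid-body parameters of the absolute frame-to-frame change, with
#' rotations (radians) converted to arc length on a 50 mm sphere -- exceeds
#' `fd_thresh` mm; (2) DVARS -- the RMS across grayordinates of the
#' frame-difference intensity divided by the mean intensity -- exceeds
#' `dvars_factor` times the median of that series.  DVARS is computed on the
#' raw (unfiltered, unregressed) intensities.  Flags are dilated one frame
#' back and two frames forward; frame 1 has no defined displacement and can
#' only be flagged by dilation.  Subjects with more than half their frames
#' flagged are marked for exclusion.
#'
#' @param run a `bold_run`.
#' @param fd_thresh framewise-displacement threshold in mm.
#' @param dvars_factor multiple of the median normalized RMS.
#' @param radius_mm sphere radius for the rotation-to-arc-length conversion.
#' @return a `scrub_mask`: list with `flagged` (length-T logical), `fd`
#'   (mm; `NA` at frame 1), `dvars_norm` (`NA` at frame 1),
#'   `fraction_flagged`, `subject_excluded`.
#' @export
scrub <- function(run, fd_thresh = 0.5, dvars_factor = 1.6,
                  radius_mm = 50) {
  T <- nrow(run$bold)
  if (T < 4L) stop("T must be >= 4")
  dm <- abs(diff(run$motion))
  dm[, 4:6] <- dm[, 4:6] * radius_mm
  fd <- c(NA, rowSums(dm))
  dv <- sqrt(rowMeans(diff(run$bold)^2)) / mean(run$bold)
  dvars <- c(NA, dv)
  c1 <- !is.na(fd) & fd > fd_thresh
  c2 <- !is.na(dvars) & dvars > dvars_factor * stats::median(dv)
  core <- c1 | c2
  flagged <- core
  for (f in which(core)) {
    lo <- max(1L, f - 1L)
    hi <- min(T, f + 2L)
    flagged[lo:hi] <- TRUE
  }
  frac <- mean(flagged)
  structure(list(flagged = flagged, fd = fd, dvars_norm = dvars,
                 fraction_flagged = frac,
                 subject_excluded = frac > 0.5), class = "scrub_mask")
}

#' Censor flagged frames
#'
#' Deletes flagged rows from a time series before any correlation or
#' covariance computation.
#'
#' @param x T x G matrix, `bold_run`, or `nuisance_fit` (its residual).
#' @param mask a `scrub_mask` or length-T logical vector.
#' @param min_frames minimum number of surviving frames.
#' @return the censored T' x G matrix.
#' @export
apply_scrub <- function(x, mask, min_frames = 8L) {
  flagged <- if (inherits(mask, "scrub_mask")) mask$flagged else mask
  m <- if (inherits(x, "nuisance_fit")) x$residual
       else if (inherits(x, "bold_run")) x$bold
       else as.matrix(x)
  if (length(flagged) != nrow(m)) stop("mask length does not match T")
  out <- m[!flagged, , drop = FALSE]
  if (nrow(out) < min_frames)
    stop(sprintf("only %d frames survive censoring (minimum %d)",
                 nrow(out), min_frames))
  out
}

#' Quality-assurance metrics
#'
#' Per-grayordinate signal-to-noise ratio (temporal mean divided by temporal
#' standard deviation of the raw series) and the percentage of scrubbed
#' frames.
#'
#' @param run a `bold_run`.
#' @param mask a `scrub_mask` for the run.
#' @return list with `snr_map` (length-G; `NaN` where variance is zero, with
#'   a warning) and `percent_scrubbed`.
#' @export
qa_metrics <- function(run, mask) {
  mu <- colMeans(run$bold)
  s <- apply(run$bold, 2, sd)
  zero <- s < .Machine$double.eps
  if (any(zero)) warning(sum(zero), " zero-variance grayordinates masked")
  snr <- mu / s
  snr[zero] <- NaN
  list(snr_map = snr, percent_scrubbed = 100 * mask$fraction_flagged)
}

#' Correlate a QA metric with mean connectivity across subjects
#'
#' Helper for the quality-assurance check that group connectivity levels are
#' not driven by motion or image artifacts.
#'
#' @param qa per-subject QA values (e.g. mean SNR or percent scrubbed).
#' @param mean_fz per-subject mean Fisher-z connectivity.
#' @return list with `r` and `p` from a two-sided Pearson test.
#' @export
qa_fz_correlation <- function(qa, mean_fz) {
  ct <- cor.test(qa, mean_fz)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Full single-run denoising
#'
#' The fixed pipeline order is: high-pass filtering; scrub-mask computation
#' on the raw intensities; nuisance regression on all frames (ventricle,
#' white matter, motion, optionally the global signal, plus first
#' derivatives); then frame censoring of the residuals.  Setting
#' `censor_before_regression` censors the frames entering the regression
#' instead.
#'
#' @param run a `bold_run`.
#' @param space a `gray_space`.
#' @param gsr include global signal regression.
#' @param cutoff_hz high-pass cutoff.
#' @param gs_after_filter compute the global signal after filtering
#'   (default) or from the unfiltered series.
#' @param censor_before_regression censor frames before the GLM rather than
#'   after.
#' @return list with `residual` (censored T' x G matrix), `fit`
#'   (`nuisance_fit`), `mask` (`scrub_mask`), `gs`, `qa`.
#' @export
preprocess_run <- function(run, space, gsr = TRUE, cutoff_hz = 0.008,
                           gs_after_filter = TRUE,
                           censor_before_regression = FALSE) {
  mask <- scrub(run)
  filt <- highpass_filter(run, cutoff_hz)
  gs <- if (gs_after_filter) global_signal(filt, space)
        else global_signal(run, space) - mean(global_signal(run, space))
  X <- build_design(filt, include_gs = gsr, gs = if (gsr) gs else NULL)
  if (censor_before_regression) {
    keep <- !mask$flagged
    fit <- regress_nuisance(filt$bold[keep, , drop = FALSE],
                            X[keep, , drop = FALSE])
    residual <- fit$residual
  } else {
    fit <- regress_nuisance(filt, X)
    residual <- apply_scrub(fit, mask)
  }
  list(residual = residual, fit = fit, mask = mask, gs = gs,
       qa = qa_metrics(run, mask))
}
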