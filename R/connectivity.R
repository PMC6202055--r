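#' Fisher z-transform
#'
#' `atanh` of the correlation after clipping to `±clip_r` so that exact
#' unit correlations (possible with synthetic duplicates) stay finite.
#'
#' @param r correlations, `|r| <= 1` (tiny numerical overshoot tolerated).
#' @param clip_r clipping bound in (0, 1).
#' @return Fisher z values; an odd function of `r`.
#' @export
fisher_z <- function(r, clip_r = 1 - 1e-7) {
  if (clip_r <= 0 || clip_r >= 1) stop("clip_r must be in (0,1)")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| exceeds 1")
  atanh(pmin(pmax(r, -clip_r), clip_r))
}

# column-standardize so that crossprod gives correlations; zero-variance
# columns are returned as NA with an attribute marking them
standardize_cols <- function(x) {
  T <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  ss <- sqrt(colSums(xc^2))
  zero <- ss < .Machine$double.eps
  ss[zero] <- 1
  z <- sweep(xc, 2, ss, "/")
  attr(z, "zero") <- zero
  z
}

#' Global brain connectivity map
#'
#' For every grayordinate, the mean over all *other* grayordinates of the
#' Fisher-z-transformed correlation (default) or of the unbiased sample
#' covariance (`method = "covariance"`, denominator T'-1) between their
#' time series.  Computation is blocked over target columns so the full
#' G x G matrix is never materialized; the blocked result equals the dense
#' computation exactly.
#'
#' @param bold censored T' x G matrix (post-denoising residuals).
#' @param method `"correlation"` (Fisher z) or `"covariance"`.
#' @param fisher apply the Fisher transform (correlation method only).
#' @param clip_r clipping bound passed to [fisher_z()].
#' @param block_size number of target columns per block.
#' @return length-G numeric map; zero-variance grayordinates are `NaN`
#'   (with a warning) and are dropped pairwise from the means of the rest.
#' @export
gbc_map <- function(bold, method = c("correlation", "covariance"),
                    fisher = TRUE, clip_r = 1 - 1e-7, block_size = 512L) {
  method <- match.arg(method)
  bold <- as.matrix(bold)
  T <- nrow(bold)
  G <- ncol(bold)
  if (T < 8L) stop("need at least 8 frames")
  if (G < 2L) stop("need at least 2 grayordinates")
  if (block_size < 1L) stop("block_size must be >= 1")

  if (method == "correlation") {
    z <- standardize_cols(bold)
    zero <- attr(z, "zero")
  } else {
    z <- sweep(bold, 2, colMeans(bold)) / sqrt(T - 1)
    zero <- rep(FALSE, G)
  }
  if (any(zero)) {
    warning(sum(zero), " zero-variance grayordinates masked in GBC")
    z[, zero] <- 0
  }
  n_valid <- sum(!zero)
  if (n_valid < 2L) stop("fewer than 2 grayordinates with variance")

  out <- numeric(G)
  self <- numeric(G)
  starts <- seq(1L, G, by = block_size)
  for (s in starts) {
    cols <- s:min(G, s + block_size - 1L)
    v <- crossprod(z, z[, cols, drop = FALSE])  # G x b
    if (method == "correlation") {
      v[, ] <- pmin(pmax(v, -1), 1)
      if (fisher) v <- fisher_z(v, clip_r)
      if (any(zero)) v[zero, ] <- 0
    }
    out[cols] <- colSums(v)
    self[cols] <- v[cbind(cols, seq_along(cols))]
  }
  res <- (out - self) / (n_valid - 1)
  res[zero] <- NaN
  res
}

#' Seed-based functional connectivity map
#'
#' Averages the time series over the seed grayordinates and maps its
#' Fisher-z correlation (or covariance) with every grayordinate, seed
#' members included.
#'
#' @param bold censored T' x G matrix.
#' @param seed_mask logical or integer index vector selecting the seed.
#' @inheritParams gbc_map
#' @return length-G numeric map.
#' @export
seed_fc_map <- function(bold, seed_mask,
                        method = c("correlation", "covariance"),
                        fisher = TRUE, clip_r = 1 - 1e-7) {
  method <- match.arg(method)
  bold <- as.matrix(bold)
  seed <- bold[, seed_mask, drop = FALSE]
  if (ncol(seed) == 0L) stop("empty seed")
  s <- rowMeans(seed)
  if (method == "correlation") {
    r <- suppressWarnings(as.numeric(cor(s, bold)))
    if (fisher) r <- fisher_z(r, clip_r)
    r
  } else {
    sc <- s - mean(s)
    as.numeric(crossprod(sc, sweep(bold, 2, colMeans(bold)))) /
      (nrow(bold) - 1)
  }
}

#' Global-signal beta map
#'
#' Computes the global signal of the supplied (nuisance-regressed, non-GSR)
#' data as the spatial mean over the gray-matter mask, then regresses every
#' grayordinate's time series on `[intercept, GS]` by OLS.  The returned
#' betas quantify how much each grayordinate co-varies with the mean
#' gray-matter signal -- the spatial topography of the global signal.
#'
#' @param bold T x G matrix (typically residuals of the non-GS nuisance
#'   GLM).
#' @param space a `gray_space`.
#' @return length-G numeric vector of GS betas.
#' @export
gs_beta_map <- function(bold, space) {
  bold <- as.matrix(bold)
  gs <- global_signal(bold, space)
  if (sd(gs) < .Machine$double.eps) stop("zero-variance global signal")
  gc_ <- gs - mean(gs)
  as.numeric(crossprod(gc_, sweep(bold, 2, colMeans(bold)))) / sum(gc_^2)
}

#' BOLD variance summaries
#'
#' Per-grayordinate temporal variance (the local, grayordinate-wise
#' amplitude measure) and the variance of the mean gray-matter time series
#' (the global-signal variance).
#'
#' @param bold T x G matrix or `bold_run`.
#' @param space a `gray_space`.
#' @return list with `local_var` (length G) and `gs_variance` (scalar).
#' @export
variance_summaries <- function(bold, space) {
  x <- if (inherits(bold, "bold_run")) bold$bold else as.matrix(bold)
  lv <- apply(x, 2, var)
  list(local_var = lv, gs_variance = var(global_signal(x, space)))
}
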