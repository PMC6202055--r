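#' Threshold-free cluster enhancement
#'
#' For each grayordinate, integrates `extent(h)^E * h^H * dh` over
#' thresholds `h` (positive branch on the map, negative branch on the
#' negated map, re-negated), where `extent(h)` is the size of the connected
#' component of supra-threshold grayordinates containing it on the space's
#' adjacency graph.  Defaults `H = 2`, `E = 0.5`, `dh = max(|stat|)/100`
#' follow the PALM volume defaults.
#'
#' @param stat_map numeric statistic map.
#' @param space a `gray_space` supplying the adjacency graph, or a list with
#'   elements `ptr`/`idx` (0-based CSR) as from `adjacency_csr`.
#' @param H height exponent.
#' @param E extent exponent.
#' @param nsteps number of integration steps when `dh` is not given.
#' @param dh explicit threshold step (`NULL` for `max/nsteps`, computed
#'   separately for each sign).
#' @return numeric TFCE map, signed like the input.
#' @export
tfce <- function(stat_map, space, H = 2, E = 0.5, nsteps = 100L,
                 dh = NULL) {
  csr <- if (inherits(space, "gray_space")) adjacency_csr(space) else space
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  if (length(stat_map) != length(csr$ptr) - 1L)
    stop("adjacency does not cover the map support")
  tfce_cpp(as.numeric(stat_map), csr$ptr, csr$idx, H, E,
           as.integer(nsteps), if (is.null(dh)) -1 else dh)
}

new_contrast_result <- function(stat, stat_name, tfce_map, fwe_p, unc_p,
                                n_perm, alpha, seed, max_null) {
  sig_pos <- fwe_p < alpha & stat > 0
  sig_neg <- fwe_p < alpha & stat < 0
  out <- list(tfce_map = tfce_map, fwe_p = fwe_p, unc_p = unc_p,
              sig_mask_pos = sig_pos, sig_mask_neg = sig_neg,
              n_perm = n_perm, alpha = alpha, seed = seed,
              max_null = max_null)
  out[[stat_name]] <- stat
  structure(out, class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> %d grayordinates, %d permutations (seed %d)\n",
    length(x$fwe_p), x$n_perm, x$seed))
  cat(sprintf("  significant at alpha=%.3g: %d positive, %d negative\n",
              x$alpha, sum(x$sig_mask_pos), sum(x$sig_mask_neg)))
  invisible(x)
}

#' Paired group contrast with TFCE permutation inference
#'
#' Computes a one-sample t statistic on the within-subject difference maps
#' `A - B`, converts it to a z map, enhances it with TFCE, and corrects
#' family-wise error with the max-|TFCE| distribution over random sign
#' flips of the difference maps (two-sided).  Deterministic given `seed`.
#'
#' @param maps_a,maps_b n x G matrices of per-subject maps (same subject
#'   order).
#' @param space a `gray_space`.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param H,E,nsteps TFCE parameters.
#' @param alpha FWE significance level.
#' @param seed permutation seed (recorded in the result).
#' @return a `contrast_result` with `z`, `tfce_map`, `fwe_p`, `unc_p`
#'   (uncorrected per-grayordinate permutation p on |t|), significance
#'   masks, and the max-TFCE null sample.
#' @export
paired_contrast <- function(maps_a, maps_b, space, n_perm = 1000L, H = 2,
                            E = 0.5, nsteps = 100L, alpha = 0.05,
                            seed = 1L) {
  maps_a <- as.matrix(maps_a)
  maps_b <- as.matrix(maps_b)
  if (!all(dim(maps_a) == dim(maps_b)))
    stop("map sets must have equal subjects and grayordinates")
  if (nrow(maps_a) < 5L) stop("need at least 5 subjects")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  csr <- adjacency_csr(space)
  res <- paired_contrast_cpp(maps_a - maps_b, csr$ptr, csr$idx,
                             as.integer(n_perm), H, E,
                             as.integer(nsteps), as.integer(seed))
  new_contrast_result(res$z, "z", res$tfce, res$fwe_p, res$unc_p,
                      as.integer(n_perm), alpha, as.integer(seed),
                      res$max_null)
}

#' Condition main effect with TFCE permutation inference
#'
#' Per-grayordinate repeated-measures F over the three drug conditions
#' (subject as the blocking factor; sessions should be averaged per
#' condition beforehand), with a null built by permuting condition labels
#' within subject, TFCE enhancement of the (one-sided) F map, and
#' max-TFCE FWE correction.
#'
#' @param maps named list of three n x G matrices, one per condition, with
#'   identical subject order (complete data required).
#' @inheritParams paired_contrast
#' @return a `contrast_result` with `F` instead of `z`
#'   (`sig_mask_neg` is empty by construction).
#' @export
main_effect_contrast <- function(maps, space, n_perm = 1000L, H = 2,
                                 E = 0.5, nsteps = 100L, alpha = 0.05,
                                 seed = 1L) {
  if (length(maps) != 3L) stop("exactly three condition map sets required")
  maps <- lapply(maps, as.matrix)
  dims <- vapply(maps, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("missing cell: condition map sets differ in shape (subjects ",
         "must have complete 3-condition data)")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  csr <- adjacency_csr(space)
  res <- rm_anova_cpp(maps[[1]], maps[[2]], maps[[3]], csr$ptr, csr$idx,
                      as.integer(n_perm), H, E, as.integer(nsteps),
                      as.integer(seed))
  new_contrast_result(res$F, "F", res$tfce, res$fwe_p, res$unc_p,
                      as.integer(n_perm), alpha, as.integer(seed),
                      res$max_null)
}

#' Per-subject mean within a mask
#'
#' @param maps n x G matrix of per-subject maps (or a length-G vector).
#' @param mask logical or integer index vector; must select at least one
#'   grayordinate.
#' @return length-n vector of within-mask means.
#' @export
mask_means <- function(maps, mask) {
  maps <- if (is.matrix(maps)) maps else matrix(maps, nrow = 1)
  sel <- maps[, mask, drop = FALSE]
  if (ncol(sel) == 0L) stop("empty mask")
  rowMeans(sel)
}

#' Correlation between paired per-subject change scores
#'
#' @param x,y paired per-subject values (n >= 4).
#' @return list with Pearson `r` and two-sided t-test `p`.
#' @export
change_score_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 4L) stop("need at least 4 subjects")
  if (sd(x) < .Machine$double.eps || sd(y) < .Machine$double.eps)
    stop("zero variance")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spatial correlation between two maps
#'
#' @param map1,map2 numeric maps on the same space.
#' @param mask optional logical/index mask restricting the correlation.
#' @return Pearson r across in-mask grayordinates.
#' @export
spatial_correlation <- function(map1, map2, mask = NULL) {
  if (length(map1) != length(map2)) stop("maps are on mismatched spaces")
  if (is.null(mask)) mask <- rep(TRUE, length(map1))
  a <- map1[mask]
  b <- map2[mask]
  keep <- is.finite(a) & is.finite(b)
  if (!any(keep)) stop("empty mask")
  cor(a[keep], b[keep])
}

#' Top/bottom rank conjunction across analysis variants
#'
#' For each of the supplied group-mean maps, extracts the
#' `floor(fraction * G_eligible)` largest (top) and smallest (bottom)
#' values -- ties broken deterministically by lower grayordinate index --
#' and intersects the top sets and the bottom sets across maps.  The
#' resulting conjunction masks select regions whose rank is robust to the
#' processing variant (association measure, GSR on/off).
#'
#' @param maps list of numeric maps on the same space (typically the four
#'   `{correlation, covariance} x {GSR, noGSR}` group means).
#' @param fraction rank fraction in (0, 0.5].
#' @param eligible optional logical mask of eligible grayordinates
#'   (e.g. cortex only); defaults to all finite entries in every map.
#' @return list with logical `top` and `bottom` masks (disjoint), the
#'   per-map top/bottom index sets, and `fraction`.
#' @export
top_bottom_conjunction <- function(maps, fraction = 0.10, eligible = NULL) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  G <- length(maps[[1]])
  if (!all(vapply(maps, length, 1L) == G))
    stop("maps are on mismatched spaces")
  if (is.null(eligible)) eligible <- rep(TRUE, G)
  eligible <- eligible & Reduce(`&`, lapply(maps, is.finite))
  idx <- which(eligible)
  k <- floor(fraction * length(idx))
  if (k < 1L) stop("fraction selects no grayordinates")
  pick <- function(v, decreasing) {
    o <- order(v[idx], idx, decreasing = c(decreasing, FALSE),
               method = "radix")
    sort(idx[o[seq_len(k)]])
  }
  tops <- lapply(maps, pick, decreasing = TRUE)
  bots <- lapply(maps, pick, decreasing = FALSE)
  top_idx <- Reduce(intersect, tops)
  bot_idx <- Reduce(intersect, bots)
  both <- intersect(top_idx, bot_idx)
  if (length(both)) {
    # only possible when values are massively tied; keep the sets disjoint
    warning("degenerate ties: ", length(both),
            " grayordinates qualified for both top and bottom; dropped")
    top_idx <- setdiff(top_idx, both)
    bot_idx <- setdiff(bot_idx, both)
  }
  top <- logical(G); top[top_idx] <- TRUE
  bottom <- logical(G); bottom[bot_idx] <- TRUE
  list(top = top, bottom = bottom, per_map_top = tops,
       per_map_bottom = bots, fraction = fraction, k = k)
}

#' Mean map value per functional network
#'
#' @param map length-G numeric map (or n x G matrix for per-subject rows).
#' @param space a `gray_space`.
#' @return named numeric vector (or n x networks matrix) of means over each
#'   network's grayordinates; networks with no members are `NaN`.
#' @export
network_means <- function(map, space) {
  nets <- NETWORK_LABELS[seq_len(space$n_networks)]
  one <- function(v) vapply(nets, function(nw) {
    m <- space$network == nw
    if (!any(m)) NaN else mean(v[m])
  }, numeric(1))
  if (is.matrix(map)) t(apply(map, 1, one)) else one(map)
}

#' Network-wise symptom correlations with Bonferroni correction
#'
#' Pearson correlation between each network's per-subject connectivity
#' change and a behavioural score, with the p-values multiplied by the
#' number of tests (capped at 1).
#'
#' @param delta_fz n x networks matrix of per-subject connectivity changes.
#' @param scores length-n behavioural scores.
#' @param m_tests Bonferroni multiplier (defaults to the number of
#'   networks; use 5 for the five short-version scale breakdown).
#' @return data.frame with network, r, p_raw, p_bonferroni.
#' @export
symptom_correlations <- function(delta_fz, scores, m_tests = NULL) {
  delta_fz <- as.matrix(delta_fz)
  if (nrow(delta_fz) != length(scores)) stop("scores must be paired")
  if (nrow(delta_fz) < 4L) stop("need at least 4 subjects")
  if (sd(scores) < .Machine$double.eps) stop("constant scores")
  if (is.null(m_tests)) m_tests <- ncol(delta_fz)
  nets <- colnames(delta_fz)
  if (is.null(nets)) nets <- paste0("net", seq_len(ncol(delta_fz)))
  res <- lapply(seq_len(ncol(delta_fz)), function(j) {
    ct <- cor.test(delta_fz[, j], scores)
    data.frame(network = nets[j], r = unname(ct$estimate),
               p_raw = ct$p.value,
               p_bonferroni = min(1, m_tests * ct$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
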