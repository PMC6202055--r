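#' Summarize a dense map to parcels
#'
#' Mean map value per parcel over the selected hemisphere's cortical
#' grayordinates (the expression maps are built on a unilateral
#' parcellation, so matching is done on left-hemisphere parcel means by
#' default).
#'
#' @param map length-G numeric map.
#' @param space a `gray_space`.
#' @param hemisphere `"cortex-L"`, `"cortex-R"`, or `"both"`.
#' @return length-P numeric vector of parcel means; parcels with no member
#'   grayordinates are `NaN` with a warning.
#' @export
parcellate_map <- function(map, space,
                           hemisphere = c("cortex-L", "cortex-R", "both")) {
  hemisphere <- match.arg(hemisphere)
  if (length(map) != space$n_gray) stop("map does not match the space")
  sel <- if (hemisphere == "both") is_cortex(space)
         else space$structure == hemisphere
  P <- space$n_parcels
  out <- rep(NaN, P)
  for (p in seq_len(P) - 1L) {
    m <- sel & !is.na(space$parcel) & space$parcel == p
    if (any(m)) out[p + 1L] <- mean(map[m])
  }
  if (anyNA(out) || any(is.nan(out)))
    if (any(is.nan(out)))
      warning(sum(is.nan(out)), " empty parcels masked")
  out
}

#' Correlate a parcel map with every gene-expression map
#'
#' Pearson correlation of the parcel-level contrast map with each gene's
#' expression profile across parcels (masked parcels dropped pairwise), and
#' the percentile rank of named target genes among all gene correlations:
#' `100 * #{genes with r < r_target} / (n_genes - 1)`.
#'
#' @param parcel_map length-P numeric vector.
#' @param expr an `expression_matrix` with matching parcel count.
#' @param targets character vector of gene symbols to rank.
#' @param n_perm if positive, additionally compute a permutation p-value
#'   for each target by shuffling the parcel map (a guard against the
#'   optimism of naive parcel-count degrees of freedom; off by default).
#' @param perm_seed seed for the permutation p-values.
#' @return a `gene_match_result`: list with `r` (named per-gene vector,
#'   `NA` for zero-variance genes), `targets`, `percentile` (named),
#'   `n_parcels` actually used, and `perm_p` (named, when requested).
#' @export
gene_map_correlations <- function(parcel_map, expr,
                                  targets = expr$genes[1],
                                  n_perm = 0L, perm_seed = 1L) {
  if (length(parcel_map) != expr$n_parcels)
    stop("parcel count mismatch between map and expression matrix")
  if (expr$n_parcels < 4L) stop("need at least 4 parcels")
  keep <- is.finite(parcel_map)
  x <- parcel_map[keep]
  vals <- expr$values[, keep, drop = FALSE]
  sds <- apply(vals, 1, sd)
  r <- rep(NA_real_, nrow(vals))
  ok <- sds > .Machine$double.eps
  r[ok] <- as.numeric(cor(x, t(vals[ok, , drop = FALSE])))
  names(r) <- expr$genes
  if (!all(targets %in% expr$genes)) stop("unknown target gene symbol")
  pct <- vapply(targets, function(g) {
    100 * sum(r < r[g], na.rm = TRUE) / (sum(!is.na(r)) - 1)
  }, numeric(1))
  perm_p <- NULL
  if (n_perm > 0L) {
    set.seed(perm_seed)
    tv <- t(vals[match(targets, expr$genes), , drop = FALSE])
    obs <- abs(r[targets])
    exceed <- integer(length(targets))
    for (p in seq_len(n_perm)) {
      rp <- abs(as.numeric(cor(sample(x), tv)))
      exceed <- exceed + (rp >= obs)
    }
    perm_p <- (1 + exceed) / (n_perm + 1)
    names(perm_p) <- targets
  }
  structure(list(r = r, targets = targets, percentile = pct,
                 n_parcels = sum(keep), perm_p = perm_p),
            class = "gene_match_result")
}

#' @export
print.gene_match_result <- function(x, ...) {
  cat(sprintf("<gene_match_result> %d genes, %d parcels\n", length(x$r),
              x$n_parcels))
  for (g in x$targets)
    cat(sprintf("  %s: r = %.3f, percentile = %.1f\n", g, x$r[g],
                x$percentile[g]))
  invisible(x)
}

#' Compare two dependent correlations sharing one variable
#'
#' Steiger's Z-bar* test for the difference between `r_AG` and `r_BG` when
#' A and B are themselves correlated (`r_AB`) and G is the shared variable
#' (here, a gene-expression map correlated with two contrast maps).  Uses
#' the pooled-correlation form with Fisher-z transformed inputs.
#'
#' @param r_ag,r_bg the two correlations being compared.
#' @param r_ab correlation between the two non-shared variables.
#' @param n sample size (number of parcels; >= 10).
#' @return list with `z` and two-sided `p`.
#' @export
compare_dependent_correlations <- function(r_ag, r_bg, r_ab, n) {
  if (n < 10L) stop("n must be >= 10")
  if (any(abs(c(r_ag, r_bg, r_ab)) >= 1)) stop("degenerate correlation")
  R <- matrix(c(1, r_ab, r_ag, r_ab, 1, r_bg, r_ag, r_bg, 1), 3)
  if (det(R) < -1e-12)
    stop("infeasible correlation triple (not positive semi-definite)")
  z1 <- atanh(r_ag)
  z2 <- atanh(r_bg)
  rbar <- (r_ag + r_bg) / 2
  # covariance of the dependent correlations (pooled form)
  psi <- r_ab * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
    (1 - 2 * rbar^2 - r_ab^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Bonferroni helper for a set of dependent-correlation comparisons
#'
#' @param comparisons data.frame with columns r_ag, r_bg, r_ab.
#' @param n number of parcels.
#' @param m Bonferroni multiplier (defaults to the number of rows, e.g. the
#'   six candidate receptor genes).
#' @return the input with z, p_raw, p_bonferroni columns appended.
#' @export
compare_dependent_correlations_table <- function(comparisons, n, m = NULL) {
  if (is.null(m)) m <- nrow(comparisons)
  out <- comparisons
  res <- mapply(function(a, b, ab)
    unlist(compare_dependent_correlations(a, b, ab, n)),
    comparisons$r_ag, comparisons$r_bg, comparisons$r_ab)
  out$z <- res["z", ]
  out$p_raw <- res["p", ]
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  out
}

#' Mean expression per functional network and gene co-expression
#'
#' Maps each parcel to the majority network label of its member
#' grayordinates, averages each gene's z-scored expression within network,
#' and returns the gene-by-gene spatial correlation matrix as a companion.
#'
#' @param expr an `expression_matrix`.
#' @param space a `gray_space` whose parcel count matches.
#' @return list with `network_means` (gene x network matrix) and
#'   `gene_cor` (gene x gene correlation matrix; `NA` rows for
#'   zero-variance genes).
#' @export
expression_network_summary <- function(expr, space) {
  if (space$n_parcels != expr$n_parcels)
    stop("parcel count mismatch")
  nets <- NETWORK_LABELS[seq_len(space$n_networks)]
  parcel_net <- vapply(seq_len(space$n_parcels) - 1L, function(p) {
    m <- !is.na(space$parcel) & space$parcel == p
    if (!any(m)) return(NA_character_)
    tab <- table(factor(as.character(space$network[m]), levels = nets))
    names(tab)[which.max(tab)]
  }, character(1))
  nm <- matrix(NaN, length(expr$genes), length(nets),
               dimnames = list(expr$genes, nets))
  for (nw in nets) {
    cols <- which(parcel_net == nw)
    if (length(cols))
      nm[, nw] <- rowMeans(expr$values[, cols, drop = FALSE])
  }
  sds <- apply(expr$values, 1, sd)
  gc_ <- suppressWarnings(cor(t(expr$values)))
  gc_[sds < .Machine$double.eps, ] <- NA
  gc_[, sds < .Machine$double.eps] <- NA
  dimnames(gc_) <- list(expr$genes, expr$genes)
  list(network_means = nm, gene_cor = gc_)
}
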