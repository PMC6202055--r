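#' Construct a synthetic grayordinate space
#'
#' Builds a geometry-free brain model: per-grayordinate structure labels
#' (left/right cortex, thalamus, amygdala, other subcortex, ventricle and
#' white-matter proxies), functional network labels on cortex, a unilateral
#' parcellation mirrored across hemispheres, and a neighbourhood graph.
#' Grayordinates are arranged on a ring (default) or a 2-D grid so that
#' adjacency is well defined for cluster-based statistics such as TFCE.
#'
#' Structure blocks are laid out contiguously in fixed proportions
#' (42% cortex per hemisphere, 6% thalamus, 2% amygdala, 4% other subcortex,
#' 3% each ventricle/white-matter proxy).  Within each cortical hemisphere,
#' networks are contiguous blocks cycling through the requested labels and
#' parcels are `n_parcels` contiguous blocks, so parcel `p` has members in
#' both hemispheres (its left-hemisphere members are used for unilateral
#' parcel-level analyses).
#'
#' @param n_gray total number of grayordinates (>= 20).
#' @param n_networks number of functional networks to label (1..7); labels are
#'   taken in order from visual, somatomotor, dorsal-attention,
#'   ventral-attention, limbic, frontoparietal, default.
#' @param n_parcels number of cortical parcels per hemisphere.
#' @param seed integer seed (reserved for future stochastic layouts; the
#'   default layout is deterministic).
#' @param topology `"ring"` (degree-2 cycle over all grayordinates) or
#'   `"grid"` (4-neighbour rectangular lattice).
#' @return An object of class `gray_space`: a list with `n_gray`, `structure`
#'   (factor), `network` (factor, `"none"` off cortex), `parcel` (0-based
#'   integer, `NA` off cortex), and `edges` (2-column integer matrix of
#'   1-based undirected edges, each pair listed once).
#' @export
make_space <- function(n_gray, n_networks = 7L, n_parcels = 10L, seed = 1L,
                       topology = c("ring", "grid")) {
  topology <- match.arg(topology)
  n_gray <- as.integer(n_gray)
  n_networks <- as.integer(n_networks)
  n_parcels <- as.integer(n_parcels)
  if (n_gray < 20L) stop("n_gray must be at least 20")
  if (n_networks < 1L || n_networks > length(NETWORK_LABELS))
    stop("n_networks must be between 1 and ", length(NETWORK_LABELS))

  # contiguous structure blocks in fixed proportions
  n_ctx_l <- max(4L, round(0.42 * n_gray))
  n_ctx_r <- n_ctx_l
  n_thal <- max(2L, round(0.06 * n_gray))
  n_amyg <- max(1L, round(0.02 * n_gray))
  n_vent <- max(1L, round(0.03 * n_gray))
  n_wm <- max(1L, round(0.03 * n_gray))
  n_osc <- n_gray - n_ctx_l - n_ctx_r - n_thal - n_amyg - n_vent - n_wm
  if (n_osc < 1L) {
    # shrink cortex symmetrically so every structure block is non-empty
    trim <- ceiling((1L - n_osc) / 2)
    n_ctx_l <- n_ctx_l - trim
    n_ctx_r <- n_ctx_r - trim
    n_osc <- n_gray - n_ctx_l - n_ctx_r - n_thal - n_amyg - n_vent - n_wm
    if (n_ctx_l < 4L) stop("n_gray too small for the structure layout")
  }
  structure_lab <- rep(STRUCTURE_LABELS[c(1, 2, 3, 4, 5, 6, 7)],
                       times = c(n_ctx_l, n_ctx_r, n_thal, n_amyg,
                                 n_osc, n_vent, n_wm))
  structure_lab <- factor(structure_lab, levels = STRUCTURE_LABELS)

  if (n_parcels > n_ctx_l)
    stop("n_parcels exceeds the cortical grayordinate count per hemisphere")

  # networks and parcels: contiguous blocks within each hemisphere, mirrored
  blocks <- function(n, k) {
    if (k == 1L) rep(1L, n)
    else as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
  }
  hemi_labels <- function(n_ctx) {
    list(net = NETWORK_LABELS[blocks(n_ctx, n_networks)],
         parc = blocks(n_ctx, n_parcels) - 1L)
  }
  hl <- hemi_labels(n_ctx_l)
  hr <- hemi_labels(n_ctx_r)
  network <- rep("none", n_gray)
  parcel <- rep(NA_integer_, n_gray)
  network[seq_len(n_ctx_l)] <- hl$net
  network[n_ctx_l + seq_len(n_ctx_r)] <- hr$net
  parcel[seq_len(n_ctx_l)] <- hl$parc
  parcel[n_ctx_l + seq_len(n_ctx_r)] <- hr$parc
  network <- factor(network, levels = c(NETWORK_LABELS, "none"))

  edges <- switch(topology,
    ring = cbind(seq_len(n_gray), c(seq_len(n_gray)[-1L], 1L)),
    grid = {
      nc <- max(2L, floor(sqrt(n_gray)))
      nr <- ceiling(n_gray / nc)
      idx <- function(r, c) (r - 1L) * nc + c
      e <- list()
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        i <- idx(r, c)
        if (i > n_gray) next
        if (c < nc && idx(r, c + 1L) <= n_gray)
          e[[length(e) + 1L]] <- c(i, idx(r, c + 1L))
        if (r < nr && idx(r + 1L, c) <= n_gray)
          e[[length(e) + 1L]] <- c(i, idx(r + 1L, c))
      }
      do.call(rbind, e)
    })
  storage.mode(edges) <- "integer"

  space <- structure(list(n_gray = n_gray, structure = structure_lab,
                          network = network, parcel = parcel, edges = edges,
                          n_networks = n_networks, n_parcels = n_parcels,
                          topology = topology, seed = as.integer(seed)),
                     class = "gray_space")
  validate_space(space)
  space
}

#' Validate a grayordinate space
#'
#' Checks the structural invariants: symmetric self-loop-free adjacency,
#' exactly one network and parcel per cortical grayordinate, and a non-empty
#' thalamus mask.
#'
#' @param space a `gray_space`.
#' @return the space, invisibly; errors on violation.
#' @export
validate_space <- function(space) {
  stopifnot(inherits(space, "gray_space"))
  g <- space$n_gray
  if (length(space$structure) != g || length(space$network) != g ||
      length(space$parcel) != g)
    stop("space label vectors must have length n_gray")
  e <- space$edges
  if (any(e < 1L) || any(e > g)) stop("edge endpoints out of range")
  if (any(e[, 1] == e[, 2])) stop("adjacency must be self-loop-free")
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (anyDuplicated(key)) stop("duplicate edges in adjacency")
  ctx <- is_cortex(space)
  if (any(space$network[ctx] == "none"))
    stop("every cortical grayordinate needs a network label")
  if (anyNA(space$parcel[ctx]))
    stop("every cortical grayordinate needs a parcel label")
  if (!anyNA(space$parcel[!ctx]) && any(!ctx))
    stop("parcels are cortical-only")
  if (!any(space$structure == "thalamus"))
    stop("thalamus mask is empty")
  invisible(space)
}

is_cortex <- function(space) space$structure %in% c("cortex-L", "cortex-R")

#' Gray-matter mask of a space
#'
#' Gray matter comprises cortex and labelled subcortical structures,
#' explicitly excluding the ventricle and white-matter proxies; this is the
#' mask over which the global signal is averaged.
#'
#' @param space a `gray_space`.
#' @return logical vector of length `n_gray`.
#' @export
gray_mask <- function(space) space$structure %in% GRAY_STRUCTURES

#' Structure mask helper
#'
#' @param space a `gray_space`.
#' @param label one or more structure labels (e.g. `"thalamus"`).
#' @return logical vector of length `n_gray`.
#' @export
structure_mask <- function(space, label) {
  if (!all(label %in% STRUCTURE_LABELS)) stop("unknown structure label")
  space$structure %in% label
}

# Compressed sparse adjacency (0-based) for the C++ component search.
adjacency_csr <- function(space) {
  g <- space$n_gray
  e <- space$edges
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  ptr <- c(0L, cumsum(tabulate(from, nbins = g)))
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L))
}

#' @export
print.gray_space <- function(x, ...) {
  cat("<gray_space> ", x$n_gray, " grayordinates (", x$topology, ")\n",
      sep = "")
  cat("  structures: ",
      paste(sprintf("%s=%d", levels(x$structure), table(x$structure)),
            collapse = ", "), "\n", sep = "")
  cat("  networks: ", x$n_networks, ", parcels/hemisphere: ", x$n_parcels,
      "\n", sep = "")
  invisible(x)
}
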