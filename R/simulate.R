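#' Generator configuration for synthetic BOLD cohorts
#'
#' Defines the statistical structure of a simulated pharmacological cohort:
#' latent network signals with condition-dependent loadings (the active drug
#' condition raises loadings in sensory/somatomotor networks and lowers them
#' in associative networks), a global fluctuation whose spatial weight
#' topography shifts under the drug, correlated subject-level hyper/hypo
#' effect sizes, motion/intensity spikes, and behavioural scores coupled to
#' each subject's somatomotor connectivity change.
#'
#' Baseline network loadings default to 0.6 in the sensory/somatomotor
#' networks and 1.0 in associative networks, so that baseline (placebo)
#' connectivity is strongest in associative cortex.  The drug effect
#' `loading_delta` (+ in sensory, - in associative, scaled by subject-level
#' multipliers) expresses a change in network coherence: it is applied to
#' the private-noise gain of each cortical grayordinate, leaving the
#' network's shared amplitude -- and therefore its contribution to the
#' global mean signal -- unchanged.  This encodes hyper-connectivity as
#' increased participation of an area in its distributed network rather
#' than as a louder network signal, which would be inseparable from a
#' global-signal change.  The global fluctuation g(t) is an AR(1) process
#' (phi = 0.4)
#' band-limited below 0.1 Hz, entering every gray-matter grayordinate with
#' weight `w_k`; under the drug the (mean-centred) weight topography shifts
#' upward in associative cortex and subcortex and downward in sensory cortex.
#'
#' @param n_subjects number of subjects (full 3 condition x 2 session
#'   crossing per subject).
#' @param n_gray,T,tr,n_networks,n_parcels space and acquisition dimensions.
#' @param loading_base named per-network baseline loadings.
#' @param loading_delta named per-network drug-induced coupling change
#'   relative to `loading_base` (applies fully in the drug condition,
#'   `ket_fraction` of it in the blocked condition, 0 under placebo);
#'   positive values raise within-network coherence, negative lower it.
#' @param gs_amplitude named per-condition amplitude of the global
#'   fluctuation.
#' @param gs_shift magnitude of the drug-induced spatial shift of the global
#'   signal topography.
#' @param rho_hh target correlation between subject-level signed hyper and
#'   hypo effect sizes, in `[-1, 1]`.
#' @param effect_sd relative spread of the subject-level effect multipliers.
#' @param network_jitter_sd sd of per-subject-per-network multiplicative
#'   jitter on `loading_delta` (gives each network a subject-specific
#'   component; keep small unless testing network selectivity).
#' @param behav_coupling slope of the drug-condition behavioural score
#'   (percent of scale maximum) on the subject somatomotor effect multiplier.
#' @param behav_noise_sd behavioural score noise sd.
#' @param noise_sd per-grayordinate white-noise sd.
#' @param noise_profile named per-network multiplier on `noise_sd`
#'   (baseline).  The default gives sensory cortex more private noise than
#'   associative cortex, so that at baseline associative areas are the most
#'   globally coupled under every processing variant -- the ranking the
#'   conjunction analysis relies on.
#' @param motion_spike_rate per-frame probability of a motion/intensity
#'   spike.
#' @param spike_mm,spike_intensity single-frame motion jump (mm) and bold
#'   intensity jump (in units of `noise_sd`) at spike frames.
#' @param bold_baseline additive mean intensity (arbitrary BOLD units).
#' @param thal_base,thal_delta thalamic coupling to each network's latent
#'   signal (baseline and drug-induced change; sensory vs associative).
#' @param ket_fraction fraction of the drug effects (loading and GS shift)
#'   retained when the drug is blocked by the antagonist (0 = full blockade).
#' @param vent_share share of the global fluctuation present in the
#'   ventricle/white-matter channels and proxy grayordinates.
#' @param seed master integer seed.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 24L, n_gray = 2000L, T = 240L,
                             tr = 2.5, n_networks = 7L, n_parcels = 180L,
                             loading_base = NULL, loading_delta = NULL,
                             gs_amplitude = c(Pla = 2, LSD = 2, KetLSD = 2),
                             gs_shift = 0.4, rho_hh = -0.9, effect_sd = 0.3,
                             network_jitter_sd = 0.1, behav_coupling = 30,
                             behav_noise_sd = 5, noise_sd = 1,
                             noise_profile = NULL,
                             motion_spike_rate = 0.02, spike_mm = 0.8,
                             spike_intensity = 5, bold_baseline = 1000,
                             thal_base = c(sensory = 0.25, associative = 1.2),
                             thal_delta = c(sensory = 0.3, associative = -0.3),
                             ket_fraction = 0, vent_share = 0.3,
                             seed = 1L) {
  nets <- NETWORK_LABELS[seq_len(n_networks)]
  if (is.null(loading_base)) {
    # graded baseline: association networks carry the strongest distributed
    # signal (default-mode highest), sensory networks the weakest, giving
    # every map variant a consistent connectivity topography at baseline
    loading_base <- c(visual = 0.55, somatomotor = 0.65,
                      `dorsal-attention` = 0.9, `ventral-attention` = 1.0,
                      limbic = 0.85, frontoparietal = 1.1,
                      default = 1.2)[nets]
    names(loading_base) <- nets
  }
  if (is.null(loading_delta)) {
    loading_delta <- ifelse(nets %in% SENSORY_NETWORKS, 0.3, -0.3)
    names(loading_delta) <- nets
  }
  if (is.null(noise_profile)) {
    # keep total non-global variance (loading^2 + noise^2) approximately
    # flat across networks so that correlation- and covariance-based
    # connectivity rank areas identically, before and after GSR
    noise_profile <- sqrt(pmax(1.69 - loading_base[nets]^2, 0.04))
    names(noise_profile) <- nets
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_gray = as.integer(n_gray), T = as.integer(T),
              tr = as.numeric(tr), n_networks = as.integer(n_networks),
              n_parcels = as.integer(n_parcels),
              loading_base = loading_base, loading_delta = loading_delta,
              gs_amplitude = gs_amplitude, gs_shift = gs_shift,
              rho_hh = rho_hh, effect_sd = effect_sd,
              network_jitter_sd = network_jitter_sd,
              behav_coupling = behav_coupling,
              behav_noise_sd = behav_noise_sd, noise_sd = noise_sd,
              noise_profile = noise_profile,
              motion_spike_rate = motion_spike_rate, spike_mm = spike_mm,
              spike_intensity = spike_intensity,
              bold_baseline = bold_baseline, thal_base = thal_base,
              thal_delta = thal_delta, ket_fraction = ket_fraction,
              vent_share = vent_share, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_config <- function(cfg) {
  if (abs(cfg$rho_hh) > 1) stop("|rho_hh| must be <= 1")
  if (cfg$motion_spike_rate < 0 || cfg$motion_spike_rate > 1)
    stop("motion_spike_rate must be a probability")
  for (f in c("n_subjects", "n_gray", "T", "n_networks", "n_parcels"))
    if (cfg[[f]] < 1L) stop(f, " must be >= 1")
  if (!all(CONDITIONS %in% names(cfg$gs_amplitude)))
    stop("gs_amplitude needs one value per condition")
  nets <- NETWORK_LABELS[seq_len(cfg$n_networks)]
  if (!all(nets %in% names(cfg$loading_base)) ||
      !all(nets %in% names(cfg$loading_delta)))
    stop("loading_base/loading_delta need one value per network")
  invisible(cfg)
}

# AR(1) process band-limited below f_max (Hz), standardized.  The DCT basis
# is orthogonal, so the low-pass is a plain projection onto the components
# whose frequency lies below f_max.
make_global_fluctuation <- function(T, tr, phi = 0.4, f_max = 0.1) {
  g <- as.numeric(stats::filter(rnorm(T), phi, method = "recursive"))
  k_max <- min(T - 1L, floor(2 * T * tr * f_max))
  if (k_max < 1L) return(rep(0, T))
  B <- dct_basis(T, n_comp = k_max)
  g_lp <- drop(B %*% (crossprod(B, g) / colSums(B^2)))
  g_lp <- g_lp - mean(g_lp)
  s <- sd(g_lp)
  if (s < .Machine$double.eps) return(rep(0, T))
  g_lp / s
}

#' Simulate a multi-subject, multi-condition BOLD cohort
#'
#' Generates the full 3 condition x 2 session crossing for every subject
#' under the generative model
#' `bold_k(t) = baseline + a_c * w_k^{cond} g(t) + sum_c L_kc eta_c(t) +
#' spikes + eps_k(t)`, where `eta_c` are latent network signals, `g` the
#' band-limited global fluctuation, and the loadings `L` carry the
#' condition-dependent drug effects scaled by bivariate-normal subject
#' multipliers with the configured hyper/hypo correlation.  Motion spikes
#' co-occur with transient intensity jumps so that scrubbing is exercised.
#' All randomness flows from `config$seed`.
#'
#' @param space a `gray_space` whose dimensions match the config.
#' @param config a `generator_config`.
#' @return a `cohort` whose `truth` element holds the ground truth:
#'   per-condition GS topographies, the signed coupling-change map, subject
#'   hyper/hypo effect sizes, subject multipliers, and behavioural scores.
#' @export
simulate_cohort <- function(space, config) {
  validate_config(config)
  validate_space(space)
  if (space$n_gray != config$n_gray)
    stop("space n_gray does not match config")
  G <- space$n_gray
  T <- config$T
  nets <- NETWORK_LABELS[seq_len(config$n_networks)]
  net_idx <- match(as.character(space$network), nets)  # NA off cortex
  sensory <- nets %in% SENSORY_NETWORKS
  subjects <- sprintf("sub%03d", seq_len(config$n_subjects))

  set.seed(config$seed)

  # subject-level hyper/hypo multipliers: bivariate normal, mean 1.  The
  # signed effect sizes are multiplier x loading_delta, so the multiplier
  # correlation is rho_hh adjusted for the sign of the delta product.
  d_s <- mean(config$loading_delta[sensory])
  d_a <- mean(config$loading_delta[!sensory])
  sgn <- sign(d_s * d_a)
  if (sgn == 0) sgn <- 1
  rho_mult <- config$rho_hh * sgn
  z1 <- rnorm(config$n_subjects)
  z2 <- rho_mult * z1 + sqrt(max(0, 1 - rho_mult^2)) *
    rnorm(config$n_subjects)
  mult_hyper <- 1 + config$effect_sd * z1
  mult_hypo <- 1 + config$effect_sd * z2
  jitter <- matrix(1 + config$network_jitter_sd *
                     rnorm(config$n_subjects * config$n_networks),
                   config$n_subjects, config$n_networks,
                   dimnames = list(subjects, nets))

  # GS topography per condition: mean-one over gray matter, the drug shift
  # is mean-centred so the spatial average weight is condition-invariant.
  gm <- gray_mask(space)
  w_base <- ifelse(gm, 1, config$vent_share)
  shift <- numeric(G)
  ctx <- is_cortex(space)
  shift[ctx & !is.na(net_idx) & sensory[pmax(net_idx, 1)]] <- -1
  shift[ctx & !is.na(net_idx) & !sensory[pmax(net_idx, 1)]] <- 1
  shift[space$structure %in% c("thalamus", "amygdala", "other-subcortex")] <- 0.5
  shift[gm] <- shift[gm] - mean(shift[gm])
  shift[!gm] <- 0
  cond_frac <- c(Pla = 0, LSD = 1, KetLSD = config$ket_fraction)
  w_cond <- lapply(CONDITIONS, function(cn)
    w_base + cond_frac[[cn]] * config$gs_shift * shift)
  names(w_cond) <- CONDITIONS

  # signed coupling-change map (drug vs placebo), the recovery target
  coupling_change <- numeric(G)
  coupling_change[!is.na(net_idx)] <-
    config$loading_delta[net_idx[!is.na(net_idx)]]
  thal <- space$structure == "thalamus"
  coupling_change[thal] <- mean(config$thal_delta)

  # Baseline loading matrix rows: one grayordinate's loading on each
  # network.  A deterministic within-block ramp (+-15%) grades the loading
  # across each network's extent so that connectivity ranks are a stable
  # topography rather than exchangeable within network.
  base_load <- matrix(0, G, config$n_networks)
  on_ctx <- which(!is.na(net_idx))
  ramp <- numeric(G)
  for (hemi in c("cortex-L", "cortex-R")) {
    for (c_ in seq_len(config$n_networks)) {
      blk <- which(space$structure == hemi & net_idx == c_)
      n_blk <- length(blk)
      if (n_blk > 1L)
        ramp[blk] <- seq(-0.5, 0.5, length.out = n_blk)
    }
  }
  base_load[cbind(on_ctx, net_idx[on_ctx])] <-
    config$loading_base[net_idx[on_ctx]] * (1 + 0.3 * ramp[on_ctx])
  base_load[thal, ] <- rep(ifelse(sensory, config$thal_base[["sensory"]],
                                  config$thal_base[["associative"]]),
                           each = sum(thal)) / sqrt(config$n_networks)
  osc <- space$structure %in% c("amygdala", "other-subcortex")
  base_load[osc, ] <- 0.2 / sqrt(config$n_networks)

  # behavioural scores: coupled to the somatomotor subject effect in the
  # drug condition, near zero otherwise; intensity decays over assessments
  times <- c(180, 250, 360)
  profile <- c(1.0, 0.8, 0.5)
  som <- if ("somatomotor" %in% nets) "somatomotor" else nets[1]
  m_som <- mult_hyper * jitter[, som]
  behav <- expand.grid(subject = subjects, condition = CONDITIONS,
                       time = times, stringsAsFactors = FALSE)
  behav$score <- 0
  for (i in seq_len(nrow(behav))) {
    s <- match(behav$subject[i], subjects)
    tphase <- profile[match(behav$time[i], times)]
    mu <- if (behav$condition[i] == "LSD")
      config$behav_coupling * m_som[s] * tphase else 0
    behav$score[i] <- max(0, min(100,
      mu + abs(rnorm(1, 0, ifelse(mu > 0, config$behav_noise_sd, 1)))))
  }

  grid <- expand.grid(session = c(1L, 2L), condition = CONDITIONS,
                      subject = subjects, stringsAsFactors = FALSE)
  run_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))

  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set.seed(run_seeds[i])
    s <- match(grid$subject[i], subjects)
    cn <- grid$condition[i]
    fr <- cond_frac[[cn]]

    # Condition effects.  Cortical coupling changes enter through the
    # private-noise gain: the drug leaves each network's shared amplitude
    # (and hence its contribution to the global mean) untouched and instead
    # raises or lowers how coherent each grayordinate is with its network.
    # A positive loading_delta shrinks the private noise (hyper-coupling),
    # a negative one inflates it (hypo-coupling).  Thalamic coupling, a
    # small fraction of gray matter, shifts its loadings directly.
    L <- base_load
    noise_k <- rep(config$noise_sd, G)
    noise_k[on_ctx] <- config$noise_sd *
      config$noise_profile[net_idx[on_ctx]]
    if (fr != 0) {
      mult_net <- ifelse(sensory, mult_hyper[s], mult_hypo[s]) * jitter[s, ]
      gain <- 1 + fr * mult_net * config$loading_delta /
        config$loading_base
      gain <- pmax(gain, 0.2)
      noise_k[on_ctx] <- noise_k[on_ctx] / gain[net_idx[on_ctx]]
      thal_dl <- fr * ifelse(sensory, mult_hyper[s], mult_hypo[s]) *
        ifelse(sensory, config$thal_delta[["sensory"]],
               config$thal_delta[["associative"]])
      L[thal, ] <- L[thal, ] + rep(thal_dl, each = sum(thal)) /
        sqrt(config$n_networks)
    }

    g <- make_global_fluctuation(T, config$tr)
    # latent network signals share the slow BOLD spectrum
    eta <- vapply(seq_len(config$n_networks),
                  function(c_) make_global_fluctuation(T, config$tr),
                  numeric(T))
    amp <- config$gs_amplitude[[cn]]
    bold <- config$bold_baseline +
      amp * tcrossprod(g, w_cond[[cn]]) +
      eta %*% t(L) +
      matrix(rnorm(T * G), T, G) * rep(noise_k, each = T)

    motion <- apply(matrix(rnorm(T * 6, 0, 0.005), T, 6), 2, cumsum)
    motion[, 4:6] <- motion[, 4:6] / 50  # rotations in radians, small
    spikes <- which(runif(T) < config$motion_spike_rate)
    spikes <- spikes[spikes > 1L]
    for (f in spikes) {
      motion[f, 1] <- motion[f, 1] + config$spike_mm
      bold[f, ] <- bold[f, ] +
        rnorm(G, 0, config$spike_intensity * config$noise_sd)
    }

    vent <- config$vent_share * amp * g + rnorm(T)
    wm <- config$vent_share * amp * g + rnorm(T)

    runs[[i]] <- bold_run(grid$subject[i], cn, grid$session[i], bold,
                          config$tr, motion, vent, wm)
  }
  names(runs) <- vapply(runs, run_id, character(1))

  truth <- list(gs_topography = w_cond, coupling_change = coupling_change,
                hyper_es = mult_hyper * d_s, hypo_es = mult_hypo * d_a,
                mult_hyper = mult_hyper, mult_hypo = mult_hypo,
                somatomotor_effect = m_som, behavior = behav,
                gs_shift_map = shift, config = config)
  cohort(space, runs, truth = truth)
}

#' Simulate a parcel-level gene-expression matrix
#'
#' Builds a gene x parcel matrix in which the first gene is constructed to
#' correlate approximately `r_target` with a supplied reference parcel map,
#' the second approximately `r_anti`, and the remaining genes are spatially
#' random.  Every gene row is z-scored across parcels.
#'
#' @param space a `gray_space` (used only for its parcel count check).
#' @param reference_parcel_map numeric vector of length P.
#' @param n_genes number of genes (>= 3).
#' @param r_target,r_anti target correlations for genes 1 and 2 (|r| < 1).
#' @param seed integer seed.
#' @param symbols optional gene symbols; defaults give the two constructed
#'   genes the labels `GENE_TARGET` and `GENE_ANTI`.
#' @return an `expression_matrix`: list with `genes`, `values` (gene x
#'   parcel), `n_parcels`.
#' @export
simulate_expression <- function(space, reference_parcel_map, n_genes = 1000L,
                                r_target = 0.5, r_anti = -0.3, seed = 1L,
                                symbols = NULL) {
  P <- length(reference_parcel_map)
  if (P < 4L) stop("at least 4 parcels are required")
  if (abs(r_target) >= 1 || abs(r_anti) >= 1)
    stop("|r_target| and |r_anti| must be < 1")
  if (n_genes < 3L) stop("n_genes must be >= 3")
  set.seed(seed)
  refz <- zscore(reference_parcel_map)
  mix <- function(a) {
    v <- a * refz + sqrt(1 - a^2) * zscore(rnorm(P))
    zscore(v)
  }
  vals <- matrix(0, n_genes, P)
  vals[1, ] <- mix(r_target)
  vals[2, ] <- mix(r_anti)
  for (g in seq(3L, n_genes)) vals[g, ] <- zscore(rnorm(P))
  if (is.null(symbols))
    symbols <- c("GENE_TARGET", "GENE_ANTI",
                 sprintf("GENE_%04d", seq_len(n_genes - 2L) + 2L))
  if (anyDuplicated(symbols)) stop("gene symbols must be unique")
  expression_matrix(symbols, vals)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Construct an expression matrix
#'
#' @param genes character vector of unique gene symbols.
#' @param values gene x parcel numeric matrix, z-scored within gene.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(genes, values) {
  stopifnot(length(genes) == nrow(values), !anyDuplicated(genes))
  structure(list(genes = as.character(genes), values = values,
                 n_parcels = ncol(values)), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d parcels\n",
              length(x$genes), x$n_parcels))
  invisible(x)
}

#' Expression matrix TSV round trip
#'
#' Rows are genes, columns `parcel_000 .. parcel_(P-1)`; the first column
#' holds the gene symbol.
#'
#' @param expr an `expression_matrix`.
#' @param path file path.
#' @return `path` (save) or an `expression_matrix` (load).
#' @export
save_expression_tsv <- function(expr, path) {
  tab <- data.frame(gene = expr$genes,
                    matrix(sprintf("%.17g", expr$values),
                           nrow(expr$values), ncol(expr$values)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- c("gene", sprintf("parcel_%03d",
                                  seq_len(expr$n_parcels) - 1L))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_expression_tsv
#' @export
load_expression_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- NULL
  expression_matrix(tab$gene, vals)
}
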