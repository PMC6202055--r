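# Shared fixture builders.  Everything is generated in code at test time.

tiny_space <- function(n_gray = 100L, n_networks = 7L, n_parcels = 10L,
                       topology = "ring") {
  make_space(n_gray, n_networks, n_parcels, topology = topology)
}

# a quiet run with controllable motion/bold for scrubbing tests
manual_run <- function(T = 240L, G = 20L, baseline = 100, tr = 2.5,
                       subject = "s01", condition = "Pla", session = 1L) {
  bold_run(subject, condition, session,
           bold = matrix(baseline, T, G), tr = tr,
           motion = matrix(0, T, 6),
           ventricle_ts = rep(0, T), wm_ts = rep(0, T))
}

# small synthetic cohort for integration-style tests
small_cohort <- function(n_subjects = 4L, n_gray = 200L, T = 120L,
                         n_parcels = 10L, seed = 1L, ...) {
  sp <- make_space(n_gray, 7L, n_parcels)
  cfg <- generator_config(n_subjects = n_subjects, n_gray = n_gray, T = T,
                          n_parcels = n_parcels, seed = seed, ...)
  list(space = sp, cohort = simulate_cohort(sp, cfg), config = cfg)
}

# session-averaged per-subject maps for one condition
subject_maps <- function(co, sp, condition, gsr, fun = NULL) {
  if (is.null(fun)) fun <- function(pp) gbc_map(pp$residual)
  subj <- sort(unique(co$design$subject))
  t(vapply(subj, function(s) {
    ids <- co$design$run_id[co$design$subject == s &
                              co$design$condition == condition]
    rowMeans(vapply(ids, function(id)
      fun(preprocess_run(co$runs[[id]], sp, gsr = gsr)),
      numeric(sp$n_gray)))
  }, numeric(sp$n_gray)))
}

# independent TFCE oracle: literal threshold-sum with igraph components
tfce_oracle <- function(stat, edges, H = 2, E = 0.5, nsteps = 100) {
  n <- length(stat)
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  one_sign <- function(s) {
    out <- numeric(n)
    hmax <- max(s)
    if (hmax <= 0) return(out)
    dh <- hmax / nsteps
    steps <- seq_len(10 * nsteps)
    hs <- steps * dh
    for (h in hs[hs <= hmax * (1 + 1e-12)]) {
      keep <- which(s >= h)
      if (!length(keep)) next
      sub <- igraph::induced_subgraph(gr, keep)
      comp <- igraph::components(sub)
      sizes <- comp$csize[comp$membership]
      out[keep] <- out[keep] + sizes^E * h^H * dh
    }
    out
  }
  one_sign(stat) - one_sign(-stat)
}

# independent Steiger Z oracle, coded directly from the published formula
steiger_oracle <- function(r_ag, r_bg, r_ab, n) {
  zb <- function(r) 0.5 * log((1 + r) / (1 - r))
  rb <- (r_ag + r_bg) / 2
  num <- r_ab * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r_ab^2)
  sbar <- num / (1 - rb^2)^2
  (zb(r_ag) - zb(r_bg)) * sqrt((n - 3) / (2 - 2 * sbar))
}
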