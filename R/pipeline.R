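#' Default study configuration
#'
#' Parameters for a full synthetic study run: cohort dimensions, denoising
#' variants, permutation and TFCE settings, conjunction fraction, gene set
#' size, and the master seed from which every stochastic stage draws a
#' named substream.
#'
#' @param n_subjects,n_gray,T,n_networks,n_parcels cohort dimensions.
#' @param gsr `"both"`, `"on"`, or `"off"`.
#' @param n_perm permutations for group inference.
#' @param tfce_h,tfce_e,tfce_nsteps TFCE parameters.
#' @param conjunction_fraction rank fraction for the 4-way conjunction.
#' @param alpha FWE level.
#' @param n_genes size of the synthetic gene set.
#' @param seed master seed.
#' @param generator named list of overrides passed to [generator_config()].
#' @return a `study_config` list.
#' @export
study_config <- function(n_subjects = 24L, n_gray = 2000L, T = 240L,
                         n_networks = 7L, n_parcels = 180L,
                         gsr = c("both", "on", "off"), n_perm = 1000L,
                         tfce_h = 2, tfce_e = 0.5, tfce_nsteps = 100L,
                         conjunction_fraction = 0.10, alpha = 0.05,
                         n_genes = 1000L, seed = 1L, generator = list()) {
  gsr <- match.arg(gsr)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_gray = as.integer(n_gray), T = as.integer(T),
                 n_networks = as.integer(n_networks),
                 n_parcels = as.integer(n_parcels), gsr = gsr,
                 n_perm = as.integer(n_perm), tfce_h = tfce_h,
                 tfce_e = tfce_e, tfce_nsteps = as.integer(tfce_nsteps),
                 conjunction_fraction = conjunction_fraction,
                 alpha = alpha, n_genes = as.integer(n_genes),
                 seed = as.integer(seed), generator = generator),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose top-level keys are [study_config()]
#'   arguments (a `generator:` mapping is passed through as overrides).
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

# deterministic sub-seeds for the named stochastic stages
substream <- function(seed, stage) {
  offs <- c(cohort = 11L, perm = 23L, expr = 37L)
  (seed * 97L + offs[[stage]]) %% .Machine$integer.max
}

# fixed-format TSV writer so identical inputs give byte-identical files
write_report_tsv <- function(df, path) {
  df[] <- lapply(df, function(col)
    if (is.numeric(col) && !is.integer(col)) sprintf("%.10g", col) else col)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

session_mean_maps <- function(maps_by_run, design, subjects, condition,
                              session = NULL) {
  rows <- lapply(subjects, function(s) {
    sel <- design$subject == s & design$condition == condition
    if (!is.null(session)) sel <- sel & design$session == session
    ids <- design$run_id[sel]
    colMeans(do.call(rbind, maps_by_run[ids]))
  })
  do.call(rbind, rows)
}

#' Run the full analysis battery on a synthetic cohort
#'
#' Executes, in order: cohort simulation; per-run denoising with and
#' without GSR; per-run GBC (correlation and covariance), thalamic seed
#' FC, GS-beta and variance maps; group contrasts (condition main effect,
#' the three pairwise drug contrasts, drug versus the mean of the two
#' control conditions, and session contrasts); hyper/hypo mask means and
#' change-score correlations; the 4-way rank conjunction; network
#' summaries; behavioural correlations; and gene-expression matching.
#' Writes a TSV/JSON report bundle and returns the key results invisibly.
#'
#' @param config a `study_config`.
#' @param out_dir report directory (created if missing).
#' @return invisibly, a list with the cohort truth, contrast results,
#'   summary tables and the manifest.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  manifest <- list(package = "pharmaconn",
                   version = as.character(utils::packageVersion("pharmaconn")),
                   seed = config$seed, parameters = unclass(config),
                   sections = list())
  note <- function(name, status) {
    manifest$sections[[name]] <<- status
  }
  gsr_variants <- switch(config$gsr, both = c(TRUE, FALSE), on = TRUE,
                         off = FALSE)

  ## stage: cohort ---------------------------------------------------------
  gen_args <- utils::modifyList(
    list(n_subjects = config$n_subjects, n_gray = config$n_gray,
         T = config$T, n_networks = config$n_networks,
         n_parcels = config$n_parcels,
         seed = substream(config$seed, "cohort")),
    config$generator)
  gcfg <- do.call(generator_config, gen_args)
  space <- make_space(config$n_gray, config$n_networks, config$n_parcels)
  coh <- simulate_cohort(space, gcfg)
  subjects <- sort(unique(coh$design$subject))
  note("cohort", sprintf("simulated %d runs", length(coh$runs)))

  ## stage: preprocessing + per-run maps -----------------------------------
  thal <- structure_mask(space, "thalamus")
  maps <- list()   # maps[[metric]][[run_id]] = numeric map
  scrub_tab <- NULL
  var_tab <- NULL
  for (id in names(coh$runs)) {
    run <- coh$runs[[id]]
    for (gsr_on in gsr_variants) {
      pp <- preprocess_run(run, space, gsr = gsr_on)
      tag <- if (gsr_on) "gsr" else "nogsr"
      maps[[paste0("gbc_r_", tag)]][[id]] <- gbc_map(pp$residual)
      maps[[paste0("gbc_cov_", tag)]][[id]] <-
        gbc_map(pp$residual, method = "covariance")
      maps[[paste0("seed_r_", tag)]][[id]] <- seed_fc_map(pp$residual, thal)
      maps[[paste0("seed_cov_", tag)]][[id]] <-
        seed_fc_map(pp$residual, thal, method = "covariance")
      if (!gsr_on) {
        maps[["gs_beta"]][[id]] <- gs_beta_map(pp$residual, space)
        vs <- variance_summaries(pp$residual, space)
        maps[["local_var"]][[id]] <- vs$local_var
        var_tab <- rbind(var_tab,
                         data.frame(run_id = id, subject = run$subject,
                                    condition = run$condition,
                                    session = run$session,
                                    gs_variance = vs$gs_variance))
      }
    }
    mk <- scrub(run)
    scrub_tab <- rbind(scrub_tab,
                       data.frame(subject = run$subject,
                                  condition = run$condition,
                                  session = run$session,
                                  fraction_flagged = mk$fraction_flagged,
                                  excluded = mk$subject_excluded))
    coh$runs[[id]] <- NA  # release the bold matrix
  }
  write_report_tsv(scrub_tab, file.path(out_dir, "scrub_report.tsv"))
  write_report_tsv(var_tab, file.path(out_dir, "gs_variance.tsv"))
  note("preprocess", sprintf("gsr variants: %s",
                             paste(gsr_variants, collapse = "/")))
  note("variance_maps", "gs_variance.tsv + local_var maps")

  design <- coh$design
  cond_maps <- function(metric, condition, session = NULL)
    session_mean_maps(maps[[metric]], design, subjects, condition, session)

  ## stage: contrasts ------------------------------------------------------
  tf <- list(H = config$tfce_h, E = config$tfce_e,
             nsteps = config$tfce_nsteps)
  pseed <- substream(config$seed, "perm")
  contrasts <- list()
  contrast_tab <- NULL
  for (gsr_on in gsr_variants) {
    tag <- if (gsr_on) "gsr" else "nogsr"
    metric <- paste0("gbc_r_", tag)
    by_cond <- lapply(CONDITIONS, function(cn) cond_maps(metric, cn))
    names(by_cond) <- CONDITIONS
    rest <- (by_cond$Pla + by_cond$KetLSD) / 2
    specs <- list(
      main_effect = function() main_effect_contrast(
        by_cond, space, config$n_perm, tf$H, tf$E, tf$nsteps,
        config$alpha, pseed),
      lsd_vs_rest = function() paired_contrast(
        by_cond$LSD, rest, space, config$n_perm, tf$H, tf$E, tf$nsteps,
        config$alpha, pseed + 1L),
      lsd_vs_pla = function() paired_contrast(
        by_cond$LSD, by_cond$Pla, space, config$n_perm, tf$H, tf$E,
        tf$nsteps, config$alpha, pseed + 2L),
      lsd_vs_ketlsd = function() paired_contrast(
        by_cond$LSD, by_cond$KetLSD, space, config$n_perm, tf$H, tf$E,
        tf$nsteps, config$alpha, pseed + 3L),
      ketlsd_vs_pla = function() paired_contrast(
        by_cond$KetLSD, by_cond$Pla, space, config$n_perm, tf$H, tf$E,
        tf$nsteps, config$alpha, pseed + 4L))
    for (cn in CONDITIONS)
      specs[[paste0("session1_vs_2_", cn)]] <- local({
        cn0 <- cn
        function() paired_contrast(
          cond_maps(metric, cn0, 1L), cond_maps(metric, cn0, 2L), space,
          config$n_perm, tf$H, tf$E, tf$nsteps, config$alpha, pseed + 5L)
      })
    for (nm in names(specs)) {
      cr <- specs[[nm]]()
      contrasts[[paste(nm, tag, sep = "_")]] <- cr
      stat <- if (!is.null(cr$z)) cr$z else cr$F
      contrast_tab <- rbind(contrast_tab, data.frame(
        contrast = nm, gsr = tag, n_perm = cr$n_perm, seed = cr$seed,
        n_sig_pos = sum(cr$sig_mask_pos), n_sig_neg = sum(cr$sig_mask_neg),
        stat_min = min(stat), stat_max = max(stat)))
      save_map(stat, file.path(out_dir, "maps",
                               sprintf("%s_%s_stat.tsv", nm, tag)))
    }
    # GS-beta second-level contrast (non-GSR residual betas)
    if (!gsr_on) {
      gsb <- paired_contrast(
        session_mean_maps(maps$gs_beta, design, subjects, "LSD"),
        session_mean_maps(maps$gs_beta, design, subjects, "Pla"),
        space, config$n_perm, tf$H, tf$E, tf$nsteps, config$alpha,
        pseed + 6L)
      contrasts[["gs_beta_lsd_vs_pla"]] <- gsb
      contrast_tab <- rbind(contrast_tab, data.frame(
        contrast = "gs_beta_lsd_vs_pla", gsr = "nogsr",
        n_perm = gsb$n_perm, seed = gsb$seed,
        n_sig_pos = sum(gsb$sig_mask_pos),
        n_sig_neg = sum(gsb$sig_mask_neg),
        stat_min = min(gsb$z), stat_max = max(gsb$z)))
      save_map(gsb$z, file.path(out_dir, "maps", "gs_beta_contrast.tsv"))
    }
  }
  write_report_tsv(contrast_tab, file.path(out_dir, "contrasts.tsv"))
  note("contrasts", sprintf("%d contrasts", nrow(contrast_tab)))

  ## stage: GS-beta vs GBC contrast correlations ---------------------------
  gsr_tables <- NULL
  if (isTRUE(all(c(TRUE, FALSE) %in% gsr_variants))) {
    d_gsr <- colMeans(cond_maps("gbc_r_gsr", "LSD")) -
      colMeans(cond_maps("gbc_r_gsr", "Pla"))
    d_nogsr <- colMeans(cond_maps("gbc_r_nogsr", "LSD")) -
      colMeans(cond_maps("gbc_r_nogsr", "Pla"))
    gsb_z <- contrasts$gs_beta_lsd_vs_pla$z
    gsr_tables <- data.frame(
      comparison = c("gsbeta_vs_gbc_gsr", "gsbeta_vs_gbc_nogsr"),
      r = c(spatial_correlation(gsb_z, d_gsr),
            spatial_correlation(gsb_z, d_nogsr)))
    write_report_tsv(gsr_tables, file.path(out_dir,
                                           "gs_beta_correlations.tsv"))
    note("gs_beta_topography", "gs_beta_correlations.tsv")
  } else {
    note("gs_beta_topography",
         "skipped: requires both GSR variants (gsr=both)")
  }

  ## stage: hyper/hypo mask means and change scores ------------------------
  change_tab <- NULL
  for (gsr_on in gsr_variants) {
    tag <- if (gsr_on) "gsr" else "nogsr"
    cr <- contrasts[[paste0("lsd_vs_rest_", tag)]]
    if (sum(cr$sig_mask_pos) == 0 || sum(cr$sig_mask_neg) == 0) next
    metric <- paste0("gbc_r_", tag)
    pla <- cond_maps(metric, "Pla")
    lsd <- cond_maps(metric, "LSD")
    hyper <- mask_means(pla, cr$sig_mask_pos) -
      mask_means(lsd, cr$sig_mask_pos)
    hypo <- mask_means(pla, cr$sig_mask_neg) -
      mask_means(lsd, cr$sig_mask_neg)
    cc <- change_score_correlation(hyper, hypo)
    change_tab <- rbind(change_tab, data.frame(
      gsr = tag, n_hyper = sum(cr$sig_mask_pos),
      n_hypo = sum(cr$sig_mask_neg), r = cc$r, p = cc$p))
  }
  if (!is.null(change_tab)) {
    write_report_tsv(change_tab, file.path(out_dir, "change_scores.tsv"))
    note("hyper_hypo_coupling", "change_scores.tsv")
  } else {
    note("hyper_hypo_coupling",
         "skipped: no significant hyper/hypo regions")
  }

  ## stage: conjunction ----------------------------------------------------
  conj_tab <- NULL
  conj <- NULL
  if (isTRUE(all(c(TRUE, FALSE) %in% gsr_variants))) {
    # mask from the four thalamic-seed placebo means (r/cov x GSR/noGSR);
    # the mask is then applied to every connectivity variant
    ctx <- is_cortex(space)
    pla4 <- lapply(c("seed_r_gsr", "seed_cov_gsr", "seed_r_nogsr",
                     "seed_cov_nogsr"),
                   function(v) colMeans(cond_maps(v, "Pla")))
    conj <- top_bottom_conjunction(pla4, config$conjunction_fraction,
                                   eligible = ctx)
    if (sum(conj$top) > 0 && sum(conj$bottom) > 0) {
      for (family in c("seed", "gbc"))
        for (v in c("r_gsr", "cov_gsr", "r_nogsr", "cov_nogsr")) {
          metric <- paste0(family, "_", v)
          dmap <- colMeans(cond_maps(metric, "LSD")) -
            colMeans(cond_maps(metric, "Pla"))
          conj_tab <- rbind(conj_tab, data.frame(
            family = family, variant = v, n_top = sum(conj$top),
            n_bottom = sum(conj$bottom),
            delta_top = mean(dmap[conj$top]),
            delta_bottom = mean(dmap[conj$bottom])))
        }
      write_report_tsv(conj_tab, file.path(out_dir, "conjunction.tsv"))
      note("conjunction", "conjunction.tsv")
    } else {
      note("conjunction", "skipped: empty top/bottom conjunction")
    }
  } else {
    note("conjunction", "skipped: requires both GSR variants (gsr=both)")
  }

  ## stage: network means + symptom correlations ---------------------------
  net_tab <- NULL
  symp_tab <- NULL
  for (gsr_on in gsr_variants) {
    tag <- if (gsr_on) "gsr" else "nogsr"
    metric <- paste0("gbc_r_", tag)
    for (cn in CONDITIONS) for (ss in c(1L, 2L)) {
      nm <- colMeans(network_means(cond_maps(metric, cn, ss), space))
      net_tab <- rbind(net_tab, data.frame(
        gsr = tag, condition = cn, session = ss,
        network = names(nm), mean_fz = unname(nm)))
    }
    dnet <- network_means(cond_maps(metric, "LSD", 2L), space) -
      network_means(cond_maps(metric, "Pla", 2L), space)
    beh <- coh$truth$behavior
    sc <- beh$score[beh$condition == "LSD" & beh$time == 250]
    names(sc) <- beh$subject[beh$condition == "LSD" & beh$time == 250]
    st <- symptom_correlations(dnet, sc[subjects])
    st$gsr <- tag
    symp_tab <- rbind(symp_tab, st)
  }
  write_report_tsv(net_tab, file.path(out_dir, "network_means.tsv"))
  write_report_tsv(symp_tab, file.path(out_dir,
                                       "symptom_correlations.tsv"))
  note("network_summaries", "network_means.tsv")
  note("symptom_correlations", "symptom_correlations.tsv")

  ## stage: gene matching --------------------------------------------------
  gene_section <- NULL
  if (isTRUE(all(c(TRUE, FALSE) %in% gsr_variants))) {
    truth_parcel <- parcellate_map(coh$truth$coupling_change, space)
    expr <- simulate_expression(space, truth_parcel, config$n_genes,
                                seed = substream(config$seed, "expr"))
    z_gsr <- parcellate_map(contrasts$lsd_vs_rest_gsr$z, space)
    z_nogsr <- parcellate_map(contrasts$lsd_vs_rest_nogsr$z, space)
    gm_gsr <- gene_map_correlations(z_gsr, expr)
    gm_nogsr <- gene_map_correlations(z_nogsr, expr)
    r_maps <- spatial_correlation(z_gsr, z_nogsr)
    target <- expr$genes[1]
    steiger <- compare_dependent_correlations(
      gm_gsr$r[target], gm_nogsr$r[target], r_maps, gm_gsr$n_parcels)
    gene_section <- data.frame(
      gene = target, r_gsr = unname(gm_gsr$r[target]),
      r_nogsr = unname(gm_nogsr$r[target]),
      percentile_gsr = unname(gm_gsr$percentile[target]),
      steiger_z = steiger$z, steiger_p = steiger$p)
    write_report_tsv(gene_section, file.path(out_dir, "gene_match.tsv"))
    ens <- expression_network_summary(expr, space)
    write_report_tsv(
      data.frame(gene = rownames(ens$network_means)[1:2],
                 ens$network_means[1:2, , drop = FALSE]),
      file.path(out_dir, "gene_network_means.tsv"))
    note("gene_matching", "gene_match.tsv")
  } else {
    note("gene_matching",
         "skipped: requires both GSR variants (gsr=both)")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truth = coh$truth, space = space, contrasts = contrasts,
                 scrub = scrub_tab, change_scores = change_tab,
                 conjunction = conj_tab, conjunction_mask = conj,
                 networks = net_tab,
                 symptoms = symp_tab, gs_beta = gsr_tables,
                 genes = gene_section, manifest = manifest))
}
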