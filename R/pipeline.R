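#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full pipeline run:
#' cohort composition, atlas resolution, bands, generator parameters,
#' statistical thresholds and seeds. Defaults are desk-scale (24-node atlas,
#' 250 Hz, 16 trials, 199 permutations) so a complete run finishes in
#' minutes; the full-scale layout (156 nodes, 1000 Hz, 5000 permutations)
#' is a matter of overriding `nodes_per_roi`, `fs` and `n_perm`.
#'
#' @param n_control,n_bd,females cohort composition (see [make_design()]).
#' @param nodes_per_roi atlas resolution (26 for the full 156-node layout).
#' @param bands character vector of band names to analyse.
#' @param fs,trial_len,n_trials sampling rate (Hz), trial length (s), trials
#'   per subject.
#' @param kind `"phase"` (direct phase simulation) or `"signal"` (continuous
#'   signal simulation followed by FIR band-pass filtering and
#'   segmentation).
#' @param amp,noise_sd,drift_sd signal-kind generator parameters.
#' @param base_kappa baseline coupling concentration of every analysed ROI
#'   pair's block.
#' @param control_post_gain multiplier on kappa at the post session for
#'   controls; the default 0.95 emulates normal maturation (ratio slightly
#'   below 1).
#' @param bd_post_gain multiplier on kappa at the post session for the bd
#'   group; the default 1.15 plants the hypersynchronisation pattern.
#' @param roi_pairs list of length-2 character vectors of ROI labels to
#'   analyse.
#' @param alpha,node_frac,link_frac,n_perm,bonferroni statistical thresholds
#'   (see [linkwise_perm_ancova()], [extract_motifs()],
#'   [degree_group_test()]).
#' @param include_dti run the structural (DTI) arm on a synthetic null
#'   table.
#' @param dti_tracts tract labels for the DTI arm.
#' @param seed master seed; expanded into independent per-stage sub-streams.
#' @param out_dir directory for reports (`NULL` = return only).
#' @return a validated `plv_run_config` list.
#' @export
run_config <- function(n_control = 22, n_bd = 17,
                       females = list(control = 12, bd = 8),
                       nodes_per_roi = 4,
                       bands = "theta",
                       fs = 250, trial_len = 4, n_trials = 16,
                       kind = "phase",
                       amp = 1, noise_sd = 0.5, drift_sd = 0.02,
                       base_kappa = 2,
                       control_post_gain = 0.95, bd_post_gain = 1.15,
                       roi_pairs = list(c("FMC", "rIPL")),
                       alpha = 0.05, node_frac = 0.25, link_frac = 0.10,
                       n_perm = 199, bonferroni = 5,
                       include_dti = TRUE, dti_tracts = jhu_tracts()[1:5],
                       seed = 1, out_dir = NULL) {
  cfg <- structure(list(
    n_control = n_control, n_bd = n_bd, females = females,
    nodes_per_roi = nodes_per_roi, bands = bands, fs = fs,
    trial_len = trial_len, n_trials = n_trials, kind = kind, amp = amp,
    noise_sd = noise_sd, drift_sd = drift_sd, base_kappa = base_kappa,
    control_post_gain = control_post_gain, bd_post_gain = bd_post_gain,
    roi_pairs = roi_pairs, alpha = alpha, node_frac = node_frac,
    link_frac = link_frac, n_perm = n_perm, bonferroni = bonferroni,
    include_dti = include_dti, dti_tracts = dti_tracts, seed = seed,
    out_dir = out_dir), class = "plv_run_config")
  validate_config(cfg)
  cfg
}

#' @rdname run_config
#' @export
validate_config <- function(config) {
  bad <- function(field, why) {
    .stopf("plvmotif_config_error", "config error at $%s: %s", field, why)
  }
  with(config, {
    if (!is.numeric(n_perm) || n_perm < 1) bad("n_perm", "must be >= 1")
    for (f in c("alpha", "node_frac", "link_frac")) {
      v <- config[[f]]
      if (!is.numeric(v) || v <= 0 || v > 1) bad(f, "must lie in (0, 1]")
    }
    if (!kind %in% c("phase", "signal")) bad("kind", "must be 'phase' or 'signal'")
    if (kind == "signal" && n_trials < 15) {
      bad("n_trials", "signal runs need at least 15 trials per subject")
    }
    if (!all(bands %in% names(dmn_bands()))) {
      bad("bands", paste("unknown band(s):",
                         paste(setdiff(bands, names(dmn_bands())), collapse = ", ")))
    }
    rois <- c("Pc", "PCC", "ACC", "FMC", "lIPL", "rIPL")
    for (i in seq_along(roi_pairs)) {
      rp <- roi_pairs[[i]]
      if (length(rp) != 2 || !all(rp %in% rois)) {
        bad(sprintf("roi_pairs[[%d]]", i), "must be two valid ROI labels")
      }
    }
    if (abs(fs * trial_len - round(fs * trial_len)) > 1e-9) {
      bad("fs", "fs * trial_len must be an integer sample count")
    }
    if (base_kappa < 0 || control_post_gain < 0 || bd_post_gain < 0) {
      bad("base_kappa", "coupling parameters must be >= 0")
    }
    if (!is.null(out_dir) && !is.character(out_dir)) bad("out_dir", "must be a path")
  })
  invisible(config)
}

#' @rdname run_config
#' @param ... overrides passed on to [run_config()].
#' @export
demo_config <- function(seed = 1, ...) {
  run_config(seed = seed, ...)
}

#' @rdname run_config
#' @export
null_config <- function(seed = 1, ...) {
  run_config(seed = seed, bd_post_gain = 0.95, ...)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stopf("plvmotif_stage_error", "pipeline stage '%s' failed: %s", name,
           conditionMessage(e))
  })
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate -> (filter ->) PLV -> ratio -> link statistics ->
#' motif extraction and correction -> degree summaries -> classification,
#' plus the structural DTI arm, as one reproducible run. All randomness
#' derives from `config$seed` through per-stage sub-streams, so the same
#' configuration yields a byte-identical JSON report.
#'
#' @param config a [run_config()].
#' @return a `plv_run_report` list: per band and ROI pair, the link
#'   statistics summary and every significant-motif record (mass, corrected
#'   p, per-group degree mean and SD, Cohen's d, LOO accuracy, per-group
#'   one-sample t-tests against 1, per-ROI centroids); the DTI table; the
#'   configuration echo and its MD5 hash. Written to `config$out_dir` as
#'   JSON + CSV + a timestamped log when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  t0 <- Sys.time()
  log_lines <- character(0)
  logit <- function(fmt, ...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  logit("run start; config hash %s", .config_hash(config))
  seeds <- .seed_streams(config$seed, 4 + 2 * length(config$bands))
  design <- .stage("design", make_design(config$n_control, config$n_bd,
                                         unlist(config$females), seeds[1]))
  atlas <- .stage("atlas", dmn_atlas(config$nodes_per_roi))
  logit("cohort: %d control, %d bd; atlas: %d nodes", config$n_control,
        config$n_bd, nrow(atlas))
  bands <- dmn_bands()[config$bands]
  band_reports <- list()
  n_sig_motifs <- 0L
  for (bi in seq_along(bands)) {
    band <- bands[[bi]]
    seed_pre <- seeds[3 + 2 * bi]
    seed_post <- seeds[4 + 2 * bi]
    ratios <- .stage(paste0("connectivity/", band$name),
                     .band_ratios(config, design, atlas, band,
                                  seed_pre, seed_post))
    pair_reports <- list()
    for (rp in config$roi_pairs) {
      key <- paste(rp, collapse = "-")
      pr <- .stage(paste0("stats/", band$name, "/", key),
                   .analyse_pair(config, design, atlas, band, ratios, rp))
      n_sig_motifs <- n_sig_motifs + pr$n_significant_motifs
      pair_reports[[key]] <- pr
      logit("band %s pair %s: %d link(s) significant, %d motif(s), %d significant",
            band$name, key, pr$n_significant_links, pr$n_motifs,
            pr$n_significant_motifs)
    }
    band_reports[[band$name]] <- pair_reports
  }
  dti_report <- NULL
  if (isTRUE(config$include_dti)) {
    dti_report <- .stage("dti", {
      tab <- simulate_dti_table(design, tract_labels = config$dti_tracts,
                                seed = seeds[2])
      as.data.frame(rm_ancova_dti(tab, design))
    })
    logit("dti arm: %d tract x metric cells, %d interaction p < 0.05",
          nrow(dti_report), sum(dti_report$p_interaction < 0.05))
  }
  report <- list(config = unclass(config),
                 config_hash = .config_hash(config),
                 design = as.data.frame(design),
                 bands = band_reports,
                 dti = dti_report,
                 n_significant_motifs = n_sig_motifs)
  class(report) <- "plv_run_report"
  logit("run finished in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(config$out_dir)) {
    .write_report(report, log_lines, config$out_dir)
  }
  attr(report, "log") <- log_lines
  report
}

# Per-subject post/pre ratio matrices for one band.
.band_ratios <- function(config, design, atlas, band, seed_pre, seed_post) {
  n_nodes <- nrow(atlas)
  kap <- matrix(0, n_nodes, n_nodes)
  for (rp in config$roi_pairs) {
    kap <- kappa_block(kap, nodes_a = which(atlas$roi == rp[1]),
                       nodes_b = which(atlas$roi == rp[2]),
                       value = config$base_kappa)
  }
  f0 <- (band$f_lo + band$f_hi) / 2
  make_plan <- function(gain) {
    if (config$kind == "signal") {
      coupling_plan(n_nodes, kap * gain, fs = config$fs,
                    trial_len = config$n_trials * config$trial_len,
                    n_trials = 1, f0 = f0, kind = "signal",
                    amp = config$amp, noise_sd = config$noise_sd,
                    drift_sd = config$drift_sd)
    } else {
      coupling_plan(n_nodes, kap * gain, fs = config$fs,
                    trial_len = config$trial_len, n_trials = config$n_trials,
                    f0 = f0, kind = "phase")
    }
  }
  sims <- list(
    pre = simulate_session(design, make_plan(1), seed = seed_pre,
                           session = "pre", node_ids = atlas$node_id),
    post = c(simulate_session(design, make_plan(config$control_post_gain),
                              seed = seed_post, session = "post",
                              subjects = design$subject_id[design$group == "control"],
                              node_ids = atlas$node_id),
             simulate_session(design, make_plan(config$bd_post_gain),
                              seed = seed_post, session = "post",
                              subjects = design$subject_id[design$group == "bd"],
                              node_ids = atlas$node_id)))
  conn <- lapply(sims, function(session_trials) {
    lapply(session_trials, function(ts) {
      if (config$kind == "signal") {
        filtered <- bandpass(ts$data[1, , ], band, config$fs)
        ts <- segment_trials(filtered, config$fs, config$trial_len,
                             min_trials = 15, subject_id = ts$subject_id,
                             session = ts$session, band = band,
                             kind = "signal")
        ts$node_ids <- atlas$node_id
      }
      ts$band <- band
      plv_matrix(ts)
    })
  })
  ratios <- lapply(design$subject_id, function(sid) {
    ratio_matrix(conn$post[[sid]], conn$pre[[sid]])
  })
  names(ratios) <- design$subject_id
  ratios
}

# Link test, motif extraction/correction and motif summaries for one pair.
.analyse_pair <- function(config, design, atlas, band, ratios, rp) {
  universe <- link_universe(atlas, rp[1], rp[2])
  stat_seed <- .seed_streams(config$seed + match(band$name, names(dmn_bands())),
                             1)
  stats <- linkwise_perm_ancova(ratios, design, universe,
                                n_perm = config$n_perm, alpha = config$alpha,
                                seed = stat_seed)
  motifs <- extract_motifs(stats, atlas, node_frac = config$node_frac,
                           link_frac = config$link_frac)
  motifs <- motif_perm_test(motifs, ratios, design, universe, atlas = atlas)
  motif_records <- lapply(motifs, function(m) {
    deg <- motif_degree(m, ratios)
    gt <- degree_group_test(deg, design, n_bands = config$bonferroni)
    acc <- loo_logreg_accuracy(deg[design$subject_id], design$group)
    t_bd <- one_sample_t_vs1(deg[design$subject_id[design$group == "bd"]])
    t_cn <- one_sample_t_vs1(deg[design$subject_id[design$group == "control"]])
    list(nodes = m$nodes,
         links = m$links,
         n_links = m$n_links,
         mass = m$mass,
         p_corrected = m$p_corrected,
         significant = m$p_corrected < config$alpha,
         degree_mean_bd = unname(gt$group_stats$mean[gt$group_stats$group == "bd"]),
         degree_sd_bd = unname(gt$group_stats$sd[gt$group_stats$group == "bd"]),
         degree_mean_control = unname(gt$group_stats$mean[gt$group_stats$group == "control"]),
         degree_sd_control = unname(gt$group_stats$sd[gt$group_stats$group == "control"]),
         ancova_F = gt$F, ancova_p = gt$p_raw,
         ancova_p_corrected = gt$p_corrected,
         cohen_d = gt$cohen_d,
         accuracy = as.numeric(acc),
         ttest_bd = t_bd,
         ttest_control = t_cn,
         centroids = motif_centroid(m$nodes, atlas))
  })
  list(roi_pair = rp,
       n_links = nrow(universe),
       n_significant_links = sum(stats$significant),
       n_motifs = length(motifs),
       n_significant_motifs = sum(vapply(motif_records, function(m) m$significant,
                                         logical(1))),
       link_stats = as.data.frame(stats),
       motifs = motif_records)
}

.write_report <- function(report, log_lines, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  rows <- list()
  for (bn in names(report$bands)) {
    for (key in names(report$bands[[bn]])) {
      pr <- report$bands[[bn]][[key]]
      for (m in pr$motifs) {
        rows[[length(rows) + 1]] <- data.frame(
          band = bn, roi_pair = key, n_nodes = length(m$nodes),
          n_links = m$n_links, mass = m$mass, p_corrected = m$p_corrected,
          degree_mean_bd = m$degree_mean_bd, degree_sd_bd = m$degree_sd_bd,
          degree_mean_control = m$degree_mean_control,
          degree_sd_control = m$degree_sd_control,
          ancova_p = m$ancova_p, ancova_p_corrected = m$ancova_p_corrected,
          cohen_d = m$cohen_d, accuracy = m$accuracy,
          t_bd = m$ttest_bd$t, p_bd = m$ttest_bd$p,
          t_control = m$ttest_control$t, p_control = m$ttest_control$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) {
    utils::write.csv(do.call(rbind, rows), file.path(out_dir, "motifs.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$dti)) {
    utils::write.csv(report$dti, file.path(out_dir, "dti_ancova.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
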