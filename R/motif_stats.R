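#' Link-wise permutation ANCOVA on connectivity ratios
#'
#' For every link of a universe, fits an ordinary least-squares ANCOVA of the
#' per-subject PLV ratio on group with sex as covariate, and assesses the
#' group F statistic against a Freedman-Lane permutation null: residuals of
#' the sex-only model are permuted over whole subjects and added back to the
#' reduced-model fit. P-values use the add-one estimator
#' `(1 + #permuted F >= observed F) / (n_perm + 1)`, so they are valid and
#' never zero. Links with constant ratios across all subjects have an
#' undefined statistic and are flagged not-significant with a warning.
#'
#' @param ratios named list of [ratio_matrix()] results (or node x node
#'   matrices), one per subject.
#' @param design a [make_design()] roster (at least 2 subjects per group).
#' @param universe a [link_universe()] data frame.
#' @param n_perm number of label permutations (default 5000).
#' @param alpha per-link significance threshold: links with `p < alpha` are
#'   flagged significant.
#' @param seed integer seed for the permutation stream.
#' @return a `link_stats` data frame with one row per universe link:
#'   `node_i`, `node_j`, `F`, `p`, `significant`; attributes carry the
#'   universe, thresholds and seed so downstream stages can reproduce the
#'   ensemble.
#' @export
linkwise_perm_ancova <- function(ratios, design, universe, n_perm = 5000,
                                 alpha = 0.05, seed = 1) {
  if (min(table(design$group)) < 2) {
    .stopf("plvmotif_design_error", "each group needs at least 2 subjects")
  }
  if (nrow(universe) < 1) {
    .stopf("plvmotif_design_error", "link universe is empty")
  }
  Y <- ratio_link_matrix(ratios, universe, design)
  ens <- .perm_F_ensemble(Y, design$group, design$sex, n_perm, seed)
  p <- (1 + colSums(ens$F_perm >= matrix(ens$F_obs, n_perm, ncol(Y),
                                         byrow = TRUE))) / (n_perm + 1)
  if (any(ens$constant)) {
    .warnf("%d link(s) have constant ratios across subjects; statistic undefined, flagged not-significant",
           sum(ens$constant))
    p[ens$constant] <- 1
  }
  out <- data.frame(node_i = universe$node_i, node_j = universe$node_j,
                    F = ens$F_obs, p = p,
                    significant = p < alpha & !ens$constant,
                    stringsAsFactors = FALSE)
  attr(out, "universe") <- universe
  attr(out, "roi_a") <- attr(universe, "roi_a")
  attr(out, "roi_b") <- attr(universe, "roi_b")
  attr(out, "n_perm") <- n_perm
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  class(out) <- c("link_stats", "data.frame")
  out
}

# Connected components of a significant-link graph together with the motif
# qualification criteria. `sig` is a data frame (node_i, node_j, F).
# Returns a list of candidate components with qualification flags.
.motif_components <- function(sig, roi_of, roi_sizes, roi_pair, universe_size,
                              node_frac, link_frac,
                              density_denom = c("universe", "component")) {
  density_denom <- match.arg(density_denom)
  if (nrow(sig) == 0) return(list())
  sig$node_i <- as.character(sig$node_i)
  sig$node_j <- as.character(sig$node_j)
  g <- igraph::graph_from_data_frame(sig[, c("node_i", "node_j")],
                                     directed = FALSE)
  memb <- igraph::components(g)$membership
  verts <- names(memb)
  comp_i <- memb[sig$node_i]
  lapply(seq_len(max(memb)), function(cid) {
    nodes <- verts[memb == cid]
    links <- sig[comp_i == cid, , drop = FALSE]
    rois <- unique(roi_pair)
    n_in_roi <- vapply(rois, function(r) sum(roi_of[nodes] == r), integer(1))
    cover_ok <- all(n_in_roi + 1e-9 >= node_frac * roi_sizes[rois])
    denom <- if (density_denom == "universe") {
      universe_size
    } else if (roi_pair[1] == roi_pair[2]) {
      length(nodes) * (length(nodes) - 1) / 2
    } else {
      prod(pmax(n_in_roi, 1))
    }
    density_ok <- nrow(links) + 1e-9 >= link_frac * denom
    list(nodes = nodes, links = links, mass = sum(links$F),
         n_in_roi = n_in_roi, cover_ok = cover_ok, density_ok = density_ok)
  })
}

#' Extract network motifs from link-wise statistics
#'
#' A motif is a connected component of the significant-link graph that
#' additionally satisfies two size criteria: (a) node coverage - for each ROI
#' of the pair, the component must contain at least `node_frac` of that ROI's
#' nodes; and (b) link density - the component's significant links must be at
#' least `link_frac` of the analysed link universe. Connectedness holds by
#' construction. An empty result is allowed.
#'
#' @param stats a [linkwise_perm_ancova()] result.
#' @param atlas the [dmn_atlas()] the universe was built from.
#' @param node_frac minimum per-ROI node coverage fraction (default 0.25).
#' @param link_frac minimum link-density fraction (default 0.10).
#' @param density_denom denominator of the link-density criterion: the full
#'   ROI-pair `"universe"` (default) or the `"component"`-internal pair
#'   count.
#' @return a `plv_motif_list`: list of `plv_motif` objects, each with member
#'   `nodes`, significant `links`, `mass` (sum of member-link F statistics),
#'   coverage/density diagnostics and (initially `NA`) `p_corrected`.
#' @export
extract_motifs <- function(stats, atlas, node_frac = 0.25, link_frac = 0.10,
                           density_denom = c("universe", "component")) {
  density_denom <- match.arg(density_denom)
  roi_pair <- c(attr(stats, "roi_a"), attr(stats, "roi_b"))
  roi_of <- stats::setNames(atlas$roi, atlas$node_id)
  roi_sizes <- attr(atlas, "roi_sizes")
  comps <- .motif_components(stats[stats$significant, , drop = FALSE],
                             roi_of, roi_sizes, roi_pair, nrow(stats),
                             node_frac, link_frac, density_denom)
  keep <- Filter(function(cm) cm$cover_ok && cm$density_ok, comps)
  motifs <- lapply(keep, function(cm) {
    structure(list(roi_pair = roi_pair, nodes = sort(cm$nodes),
                   links = cm$links[, c("node_i", "node_j", "F", "p")],
                   n_links = nrow(cm$links), mass = cm$mass,
                   node_coverage = cm$n_in_roi / roi_sizes[unique(roi_pair)],
                   link_density = nrow(cm$links) / nrow(stats),
                   p_corrected = NA_real_),
              class = "plv_motif")
  })
  structure(motifs, class = "plv_motif_list",
            node_frac = node_frac, link_frac = link_frac,
            density_denom = density_denom,
            roi_a = roi_pair[1], roi_b = roi_pair[2],
            alpha = attr(stats, "alpha"), n_perm = attr(stats, "n_perm"),
            seed = attr(stats, "seed"))
}

#' Motif-level permutation correction (max-mass family-wise control)
#'
#' Controls the family-wise error over all candidate motifs of a universe by
#' the max-statistic construction used in cluster-based permutation tests:
#' one Freedman-Lane F ensemble is computed (with the same seed as the
#' link-wise test, so observed link significance is reproduced exactly); for
#' each permutation, per-link p-values are the pooled ranks of that
#' permutation's F within the (n_perm + 1)-row ensemble, links are
#' thresholded at `alpha`, the motif criteria are re-applied, and the maximum
#' qualifying motif mass is recorded (0 if none). The corrected p of an
#' observed motif is `(1 + #max-mass >= observed mass) / (n_perm + 1)`.
#'
#' @inheritParams linkwise_perm_ancova
#' @param motifs a [extract_motifs()] result for the same universe.
#' @param atlas the [dmn_atlas()] the universe was built from.
#' @param node_frac,link_frac,density_denom motif criteria (defaults taken
#'   from `motifs`).
#' @param alpha per-link threshold (default taken from `motifs`).
#' @param seed permutation seed; must equal the link-wise seed to reproduce
#'   the observed significance pattern (default taken from `motifs`).
#' @return `motifs` with `p_corrected` filled in; the permutation max-mass
#'   distribution is attached as attribute `null_max_mass`.
#' @export
motif_perm_test <- function(motifs, ratios, design, universe,
                            n_perm = attr(motifs, "n_perm"),
                            alpha = attr(motifs, "alpha"),
                            seed = attr(motifs, "seed"),
                            atlas = NULL,
                            node_frac = attr(motifs, "node_frac"),
                            link_frac = attr(motifs, "link_frac"),
                            density_denom = attr(motifs, "density_denom")) {
  if (is.null(n_perm) || n_perm < 1) {
    .stopf("plvmotif_parameter_error", "n_perm must be >= 1")
  }
  if (length(motifs) == 0) return(motifs)
  if (is.null(atlas)) {
    .stopf("plvmotif_parameter_error", "atlas is required")
  }
  roi_pair <- c(attr(universe, "roi_a"), attr(universe, "roi_b"))
  roi_of <- stats::setNames(atlas$roi, atlas$node_id)
  roi_sizes <- attr(atlas, "roi_sizes")
  Y <- ratio_link_matrix(ratios, universe, design)
  ens <- .perm_F_ensemble(Y, design$group, design$sex, n_perm, seed)
  F_all <- rbind(ens$F_obs, ens$F_perm)   # (n_perm + 1) x L, row 1 observed
  B1 <- n_perm + 1
  # pooled ranks within the ensemble: p = #(F >= F_r) / (B + 1); for the
  # observed row this equals the add-one link-wise estimator exactly
  p_all <- apply(F_all, 2, function(f) (B1 + 1 - rank(f, ties.method = "min")) / B1)
  min_links <- link_frac * nrow(universe)  # cheap lower bound for skipping
  null_max <- vapply(seq_len(n_perm) + 1L, function(r) {
    sig_idx <- which(p_all[r, ] < alpha)
    if (length(sig_idx) + 1e-9 < min_links && density_denom == "universe") return(0)
    if (length(sig_idx) == 0) return(0)
    sig <- data.frame(node_i = universe$node_i[sig_idx],
                      node_j = universe$node_j[sig_idx],
                      F = F_all[r, sig_idx], stringsAsFactors = FALSE)
    comps <- .motif_components(sig, roi_of, roi_sizes, roi_pair,
                               nrow(universe), node_frac, link_frac,
                               density_denom)
    masses <- vapply(comps, function(cm) {
      if (cm$cover_ok && cm$density_ok) cm$mass else 0
    }, numeric(1))
    if (length(masses)) max(masses) else 0
  }, numeric(1))
  out <- lapply(motifs, function(m) {
    m$p_corrected <- (1 + sum(null_max >= m$mass - 1e-12)) / B1
    m
  })
  attributes(out) <- attributes(motifs)
  attr(out, "null_max_mass") <- null_max
  out
}

#' Per-subject motif degree
#'
#' The motif summary score of one subject: the arithmetic mean of that
#' subject's PLV ratios over the motif's member links (the "degree" of the
#' motif, not the graph-theoretic node degree).
#'
#' @param motif a `plv_motif`.
#' @param ratios named list of [ratio_matrix()] results (or matrices).
#' @return named numeric vector, one degree per subject.
#' @export
motif_degree <- function(motif, ratios) {
  idx <- cbind(motif$links$node_i, motif$links$node_j)
  vapply(ratios, function(r) {
    m <- if (inherits(r, "plv_ratio")) r$ratio else as.matrix(r)
    mean(m[idx])
  }, numeric(1))
}

#' Group comparison of motif degrees
#'
#' ANCOVA of per-subject degree on group with sex as covariate, Bonferroni
#' corrected for the number of analysed frequency bands by multiplying the
#' p-value (capped at 1), plus Cohen's d with the pooled standard deviation
#' (oriented bd - control).
#'
#' @param degrees named per-subject degrees (names = subject ids).
#' @param design a [make_design()] roster.
#' @param n_bands Bonferroni factor (default 5 frequency bands).
#' @return list with `F`, `p_raw`, `p_corrected`, `cohen_d`, `df` and
#'   per-group `mean`/`sd`/`n`.
#' @export
degree_group_test <- function(degrees, design, n_bands = 5) {
  d <- design
  d$degree <- as.numeric(degrees[d$subject_id])
  if (length(unique(d$group)) < 2) {
    .stopf("plvmotif_design_error", "both groups must be represented")
  }
  x_bd <- d$degree[d$group == "bd"]
  x_cn <- d$degree[d$group == "control"]
  cohen_d <- .cohens_d(x_bd, x_cn)   # errors first on zero pooled SD
  fit <- stats::anova(stats::lm(degree ~ sex + group, data = d))
  p_raw <- fit["group", "Pr(>F)"]
  list(F = fit["group", "F value"],
       p_raw = p_raw,
       p_corrected = min(1, n_bands * p_raw),
       cohen_d = cohen_d,
       df = c(fit["group", "Df"], fit["Residuals", "Df"]),
       group_stats = data.frame(
         group = c("bd", "control"),
         mean = c(mean(x_bd), mean(x_cn)),
         sd = c(stats::sd(x_bd), stats::sd(x_cn)),
         n = c(length(x_bd), length(x_cn))))
}

#' One-sample t-test against a unit mean
#'
#' Two-sided t-test of whether a group's mean PLV ratio differs from 1
#' (ratio 1 = no longitudinal change). Accepts either the raw per-subject
#' values or printed summary statistics (mean, SD, n).
#'
#' @param x numeric vector of per-subject values, or `NULL` when summary
#'   statistics are supplied.
#' @param mean,sd,n summary statistics (used when `x` is `NULL`).
#' @param mu null mean (default 1).
#' @return list with `t`, `df`, `p` (two-sided).
#' @examples
#' one_sample_t_vs1(mean = 1.07, sd = 0.07, n = 17)  # t = 4.12, p < 1e-3
#' @export
one_sample_t_vs1 <- function(x = NULL, mean = NULL, sd = NULL, n = NULL,
                             mu = 1) {
  if (!is.null(x)) {
    n <- length(x)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  if (n < 2) .stopf("plvmotif_degenerate_test", "need n >= 2")
  if (!is.finite(sd) || sd <= 0) {
    .stopf("plvmotif_degenerate_test", "zero or undefined standard deviation")
  }
  t_stat <- (mean - mu) / (sd / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * stats::pt(-abs(t_stat), n - 1))
}

#' Leave-one-out logistic-regression classification accuracy
#'
#' For each subject in turn, a logistic regression of group on degree is fit
#' to the remaining subjects and the held-out subject's label predicted at a
#' probability threshold of 0.5 (exactly 0.5 classifies as control).
#'
#' @param degrees per-subject degrees.
#' @param groups factor with levels `control`, `bd` (same order as
#'   `degrees`).
#' @return accuracy in `[0, 1]`; per-fold predictions in attribute
#'   `predicted`.
#' @export
loo_logreg_accuracy <- function(degrees, groups) {
  groups <- factor(groups, levels = c("control", "bd"))
  if (length(unique(groups[!is.na(groups)])) < 2 ||
      min(table(groups)) < 2) {
    .stopf("plvmotif_design_error", "need at least 2 subjects in each of the two groups")
  }
  n <- length(degrees)
  dat <- data.frame(y = as.integer(groups == "bd"), degree = as.numeric(degrees))
  pred <- vapply(seq_len(n), function(i) {
    fit <- suppressWarnings(stats::glm(y ~ degree, family = stats::binomial(),
                                       data = dat[-i, ]))
    prob <- suppressWarnings(stats::predict(fit, newdata = dat[i, , drop = FALSE],
                                            type = "response"))
    as.integer(prob > 0.5)
  }, integer(1))
  acc <- base::mean(pred == dat$y)
  attr(acc, "predicted") <- factor(ifelse(pred == 1, "bd", "control"),
                                   levels = c("control", "bd"))
  acc
}
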