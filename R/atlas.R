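#' Default-mode-network atlas layout
#'
#' Node bookkeeping for the six-ROI DMN layout: precuneus (Pc), posterior
#' cingulate cortex (PCC), anterior cingulate cortex (ACC), frontal medial
#' cortex (FMC), and left/right inferior parietal lobes (lIPL, rIPL). Nodes
#' are placed on a 1-cm lattice around per-ROI seed coordinates in MNI space;
#' coordinates feed motif reporting only, never the statistics. The full
#' layout carries 156 nodes (26 per ROI); a reduced layout (e.g. 4 per ROI)
#' is convenient for simulation studies.
#'
#' @param nodes_per_roi either a single count applied to every ROI or a named
#'   vector over the six ROI labels. Default 26 (total 156).
#' @return a `dmn_atlas` data frame with columns `node_id`, `roi`, `x`, `y`,
#'   `z` (MNI mm), and attributes `roi_labels` and `roi_sizes`.
#' @examples
#' atlas <- dmn_atlas(4)
#' table(atlas$roi)
#' @export
dmn_atlas <- function(nodes_per_roi = 26) {
  rois <- c("Pc", "PCC", "ACC", "FMC", "lIPL", "rIPL")
  centers <- rbind(
    Pc   = c(5, -60, 35),
    PCC  = c(0, -52, 26),
    ACC  = c(0, 19, 28),
    FMC  = c(-1, 43, -16),
    lIPL = c(-53, -45, 35),
    rIPL = c(54, -43, 33)
  )
  if (length(nodes_per_roi) == 1) {
    nodes_per_roi <- stats::setNames(rep(nodes_per_roi, 6), rois)
  }
  nodes_per_roi <- nodes_per_roi[rois]
  if (anyNA(nodes_per_roi) || any(nodes_per_roi < 1)) {
    .stopf("plvmotif_atlas_error", "nodes_per_roi must give a positive count for each of: %s",
           paste(rois, collapse = ", "))
  }
  # deterministic 1-cm lattice offsets, closest to the ROI centre first
  g <- expand.grid(dx = seq(-30, 30, 10), dy = seq(-30, 30, 10),
                   dz = seq(-30, 30, 10))
  g <- g[order(g$dx^2 + g$dy^2 + g$dz^2, g$dx, g$dy, g$dz), ]
  out <- do.call(rbind, lapply(rois, function(r) {
    n <- nodes_per_roi[[r]]
    if (n > nrow(g)) {
      .stopf("plvmotif_atlas_error", "nodes_per_roi too large (max %d)", nrow(g))
    }
    data.frame(node_id = sprintf("%s_%02d", r, seq_len(n)),
               roi = r,
               x = centers[r, 1] + g$dx[seq_len(n)],
               y = centers[r, 2] + g$dy[seq_len(n)],
               z = centers[r, 3] + g$dz[seq_len(n)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "roi_labels") <- rois
  attr(out, "roi_sizes") <- stats::setNames(as.integer(nodes_per_roi), rois)
  class(out) <- c("dmn_atlas", "data.frame")
  out
}

.check_roi <- function(atlas, roi) {
  if (!roi %in% attr(atlas, "roi_labels")) {
    .stopf("plvmotif_atlas_error", "unknown ROI label '%s'", roi)
  }
}

#' Link universe for a pair of ROIs
#'
#' Enumerates, in deterministic order, every node pair analysed for one ROI
#' pair: all cross pairs for two distinct ROIs (inter-ROI analysis), or all
#' within-ROI pairs when `roi_a == roi_b` (intra-ROI analysis).
#'
#' @param atlas a [dmn_atlas()] layout.
#' @param roi_a,roi_b ROI labels.
#' @return data frame with columns `node_i`, `node_j` and attributes `roi_a`,
#'   `roi_b`.
#' @export
link_universe <- function(atlas, roi_a, roi_b = roi_a) {
  .check_roi(atlas, roi_a)
  .check_roi(atlas, roi_b)
  a <- atlas$node_id[atlas$roi == roi_a]
  b <- atlas$node_id[atlas$roi == roi_b]
  if (roi_a == roi_b) {
    idx <- utils::combn(seq_along(a), 2)
    uni <- data.frame(node_i = a[idx[1, ]], node_j = a[idx[2, ]],
                      stringsAsFactors = FALSE)
  } else {
    uni <- expand.grid(node_j = b, node_i = a,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, c("node_i", "node_j")]
  }
  rownames(uni) <- NULL
  attr(uni, "roi_a") <- roi_a
  attr(uni, "roi_b") <- roi_b
  uni
}

#' Per-ROI centroid of a motif's nodes
#'
#' Unweighted mean MNI coordinate of the motif's member nodes, reported
#' separately for each ROI represented in the motif.
#'
#' @param motif_nodes character vector of node ids (non-empty).
#' @param atlas a [dmn_atlas()] layout.
#' @return data frame with one row per represented ROI: `roi`, `x`, `y`, `z`,
#'   `n_nodes`.
#' @export
motif_centroid <- function(motif_nodes, atlas) {
  if (length(motif_nodes) == 0) {
    .stopf("plvmotif_domain_error", "motif node set is empty")
  }
  idx <- match(motif_nodes, atlas$node_id)
  if (anyNA(idx)) {
    .stopf("plvmotif_atlas_error", "unknown node id(s): %s",
           paste(motif_nodes[is.na(idx)], collapse = ", "))
  }
  sub <- atlas[idx, ]
  out <- do.call(rbind, lapply(split(sub, sub$roi, drop = TRUE), function(d) {
    data.frame(roi = d$roi[1], x = mean(d$x), y = mean(d$y), z = mean(d$z),
               n_nodes = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$roi, attr(atlas, "roi_labels"))), , drop = FALSE]
}
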