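#' Phase-locking value connectivity matrix
#'
#' For every node pair, the PLV is the modulus of the within-trial time
#' average of the unit phasor of the instantaneous phase difference,
#' averaged across trials. Phases come either directly from a phase-kind
#' trial set or from the analytic signal (FFT Hilbert construction) of each
#' band-limited trial. For signals, a fraction of samples at each trial end
#' is discarded before the time average to avoid analytic-signal edge bias;
#' exact phases need no trimming.
#'
#' @param trials a [trial_set()] with at least one trial and finite data.
#' @param edge_trim fraction of samples dropped at *each* trial end before
#'   the time average; default 0.1 for signal data, 0 for phase data.
#' @return a `plv_connectivity` object: list with the symmetric `plv` matrix
#'   (unit diagonal, values in `[0, 1]`) and the trial-set metadata.
#' @examples
#' ph <- array(rep(seq(0, 8 * pi, length.out = 100), each = 2), c(1, 2, 100))
#' plv_matrix(trial_set(ph, fs = 25, kind = "phase"))$plv
#' @export
plv_matrix <- function(trials, edge_trim = NULL) {
  if (!inherits(trials, "trial_set")) {
    .stopf("plvmotif_data_error", "trials must be a trial_set")
  }
  if (any(!is.finite(trials$data))) {
    .stopf("plvmotif_data_error", "trial data contains non-finite samples")
  }
  if (is.null(edge_trim)) {
    edge_trim <- if (trials$kind == "phase") 0 else 0.1
  }
  d <- dim(trials$data)
  n_trials <- d[1]; n_nodes <- d[2]; n_samp <- d[3]
  drop_k <- floor(edge_trim * n_samp)
  keep <- seq.int(drop_k + 1, n_samp - drop_k)
  acc <- matrix(0, n_nodes, n_nodes)
  for (k in seq_len(n_trials)) {
    seg <- trials$data[k, , keep, drop = FALSE]
    dim(seg) <- c(n_nodes, length(keep))
    if (trials$kind == "phase") {
      ph <- seg
    } else {
      ph <- Arg(.analytic_signal(seg))
    }
    E <- exp(1i * ph)
    acc <- acc + Mod(E %*% Conj(t(E))) / length(keep)
  }
  plv <- acc / n_trials
  plv <- (plv + t(plv)) / 2
  plv[plv > 1] <- 1
  diag(plv) <- 1
  if (!is.null(trials$node_ids)) {
    dimnames(plv) <- list(trials$node_ids, trials$node_ids)
  }
  structure(list(plv = plv, subject_id = trials$subject_id,
                 session = trials$session, band = trials$band,
                 n_trials = n_trials),
            class = "plv_connectivity")
}

#' Post/pre connectivity ratio matrix
#'
#' Elementwise quotient of the follow-up (post) PLV matrix over the baseline
#' (pre) matrix for the same subject and band. Values above 1 indicate
#' increased synchronisation over time. Baseline entries below `eps` are
#' floored at `eps` (with a warning) so the ratio stays finite.
#'
#' @param post,pre [plv_matrix()] results for the two sessions of one
#'   subject, same band and node order.
#' @param eps floor applied to the baseline matrix.
#' @return a `plv_ratio` object: list with the symmetric positive `ratio`
#'   matrix (unit diagonal), `subject_id`, `band` and the count of floored
#'   entries in attribute `n_floored`.
#' @export
ratio_matrix <- function(post, pre, eps = 1e-6) {
  if (!inherits(post, "plv_connectivity") || !inherits(pre, "plv_connectivity")) {
    .stopf("plvmotif_alignment_error", "post and pre must be plv_connectivity objects")
  }
  same_band <- identical(post$band, pre$band) ||
    (is.null(post$band) && is.null(pre$band))
  if (!identical(post$subject_id, pre$subject_id) || !same_band ||
      !identical(dim(post$plv), dim(pre$plv))) {
    .stopf("plvmotif_alignment_error", "post and pre matrices do not align (subject, band or shape differ)")
  }
  denom <- pre$plv
  floored <- denom < eps
  diag(floored) <- FALSE
  if (any(floored)) {
    .warnf("%d baseline PLV value(s) below %g floored before forming ratios",
           sum(floored) / 2, eps)
    denom[floored] <- eps
  }
  ratio <- post$plv / denom
  diag(ratio) <- 1
  out <- structure(list(ratio = ratio, subject_id = post$subject_id,
                        band = post$band),
                   class = "plv_ratio")
  attr(out, "n_floored") <- sum(floored) / 2
  out
}

#' Assemble per-subject link ratios into a subjects x links matrix
#'
#' @param ratios named list of [ratio_matrix()] results (or bare node x node
#'   matrices), one per subject, named by subject id.
#' @param universe a [link_universe()] data frame; node ids index rows and
#'   columns of each ratio matrix (names or integer indices).
#' @param design a [make_design()] roster; row order defines the subject
#'   order of the result.
#' @return numeric matrix, subjects x links.
#' @export
ratio_link_matrix <- function(ratios, universe, design) {
  if (!all(design$subject_id %in% names(ratios))) {
    .stopf("plvmotif_alignment_error", "ratios must be named by subject id and cover the whole design")
  }
  get_mat <- function(r) if (inherits(r, "plv_ratio")) r$ratio else as.matrix(r)
  idx <- cbind(universe$node_i, universe$node_j)
  Y <- t(vapply(design$subject_id, function(sid) {
    m <- get_mat(ratios[[sid]])
    m[idx]
  }, numeric(nrow(universe))))
  rownames(Y) <- design$subject_id
  Y
}
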