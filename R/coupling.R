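#' Specify the phase-coupling structure of a simulated session
#'
#' A coupling plan describes, for one session of one group, which node pairs
#' are phase-coupled and how strongly. Coupling strength is the concentration
#' `kappa` of the von Mises phase-offset distribution, so a coupled pair's
#' population PLV is [expected_plv()]`(kappa)`. Coupled pairs must form
#' blocks of uniform `kappa` (each connected component of the coupling graph
#' carries one concentration): every node of a block is jittered around a
#' shared latent driver phase with a per-node concentration chosen so that
#' each pair's resultant equals `expected_plv(kappa)` exactly.
#'
#' @param n_nodes number of nodes.
#' @param kappa symmetric `n_nodes x n_nodes` matrix of concentrations
#'   (`0` = uncoupled, diagonal ignored), or `NULL` for no coupling.
#' @param fs sampling rate in Hz.
#' @param trial_len trial length in seconds (`fs * trial_len` must be an
#'   integer).
#' @param n_trials trials per subject.
#' @param f0 carrier frequency in Hz of the narrowband oscillation.
#' @param kind `"phase"` to store instantaneous phases directly, `"signal"`
#'   to store `amp * cos(phase)` plus additive Gaussian sensor noise.
#' @param amp,noise_sd amplitude and additive noise SD for `kind = "signal"`.
#' @param drift_sd per-sample SD (radians) of the slow random-walk frequency
#'   drift of each driver; widens the emitted band for `kind = "signal"`.
#' @return a `coupling_plan` object.
#' @seealso [kappa_block()] to assemble `kappa` matrices.
#' @export
coupling_plan <- function(n_nodes, kappa = NULL, fs = 250, trial_len = 4,
                          n_trials = 20, f0 = 10, kind = c("phase", "signal"),
                          amp = 1, noise_sd = 0.5, drift_sd = 0) {
  kind <- match.arg(kind)
  if (is.null(kappa)) kappa <- matrix(0, n_nodes, n_nodes)
  kappa <- as.matrix(kappa)
  if (nrow(kappa) != n_nodes || ncol(kappa) != n_nodes) {
    .stopf("plvmotif_plan_error", "kappa must be a %d x %d matrix", n_nodes, n_nodes)
  }
  diag(kappa) <- 0
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    .stopf("plvmotif_plan_error", "kappa entries must be finite and >= 0")
  }
  if (!isTRUE(all.equal(kappa, t(kappa)))) {
    .stopf("plvmotif_plan_error", "kappa must be symmetric")
  }
  n_samp <- fs * trial_len
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    .stopf("plvmotif_plan_error", "fs * trial_len must be an integer sample count")
  }
  # connected coupling blocks; each must carry a single concentration
  adj <- kappa > 0
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  kappa_comp <- rep(0, max(comp))
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) > 1) {
      vals <- unique(kappa[members, members][adj[members, members]])
      if (length(vals) != 1) {
        .stopf("plvmotif_plan_error", "mixed coupling strengths within one connected block are not supported")
      }
      kappa_comp[cid] <- vals
    }
  }
  structure(list(n_nodes = n_nodes, kappa = kappa, fs = fs,
                 trial_len = trial_len, n_trials = n_trials, f0 = f0,
                 kind = kind, amp = amp, noise_sd = noise_sd,
                 drift_sd = drift_sd, component = comp,
                 kappa_component = kappa_comp),
            class = "coupling_plan")
}

#' Add a uniform coupling block to a kappa matrix
#'
#' @param kappa existing symmetric matrix (or `NULL` to start from zeros).
#' @param n_nodes matrix dimension when `kappa` is `NULL`.
#' @param nodes_a,nodes_b integer node indices; every cross pair
#'   (`nodes_a` x `nodes_b`) receives concentration `value`.
#' @param value concentration for the block.
#' @return the updated matrix.
#' @export
kappa_block <- function(kappa = NULL, n_nodes = NULL, nodes_a, nodes_b, value) {
  if (is.null(kappa)) kappa <- matrix(0, n_nodes, n_nodes)
  kappa[nodes_a, nodes_b] <- value
  kappa[nodes_b, nodes_a] <- value
  diag(kappa) <- 0
  kappa
}

#' Simulate one session of phase-coupled node activity for a cohort
#'
#' For each subject, generates `n_trials` trials of `n_nodes` narrowband
#' oscillators. Every connected coupling block shares a latent driver phase
#' (a carrier at `f0` Hz with uniform per-trial initial phase and optional
#' slow frequency drift); each member node adds fast-mixing per-sample von
#' Mises phase jitter whose concentration is calibrated so that the empirical
#' PLV of every coupled pair converges to `expected_plv(kappa)` as trials
#' accumulate. Uncoupled nodes carry independent drivers and uniform jitter,
#' so their PLV sits at the estimator's independence noise floor.
#'
#' @param design a [make_design()] roster.
#' @param plan a [coupling_plan()]; one plan applies to all subjects of the
#'   session (group/session differences are expressed by passing different
#'   plans).
#' @param seed integer seed; every subject receives an independent
#'   sub-stream, so results are bit-reproducible.
#' @param session session label stored in each trial set.
#' @param subjects optional subset of `design$subject_id`.
#' @param node_ids optional character node labels stored with each trial set.
#' @return named list (by subject id) of [trial_set()] objects with
#'   dimensions trials x nodes x samples.
#' @export
simulate_session <- function(design, plan, seed = 1, session = "pre",
                             subjects = design$subject_id, node_ids = NULL) {
  if (!inherits(plan, "coupling_plan")) {
    .stopf("plvmotif_plan_error", "plan must be a coupling_plan object")
  }
  seeds <- .seed_streams(seed, nrow(design))
  names(seeds) <- design$subject_id
  out <- lapply(subjects, function(sid) {
    data <- .with_seed(seeds[[sid]], .simulate_subject(plan))
    trial_set(data, fs = plan$fs, subject_id = sid, session = session,
              kind = plan$kind, node_ids = node_ids, min_trials = 1)
  })
  names(out) <- subjects
  out
}

# One subject's trials x nodes x samples array under `plan`.
.simulate_subject <- function(plan) {
  n_t <- plan$n_trials
  n_n <- plan$n_nodes
  T_s <- as.integer(round(plan$fs * plan$trial_len))
  total <- n_t * T_s
  comp <- plan$component
  # per-node jitter concentration: each pair in a block with concentration k
  # must have resultant R(k); nodes jitter independently, so per-node
  # resultant is sqrt(R(k)).
  kappa_node <- rep(0, n_n)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) > 1) {
      kappa_node[members] <- plv_concentration(sqrt(expected_plv(plan$kappa_component[cid])))
    }
  }
  # driver phases per component: carrier + per-trial initial phase (+ drift)
  step <- 2 * pi * plan$f0 / plan$fs
  drivers <- matrix(0, length(unique(comp)), total)
  for (cid in unique(comp)) {
    inc <- rep(step, total)
    if (plan$drift_sd > 0) inc <- inc + stats::rnorm(total, 0, plan$drift_sd)
    cs <- cumsum(inc)
    starts <- (seq_len(n_t) - 1) * T_s
    offset <- stats::runif(n_t, 0, 2 * pi) - c(0, cs[starts[-1]])
    drivers[cid, ] <- cs + rep(offset, each = T_s)
  }
  data <- array(0, dim = c(n_t, n_n, T_s))
  for (v in seq_len(n_n)) {
    phase <- drivers[comp[v], ] + rvon_mises(total, kappa_node[v])
    if (plan$kind == "signal") {
      x <- plan$amp * cos(phase)
      if (plan$noise_sd > 0) x <- x + stats::rnorm(total, 0, plan$noise_sd)
      data[, v, ] <- matrix(x, n_t, T_s, byrow = TRUE)
    } else {
      data[, v, ] <- matrix(phase, n_t, T_s, byrow = TRUE)
    }
  }
  data
}
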