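# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# Brute-force PLV from a phase array (trials x nodes x samples): per trial,
# per pair, loop over samples accumulating the phasor of the phase
# difference; average the per-trial moduli.
oracle_plv <- function(phases) {
  d <- dim(phases)
  plv <- matrix(0, d[2], d[2])
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[2])) {
      acc <- 0
      for (k in seq_len(d[1])) {
        s <- 0 + 0i
        for (t in seq_len(d[3])) {
          s <- s + exp(1i * (phases[k, i, t] - phases[k, j, t]))
        }
        acc <- acc + Mod(s / d[3])
      }
      plv[i, j] <- acc / d[1]
    }
  }
  diag(plv) <- 1
  plv
}

# Exhaustive motif checker: repeated breadth-first search for connected
# components of the significant-link graph, then direct application of the
# node-coverage and link-density rules. Node ids are characters; `roi_of`
# maps node -> ROI; `roi_sizes` named ROI sizes; `roi_pair` length 2.
oracle_motifs <- function(sig, roi_of, roi_sizes, roi_pair, universe_size,
                          node_frac = 0.25, link_frac = 0.10) {
  if (nrow(sig) == 0) return(list())
  nodes <- unique(c(sig$node_i, sig$node_j))
  visited <- character(0)
  comps <- list()
  for (start in nodes) {
    if (start %in% visited) next
    queue <- start
    comp <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- c(sig$node_j[sig$node_i == v], sig$node_i[sig$node_j == v])
      queue <- c(queue, setdiff(nb, comp))
    }
    visited <- c(visited, comp)
    comps[[length(comps) + 1]] <- comp
  }
  out <- list()
  for (comp in comps) {
    links <- sig[sig$node_i %in% comp & sig$node_j %in% comp, , drop = FALSE]
    ok <- TRUE
    for (r in unique(roi_pair)) {
      if (sum(roi_of[comp] == r) < node_frac * roi_sizes[[r]] - 1e-9) ok <- FALSE
    }
    if (nrow(links) < link_frac * universe_size - 1e-9) ok <- FALSE
    if (ok) {
      out[[length(out) + 1]] <- list(nodes = sort(comp), mass = sum(links$F),
                                     n_links = nrow(links))
    }
  }
  out
}

# Two-sided tail probability of the t distribution by numerical integration
# of its density.
oracle_t_p <- function(t_stat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-12)$value
}

# Random per-subject ratio matrices with iid lognormal links (exchangeable
# null) and an optional additive shift on a node block for the bd group.
make_null_ratios <- function(design, atlas, sdlog = 0.05, shift = 0,
                             shift_rois = c("FMC", "rIPL")) {
  n <- nrow(atlas)
  ids_a <- atlas$node_id[atlas$roi == shift_rois[1]]
  ids_b <- atlas$node_id[atlas$roi == shift_rois[2]]
  out <- lapply(seq_len(nrow(design)), function(i) {
    v <- matrix(exp(stats::rnorm(n * n, 0, sdlog)), n, n)
    m <- (v + t(v)) / 2
    dimnames(m) <- list(atlas$node_id, atlas$node_id)
    if (shift != 0 && design$group[i] == "bd") {
      m[ids_a, ids_b] <- m[ids_a, ids_b] + shift
      m[ids_b, ids_a] <- t(m[ids_a, ids_b])
    }
    diag(m) <- 1
    m
  })
  names(out) <- design$subject_id
  out
}

desk_atlas <- function() dmn_atlas(4)
desk_design <- function(seed = 1) make_design(22, 17, c(control = 12, bd = 8), seed)
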