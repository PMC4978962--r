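#' Build a two-group, two-session cohort roster
#'
#' Creates the subject roster used throughout the pipeline: a control group
#' and a binge-drinking (bd) group, each subject measured at a baseline
#' (`pre`) and a follow-up (`post`) session. The roster is the exchangeability
#' unit for all permutation tests. Defaults mirror the cohort the pipeline is
#' designed around: 22 controls (12 female) and 17 binge drinkers (8 female).
#'
#' @param n_control,n_bd number of subjects per group (each at least 2).
#' @param females named counts of female subjects per group,
#'   `c(control = ..., bd = ...)`.
#' @param seed integer seed controlling the (deterministic) within-group
#'   ordering of the sex labels.
#' @return A `cohort_design` data frame with columns `subject_id`, `group`
#'   (factor, levels `control`, `bd`) and `sex` (factor, levels `F`, `M`),
#'   plus a `sessions` attribute `c("pre", "post")`.
#' @examples
#' d <- make_design()
#' table(d$group, d$sex)
#' @export
make_design <- function(n_control = 22, n_bd = 17,
                        females = c(control = 12, bd = 8), seed = 1) {
  if (n_control < 2 || n_bd < 2) {
    .stopf("plvmotif_design_error", "each group needs at least 2 subjects (got %d control, %d bd)",
           n_control, n_bd)
  }
  females <- females[c("control", "bd")]
  if (anyNA(females) || any(females < 0)) {
    .stopf("plvmotif_design_error", "females must be named non-negative counts for 'control' and 'bd'")
  }
  if (females[["control"]] > n_control || females[["bd"]] > n_bd) {
    .stopf("plvmotif_design_error", "female count exceeds group size")
  }
  sex_for <- function(n, n_f, sub_seed) {
    s <- rep(c("F", "M"), c(n_f, n - n_f))
    .with_seed(sub_seed, sample(s))
  }
  seeds <- .seed_streams(seed, 2)
  design <- data.frame(
    subject_id = c(sprintf("ctrl%02d", seq_len(n_control)),
                   sprintf("bd%02d", seq_len(n_bd))),
    group = factor(rep(c("control", "bd"), c(n_control, n_bd)),
                   levels = c("control", "bd")),
    sex = factor(c(sex_for(n_control, females[["control"]], seeds[1]),
                   sex_for(n_bd, females[["bd"]], seeds[2])),
                 levels = c("F", "M")),
    stringsAsFactors = FALSE
  )
  attr(design, "sessions") <- c("pre", "post")
  class(design) <- c("cohort_design", "data.frame")
  design
}

#' Expected phase-locking value of a von Mises phase offset
#'
#' For two oscillators whose instantaneous phase difference is von Mises
#' distributed with concentration `kappa`, the population phase-locking value
#' is the mean resultant length \eqn{R(\kappa) = I_1(\kappa)/I_0(\kappa)},
#' the ratio of modified Bessel functions of the first kind. This closed form
#' links the generator's coupling parameter to the PLV it induces.
#'
#' @param kappa non-negative, finite concentration(s).
#' @return PLV value(s) in `[0, 1)`; monotone increasing and continuous in
#'   `kappa`.
#' @examples
#' expected_plv(c(0, 2))  # 0 and I1(2)/I0(2) = 0.698
#' @export
expected_plv <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    .stopf("plvmotif_domain_error", "kappa must be finite and >= 0")
  }
  r <- numeric(length(kappa))
  small <- kappa <= 1e4
  if (any(small)) {
    k <- kappa[small]
    r[small] <- ifelse(k == 0, 0,
                       besselI(k, 1, expon.scaled = TRUE) /
                         besselI(k, 0, expon.scaled = TRUE))
  }
  if (any(!small)) {
    # large-concentration asymptotic expansion of I1/I0
    k <- kappa[!small]
    r[!small] <- 1 - 1 / (2 * k) - 1 / (8 * k^2) - 1 / (8 * k^3)
  }
  r
}

#' Concentration that yields a target phase-locking value
#'
#' Numerical inverse of [expected_plv()].
#'
#' @param plv target PLV value(s) in `[0, 1)`.
#' @return concentration(s) `kappa >= 0` with `expected_plv(kappa) == plv`.
#' @export
plv_concentration <- function(plv) {
  if (any(!is.finite(plv)) || any(plv < 0) || any(plv >= 1)) {
    .stopf("plvmotif_domain_error", "plv must lie in [0, 1)")
  }
  vapply(plv, function(r) {
    if (r < 1e-12) return(0)
    upper <- max(4, 1 / (1 - r))
    while (expected_plv(upper) < r) upper <- upper * 2
    stats::uniroot(function(k) expected_plv(k) - r, c(1e-10, upper),
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Draw from the von Mises distribution
#'
#' Best-Fisher (1979) wrapped-Cauchy rejection sampler. Used by the cohort
#' generator to produce phase offsets with a prescribed mean resultant length.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0, finite); `0` gives the uniform
#'   distribution on the circle.
#' @param mu mean direction in radians.
#' @return angles in `(-pi, pi]` (shifted by `mu`).
#' @export
rvon_mises <- function(n, kappa, mu = 0) {
  if (!is.finite(kappa) || kappa < 0) {
    .stopf("plvmotif_domain_error", "kappa must be finite and >= 0")
  }
  if (kappa < 1e-9) {
    theta <- stats::runif(n, -pi, pi)
  } else {
    tau <- 1 + sqrt(1 + 4 * kappa^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
    r <- (1 + rho^2) / (2 * rho)
    theta <- numeric(n)
    need <- seq_len(n)
    while (length(need) > 0) {
      m <- length(need)
      z <- cos(pi * stats::runif(m))
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- stats::runif(m)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      theta[need[ok]] <- sign(stats::runif(sum(ok)) - 0.5) * acos(f[ok])
      need <- need[!ok]
    }
  }
  if (mu != 0) {
    theta <- (theta + mu + pi) %% (2 * pi) - pi
  }
  theta
}

#' Default white-matter tract labels
#'
#' The 20 tracts of the JHU white-matter tractography atlas, used as the
#' default tract list for the structural (DTI) arm.
#'
#' @return character vector of 20 tract labels.
#' @export
jhu_tracts <- function() {
  c("ATR_L", "ATR_R", "CST_L", "CST_R", "CGC_L", "CGC_R", "CGH_L", "CGH_R",
    "FMAJ", "FMIN", "IFOF_L", "IFOF_R", "ILF_L", "ILF_R", "SLF_L", "SLF_R",
    "UF_L", "UF_R", "SLFT_L", "SLFT_R")
}

#' Simulate a per-tract DTI metric table
#'
#' Generates a complete subject x session x tract x metric table of diffusion
#' scalars (FA, MD, RD, AD) as Gaussian noise around metric-specific
#' baselines, optionally planting a group x session interaction: the shift is
#' added to the bd group's post session only.
#'
#' @param design a [make_design()] roster.
#' @param tract_labels character vector of tract names.
#' @param baselines named per-metric baselines; FA is dimensionless in
#'   `[0, 1]`, MD/RD/AD are in mm^2/s.
#' @param group_session_effect named per-metric shift added to bd-post cells.
#' @param noise_sd named per-metric Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @return a `dti_table` data frame with columns `subject_id`, `group`,
#'   `sex`, `session`, `tract`, `metric`, `value`.
#' @export
simulate_dti_table <- function(design, tract_labels = jhu_tracts(),
                               baselines = c(FA = 0.45, MD = 7.5e-4,
                                             RD = 6.0e-4, AD = 1.1e-3),
                               group_session_effect = c(FA = 0, MD = 0,
                                                        RD = 0, AD = 0),
                               noise_sd = c(FA = 0.02, MD = 3e-5,
                                            RD = 3e-5, AD = 5e-5),
                               seed = 1) {
  metrics <- c("FA", "MD", "RD", "AD")
  baselines <- baselines[metrics]
  group_session_effect <- group_session_effect[metrics]
  noise_sd <- noise_sd[metrics]
  if (anyNA(baselines) || anyNA(group_session_effect) || anyNA(noise_sd)) {
    .stopf("plvmotif_parameter_error", "baselines, group_session_effect and noise_sd must name all of FA, MD, RD, AD")
  }
  if (baselines[["FA"]] < 0 || baselines[["FA"]] > 1) {
    .stopf("plvmotif_parameter_error", "FA baseline must lie in [0, 1]")
  }
  if (any(noise_sd < 0)) {
    .stopf("plvmotif_parameter_error", "noise_sd must be >= 0")
  }
  tab <- expand.grid(subject_id = design$subject_id,
                     session = c("pre", "post"),
                     tract = tract_labels,
                     metric = metrics,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- merge(tab, design[, c("subject_id", "group", "sex")],
               by = "subject_id", sort = FALSE)
  tab <- tab[order(tab$metric, tab$tract, tab$session, tab$subject_id), ]
  rownames(tab) <- NULL
  base <- baselines[tab$metric]
  eff <- ifelse(tab$group == "bd" & tab$session == "post",
                group_session_effect[tab$metric], 0)
  noise <- .with_seed(seed, stats::rnorm(nrow(tab), 0, noise_sd[tab$metric]))
  tab$value <- as.numeric(base + eff + noise)
  tab <- tab[, c("subject_id", "group", "sex", "session", "tract", "metric", "value")]
  class(tab) <- c("dti_table", "data.frame")
  tab
}
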