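test_that("observed link F equals the single-link ANCOVA fit", {
  withr::with_seed(41, {
    d <- desk_design()
    atlas <- desk_atlas()
    uni <- link_universe(atlas, "FMC", "rIPL")
    ratios <- make_null_ratios(d, atlas)
    st <- linkwise_perm_ancova(ratios, d, uni, n_perm = 9, seed = 2)
    Y <- ratio_link_matrix(ratios, uni, d)
    for (l in c(1, 7, 16)) {
      fit <- stats::anova(stats::lm(Y[, l] ~ sex + group, data = d))
      expect_equal(st$F[l], fit["group", "F value"], tolerance = 1e-8)
    }
  })
})

test_that("permutation p-values have the discrete add-one support", {
  withr::with_seed(42, {
    d <- desk_design()
    atlas <- desk_atlas()
    uni <- link_universe(atlas, "FMC", "rIPL")
    ratios <- make_null_ratios(d, atlas)
    st <- linkwise_perm_ancova(ratios, d, uni, n_perm = 19, seed = 5)
    expect_true(all(st$p %in% ((1:20) / 20)))
    expect_true(all(st$p >= 1 / 20))
  })
})

test_that("a hugely separated link reaches the minimum attainable p", {
  withr::with_seed(43, {
    d <- desk_design()
    atlas <- desk_atlas()
    uni <- link_universe(atlas, "FMC", "rIPL")
    ratios <- make_null_ratios(d, atlas)
    # plant a 5-pooled-SD group difference on one link
    i <- uni$node_i[1]; j <- uni$node_j[1]
    for (sid in d$subject_id[d$group == "bd"]) {
      m <- ratios[[sid]]
      m[i, j] <- m[i, j] + 5 * 0.05
      m[j, i] <- m[i, j]
      ratios[[sid]] <- m
    }
    st <- linkwise_perm_ancova(ratios, d, uni, n_perm = 199, seed = 5)
    expect_equal(st$p[1], 1 / 200)
    expect_true(st$significant[1])
  })
})

test_that("constant links are flagged not-significant with a warning", {
  d <- desk_design()
  atlas <- desk_atlas()
  uni <- link_universe(atlas, "FMC", "rIPL")
  ratios <- make_null_ratios(d, atlas)
  for (sid in d$subject_id) {
    m <- ratios[[sid]]
    m[uni$node_i[2], uni$node_j[2]] <- 1.07
    m[uni$node_j[2], uni$node_i[2]] <- 1.07
    ratios[[sid]] <- m
  }
  expect_warning(st <- linkwise_perm_ancova(ratios, d, uni, n_perm = 19, seed = 1),
                 "constant")
  expect_false(st$significant[2])
  expect_equal(st$p[2], 1)
})

test_that("design with a tiny group is rejected", {
  d <- desk_design()
  atlas <- desk_atlas()
  uni <- link_universe(atlas, "FMC", "rIPL")
  d1 <- d[c(1:22, 23), ]
  ratios <- make_null_ratios(d1, atlas)
  expect_error(linkwise_perm_ancova(ratios, d1, uni, n_perm = 9, seed = 1),
               class = "plvmotif_design_error")
})

make_stats <- function(uni, sig_idx, F_sig = 10, roi_a, roi_b, alpha = 0.05) {
  st <- data.frame(node_i = uni$node_i, node_j = uni$node_j,
                   F = 0.1, p = 0.9, significant = FALSE,
                   stringsAsFactors = FALSE)
  st$F[sig_idx] <- F_sig
  st$p[sig_idx] <- 0.01
  st$significant[sig_idx] <- TRUE
  attr(st, "universe") <- uni
  attr(st, "roi_a") <- roi_a
  attr(st, "roi_b") <- roi_b
  attr(st, "alpha") <- alpha
  attr(st, "n_perm") <- 199
  attr(st, "seed") <- 1
  class(st) <- c("link_stats", "data.frame")
  st
}

test_that("motif criteria enforce node coverage, link density and connectedness", {
  atlas <- dmn_atlas(8)   # two 8-node ROIs -> 64-link universe
  uni <- link_universe(atlas, "FMC", "rIPL")
  fmc <- atlas$node_id[atlas$roi == "FMC"]
  rip <- atlas$node_id[atlas$roi == "rIPL"]
  pick <- function(pairs) {
    vapply(pairs, function(p) which(uni$node_i == p[1] & uni$node_j == p[2]),
           integer(1))
  }
  # 2+2 nodes, 3 links: coverage 25% ok, density 3/64 < 10% -> rejected
  idx3 <- pick(list(c(fmc[1], rip[1]), c(fmc[1], rip[2]), c(fmc[2], rip[1])))
  st <- make_stats(uni, idx3, roi_a = "FMC", roi_b = "rIPL")
  expect_length(extract_motifs(st, atlas), 0)

  # 3+3 nodes, 7 links in one component: 37.5% and 10.9% -> accepted
  idx7 <- pick(list(c(fmc[1], rip[1]), c(fmc[1], rip[2]), c(fmc[2], rip[1]),
                    c(fmc[2], rip[3]), c(fmc[3], rip[1]), c(fmc[3], rip[2]),
                    c(fmc[3], rip[3])))
  st7 <- make_stats(uni, idx7, roi_a = "FMC", roi_b = "rIPL")
  mo <- extract_motifs(st7, atlas)
  expect_length(mo, 1)
  expect_equal(mo[[1]]$n_links, 7)
  expect_setequal(mo[[1]]$nodes, c(fmc[1:3], rip[1:3]))
  expect_equal(mo[[1]]$mass, 70)

  # 7 links split 4 + 3 into two components: only the 4-link one can pass
  # density, and with 2 nodes per ROI it still fails nothing -> evaluated
  # separately
  idx_split <- pick(list(
    c(fmc[1], rip[1]), c(fmc[1], rip[2]), c(fmc[2], rip[1]), c(fmc[2], rip[2]),
    c(fmc[5], rip[5]), c(fmc[5], rip[6]), c(fmc[6], rip[5])))
  st_split <- make_stats(uni, idx_split, roi_a = "FMC", roi_b = "rIPL")
  mo_split <- extract_motifs(st_split, atlas)
  expect_length(mo_split, 0)   # 4/64 and 3/64 both under 10%
})

test_that("extract_motifs agrees with the exhaustive oracle on random graphs", {
  atlas <- dmn_atlas(c(Pc = 4, PCC = 4, ACC = 4, FMC = 5, lIPL = 4, rIPL = 5))
  uni <- link_universe(atlas, "FMC", "rIPL")   # 25 links, 10 nodes
  roi_of <- stats::setNames(atlas$roi, atlas$node_id)
  roi_sizes <- attr(atlas, "roi_sizes")
  withr::with_seed(77, {
    for (rep in 1:40) {
      k <- sample(0:10, 1)
      sig_idx <- sample(nrow(uni), k)
      st <- make_stats(uni, sig_idx, F_sig = round(stats::runif(1, 5, 20), 2),
                       roi_a = "FMC", roi_b = "rIPL")
      got <- extract_motifs(st, atlas)
      want <- oracle_motifs(st[st$significant, c("node_i", "node_j", "F")],
                            roi_of, roi_sizes, c("FMC", "rIPL"), nrow(uni))
      expect_equal(length(got), length(want))
      if (length(got)) {
        got_key <- sort(vapply(got, function(m) paste(m$nodes, collapse = ","), ""))
        want_key <- sort(vapply(want, function(m) paste(m$nodes, collapse = ","), ""))
        expect_equal(got_key, want_key)
        expect_equal(sort(vapply(got, function(m) m$mass, 0)),
                     sort(vapply(want, function(m) m$mass, 0)), tolerance = 1e-10)
      }
    }
  })
})

test_that("motif correction gives minimum p under separation and allows empty input", {
  withr::with_seed(51, {
    d <- desk_design()
    atlas <- desk_atlas()
    uni <- link_universe(atlas, "FMC", "rIPL")
    ratios <- make_null_ratios(d, atlas, shift = 0.5)
    st <- linkwise_perm_ancova(ratios, d, uni, n_perm = 199, seed = 9)
    mo <- extract_motifs(st, atlas)
    expect_gte(length(mo), 1)
    mo <- motif_perm_test(mo, ratios, d, uni, atlas = atlas)
    expect_equal(mo[[1]]$p_corrected, 1 / 200)

    empty <- extract_motifs(linkwise_perm_ancova(
      make_null_ratios(d, atlas), d, uni, n_perm = 19, seed = 1), atlas)
    if (length(empty) == 0) {
      expect_length(motif_perm_test(empty, ratios, d, uni, atlas = atlas), 0)
    }
    expect_error(motif_perm_test(mo, ratios, d, uni, atlas = atlas, n_perm = 0),
                 class = "plvmotif_parameter_error")
  })
})

test_that("motif mass grows monotonically with the planted effect", {
  d <- desk_design()
  atlas <- desk_atlas()
  uni <- link_universe(atlas, "FMC", "rIPL")
  masses <- vapply(c(0.1, 0.25, 0.5), function(shift) {
    ratios <- withr::with_seed(60, make_null_ratios(d, atlas, shift = shift))
    st <- linkwise_perm_ancova(ratios, d, uni, n_perm = 99, seed = 3)
    mo <- extract_motifs(st, atlas)
    if (length(mo)) max(vapply(mo, function(m) m$mass, 0)) else 0
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("motif degree is the mean ratio over member links", {
  atlas <- desk_atlas()
  fmc <- atlas$node_id[atlas$roi == "FMC"]
  rip <- atlas$node_id[atlas$roi == "rIPL"]
  motif <- structure(list(
    roi_pair = c("FMC", "rIPL"), nodes = c(fmc[1:2], rip[1:2]),
    links = data.frame(node_i = c(fmc[1], fmc[2]), node_j = c(rip[1], rip[2]),
                       F = c(5, 6), p = c(0.01, 0.01)),
    n_links = 2, mass = 11), class = "plv_motif")
  m <- matrix(1, 24, 24, dimnames = list(atlas$node_id, atlas$node_id))
  m[fmc[1], rip[1]] <- m[rip[1], fmc[1]] <- 0.8
  m[fmc[2], rip[2]] <- m[rip[2], fmc[2]] <- 1.2
  deg <- motif_degree(motif, list(s1 = m))
  expect_equal(unname(deg), 1.0)

  ones <- matrix(1, 24, 24, dimnames = list(atlas$node_id, atlas$node_id))
  expect_equal(unname(motif_degree(motif, list(a = ones, b = ones))), c(1, 1))

  single <- motif
  single$links <- single$links[1, ]
  expect_equal(unname(motif_degree(single, list(s1 = m))), 0.8)
})

test_that("degree group test reproduces the pooled-SD effect size", {
  d <- desk_design()
  # construct degrees with exact group summaries: bd 1.07 +/- 0.07,
  # control 0.99 +/- 0.05
  mk <- function(n, mean, sd) {
    x <- seq_len(n)
    x <- (x - base::mean(x)) / stats::sd(x)
    mean + sd * x
  }
  deg <- numeric(nrow(d))
  names(deg) <- d$subject_id
  deg[d$group == "bd"] <- mk(17, 1.07, 0.07)
  deg[d$group == "control"] <- mk(22, 0.99, 0.05)
  gt <- degree_group_test(deg, d, n_bands = 5)
  pooled <- sqrt((16 * 0.07^2 + 21 * 0.05^2) / 37)
  expect_equal(gt$cohen_d, 0.08 / pooled, tolerance = 1e-10)
  expect_equal(gt$cohen_d, 1.345, tolerance = 1e-3)
  expect_equal(gt$p_corrected, min(1, 5 * gt$p_raw))

  # identical groups: d = 0, corrected p saturates at 1
  deg0 <- deg
  deg0[d$group == "bd"] <- mk(17, 1, 0.05)
  deg0[d$group == "control"] <- mk(22, 1, 0.05)
  gt0 <- degree_group_test(deg0, d)
  expect_equal(gt0$cohen_d, 0, tolerance = 1e-10)
  expect_equal(gt0$p_corrected, 1)

  expect_error(degree_group_test(stats::setNames(rep(1, nrow(d)), d$subject_id), d),
               class = "plvmotif_undefined_effect")
})

test_that("p x 5 Bonferroni arithmetic is applied to the raw ANCOVA p", {
  d <- desk_design()
  withr::with_seed(66, {
    deg <- stats::setNames(rnorm(nrow(d), 1, 0.05), d$subject_id)
    deg[d$group == "bd"] <- deg[d$group == "bd"] + 0.03
    gt <- degree_group_test(deg, d, n_bands = 5)
    expect_equal(gt$p_corrected, min(1, 5 * gt$p_raw), tolerance = 1e-12)
  })
})

test_that("one-sample t against 1 matches t.test and the integration oracle", {
  r <- one_sample_t_vs1(mean = 1.07, sd = 0.07, n = 17)
  expect_equal(r$t, 4.123106, tolerance = 1e-6)
  expect_lt(r$p, 1e-3)
  expect_equal(r$p, oracle_t_p(r$t, 16), tolerance = 1e-8)

  expect_equal(one_sample_t_vs1(mean = 1, sd = 0.05, n = 20)$p, 1)

  r2 <- one_sample_t_vs1(mean = 0.96, sd = 0.04, n = 22)
  expect_equal(r2$t, -4.690416, tolerance = 1e-6)
  expect_equal(r2$p, oracle_t_p(r2$t, 21), tolerance = 1e-8)
  expect_equal(r2$p, 1.249e-4, tolerance = 1e-3)

  withr::with_seed(70, {
    x <- rnorm(25, 1.03, 0.08)
    mine <- one_sample_t_vs1(x)
    ref <- stats::t.test(x, mu = 1)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  })
  expect_error(one_sample_t_vs1(rep(1.2, 10)), class = "plvmotif_degenerate_test")
})

test_that("LOO logistic accuracy handles separation, constancy and null data", {
  d <- desk_design()
  deg <- numeric(nrow(d))
  names(deg) <- d$subject_id
  deg[d$group == "bd"] <- seq(1.2, 1.4, length.out = 17)
  deg[d$group == "control"] <- seq(0.8, 0.99, length.out = 22)
  expect_equal(as.numeric(loo_logreg_accuracy(deg[d$subject_id], d$group)), 1)

  # constant predictor: every fold predicts the majority class (control)
  const <- stats::setNames(rep(1, nrow(d)), d$subject_id)
  expect_equal(as.numeric(loo_logreg_accuracy(const[d$subject_id], d$group)),
               22 / 39, tolerance = 1e-12)

  withr::with_seed(81, {
    accs <- replicate(20, {
      x <- rnorm(nrow(d), 1, 0.05)
      as.numeric(loo_logreg_accuracy(x, d$group))
    })
    expect_lt(mean(accs), 0.7)
    expect_gt(mean(accs), 0.3)
  })
  expect_error(loo_logreg_accuracy(deg[1:22], rep("control", 22)),
               class = "plvmotif_design_error")
})
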