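test_that("difference-score ANCOVA matches the mixed two-way oracle", {
  withr::with_seed(90, {
    d <- desk_design()
    tab <- simulate_dti_table(d, tract_labels = c("ATR_L", "FMIN"), seed = 12)
    res <- as.data.frame(rm_ancova_dti(tab, d))
    for (tract in c("ATR_L", "FMIN")) {
      for (metric in c("FA", "MD")) {
        sub <- tab[tab$tract == tract & tab$metric == metric, ]
        sub$session <- factor(sub$session, levels = c("pre", "post"))
        sub$subject_id <- factor(sub$subject_id)
        fit <- summary(stats::aov(value ~ (sex + group) * session +
                                    Error(subject_id), data = sub))
        w <- fit[["Error: Within"]][[1]]
        b <- fit[["Error: subject_id"]][[1]]
        row <- res[res$tract == tract & res$metric == metric, ]
        expect_equal(row$F_interaction, w["group:session", "F value"],
                     tolerance = 1e-8)
        expect_equal(row$F_session, w["session", "F value"], tolerance = 1e-8)
        expect_equal(row$F_group, b["group", "F value"], tolerance = 1e-8)
      }
    }
  })
})

test_that("adding a constant to every value changes no F statistic", {
  d <- desk_design()
  tab <- simulate_dti_table(d, tract_labels = "CST_L", seed = 3)
  shifted <- tab
  shifted$value <- shifted$value + 0.37
  a <- as.data.frame(rm_ancova_dti(tab, d))
  b <- as.data.frame(rm_ancova_dti(shifted, d))
  expect_equal(a$F_group, b$F_group, tolerance = 1e-8)
  expect_equal(a$F_session, b$F_session, tolerance = 1e-8)
  expect_equal(a$F_interaction, b$F_interaction, tolerance = 1e-8)
})

test_that("incomplete crossings and degenerate tables are rejected", {
  d <- desk_design()
  tab <- simulate_dti_table(d, tract_labels = "ATR_L", seed = 3)
  broken <- tab[!(tab$subject_id == d$subject_id[1] & tab$session == "post"), ]
  expect_error(rm_ancova_dti(broken, d), class = "plvmotif_incomplete_design")

  flat <- simulate_dti_table(d, tract_labels = "ATR_L",
                             noise_sd = c(FA = 0, MD = 0, RD = 0, AD = 0))
  expect_error(rm_ancova_dti(flat, d), class = "plvmotif_degenerate")
})

test_that("a planted group x session interaction is detected reliably", {
  d <- desk_design()
  hits <- vapply(1:15, function(r) {
    tab <- simulate_dti_table(d, tract_labels = "SLF_L",
                              group_session_effect = c(FA = 3 * 0.02, MD = 0,
                                                       RD = 0, AD = 0),
                              seed = 1000 + r)
    res <- as.data.frame(rm_ancova_dti(tab, d))
    res$p_interaction[res$metric == "FA"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null interaction p-values are roughly uniform", {
  d <- desk_design()
  ps <- unlist(lapply(1:30, function(r) {
    tab <- simulate_dti_table(d, tract_labels = c("ATR_L", "CGC_R"),
                              seed = 2000 + r)
    as.data.frame(rm_ancova_dti(tab, d))$p_interaction
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("BH adjustment column is added on request", {
  d <- desk_design()
  tab <- simulate_dti_table(d, tract_labels = c("ATR_L", "UF_R"), seed = 8)
  res <- rm_ancova_dti(tab, d, p_adjust = "BH")
  expect_true("p_interaction_adj" %in% names(res))
  expect_equal(res$p_interaction_adj,
               stats::p.adjust(res$p_interaction, "BH"))
})
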