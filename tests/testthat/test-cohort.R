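test_that("make_design builds the requested roster exactly", {
  d <- make_design(22, 17, c(control = 12, bd = 8), seed = 4)
  expect_equal(nrow(d), 39)
  expect_equal(sum(d$sex == "F"), 20)
  expect_equal(as.vector(table(d$group)), c(22, 17))
  expect_equal(sum(d$sex == "F" & d$group == "control"), 12)
  expect_false(any(duplicated(d$subject_id)))
  expect_equal(attr(d, "sessions"), c("pre", "post"))

  all_male <- make_design(2, 2, c(control = 0, bd = 0), seed = 1)
  expect_equal(nrow(all_male), 4)
  expect_true(all(all_male$sex == "M"))

  expect_error(make_design(1, 0, c(control = 0, bd = 0)),
               class = "plvmotif_design_error")
  expect_error(make_design(5, 5, c(control = 6, bd = 0)),
               class = "plvmotif_design_error")
  expect_identical(make_design(seed = 9), make_design(seed = 9))
})

test_that("expected_plv matches the Bessel series and is monotone", {
  # independent oracle: truncated power series of I0 and I1
  bessel_series <- function(x, nu) {
    k <- 0:40
    sum((x / 2)^(2 * k + nu) / (factorial(k) * gamma(k + nu + 1)))
  }
  expect_equal(expected_plv(2), bessel_series(2, 1) / bessel_series(2, 0),
               tolerance = 1e-10)
  expect_equal(expected_plv(2), 0.6977747, tolerance = 1e-6)
  expect_identical(expected_plv(0), 0)
  expect_gt(expected_plv(1e6), 0.999)
  kappas <- seq(0, 20, by = 0.25)
  expect_true(all(diff(expected_plv(kappas)) > 0))
  expect_error(expected_plv(-1), class = "plvmotif_domain_error")
  expect_error(expected_plv(Inf), class = "plvmotif_domain_error")
})

test_that("plv_concentration inverts expected_plv", {
  r <- c(0, 0.1, 0.45, 0.698, 0.9, 0.99)
  expect_equal(expected_plv(plv_concentration(r)), r, tolerance = 1e-8)
  expect_error(plv_concentration(1), class = "plvmotif_domain_error")
})

test_that("von Mises sampler has the prescribed resultant and symmetry", {
  withr::with_seed(11, {
    for (kappa in c(0.5, 2, 8)) {
      th <- rvon_mises(4e4, kappa)
      z <- mean(exp(1i * th))
      expect_equal(Mod(z), expected_plv(kappa), tolerance = 0.015)
      expect_lt(abs(Arg(z)), 0.05)
    }
    th0 <- rvon_mises(4e4, 0)
    expect_lt(Mod(mean(exp(1i * th0))), 0.02)
  })
  expect_error(rvon_mises(5, -1), class = "plvmotif_domain_error")
})

test_that("simulate_session is reproducible and PLV-calibrated", {
  d <- make_design(3, 3, c(control = 1, bd = 1), seed = 1)
  kap <- kappa_block(n_nodes = 4, nodes_a = 1, nodes_b = 2, value = 2)
  plan <- coupling_plan(4, kap, n_trials = 100, kind = "phase")
  s1 <- simulate_session(d, plan, seed = 3)
  s2 <- simulate_session(d, plan, seed = 3)
  expect_identical(s1, s2)

  pm <- plv_matrix(s1[[1]])$plv
  expect_equal(pm[1, 2], expected_plv(2), tolerance = 0.03)
  # uncoupled pairs sit at the single-trial Rayleigh noise floor
  floor_bound <- 1.5 * sqrt(pi / (4 * 1000))
  expect_lt(pm[1, 3], floor_bound)
  expect_lt(pm[3, 4], floor_bound)

  bad <- kap; bad[1, 2] <- 3   # asymmetric
  expect_error(coupling_plan(4, bad), class = "plvmotif_plan_error")
  expect_error(coupling_plan(4, -kap), class = "plvmotif_plan_error")
})

test_that("identical series give PLV exactly 1", {
  ph <- array(0, dim = c(2, 2, 64))
  base <- seq(0, 12 * pi, length.out = 64)
  ph[1, 1, ] <- base; ph[1, 2, ] <- base
  ph[2, 1, ] <- base + 1; ph[2, 2, ] <- base + 1
  pm <- plv_matrix(trial_set(ph, fs = 16, kind = "phase"))
  expect_equal(pm$plv[1, 2], 1, tolerance = 1e-12)
})

test_that("simulate_dti_table is complete, bounded and seeded", {
  d <- make_design(4, 4, c(control = 2, bd = 2), seed = 1)
  tab <- simulate_dti_table(d, tract_labels = c("ATR_L", "CST_R"), seed = 5)
  expect_equal(nrow(tab), 8 * 2 * 2 * 4)
  expect_true(all(table(tab$subject_id, tab$session, tab$tract, tab$metric) == 1))
  expect_identical(tab, simulate_dti_table(d, tract_labels = c("ATR_L", "CST_R"), seed = 5))

  quiet <- simulate_dti_table(d, tract_labels = "ATR_L",
                              noise_sd = c(FA = 0, MD = 0, RD = 0, AD = 0))
  expect_equal(length(unique(quiet$value[quiet$metric == "FA"])), 1)

  expect_error(simulate_dti_table(d, baselines = c(FA = 1.4, MD = 7.5e-4,
                                                   RD = 6e-4, AD = 1.1e-3)),
               class = "plvmotif_parameter_error")
})
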