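test_that("Kratky-Porod expectation has the right values and limits", {
  # direct evaluation, checked against independent arithmetic
  expect_equal(wlc_expected_r2(0.74, 1.48),
               2 * 0.74 * 1.48 * (1 - 0.5 * (1 - exp(-2))),
               tolerance = 1e-12)
  expect_equal(wlc_expected_r2(0.74, 1.48), 1.2434, tolerance = 1e-4)
  # rigid limit R^2 -> L^2; flexible limit R^2 -> 2PL - 2P^2
  expect_equal(wlc_expected_r2(100, 0.001), 1e-6, tolerance = 1e-4)
  expect_equal(wlc_expected_r2(0.01, 10), 0.1998, tolerance = 1e-6)
  expect_equal(wlc_expected_r2(5, 5000), 2 * 5 * 5000 - 2 * 25,
               tolerance = 1e-6)
  expect_error(wlc_expected_r2(-1, 1), "positive")
  expect_error(wlc_expected_r2(1, 0), "positive")
})

test_that("series branch joins the direct evaluation smoothly", {
  p <- 1
  just_above <- wlc_expected_r2(p, p * 1.0001e-4)
  just_below <- wlc_expected_r2(p, p * 0.9999e-4)
  expect_equal(just_above / just_below, (1.0001 / 0.9999)^2,
               tolerance = 1e-6)
})

test_that("expected R^2 is strictly increasing in P and in L", {
  p_grid <- c(0.05, 0.2, 0.74, 3, 10)
  l_grid <- c(0.1, 0.5, 1.48, 4)
  for (l in l_grid) expect_true(all(diff(wlc_expected_r2(p_grid, l)) > 0))
  for (p in p_grid) expect_true(all(diff(wlc_expected_r2(p, l_grid)) > 0))
})

test_that("noiseless model data is recovered exactly", {
  l <- seq(0.1, 2, length.out = 50)
  geom <- data.frame(contour_length_um = l,
                     r2_um2 = wlc_expected_r2(0.5, l))
  fit <- fit_persistence_length(geom)
  expect_s3_class(fit, "wlc_fit")
  expect_equal(fit$p_hat_um, 0.5, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$at_boundary)
  expect_equal(fit$n_fibrils, 50)
  expect_lt(fit$rss_um4, 1e-12)
})

test_that("fit preconditions and degenerate inputs are handled", {
  l <- c(0.5, 1)
  expect_error(
    fit_persistence_length(data.frame(contour_length_um = l,
                                      r2_um2 = wlc_expected_r2(1, l))),
    ">= 3 fibrils")
  expect_error(
    fit_persistence_length(data.frame(contour_length_um = c(1, 1, 1),
                                      r2_um2 = c(0.5, 0.6, 1.5))),
    "exceeding contour length")
  # perfectly straight chains: R^2 = L^2 fits any large P -> boundary
  l <- seq(0.2, 1, length.out = 10)
  expect_warning(
    fit <- fit_persistence_length(data.frame(contour_length_um = l,
                                             r2_um2 = l^2)),
    "bound")
  expect_true(fit$at_boundary)
})

test_that("simulated cohorts recover the generating persistence length", {
  sim <- simulate_study(simulation_spec(seed = 20211105))
  geom <- measure_all(sim$traces)
  fit <- fit_persistence_length(geom)
  expect_equal(fit$n_fibrils, 195)
  expect_lt(abs(fit$p_hat_um - 0.74), 0.08)
  expect_lte(fit$ci95_lo_um, fit$p_hat_um)
  expect_gte(fit$ci95_hi_um, fit$p_hat_um)
})

test_that("bootstrap CI is seeded, reproducible, and brackets the estimate", {
  sim <- simulate_study(simulation_spec(n_fibrils = 60, seed = 13))
  geom <- measure_all(sim$traces)
  f1 <- fit_persistence_length(geom, ci_method = "bootstrap",
                               bootstrap_B = 100, seed = 5)
  f2 <- fit_persistence_length(geom, ci_method = "bootstrap",
                               bootstrap_B = 100, seed = 5)
  expect_identical(f1$ci95_lo_um, f2$ci95_lo_um)
  expect_identical(f1$ci95_hi_um, f2$ci95_hi_um)
  expect_lt(f1$ci95_lo_um, f1$p_hat_um)
  expect_gt(f1$ci95_hi_um, f1$p_hat_um)
  expect_identical(f1$ci_method, "bootstrap")
})

test_that("bending rigidity is k_B T P with linear error propagation", {
  r <- bending_rigidity(0.74, 300)
  expect_equal(r$b_Nm2, 1.380649e-23 * 300 * 0.74e-6, tolerance = 1e-12)
  expect_equal(bending_rigidity(1, 300)$b_Nm2, 4.141947e-27,
               tolerance = 1e-6)
  expect_equal(bending_rigidity(0, 300)$b_Nm2, 0)
  # linear in T and in P (ratio test)
  expect_equal(bending_rigidity(0.74, 600)$b_Nm2 / r$b_Nm2, 2)
  expect_equal(bending_rigidity(1.48, 300)$b_Nm2 / r$b_Nm2, 2)
  # SE propagation
  r2 <- bending_rigidity(0.74, 300, se_um = 0.08)
  expect_equal(r2$se_Nm2, 1.380649e-23 * 300 * 0.08e-6, tolerance = 1e-12)
  expect_error(bending_rigidity(-0.1), "non-negative")
})

test_that("fitted model predictions agree with Monte-Carlo mean R^2", {
  set.seed(77)
  sim <- simulate_study(simulation_spec(
    n_fibrils = 800, seed = 77,
    length_dist = list(kind = "fixed", l_um = 0.74)))
  r2 <- vapply(sim$traces, function(t) end_to_end(t)^2, numeric(1))
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - wlc_expected_r2(0.74, 0.74)), 3 * se)
})
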