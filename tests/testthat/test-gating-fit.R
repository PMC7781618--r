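# I-V, G-V and SSI fits, r-value extraction, and their oracles.

test_that("the I-V fit recovers generating parameters from exact data", {
  v <- seq(-89, 71, 5)
  peaks <- analytic_peaks(v, v_half = -13.40, slope = 7.60, g_max = 8,
                          v_rev = 64.75)
  fit <- fit_iv(peaks)
  expect_true(fit$converged)
  expect_equal(fit$v_half, -13.40, tolerance = 1e-4)
  expect_equal(fit$slope, 7.60, tolerance = 1e-4)
  expect_equal(fit$v_rev, 64.75, tolerance = 1e-4)
  expect_equal(fit$g_max, 8, tolerance = 1e-4)
})

test_that("the I-V fit is scale- and translation-equivariant", {
  v <- seq(-89, 71, 5)
  peaks <- analytic_peaks(v, -13.40, 7.60, 8, 64.75)
  base <- fit_iv(peaks)

  scaled <- peaks
  scaled$peak_pa <- scaled$peak_pa * 3.7
  fs <- fit_iv(scaled)
  expect_equal(fs$g_max, base$g_max * 3.7, tolerance = 1e-5)
  expect_equal(fs$v_half, base$v_half, tolerance = 1e-5)
  expect_equal(fs$slope, base$slope, tolerance = 1e-5)
  expect_equal(fs$v_rev, base$v_rev, tolerance = 1e-5)

  shifted <- peaks
  shifted$test_v <- shifted$test_v + 12
  ft <- fit_iv(shifted)
  expect_equal(ft$v_half, base$v_half + 12, tolerance = 1e-5)
  expect_equal(ft$v_rev, base$v_rev + 12, tolerance = 1e-5)
  expect_equal(ft$slope, base$slope, tolerance = 1e-5)
})

test_that("the conductance transform inverts the I-V product exactly", {
  v <- seq(-89, 71, 5)
  peaks <- analytic_peaks(v, -13.40, 7.60, 8, 64.75)
  gv <- gv_transform(peaks, v_rev = 64.75, g_max = 8)
  act <- activation_params(-13.40, 7.60, 8, 64.75)
  expect_equal(gv$g_norm, steady_state_activation(gv$v, act),
               tolerance = 1e-12)
  # voltages within 5 mV of v_rev are dropped
  expect_true(all(abs(gv$v - 64.75) >= 5))
  # the midpoint identity: G/Gmax = 0.5 at V0.5
  g_at_vhalf <- 8 / (1 + exp(0)) # closed form at v = v_half
  expect_equal(g_at_vhalf / 8, 0.5)
  # zero current gives zero conductance
  z <- peaks
  z$peak_pa <- 0 * z$peak_pa
  expect_true(all(gv_transform(z, 64.75)$g == 0))
})

test_that("the G-V Boltzmann fit recovers exact inputs and reflects", {
  v <- seq(-80, 40, 5)
  act <- activation_params(0.45, 9.51, 8, 66.56)
  gv <- data.frame(v = v, g = 8 * steady_state_activation(v, act))
  fit <- fit_gv(gv)
  expect_true(fit$converged)
  expect_equal(fit$v_half, 0.45, tolerance = 1e-3)
  expect_equal(fit$slope, 9.51, tolerance = 1e-3)

  # reflecting the voltage axis negates v_half; slope magnitude unchanged
  # (8 - G(-v) is again a rising Boltzmann, centred at -V0.5)
  refl <- data.frame(v = -v, g = 8 - gv$g)
  refl <- refl[order(refl$v), ]
  fit_r <- fit_gv(refl)
  expect_equal(fit_r$v_half, -0.45, tolerance = 1e-3)
  expect_equal(abs(fit_r$slope), 9.51, tolerance = 1e-3)
})

test_that("G-V fit agrees with a brute-force grid search", {
  # noisy normalized conductances on a dense voltage grid
  v <- seq(-60, 40, length.out = 201)
  act <- activation_params(-10.21, 8.51, 1, 65.7)
  set.seed(42)
  g <- steady_state_activation(v, act) + rnorm(201, 0, 0.02)
  fit <- fit_gv(data.frame(v = v, g = g))

  # profile the linear scale analytically, scan (v_half, slope) at 0.01 mV
  vh_grid <- seq(fit$v_half - 1, fit$v_half + 1, by = 0.01)
  k_grid <- seq(fit$slope - 1, fit$slope + 1, by = 0.01)
  best <- c(Inf, NA, NA)
  for (k in k_grid) {
    sse <- vapply(vh_grid, function(vh) {
      f <- 1 / (1 + exp(-(v - vh) / k))
      sc <- sum(g * f) / sum(f * f)
      sum((g - sc * f)^2)
    }, numeric(1))
    j <- which.min(sse)
    if (sse[j] < best[1]) best <- c(sse[j], vh_grid[j], k)
  }
  expect_equal(fit$v_half, best[2], tolerance = 0.011)
  expect_equal(fit$slope, best[3], tolerance = 0.011)
})

test_that("the SSI fit recovers exact availability parameters", {
  inact <- inactivation_params(-39.94, 4.94, 0.1082)
  v <- seq(-119, 1, 10)
  ssi <- data.frame(cond_v = v, ratio = steady_state_availability(v, inact))
  fit <- fit_ssi(ssi)
  expect_true(fit$converged)
  expect_equal(fit$v_half, -39.94, tolerance = 1e-4)
  expect_equal(fit$slope, 4.94, tolerance = 1e-4)
  expect_equal(fit$plateau, 0.1082, tolerance = 1e-4)
})

test_that("an all-available SSI input is flagged degenerate", {
  ssi <- data.frame(cond_v = seq(-119, 1, 10), ratio = 1)
  fit <- fit_ssi(ssi)
  expect_false(fit$converged)
  # near-flat input with tiny jitter likewise
  set.seed(1)
  ssi$ratio <- 1 - abs(rnorm(nrow(ssi), 0, 0.005))
  expect_false(fit_ssi(ssi)$converged)
})

test_that("SSI normalization makes the most negative conditioning ratio ~1", {
  p <- demo_params(noise_sd = 5)
  pr <- default_protocols()
  rec <- simulate_recording(p, pr$ssi, leak = "offline", v_max = -5,
                            seed = 4)
  ratios <- ssi_ratios(leak_subtract(rec))
  expect_equal(ratios$ratio[which.min(ratios$cond_v)], 1, tolerance = 0.05)
})

test_that("r-values follow closed-form decay for known kinetics", {
  # mono-exponential, tau = 500 ms, no plateau: r500 = 100/e
  p <- channel_params(
    activation_params(-10, 8, 8, 65, tau_act = 0.05),
    inactivation_params(-60, 5, plateau = 0, tau_fast = 500, tau_slow = 500,
                        frac_fast = 1),
    passive_params(g_leak = 0, noise_sd = 0, tau_cap = 0.02))
  rec <- simulate_recording(p, default_protocols()$inact5s, leak = "none",
                            v_max = 10)
  kin <- inactivation_kinetics(rec)
  expect_equal(unname(kin$r["r500"]), 100 * exp(-1), tolerance = 0.8)
  expect_equal(kin$v_max_used, 10)
  # r monotonically non-increasing on a noiseless trace
  expect_true(all(diff(kin$r) <= 0))
})

test_that("a non-inactivating current keeps r = 100 at all read-outs", {
  p <- channel_params(
    activation_params(-10, 8, 8, 65, tau_act = 0.05),
    inactivation_params(-60, 5, plateau = 1),
    passive_params(g_leak = 0, noise_sd = 0, tau_cap = 0.02))
  rec <- simulate_recording(p, default_protocols()$inact5s, leak = "none",
                            v_max = -5)
  kin <- inactivation_kinetics(rec)
  expect_equal(unname(kin$r), rep(100, 6), tolerance = 1e-3)
})

test_that("r-value extraction errors when the peak is below the noise floor", {
  p <- channel_params(
    activation_params(-10, 8, 1e-4, 65),
    inactivation_params(-36, 5.5, 0.18),
    passive_params(g_leak = 0, noise_sd = 5))
  rec <- simulate_recording(p, default_protocols()$inact5s, leak = "none",
                            v_max = -5, seed = 8)
  expect_error(inactivation_kinetics(rec), "noise floor")
})

test_that("bi-exponential kinetics fits reproduce tabulated r-values", {
  times <- c(50, 100, 250, 500, 1000, 5000)
  # an exactly bi-exponential-with-plateau target is recovered
  truth <- list(f = 0.55, tf = 90, ts = 900, c = 0.07)
  r <- 100 * ((1 - truth$c) * (truth$f * exp(-times / truth$tf) +
                (1 - truth$f) * exp(-times / truth$ts)) + truth$c)
  fit <- fit_rvalue_kinetics(times, r)
  expect_true(fit$converged)
  expect_equal(fit$tau_fast, truth$tf, tolerance = 1e-3)
  expect_equal(fit$tau_slow, truth$ts, tolerance = 1e-3)
  expect_equal(fit$plateau, truth$c, tolerance = 1e-5)
  expect_lte(fit$tau_fast, fit$tau_slow)

  # tabulated reference kinetics are approximated closely (4 parameters,
  # 6 constraints: small residual, not exact)
  row <- reference_kinetics()[1, ]
  r_tab <- as.numeric(row[paste0("r", times)])
  fit2 <- fit_rvalue_kinetics(times, r_tab)
  expect_true(fit2$converged)
  expect_lt(max(abs(fit2$fitted - r_tab)), 2.5)
})

test_that("G-V refit of I-V-conforming data is self-consistent", {
  v <- seq(-89, 71, 5)
  peaks <- analytic_peaks(v, -13.40, 7.60, 8, 64.75)
  iv <- fit_iv(peaks)
  gv <- fit_gv(gv_transform(peaks, v_rev = iv$v_rev, g_max = iv$g_max))
  expect_equal(gv$v_half, iv$v_half, tolerance = 0.01)
  expect_equal(gv$slope, iv$slope, tolerance = 0.01)
})
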