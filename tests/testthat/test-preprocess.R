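# Junction-potential correction, leak subtraction, peak extraction, QC.

test_that("liquid-junction-potential correction is plain voltage addition", {
  expect_equal(correct_ljp(-80), -89.3)
  expect_equal(correct_ljp(10, ljp = -9.3), 0.7)
  expect_equal(correct_ljp(c(-80, 0, 40), ljp = 0), c(-80, 0, 40))
})

test_that("offline subtraction cancels pure ohmic leak to numerical zero", {
  # channel-free cell: only leak and capacitive transients
  p <- channel_params(
    activation_params(-10, 8.5, 0, 65),
    inactivation_params(-36, 5.5, 0.18),
    passive_params(g_leak = 2.5, e_leak = -10, noise_sd = 0))
  rec <- simulate_recording(p, default_protocols()$iv, leak = "offline")
  rec2 <- leak_subtract(rec)
  for (sw in rec2$sweeps) {
    idx <- cavgating:::segment_index(sw$segments, rec2$dt)
    # residual judged away from step edges, where capacitive spikes live
    # (the transient itself decays below 1e-9 pA only after ~8 ms)
    keep <- unlist(lapply(seq_len(nrow(idx)), function(s) {
      (idx[s, "lo"] + round(8 / rec2$dt)):idx[s, "hi"]
    }))
    expect_lt(max(abs(sw$current[keep])), 1e-9)
  }
})

test_that("offline subtraction restores the leak-free peak table", {
  p_leaky <- demo_params(g_leak = 2, noise_sd = 0, tau_cap = 0.02)
  p_clean <- demo_params(g_leak = 0, noise_sd = 0, tau_cap = 0.02)
  pr <- default_protocols()$iv
  pk_sub <- extract_peaks(leak_subtract(
    simulate_recording(p_leaky, pr, leak = "offline")))
  pk_ref <- extract_peaks(simulate_recording(p_clean, pr, leak = "none"))
  # agreement within the recording noise scale (here: channel contamination
  # of the reference step, a fraction of a pA per mV)
  expect_lt(max(abs(pk_sub$peak_pa - pk_ref$peak_pa)), 5)
})

test_that("offline subtraction is a no-op for a leak-free cell", {
  # channel-free, leak-free: the estimated leak is exactly zero
  p0 <- channel_params(
    activation_params(-10, 8.5, 0, 65),
    inactivation_params(-36, 5.5, 0.18),
    passive_params(g_leak = 0, noise_sd = 0))
  rec <- simulate_recording(p0, default_protocols()$iv, leak = "offline")
  rec2 <- leak_subtract_offline(rec)
  expect_equal(rec2$sweeps[[10]]$current, rec$sweeps[[10]]$current,
               tolerance = 1e-12)
  # with channels present the reference step picks up a sub-pA channel
  # current, so the peak table may shift by at most a few pA
  p <- demo_params(g_leak = 0, noise_sd = 0)
  rec <- simulate_recording(p, default_protocols()$iv, leak = "offline")
  pk_raw <- extract_peaks(rec)
  pk_sub <- extract_peaks(leak_subtract_offline(rec))
  expect_lt(max(abs(pk_sub$peak_pa - pk_raw$peak_pa)), 5)
})

test_that("P/4 cancels linear leak and capacitance exactly", {
  p <- channel_params(
    activation_params(-10, 8.5, 0, 65),
    inactivation_params(-36, 5.5, 0.18),
    passive_params(g_leak = 3, e_leak = -5, noise_sd = 0))
  rec <- simulate_recording(p, default_protocols()$iv, leak = "p4")
  rec2 <- leak_subtract(rec)
  resid <- vapply(Filter(function(s) s$role == "main", rec2$sweeps),
                  function(s) max(abs(s$current)), numeric(1))
  expect_lt(max(resid), 1e-9)
})

test_that("P/4 preserves channel current carried by the main sweep", {
  # below-threshold subsweeps: compare against the same cell without leak
  p_leaky <- demo_params(g_leak = 2, noise_sd = 0)
  p_clean <- demo_params(g_leak = 0, noise_sd = 0)
  pr <- default_protocols()$iv
  pk_p4 <- extract_peaks(leak_subtract(
    simulate_recording(p_leaky, pr, leak = "p4")))
  pk_ref <- extract_peaks(simulate_recording(p_clean, pr, leak = "none"))
  keep <- pk_p4$test_v <= 0  # quarter steps stay below activation threshold
  expect_lt(max(abs(pk_p4$peak_pa[keep] - pk_ref$peak_pa[keep])), 5)
})

test_that("offline and P/4 subtraction agree within noise", {
  p <- demo_params(g_leak = 2, noise_sd = 5)
  pr <- default_protocols()$iv
  pk1 <- extract_peaks(leak_subtract(
    simulate_recording(p, pr, leak = "p4", seed = 1)))
  pk2 <- extract_peaks(leak_subtract(
    simulate_recording(p, pr, leak = "offline", seed = 2)))
  keep <- pk1$test_v <= 0
  expect_lt(max(abs(pk1$peak_pa[keep] - pk2$peak_pa[keep])), 20)
})

test_that("P/4 validates its subsweep count", {
  expect_error(leak_subtract_p4(rnorm(10), list(rnorm(10), rnorm(10))),
               "4 subsweeps")
})

test_that("peak extraction matches the quasi-steady closed form", {
  p <- oracle_params(v_half = -10.21, slope = 8.51, g_max = 8, v_rev = 65.7)
  rec <- simulate_recording(p, default_protocols()$iv, leak = "none")
  pk <- extract_peaks(rec)
  expected <- p$act$g_max *
    steady_state_activation(pk$test_v, p$act) * (pk$test_v - p$act$v_rev)
  expect_equal(pk$peak_pa, expected, tolerance = 5e-3)
  # capacitance normalization
  expect_equal(pk$norm_pa_pf, pk$peak_pa / 20)
})

test_that("QC excludes small and large maximal currents, idempotently", {
  mk <- function(peak) {
    v <- seq(-89, 71, 5)
    f <- (v - 65.7) / (1 + exp(-(v + 10) / 8.5))
    g <- abs(peak) / max(abs(f))  # scale so max inward current = `peak`
    qc_filter(analytic_peaks(v, -10, 8.5, g, 65.7))
  }
  ok <- mk(400)
  expect_true(attr(ok, "qc_included"))
  expect_equal(attr(ok, "qc_reason"), "ok")
  small <- mk(99)
  expect_false(attr(small, "qc_included"))
  expect_equal(attr(small, "qc_reason"), "too small")
  large <- mk(1001)
  expect_false(attr(large, "qc_included"))
  expect_equal(attr(large, "qc_reason"), "too large")
  twice <- qc_filter(small)
  expect_equal(attr(twice, "qc_reason"), "too small")
})
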