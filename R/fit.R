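# Parameter estimation: I-V fit, G-V Boltzmann, steady-state inactivation
# with a non-inactivating plateau, and inactivation time-course r-values.
# Nonlinear least squares are solved with Levenberg-Marquardt (minpack.lm)
# under box bounds; every fit uses a deterministic data-driven start so that
# identical data give identical estimates.

# slope-factor bounds (mV); fits pinned at a bound are flagged non-converged
.slope_bounds <- c(0.5, 30)

nls_safely <- function(formula, data, start, lower, upper) {
  tryCatch({
    lower <- lower[names(start)]
    upper <- upper[names(start)]
    fit <- minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    est <- coef(fit)[names(start)]
    at_bound <- any(abs(est - lower) < 1e-8) || any(abs(est - upper) < 1e-8)
    list(coef = est, sse = sum(residuals(fit)^2),
         converged = fit$convInfo$isConv && !at_bound)
  }, error = function(e) {
    list(coef = setNames(rep(NA_real_, length(start)), names(start)),
         sse = NA_real_, converged = FALSE)
  })
}

#' Fit the current-voltage relationship
#'
#' Fits peak currents to
#' \eqn{I(V) = G_{max} (V - V_{rev}) / (1 + \exp(-(V - V_{0.5})/k))} by
#' nonlinear least squares. Initial values are data-driven and
#' deterministic: \eqn{V_{rev}} from the zero crossing of the positive limb
#' (linear interpolation), \eqn{V_{0.5}} from the voltage of half-maximal
#' inward current on the hyperpolarized limb, slope 8 mV, and
#' \eqn{G_{max} = |I_{min}| / (V_{rev} - V_{0.5})}.
#'
#' @param peaks A `peak_table` (or data.frame with `test_v`, `peak_pa`)
#'   with at least 8 voltages spanning both sides of the I-V minimum.
#' @return An `iv_fit` list: `v_half`, `slope`, `g_max`, `v_rev` (mV/nS),
#'   `residual_sse`, `converged`. Non-convergence (or a slope pinned at its
#'   bound) is flagged, not an error; flagged cells are dropped from cohort
#'   summaries.
#' @export
fit_iv <- function(peaks) {
  v <- peaks$test_v
  i <- peaks$peak_pa
  stopifnot(length(v) >= 8L, !anyDuplicated(v))
  k_min <- which.min(i)
  if (k_min <= 1L || k_min >= length(v)) {
    stop("I-V data must span both sides of the current minimum")
  }

  # start values (deterministic, see docs)
  v_rev0 <- {
    pos <- seq(k_min, length(v))
    cross <- which(i[pos[-length(pos)]] < 0 & i[pos[-1]] >= 0)
    if (length(cross) >= 1L) {
      a <- pos[cross[1]]; b <- a + 1L
      v[a] + (0 - i[a]) * (v[b] - v[a]) / (i[b] - i[a])
    } else {
      max(v) + 10
    }
  }
  half <- i[k_min] / 2
  lower_limb <- seq_len(k_min)
  v_half0 <- v[lower_limb[which.min(abs(i[lower_limb] - half))]]
  g0 <- abs(i[k_min]) / max(v_rev0 - v_half0, 1)

  res <- nls_safely(
    peak_pa ~ g_max * (test_v - v_rev) / (1 + exp(-(test_v - v_half) / slope)),
    data = data.frame(test_v = v, peak_pa = i),
    start = list(g_max = g0, v_rev = v_rev0, v_half = v_half0, slope = 8),
    lower = c(g_max = 1e-4, v_rev = -50, v_half = -120,
              slope = .slope_bounds[1]),
    upper = c(g_max = 1e4, v_rev = 150, v_half = 80,
              slope = .slope_bounds[2])
  )
  structure(
    list(v_half = unname(res$coef["v_half"]),
         slope = unname(res$coef["slope"]),
         g_max = unname(res$coef["g_max"]),
         v_rev = unname(res$coef["v_rev"]),
         residual_sse = res$sse, converged = res$converged),
    class = "iv_fit"
  )
}

#' Conductance-voltage transform
#'
#' Converts peak currents to conductances, \eqn{G(V) = I/(V - V_{rev})},
#' dropping test potentials within `exclude_mv` of the reversal potential
#' (where the ratio amplifies noise). When `g_max` is supplied the output
#' includes `g_norm = G/G_max`; under noise normalized values may slightly
#' exceed 1.
#'
#' @param peaks A `peak_table`.
#' @param v_rev Reversal potential (mV), normally the cell's own I-V fit.
#' @param g_max Optional maximal conductance (nS) for normalization.
#' @param exclude_mv Half-width of the exclusion band around `v_rev`.
#' @return data.frame with `v`, `g` (nS) and, if `g_max` given, `g_norm`.
#' @export
gv_transform <- function(peaks, v_rev, g_max = NULL, exclude_mv = 5) {
  stopifnot(is.numeric(v_rev), length(v_rev) == 1L, is.finite(v_rev))
  keep <- abs(peaks$test_v - v_rev) >= exclude_mv
  if (!any(keep)) stop("no voltages left after excluding the band around v_rev")
  out <- data.frame(v = peaks$test_v[keep],
                    g = peaks$peak_pa[keep] / (peaks$test_v[keep] - v_rev))
  if (!is.null(g_max)) out$g_norm <- out$g / g_max
  out
}

#' Fit the activation (G-V) Boltzmann
#'
#' Least-squares fit of \eqn{G(V) = G_{max}/(1 + \exp(-(V - V_{0.5})/k))}
#' with a free scale; the reported half-maximal activation voltage and slope
#' factor come from this fit.
#'
#' @param gv data.frame from [gv_transform()] (columns `v`, `g`); at least
#'   6 points.
#' @return A `gv_fit` list: `v_half`, `slope`, `g_max`, `residual_sse`,
#'   `converged`.
#' @export
fit_gv <- function(gv) {
  stopifnot(nrow(gv) >= 6L)
  g <- gv$g
  v <- gv$v
  scale0 <- max(abs(g))
  v_half0 <- v[which.min(abs(abs(g) - scale0 / 2))]
  res <- nls_safely(
    g ~ g_max / (1 + exp(-(v - v_half) / slope)),
    data = data.frame(v = v, g = g),
    start = list(g_max = scale0 * sign(g[which.max(abs(g))]),
                 v_half = v_half0, slope = 8),
    lower = c(g_max = -1e4, v_half = -120, slope = .slope_bounds[1]),
    upper = c(g_max = 1e4, v_half = 80, slope = .slope_bounds[2])
  )
  structure(
    list(v_half = unname(res$coef["v_half"]),
         slope = unname(res$coef["slope"]),
         g_max = unname(res$coef["g_max"]),
         residual_sse = res$sse, converged = res$converged),
    class = "gv_fit"
  )
}

#' Steady-state inactivation ratios of an SSI recording
#'
#' Per sweep, the ratio between the test-pulse and control-pulse peak
#' currents (both 20-ms pulses to the voltage of maximal inward current,
#' separated by the 5-s conditioning step).
#'
#' @param rec A leak-subtracted SSI `vc_recording`.
#' @param start_ms,smooth_ms Peak-search settings as in [extract_peaks()].
#' @return data.frame with `cond_v` (conditioning voltage, mV) and `ratio`.
#' @export
ssi_ratios <- function(rec, start_ms = 2, smooth_ms = 0.2) {
  stopifnot(inherits(rec, "vc_recording"), rec$protocol$kind == "SSI")
  mains <- Filter(function(s) s$role == "main", rec$sweeps)
  rows <- lapply(mains, function(sw) {
    ctrl <- step_peak(sw$current, sw$segments, rec$dt, sw$control_segment,
                      start_ms = start_ms, smooth_ms = smooth_ms)
    test <- step_peak(sw$current, sw$segments, rec$dt, sw$test_segment,
                      start_ms = start_ms, smooth_ms = smooth_ms)
    data.frame(cond_v = sw$cond_v, ratio = test$peak / ctrl$peak)
  })
  out <- do.call(rbind, rows)
  out[order(out$cond_v), , drop = FALSE]
}

#' Fit the steady-state inactivation curve
#'
#' Fits availability ratios to the modified Boltzmann
#' \eqn{I(V) = (1 - I_{max})/(1 + \exp((V - V_{0.5,inact})/k_{inact})) + I_{max}}
#' with the non-inactivating plateau \eqn{I_{max}} bounded to `[0, 1]`
#' (reported as "non-inactivating \%" when multiplied by 100).
#'
#' @param ssi data.frame with columns `cond_v` and `ratio` (test/control
#'   peak-current ratios); at least 6 conditioning voltages.
#' @return An `ssi_fit` list: `v_half`, `slope`, `plateau`, `residual_sse`,
#'   `converged`. Degenerate input with essentially no inactivation (ratio
#'   range < 0.05) is flagged non-converged.
#' @export
fit_ssi <- function(ssi) {
  stopifnot(all(c("cond_v", "ratio") %in% names(ssi)), nrow(ssi) >= 6L)
  v <- ssi$cond_v
  r <- ssi$ratio
  if (diff(range(r)) < 0.05) {
    return(structure(list(v_half = NA_real_, slope = NA_real_,
                          plateau = NA_real_, residual_sse = NA_real_,
                          converged = FALSE),
                     class = "ssi_fit"))
  }
  p0 <- min(1, max(0, min(r)))
  v_half0 <- v[which.min(abs(r - (1 + p0) / 2))]
  res <- nls_safely(
    ratio ~ (1 - plateau) / (1 + exp((cond_v - v_half) / slope)) + plateau,
    data = data.frame(cond_v = v, ratio = r),
    start = list(v_half = v_half0, slope = 5, plateau = p0),
    lower = c(v_half = -150, slope = .slope_bounds[1], plateau = 0),
    upper = c(v_half = 50, slope = .slope_bounds[2], plateau = 1)
  )
  structure(
    list(v_half = unname(res$coef["v_half"]),
         slope = unname(res$coef["slope"]),
         plateau = unname(res$coef["plateau"]),
         residual_sse = res$sse,
         converged = res$converged),
    class = "ssi_fit"
  )
}

#' Inactivation time-course r-values
#'
#' From a leak-subtracted 5-s depolarization at the voltage of maximal
#' inward current, computes the percentage of remaining current
#' \eqn{r_t = 100\,|I(t)|/|I_{peak}|} after `times` milliseconds from the
#' pulse onset, each read as the mean over a +/-`window_ms` window (the
#' peak itself is located as in [extract_peaks()]).
#'
#' @param rec A leak-subtracted INACT5S `vc_recording` (single 5-s sweep),
#'   or any recording whose first main sweep holds a >= 5000 ms step.
#' @param times Read-out times (ms from pulse onset).
#' @param window_ms Averaging half-window (ms).
#' @param start_ms,smooth_ms Peak-search settings as in [extract_peaks()].
#' @return A `kinetics_result` list: `r` (named vector, percent),
#'   `v_max_used` (mV), `peak_pa`.
#' @export
inactivation_kinetics <- function(rec,
                                  times = c(50, 100, 250, 500, 1000, 5000),
                                  window_ms = 2, start_ms = 2,
                                  smooth_ms = 0.2) {
  stopifnot(inherits(rec, "vc_recording"))
  sw <- Filter(function(s) s$role == "main", rec$sweeps)[[1]]
  seg <- sw$step_segment
  if (sw$segments$dur[seg] < max(times)) {
    stop("depolarizing pulse shorter than the last read-out time")
  }
  idx <- segment_index(sw$segments, rec$dt)
  onset <- idx[seg, "lo"] - 1L
  pk <- step_peak(sw$current, sw$segments, rec$dt, seg,
                  start_ms = start_ms, smooth_ms = smooth_ms)
  base <- sw$current[seq_len(max(1L, onset))]
  noise_floor <- max(5 * stats::sd(base), 1e-9)
  if (abs(pk$peak) < noise_floor) {
    stop("peak current is below the noise floor; cannot compute r-values")
  }
  w <- as.integer(round(window_ms / rec$dt))
  r <- vapply(times, function(tm) {
    k <- onset + as.integer(round(tm / rec$dt))
    lo <- max(idx[seg, "lo"], k - w)
    hi <- min(idx[seg, "hi"], k + w)
    100 * abs(mean(sw$current[lo:hi])) / abs(pk$peak)
  }, numeric(1))
  structure(
    list(r = setNames(r, paste0("r", times)), v_max_used = sw$test_v,
         peak_pa = pk$peak),
    class = "kinetics_result"
  )
}

#' Fit a bi-exponential-plus-plateau decay to r-values
#'
#' Recovers inactivation kinetics from tabulated remaining-current
#' fractions: fits
#' \eqn{r(t)/100 = (1 - c)(f e^{-t/\tau_f} + (1 - f) e^{-t/\tau_s}) + c}
#' to the six standard time points by least squares. Useful to turn a
#' published r-value row into simulator kinetics
#' (see [inactivation_params()]).
#'
#' @param times Times (ms).
#' @param r Remaining current at `times`, percent of peak.
#' @return List `frac_fast`, `tau_fast`, `tau_slow`, `plateau`, `sse`,
#'   `converged`, plus `fitted` (percent at `times`).
#' @export
fit_rvalue_kinetics <- function(times = c(50, 100, 250, 500, 1000, 5000), r) {
  stopifnot(length(times) == length(r), length(r) >= 4L, all(r >= 0))
  dat <- data.frame(t = times, y = r / 100)
  res <- nls_safely(
    y ~ (1 - c0) * (f * exp(-t / tau_f) + (1 - f) * exp(-t / tau_s)) + c0,
    data = dat,
    start = list(f = 0.6, tau_f = 80, tau_s = 800,
                 c0 = 0.9 * min(dat$y)),
    lower = c(f = 0, tau_f = 1, tau_s = 50, c0 = 0),
    upper = c(f = 1, tau_f = 2000, tau_s = 20000, c0 = 1)
  )
  cf <- res$coef
  if (!any(is.na(cf)) && cf["tau_f"] > cf["tau_s"]) {
    cf[c("tau_f", "tau_s")] <- cf[c("tau_s", "tau_f")]
    cf["f"] <- 1 - cf["f"]
  }
  fitted <- if (any(is.na(cf))) rep(NA_real_, length(times)) else {
    100 * ((1 - cf["c0"]) * (cf["f"] * exp(-times / cf["tau_f"]) +
                             (1 - cf["f"]) * exp(-times / cf["tau_s"])) +
           cf["c0"])
  }
  list(frac_fast = unname(cf["f"]), tau_fast = unname(cf["tau_f"]),
       tau_slow = unname(cf["tau_s"]), plateau = unname(cf["c0"]),
       sse = res$sse, converged = res$converged, fitted = unname(fitted))
}
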