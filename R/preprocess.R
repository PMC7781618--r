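# Trace conditioning: junction-potential correction, leak subtraction,
# peak extraction, capacitance normalization and QC exclusion.

#' Liquid-junction-potential correction
#'
#' Command voltages reported by the amplifier are offset from the true
#' membrane potential by the pipette/bath liquid junction potential;
#' the true potential is `nominal + ljp`.
#'
#' @param nominal_v Nominal command voltage(s), mV.
#' @param ljp Liquid junction potential, mV (default -9.3, the value for a
#'   CsCl-based internal against a 15 mM Ca2+ / choline-Cl bath).
#' @return Corrected voltage(s), mV. A nominal -80 mV becomes -89.3 mV.
#' @export
correct_ljp <- function(nominal_v, ljp = -9.3) {
  stopifnot(is.numeric(nominal_v), is.numeric(ljp),
            all(is.finite(nominal_v)), all(is.finite(ljp)))
  nominal_v + ljp
}

# Rolling mean with partial windows at the edges; k = half-width in samples.
roll_mean <- function(x, half) {
  if (half <= 0) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sample index ranges of each segment of a sweep
segment_index <- function(segments, dt) {
  n <- segment_samples(segments, dt)
  hi <- cumsum(n)
  lo <- hi - n + 1L
  cbind(lo = lo, hi = hi)
}

#' Offline leak subtraction from a hyperpolarizing reference step
#'
#' Estimates the ohmic leak from the recording's 50-ms reference step from
#' -80 to -90 mV, where the channel is closed and only seal leak (plus
#' settled capacitance) flows: the leak conductance is the steady current
#' change divided by the 10-mV step, and the leak reversal potential follows
#' from the baseline holding current. The fitted leak
#' `g_leak * (V(t) - e_leak)` is then subtracted from every sweep
#' (including P/4 subsweeps, if present), yielding zero-baseline traces.
#'
#' @param rec A `vc_recording` containing a reference sweep (recordings
#'   simulated with `leak = "offline"` carry one).
#' @return The recording with leak-subtracted currents; the estimated
#'   `g_leak` (nS) and `e_leak` (mV) are stored in the result.
#' @export
leak_subtract_offline <- function(rec) {
  stopifnot(inherits(rec, "vc_recording"))
  roles <- vapply(rec$sweeps, function(s) s$role, character(1))
  ref_i <- which(roles == "leakref")
  if (length(ref_i) == 0L) {
    stop("recording has no leak-reference sweep (-80 to -90 mV step)")
  }
  ref <- rec$sweeps[[ref_i[1]]]
  idx <- segment_index(ref$segments, rec$dt)
  # steady windows: last 60% of baseline, last 60% of the step
  steady <- function(seg) {
    lo <- idx[seg, "lo"]; hi <- idx[seg, "hi"]
    mean(ref$current[(lo + ceiling((hi - lo) * 0.4)):hi])
  }
  i_base <- steady(1L)
  i_step <- steady(2L)
  v_base <- ref$segments$v[1]
  v_step <- ref$segments$v[2]
  g_leak <- (i_step - i_base) / (v_step - v_base)
  if (abs(g_leak) < 1e-9) {
    g_leak <- 0
    e_leak <- 0
    offset <- i_base
  } else {
    e_leak <- v_base - i_base / g_leak
    offset <- 0
  }
  rec$sweeps <- lapply(rec$sweeps, function(sw) {
    v_t <- segment_voltage_trace(sw$segments, rec$dt)
    sw$current <- sw$current - g_leak * (v_t - e_leak) - offset
    if (!is.null(sw$p4_currents)) {
      v_s <- segment_voltage_trace(sw$p4_segments, rec$dt)
      sw$p4_currents <- lapply(sw$p4_currents, function(cur) {
        cur - g_leak * (v_s - e_leak) - offset
      })
    }
    sw
  })
  rec$leak_subtracted <- TRUE
  rec$leak_fit <- list(g_leak = g_leak, e_leak = e_leak)
  rec
}

#' P/4 leak subtraction of a single sweep
#'
#' Subtracts the summed currents of four quarter-amplitude subsweeps from
#' the main sweep. Because all sweeps share the same holding level, the
#' summed subsweeps overestimate the main sweep's leak by a constant equal
#' to three times the holding-level leak current; that constant is estimated
#' from the pre-step baseline (where main and subsweeps follow identical
#' commands) and added back, so purely linear leak and capacitive currents
#' cancel exactly and the corrected trace is referenced to zero.
#'
#' @param main Main sweep current trace (pA).
#' @param subsweeps List of exactly four quarter-amplitude subsweep traces,
#'   same length as `main`.
#' @param baseline_n Number of leading samples (pre-step holding period)
#'   used to estimate the constant offset.
#' @return Corrected current trace.
#' @export
leak_subtract_p4 <- function(main, subsweeps, baseline_n = 100L) {
  if (!is.list(subsweeps) || length(subsweeps) != 4L) {
    stop("P/4 correction requires exactly 4 subsweeps, got ",
         length(subsweeps))
  }
  lens <- vapply(subsweeps, length, integer(1))
  if (any(lens != length(main))) {
    stop("subsweep lengths differ from the main sweep")
  }
  s <- subsweeps[[1]] + subsweeps[[2]] + subsweeps[[3]] + subsweeps[[4]]
  baseline_n <- min(baseline_n, length(main))
  offset <- mean(s[seq_len(baseline_n)] - main[seq_len(baseline_n)])
  main - s + offset
}

#' Leak-subtract a recording
#'
#' Dispatches to the method the recording was acquired for: the -80/-90 mV
#' reference-step estimate (`"offline"`) or per-sweep P/4 correction
#' (`"p4"`). Recordings with `leak_method = "none"` are returned unchanged;
#' already-subtracted recordings are returned unchanged too (idempotent).
#'
#' @param rec A `vc_recording`.
#' @param method Override of the recording's own `leak_method`.
#' @return The leak-subtracted recording.
#' @export
leak_subtract <- function(rec, method = NULL) {
  stopifnot(inherits(rec, "vc_recording"))
  if (isTRUE(rec$leak_subtracted)) return(rec)
  method <- method %||% rec$leak_method
  switch(method,
         none = rec,
         offline = leak_subtract_offline(rec),
         p4 = {
           rec$sweeps <- lapply(rec$sweeps, function(sw) {
             if (sw$role != "main" || is.null(sw$p4_currents)) return(sw)
             base_n <- max(1L, as.integer(round(
               (rec$protocol$pre_ms * 0.8) / rec$dt)))
             sw$current <- leak_subtract_p4(sw$current, sw$p4_currents,
                                            baseline_n = base_n)
             sw
           })
           rec$leak_subtracted <- TRUE
           rec
         },
         stop("unknown leak method: ", method))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Peak of one step: largest-magnitude sample (signed; inward currents are
# negative) of the +/- smooth_ms-smoothed trace inside
# [onset + start_ms, step end]; ties broken by the earliest sample.
step_peak <- function(current, segments, dt, step_segment,
                      start_ms = 2, smooth_ms = 0.2) {
  idx <- segment_index(segments, dt)
  lo <- idx[step_segment, "lo"]
  hi <- idx[step_segment, "hi"]
  half <- as.integer(round(smooth_ms / dt))
  from <- lo + as.integer(ceiling(start_ms / dt))
  # keep the smoother from smearing the off-edge capacitive transient in
  hi <- hi - half - 1L
  if (from >= hi) stop("peak-search window lies outside the step")
  sm <- roll_mean(current, half)
  win <- sm[from:hi]
  k <- which.max(abs(win))
  list(peak = win[k], index = from + k - 1L)
}

#' Extract a peak-current table from a step recording
#'
#' For every main sweep of an I-V (or 5-s depolarization) recording, locates
#' the peak inward current within the test step: the trace is smoothed with
#' a +/-`smooth_ms` moving average (for peak location only; stored traces
#' are never altered) and the largest-magnitude smoothed sample (signed;
#' inward Ca2+ currents are negative) later than `start_ms` after the step
#' edge is taken, the delay rejecting the capacitive transient. Currents are also normalized to the cell membrane
#' capacitance (pA/pF).
#'
#' @param rec A leak-subtracted `vc_recording` whose main sweeps carry a
#'   single test step (IV or INACT5S).
#' @param start_ms Peak-search delay after the step edge (ms).
#' @param smooth_ms Half-width of the moving-average smoother (ms).
#' @return A `peak_table` data.frame with one row per sweep: `test_v` (mV,
#'   strictly increasing), `peak_pa` (pA, signed), `norm_pa_pf` (pA/pF).
#' @export
extract_peaks <- function(rec, start_ms = 2, smooth_ms = 0.2) {
  stopifnot(inherits(rec, "vc_recording"))
  mains <- Filter(function(s) s$role == "main" && !is.null(s$step_segment),
                  rec$sweeps)
  if (length(mains) == 0L) stop("recording has no steppable main sweeps")
  rows <- lapply(mains, function(sw) {
    pk <- step_peak(sw$current, sw$segments, rec$dt, sw$step_segment,
                    start_ms = start_ms, smooth_ms = smooth_ms)
    data.frame(test_v = sw$test_v, peak_pa = pk$peak,
               norm_pa_pf = pk$peak / rec$c_m)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$test_v), , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$test_v)) stop("duplicate test voltages in recording")
  class(out) <- c("peak_table", "data.frame")
  attr(out, "c_m") <- rec$c_m
  out
}

#' Quality-control filter on peak amplitude
#'
#' Cells with maximal inward currents smaller than 100 pA or larger than
#' 1000 pA (in magnitude, at the voltage of maximal inward current) are
#' prospectively excluded from analysis.
#'
#' @param peaks A `peak_table` from [extract_peaks()].
#' @param lower,upper QC window on `|peak|` at `v_max`, in pA.
#' @return The table with attributes `qc_included` (logical), `qc_reason`
#'   (`"ok"`, `"too small"` or `"too large"`) and `v_max` (mV). Reapplying
#'   the filter does not change the outcome.
#' @export
qc_filter <- function(peaks, lower = 100, upper = 1000) {
  stopifnot(inherits(peaks, "peak_table"))
  k <- which.min(peaks$peak_pa)
  amp <- abs(peaks$peak_pa[k])
  reason <- if (amp < lower) "too small" else if (amp > upper) "too large" else "ok"
  attr(peaks, "qc_included") <- reason == "ok"
  attr(peaks, "qc_reason") <- reason
  attr(peaks, "v_max") <- peaks$test_v[k]
  peaks
}
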