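# Per-cell analysis: leak subtraction -> peaks -> QC -> fits, and cohort
# assembly into one results row per cell.

#' Analyze an I-V recording
#'
#' Runs the full activation analysis for one cell: leak subtraction, peak
#' extraction, amplitude QC, the I-V fit, and the G-V Boltzmann fit on the
#' conductance transform (using the cell's own fitted reversal potential and
#' maximal conductance).
#'
#' @param rec An I-V `vc_recording`.
#' @param ljp Additional liquid-junction-potential correction (mV) applied
#'   to the recorded test voltages. Simulated recordings already carry true
#'   membrane potentials, so the default is 0; use -9.3 for data imported
#'   with nominal command voltages.
#' @param start_ms,smooth_ms Peak-search settings ([extract_peaks()]).
#' @return List with `peaks` (QC-annotated `peak_table`), `iv` (`iv_fit`),
#'   `gv` (`gv_fit`), `v_max`, `qc_included`, `qc_reason`.
#' @export
analyze_iv <- function(rec, ljp = 0, start_ms = 2, smooth_ms = 0.2) {
  rec <- leak_subtract(rec)
  peaks <- extract_peaks(rec, start_ms = start_ms, smooth_ms = smooth_ms)
  if (ljp != 0) peaks$test_v <- correct_ljp(peaks$test_v, ljp)
  peaks <- qc_filter(peaks)
  iv <- fit_iv(peaks)
  gv_fit_res <- if (isTRUE(iv$converged)) {
    fit_gv(gv_transform(peaks, v_rev = iv$v_rev, g_max = iv$g_max))
  } else {
    structure(list(v_half = NA_real_, slope = NA_real_, g_max = NA_real_,
                   residual_sse = NA_real_, converged = FALSE),
              class = "gv_fit")
  }
  list(peaks = peaks, iv = iv, gv = gv_fit_res,
       v_max = attr(peaks, "v_max"),
       qc_included = attr(peaks, "qc_included"),
       qc_reason = attr(peaks, "qc_reason"))
}

#' Analyze a steady-state inactivation recording
#'
#' @param rec An SSI `vc_recording`.
#' @param ljp As in [analyze_iv()].
#' @return List with `ratios` (conditioning-voltage/ratio table) and `fit`
#'   (`ssi_fit`).
#' @export
analyze_ssi <- function(rec, ljp = 0) {
  rec <- leak_subtract(rec)
  ratios <- ssi_ratios(rec)
  if (ljp != 0) ratios$cond_v <- correct_ljp(ratios$cond_v, ljp)
  list(ratios = ratios, fit = fit_ssi(ratios))
}

#' Analyze a 5-s inactivation time-course recording
#'
#' @param rec An INACT5S `vc_recording`.
#' @return A `kinetics_result` (see [inactivation_kinetics()]).
#' @export
analyze_kinetics <- function(rec) {
  inactivation_kinetics(leak_subtract(rec))
}

#' Analyze a set of recordings into a per-cell results table
#'
#' Groups recordings by cell, analyzes each protocol present (IV, SSI,
#' INACT5S) and emits one row per cell with all fitted parameters, the QC
#' outcome and convergence flags. This is the table that cohort summaries
#' and statistics consume.
#'
#' @param recordings List of `vc_recording` objects (e.g. from
#'   [simulate_cohort()] or [read_recording()]).
#' @param ljp As in [analyze_iv()].
#' @return data.frame with one row per cell: `construct`, `cell_id`,
#'   `qc_included`, `qc_reason`, `converged`, `peak_pa`, `norm_pa_pf`,
#'   `v_max`, `v_half_act`, `slope_act`, `v_rev`, `g_max`, `v_half_inact`,
#'   `slope_inact`, `plateau_pct`, `ssi_converged`, `r50` ... `r5000`.
#' @export
analyze_cohort <- function(recordings, ljp = 0) {
  stopifnot(is.list(recordings), length(recordings) >= 1)
  if (inherits(recordings, "vc_recording")) recordings <- list(recordings)
  cells <- split(recordings,
                 vapply(recordings, function(r) r$cell_id, character(1)))
  rows <- lapply(cells, function(recs) {
    kinds <- vapply(recs, function(r) r$protocol$kind, character(1))
    row <- data.frame(
      construct = recs[[1]]$construct, cell_id = recs[[1]]$cell_id,
      qc_included = NA, qc_reason = NA_character_, converged = NA,
      peak_pa = NA_real_, norm_pa_pf = NA_real_, v_max = NA_real_,
      v_half_act = NA_real_, slope_act = NA_real_, v_rev = NA_real_,
      g_max = NA_real_, v_half_inact = NA_real_, slope_inact = NA_real_,
      plateau_pct = NA_real_, ssi_converged = NA,
      r50 = NA_real_, r100 = NA_real_, r250 = NA_real_, r500 = NA_real_,
      r1000 = NA_real_, r5000 = NA_real_,
      stringsAsFactors = FALSE
    )
    if (any(kinds == "IV")) {
      res <- analyze_iv(recs[[which(kinds == "IV")[1]]], ljp = ljp)
      k <- which.min(res$peaks$peak_pa)
      row$qc_included <- res$qc_included
      row$qc_reason <- res$qc_reason
      row$converged <- res$iv$converged && res$gv$converged
      row$peak_pa <- res$peaks$peak_pa[k]
      row$norm_pa_pf <- res$peaks$norm_pa_pf[k]
      row$v_max <- res$v_max
      row$v_half_act <- res$gv$v_half
      row$slope_act <- res$gv$slope
      row$v_rev <- res$iv$v_rev
      row$g_max <- res$iv$g_max  # pA/mV = nS
    }
    if (any(kinds == "SSI")) {
      res <- analyze_ssi(recs[[which(kinds == "SSI")[1]]], ljp = ljp)
      row$v_half_inact <- res$fit$v_half
      row$slope_inact <- res$fit$slope
      row$plateau_pct <- 100 * res$fit$plateau
      row$ssi_converged <- res$fit$converged
    }
    if (any(kinds == "INACT5S")) {
      kin <- analyze_kinetics(recs[[which(kinds == "INACT5S")[1]]])
      row[paste0("r", c(50, 100, 250, 500, 1000, 5000))] <- as.list(kin$r)
      if (is.na(row$v_max)) row$v_max <- kin$v_max_used
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
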