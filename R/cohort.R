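# Synthetic cohorts: virtual cells drawn around construct-level mean gating
# parameters, run through the standard voltage protocols.

#' Reference gating parameters for Cav1.3 splice variants
#'
#' Literature-derived whole-cell gating parameters (mean, SEM, n) for a panel
#' of Cav1.3 alpha1-subunit splice variants and point mutants, as obtained
#' from Boltzmann fits of normalized activation (G-V) and steady-state
#' inactivation curves in HEK-293 cells with 15 mM Ca2+ as charge carrier.
#' These rows serve as simulator ground truth via [reference_cohort_spec()].
#'
#' Voltages are liquid-junction-potential corrected (mV); `plateau_pct` is
#' the non-inactivating fraction in percent.
#'
#' @return A data.frame, one row per construct.
#' @seealso [reference_kinetics()], [reference_cohort_spec()]
#' @export
reference_gating <- function() {
  tab <- read.csv(text = "
construct,v_half_act,sem_v_half_act,slope_act,sem_slope_act,v_rev,sem_v_rev,n_act,v_half_inact,sem_v_half_inact,slope_inact,sem_slope_inact,plateau_pct,sem_plateau_pct,n_inact
8b-43S,-10.21,0.62,8.51,0.17,65.70,0.88,25,-35.71,0.83,5.52,0.20,17.84,1.98,22
8b-11-43S,-13.40,0.63,7.60,0.15,64.75,0.72,29,-39.94,0.97,4.94,0.19,10.82,0.78,21
8b-32-43S,-13.58,0.55,8.36,0.15,63.21,0.84,16,-41.53,1.08,5.21,0.25,13.74,2.23,12
8b-11-32-43S,-12.79,0.58,8.33,0.12,65.23,0.91,19,-39.54,1.00,4.90,0.16,10.80,1.19,17
8a-43S,-10.99,0.63,8.28,0.16,65.67,0.92,24,-34.79,0.90,4.67,0.19,10.65,0.87,15
8a-11-43S,-13.21,0.63,7.60,0.14,63.75,0.91,19,-37.99,1.31,4.43,0.18,14.23,2.43,10
8a-32-43S,-13.03,0.47,7.97,0.13,63.80,0.64,16,-38.82,0.92,5.04,0.19,12.04,1.28,13
8a-11-32-43S,-12.65,0.76,8.23,0.16,64.58,0.81,17,-37.15,1.36,4.91,0.10,15.36,2.14,13
S652L-8b-11-43S,-25.50,0.74,7.61,0.14,58.26,0.71,18,-58.92,0.77,4.93,0.24,7.57,1.37,13
8a-42,0.45,0.90,9.51,0.15,66.56,0.86,44,-17.35,0.76,6.02,0.18,19.56,1.25,33
8a-11-42,-1.31,0.88,9.32,0.20,63.75,0.97,25,-17.63,0.81,6.01,0.30,15.94,1.76,17
R498L-8a-11-42,0.04,1.03,9.28,0.11,66.14,1.04,30,-16.48,0.88,6.03,0.37,17.79,1.62,23
", stringsAsFactors = FALSE)
  tab
}

#' Reference inactivation time-course r-values
#'
#' Literature-derived fractions of remaining Ca2+ current (percent of peak,
#' mean, SEM, n) after 50, 100, 250, 500, 1000 and 5000 ms of a 5-s
#' depolarization to the voltage of maximal inward current, for the
#' C-terminally long Cav1.3 constructs.
#'
#' @return A data.frame, one row per construct.
#' @export
reference_kinetics <- function() {
  read.csv(text = "
construct,r50,sem_r50,r100,sem_r100,r250,sem_r250,r500,sem_r500,r1000,sem_r1000,r5000,sem_r5000,n
8a-42,69.41,2.54,57.47,2.65,39.14,2.35,26.48,1.94,17.72,1.56,8.05,0.94,28
8a-11-42,72.97,3.29,61.20,3.12,40.67,2.69,25.87,2.13,15.61,1.80,6.47,1.25,13
R498L-8a-11-42,70.66,2.88,60.22,3.00,42.17,2.93,27.64,2.46,16.67,1.72,6.90,0.84,22
", stringsAsFactors = FALSE)
}

#' Convert a printed SEM to a between-cell SD
#'
#' Cohort tables report mean +/- SEM over n cells; the between-cell standard
#' deviation implied by such a row is `SEM * sqrt(n)`.
#'
#' @param sem Standard error of the mean.
#' @param n Number of cells.
#' @return The implied SD.
#' @export
sem_to_sd <- function(sem, n) {
  stopifnot(all(sem >= 0), all(n >= 1))
  sem * sqrt(n)
}

#' Between-cell variability settings
#'
#' Per-parameter spreads used when drawing virtual cells: absolute SDs (mV)
#' for voltage-type parameters, an absolute SD for the plateau fraction, a
#' multiplicative log-normal sigma for the maximal conductance, and an SD
#' (pF) for membrane capacitance.
#'
#' @param v_half_act,slope_act,v_rev,v_half_inact,slope_inact SDs in mV.
#' @param plateau SD of the non-inactivating fraction (0-1 scale).
#' @param g_max_sigma Log-normal sigma of `g_max` (multiplicative).
#' @param c_m_sd SD of membrane capacitance (pF); `c_m` is truncated > 5 pF.
#' @return A named list.
#' @export
cell_sd <- function(v_half_act = 0, slope_act = 0, v_rev = 0,
                    v_half_inact = 0, slope_inact = 0, plateau = 0,
                    g_max_sigma = 0, c_m_sd = 0) {
  out <- list(v_half_act = v_half_act, slope_act = slope_act, v_rev = v_rev,
              v_half_inact = v_half_inact, slope_inact = slope_inact,
              plateau = plateau, g_max_sigma = g_max_sigma, c_m_sd = c_m_sd)
  stopifnot(all(vapply(out, function(x) is.numeric(x) && length(x) == 1L &&
                         is.finite(x) && x >= 0, logical(1))))
  out
}

#' Specify a synthetic cohort
#'
#' @param construct_label Construct name attached to every recording.
#' @param n_cells Number of virtual cells (>= 1).
#' @param mean_params Cohort-mean [channel_params()].
#' @param sd Between-cell variability ([cell_sd()]).
#' @param seed Integer seed; every draw and noise stream of the cohort is
#'   derived from it.
#' @param qc_outlier_frac Fraction of cells whose maximal conductance is
#'   deliberately scaled out of the 100-1000 pA quality-control window (to
#'   exercise QC); 0 by default.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(construct_label, n_cells, mean_params,
                        sd = cell_sd(), seed = 1L, qc_outlier_frac = 0) {
  stopifnot(is.character(construct_label), length(construct_label) == 1L,
            is.numeric(n_cells), n_cells >= 1,
            inherits(mean_params, "channel_params"),
            is.numeric(seed), length(seed) == 1L,
            qc_outlier_frac >= 0, qc_outlier_frac <= 1)
  if (!all(names(cell_sd()) %in% names(sd))) {
    stop("`sd` must be a cell_sd() list")
  }
  structure(
    list(construct_label = construct_label, n_cells = as.integer(n_cells),
         mean_params = mean_params, sd = sd, seed = as.integer(seed),
         qc_outlier_frac = qc_outlier_frac),
    class = "cohort_spec"
  )
}

#' Cohort specification from the reference construct table
#'
#' Builds a [cohort_spec()] whose ground-truth means are a row of
#' [reference_gating()] and whose between-cell SDs follow the
#' `SD = SEM * sqrt(n)` convention applied to the same row (activation
#' parameters use the activation n, inactivation parameters the
#' inactivation n).
#'
#' @param construct A construct name present in [reference_gating()].
#' @param n_cells Cohort size; defaults to the row's activation n.
#' @param seed Cohort seed.
#' @param g_max Mean maximal conductance (nS). The default of 8 nS yields
#'   peak currents around -400 pA, the middle of the 100-1000 pA QC window.
#' @param noise_sd Recording noise SD (pA).
#' @param g_leak Seal leak conductance (nS).
#' @param g_max_sigma,c_m_sd Amplitude/capacitance variability
#'   (see [cell_sd()]).
#' @param tau_fast,tau_slow,frac_fast Inactivation kinetics shared by all
#'   cells (the gating table does not constrain them).
#' @param qc_outlier_frac See [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
reference_cohort_spec <- function(construct, n_cells = NULL, seed = 1L,
                                  g_max = 8, noise_sd = 5, g_leak = 1,
                                  g_max_sigma = 0.25, c_m_sd = 4,
                                  tau_fast = 80, tau_slow = 1000,
                                  frac_fast = 0.55, qc_outlier_frac = 0) {
  tab <- reference_gating()
  row <- tab[tab$construct == construct, ]
  if (nrow(row) != 1L) {
    stop("unknown construct: ", construct, "; see reference_gating()")
  }
  if (is.null(n_cells)) n_cells <- row$n_act
  mean_params <- channel_params(
    act = activation_params(v_half = row$v_half_act, slope = row$slope_act,
                            g_max = g_max, v_rev = row$v_rev),
    inact = inactivation_params(v_half = row$v_half_inact,
                                slope = row$slope_inact,
                                plateau = row$plateau_pct / 100,
                                tau_fast = tau_fast, tau_slow = tau_slow,
                                frac_fast = frac_fast),
    passive = passive_params(g_leak = g_leak, noise_sd = noise_sd)
  )
  sd <- cell_sd(
    v_half_act = sem_to_sd(row$sem_v_half_act, row$n_act),
    slope_act = sem_to_sd(row$sem_slope_act, row$n_act),
    v_rev = sem_to_sd(row$sem_v_rev, row$n_act),
    v_half_inact = sem_to_sd(row$sem_v_half_inact, row$n_inact),
    slope_inact = sem_to_sd(row$sem_slope_inact, row$n_inact),
    plateau = sem_to_sd(row$sem_plateau_pct, row$n_inact) / 100,
    g_max_sigma = g_max_sigma, c_m_sd = c_m_sd
  )
  cohort_spec(construct, n_cells, mean_params, sd = sd, seed = seed,
              qc_outlier_frac = qc_outlier_frac)
}

#' Draw one virtual cell's parameters
#'
#' Voltage-type parameters are drawn from normal distributions around the
#' cohort means; slope factors are truncated at 0.5 mV, the plateau fraction
#' is clipped to `[0, 1]`; `g_max` is log-normal (`mean * exp(sigma * Z)`);
#' `c_m` is normal around the cohort mean `c_m`, truncated at 5 pF. Draws
#' are reproducible from `(spec$seed, cell_index)` and leave the caller's
#' RNG state untouched.
#'
#' @param spec A [cohort_spec()].
#' @param cell_index Cell number in `1:n_cells`.
#' @return A [channel_params()] object.
#' @export
draw_cell_params <- function(spec, cell_index) {
  stopifnot(inherits(spec, "cohort_spec"),
            cell_index >= 1, cell_index <= spec$n_cells)
  cell_seed <- derive_seeds(spec$seed, spec$n_cells)[cell_index]
  mp <- spec$mean_params
  sd <- spec$sd
  with_local_seed(cell_seed, {
    v_half_act <- rnorm(1, mp$act$v_half, sd$v_half_act)
    slope_act <- max(0.5, rnorm(1, mp$act$slope, sd$slope_act))
    v_rev <- rnorm(1, mp$act$v_rev, sd$v_rev)
    v_half_inact <- rnorm(1, mp$inact$v_half, sd$v_half_inact)
    slope_inact <- max(0.5, rnorm(1, mp$inact$slope, sd$slope_inact))
    plateau <- min(1, max(0, rnorm(1, mp$inact$plateau, sd$plateau)))
    g_max <- mp$act$g_max * exp(sd$g_max_sigma * rnorm(1))
    c_m <- max(5, rnorm(1, mp$passive$c_m, sd$c_m_sd))
    if (spec$qc_outlier_frac > 0 &&
        cell_index <= floor(spec$qc_outlier_frac * spec$n_cells)) {
      # push alternate outlier cells well below/above the QC window
      g_max <- g_max * if (cell_index %% 2 == 1) 0.1 else 8
    }
    channel_params(
      act = activation_params(v_half_act, slope_act, g_max, v_rev,
                              tau_act = mp$act$tau_act),
      inact = inactivation_params(v_half_inact, slope_inact, plateau,
                                  tau_fast = mp$inact$tau_fast,
                                  tau_slow = mp$inact$tau_slow,
                                  frac_fast = mp$inact$frac_fast),
      passive = passive_params(g_leak = mp$passive$g_leak,
                               e_leak = mp$passive$e_leak, c_m = c_m,
                               tau_cap = mp$passive$tau_cap,
                               noise_sd = mp$passive$noise_sd)
    )
  })
}

# Internal recording constructor
new_recording <- function(sweeps, dt, c_m, protocol, cell_id, construct,
                          seed, leak_method = "none", params = NULL) {
  structure(
    list(sweeps = sweeps, dt = dt, c_m = c_m, protocol = protocol,
         cell_id = cell_id, construct = construct, seed = seed,
         leak_method = leak_method, leak_subtracted = FALSE,
         true_params = params),
    class = "vc_recording"
  )
}

#' @export
print.vc_recording <- function(x, ...) {
  cat(sprintf("<vc_recording> %s / %s: %s protocol, %d sweeps, dt %.3g ms, Cm %.1f pF\n",
              x$construct, x$cell_id, x$protocol$kind, length(x$sweeps),
              x$dt, x$c_m))
  invisible(x)
}

#' Simulate one recording (one cell, one protocol)
#'
#' Expands the protocol into sweeps, runs the forward model for each, and
#' attaches the auxiliary sweeps the requested leak-subtraction method
#' needs: a -80 to -90 mV reference step (`"offline"`) or four
#' quarter-amplitude P/4 subsweeps per main sweep (`"p4"`).
#'
#' @param params Cell [channel_params()].
#' @param protocol [voltage_protocol()].
#' @param leak `"offline"`, `"p4"` or `"none"`.
#' @param v_max Test potential of maximal inward current; required for SSI
#'   and INACT5S protocols (located from the cell's own I-V family by
#'   [simulate_cohort()]).
#' @param cell_id,construct Metadata labels.
#' @param seed Integer seed for the recording's noise streams.
#' @return A `vc_recording`.
#' @export
simulate_recording <- function(params, protocol,
                               leak = c("offline", "p4", "none"),
                               v_max = NULL, cell_id = "cell-1",
                               construct = "construct", seed = NULL) {
  leak <- match.arg(leak)
  if (leak == "p4" && protocol$kind != "IV") {
    # P/4 subsweeps are generated for the short-pulse IV protocol; the long
    # SSI/INACT5S protocols use the reference-step method.
    leak <- "offline"
  }
  plan <- protocol_sweep_plan(protocol, v_max = v_max)
  dt <- protocol$dt
  sim <- function() {
    sweeps <- lapply(plan, function(sw) {
      sw$current <- as.numeric(simulate_sweep(sw$segments, params, dt))
      if (leak == "p4") {
        sub <- p4_sub_plan(protocol, sw$test_v)
        sw$p4_segments <- sub$segments
        sw$p4_currents <- lapply(1:4, function(i) {
          as.numeric(simulate_sweep(sub$segments, params, dt))
        })
      }
      sw
    })
    if (leak == "offline") {
      ref <- leakref_sweep_plan(dt)
      ref$current <- as.numeric(simulate_sweep(ref$segments, params, dt))
      sweeps <- c(sweeps, list(ref))
    }
    sweeps
  }
  sweeps <- if (is.null(seed)) sim() else with_local_seed(seed, sim())
  new_recording(sweeps, dt, params$passive$c_m, protocol, cell_id,
                construct, seed, leak_method = leak, params = params)
}

#' Simulate a cohort of virtual cells
#'
#' Draws `n_cells` parameter sets from the cohort spec and records each cell
#' under every requested protocol. The voltage of maximal inward current
#' (`v_max`) used by SSI and INACT5S protocols is located per cell from that
#' cell's simulated I-V family (an I-V recording is simulated for this
#' purpose even when not requested). Fixed `(spec, protocols)` and seed give
#' a byte-identical recording set.
#'
#' @param spec A [cohort_spec()].
#' @param protocols List of [voltage_protocol()] objects (e.g. a subset of
#'   [default_protocols()]).
#' @param leak Leak-subtraction method the recordings should support.
#' @return List of `vc_recording` objects, one per (cell, protocol).
#' @export
simulate_cohort <- function(spec, protocols,
                            leak = c("offline", "p4", "none")) {
  leak <- match.arg(leak)
  stopifnot(inherits(spec, "cohort_spec"), is.list(protocols),
            length(protocols) >= 1)
  if (inherits(protocols, "voltage_protocol")) protocols <- list(protocols)
  kinds <- vapply(protocols, function(p) p$kind, character(1))
  streams <- derive_seeds(spec$seed, 2L)
  n <- spec$n_cells
  n_prot <- length(protocols)
  noise_seeds <- matrix(derive_seeds(streams[2], n * (n_prot + 1L)),
                        nrow = n)
  needs_vmax <- any(kinds != "IV")
  iv_proto <- if (any(kinds == "IV")) {
    protocols[[which(kinds == "IV")[1]]]
  } else {
    default_protocols(dt = protocols[[1]]$dt)$iv
  }

  out <- list()
  for (i in seq_len(n)) {
    params <- draw_cell_params(spec, i)
    cell_id <- sprintf("%s-c%02d", spec$construct_label, i)
    iv_rec <- simulate_recording(params, iv_proto, leak = leak,
                                 cell_id = cell_id,
                                 construct = spec$construct_label,
                                 seed = noise_seeds[i, 1L])
    v_max <- if (needs_vmax) locate_v_max(iv_rec) else NULL
    for (j in seq_len(n_prot)) {
      rec <- if (kinds[j] == "IV") {
        iv_rec
      } else {
        simulate_recording(params, protocols[[j]], leak = leak,
                           v_max = v_max, cell_id = cell_id,
                           construct = spec$construct_label,
                           seed = noise_seeds[i, j + 1L])
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Locate the voltage of maximal inward current
#'
#' Leak-subtracts an I-V recording and returns the test potential whose
#' sweep carries the largest (most negative) peak inward current.
#'
#' @param iv_rec An I-V `vc_recording`.
#' @return Voltage (mV).
#' @export
locate_v_max <- function(iv_rec) {
  stopifnot(inherits(iv_rec, "vc_recording"), iv_rec$protocol$kind == "IV")
  peaks <- extract_peaks(leak_subtract(iv_rec))
  peaks$test_v[which.min(peaks$peak_pa)]
}

#' Cohort specification from the reference kinetics table
#'
#' Builds a cohort whose inactivation kinetics reproduce a tabulated
#' r-value row: the six remaining-current fractions are fit with a
#' bi-exponential-plus-plateau decay ([fit_rvalue_kinetics()]) and the
#' resulting kinetics are shared by all cells. Activation parameters (and
#' their between-cell spread) come from the same construct's
#' [reference_gating()] row so that the voltage of maximal inward current is
#' realistic. The inactivation midpoint is placed far below the test
#' potential so the decay target during the 5-s pulse equals the fitted
#' plateau; the r-value time course and the steady-state inactivation curve
#' of a construct are separate measurements and are not jointly
#' representable in this voltage-independent-tau model (see the package
#' vignette).
#'
#' @param construct A construct present in [reference_kinetics()].
#' @param n_cells Cohort size; defaults to the kinetics row's n.
#' @param seed Cohort seed.
#' @param g_max,noise_sd,g_leak,g_max_sigma,c_m_sd As in
#'   [reference_cohort_spec()].
#' @return A `cohort_spec`.
#' @export
reference_kinetics_spec <- function(construct, n_cells = NULL, seed = 1L,
                                    g_max = 8, noise_sd = 5, g_leak = 1,
                                    g_max_sigma = 0.25, c_m_sd = 4) {
  kin_tab <- reference_kinetics()
  rowk <- kin_tab[kin_tab$construct == construct, ]
  if (nrow(rowk) != 1L) {
    stop("unknown construct: ", construct, "; see reference_kinetics()")
  }
  gat_tab <- reference_gating()
  rowg <- gat_tab[gat_tab$construct == construct, ]
  times <- c(50, 100, 250, 500, 1000, 5000)
  fit <- fit_rvalue_kinetics(times, as.numeric(rowk[paste0("r", times)]))
  if (!fit$converged) stop("r-value kinetics fit did not converge")
  if (is.null(n_cells)) n_cells <- rowk$n
  mean_params <- channel_params(
    act = activation_params(v_half = rowg$v_half_act, slope = rowg$slope_act,
                            g_max = g_max, v_rev = rowg$v_rev),
    inact = inactivation_params(v_half = -40, slope = 5,
                                plateau = fit$plateau,
                                tau_fast = fit$tau_fast,
                                tau_slow = fit$tau_slow,
                                frac_fast = fit$frac_fast),
    passive = passive_params(g_leak = g_leak, noise_sd = noise_sd)
  )
  sd <- cell_sd(
    v_half_act = sem_to_sd(rowg$sem_v_half_act, rowg$n_act),
    slope_act = sem_to_sd(rowg$sem_slope_act, rowg$n_act),
    v_rev = sem_to_sd(rowg$sem_v_rev, rowg$n_act),
    g_max_sigma = g_max_sigma, c_m_sd = c_m_sd
  )
  cohort_spec(construct, n_cells, mean_params, sd = sd, seed = seed)
}
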