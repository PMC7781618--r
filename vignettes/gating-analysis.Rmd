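---
title: "Voltage-clamp gating analysis for Cav1.3-type calcium channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-clamp gating analysis for Cav1.3-type calcium channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavgating)
```

## Scope

`cavgating` implements the quantitative workflow used to characterize the
voltage-dependent gating of L-type Ca$^{2+}$ channels (Cav1.3 splice
variants and point mutants) in whole-cell patch-clamp recordings, together
with a forward simulator of such recordings. The package covers:

* a deterministic conductance model that turns a command-voltage waveform
  into a whole-cell current trace;
* a synthetic-cohort generator with between-cell parameter variability;
* trace preprocessing: liquid-junction-potential (LJP) correction, offline
  and P/4 leak subtraction, peak extraction, pA/pF normalization, and
  amplitude-based quality control;
* parameter estimation: the I–V fit, the conductance–voltage (G–V)
  Boltzmann activation fit, the steady-state inactivation (SSI) fit with a
  non-inactivating plateau, and r-value inactivation kinetics;
* cohort statistics: mean ± SEM summaries, unpaired Student's t-tests,
  one-way ANOVA with Bonferroni post-hoc comparisons, and
  publication-style tables.

## The biophysical model

The channel is modelled as a single Hodgkin–Huxley-type conductance with an
ohmic driving force,

$$I_\mathrm{chan}(t) = G_\mathrm{max}\, m(t)\, h(t)\,
  \bigl(V(t) - V_\mathrm{rev}\bigr),$$

where $m$ is activation and $h$ availability. Their steady states are
Boltzmann functions of voltage,

$$m_\infty(V) = \frac{1}{1 + e^{-(V - V_{0.5})/k}}, \qquad
  h_\infty(V) = \frac{1 - p}{1 + e^{(V - V_{0.5,\mathrm{inact}})/k_\mathrm{inact}}} + p,$$

with $p$ the non-inactivating fraction (reported as a percentage in
summary tables). Within each constant-voltage segment $m$ relaxes
mono-exponentially towards $m_\infty$ with time constant $\tau_\mathrm{act}$
and $h$ as the weighted sum of two exponential pools
($\tau_\mathrm{fast}$, $\tau_\mathrm{slow}$, weight `frac_fast`), so traces
have closed-form segment-wise solutions and simulation is exact up to the
sampling grid. The measured current adds an ohmic seal leak
$g_\mathrm{leak}(V - E_\mathrm{leak})$, a capacitive transient
$C_m \Delta V/\tau_\mathrm{cap}\, e^{-t/\tau_\mathrm{cap}}$ at every step
edge, and white Gaussian noise.

The ohmic driving force is a deliberate choice, not an oversight: the
estimators fit the same functional form
($I = G_\mathrm{max}(V-V_\mathrm{rev})/(1+e^{-(V-V_{0.5})/k})$), so the
simulator and the analysis chain are self-consistent, and closed-form
oracles exist for every stage. Goldman–Hodgkin–Katz permeation,
Ca$^{2+}$-dependent inactivation, stochastic single-channel gating and
series-resistance errors are out of scope.

## Protocols and units

All voltages inside the package are true membrane potentials, i.e. already
LJP-corrected; `correct_ljp()` (default −9.3 mV) is applied once when
importing nominal command voltages, never twice. The standard protocol
triple (`default_protocols()`) is:

* **IV** — 20-ms (optionally 50-ms) square pulses from a holding potential
  of −89 mV to −89…+71 mV in 5-mV increments;
* **SSI** — 20-ms control pulse to the voltage of maximal inward current
  ($V_\mathrm{max}$), a 5-s conditioning step to −119…+1 mV in 10-mV
  increments, then a 20-ms test pulse back to $V_\mathrm{max}$ (30-s
  intersweep interval, holding −89 mV);
* **INACT5S** — a single 5-s depolarization to $V_\mathrm{max}$.

Currents are in pA, conductances in nS, capacitance in pF, time in ms. The
default sampling interval is 0.05 ms (20 kHz). $V_\mathrm{max}$ is located
per cell from that cell's own I–V family.

## Tunable parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| `tau_act` | 0.5 ms | fast relative to the 20-ms pulse; activation is ~quasi-steady at the peak |
| `tau_fast`, `tau_slow`, `frac_fast` | 80 ms, 1000 ms, 0.55 | L-type-like decay; 5-s conditioning settles to within 1% of $h_\infty$ |
| `tau_cap` | 0.2 ms | typical compensated whole-cell charging time |
| `noise_sd` | 5 pA | realistic post-filter baseline noise |
| `g_leak` | 1 nS | a decent seal |
| `c_m` | 20 pF (SD 4, truncated > 5) | typical HEK-293 cell |
| `g_max` | 8 nS | mean peak currents ≈ −400 pA, the middle of the QC window |
| peak window start | 2 ms after the edge | see below |
| peak smoother | ±0.2 ms moving average | locates the peak without altering stored traces |
| QC window | 100–1000 pA at $V_\mathrm{max}$ | prospective exclusion of too-small/too-large currents |
| G–V exclusion band | ±5 mV around $V_\mathrm{rev}$ | avoids 0/0 amplification in $G = I/(V-V_\mathrm{rev})$ |
| slope bounds | 0.5–30 mV | fits pinned at a bound are flagged non-converged |

## The synthetic cohorts

`reference_gating()` and `reference_kinetics()` tabulate literature-derived
construct-level gating parameters (mean, SEM, n) for a panel of Cav1.3
splice variants. `reference_cohort_spec()` turns a row into a cohort
specification: per-cell parameters are drawn normally around the row means
with between-cell SD equal to $\mathrm{SEM}\sqrt{n}$ — the dispersion the
printed SEMs imply. Slope factors are truncated at 0.5 mV, the plateau
fraction is clipped to $[0,1]$, the maximal conductance is log-normal
(`sigma` 0.25), and capacitance is normal(20 pF, 4 pF) truncated above
5 pF. Every random draw and noise stream derives from the cohort seed, so a
cohort is byte-reproducible.

`reference_kinetics_spec()` builds cohorts for the 5-s inactivation time
course: the six tabulated r-values are fit with a
bi-exponential-plus-plateau decay and all cells share those kinetics. The
inactivation midpoint of such a cohort is placed far below
$V_\mathrm{max}$ so the decay target equals the fitted plateau. This is
deliberate: with voltage-independent time constants a single parameter set
cannot simultaneously reproduce a construct's SSI plateau (~20%) and its
5-s r-value floor (~8%) — in real cells the difference comes from
Ca$^{2+}$-dependent inactivation, which is out of scope. The r-value
cohorts therefore reproduce the kinetics table, and the SSI cohorts the
gating table; neither claims to model both measurements at once.

## Numerical choices

* **Peak definition.** The peak is the largest-magnitude smoothed sample
  (signed; inward Ca$^{2+}$ currents are negative) inside the pulse, ties
  broken by the earliest sample. Using the most-negative sample instead
  would systematically underestimate the outward limb above
  $V_\mathrm{rev}$ (activation is still rising at the window start) and
  bias $V_\mathrm{rev}$ and $V_{0.5}$ even without noise.
* **Peak window.** The search starts 2 ms after the step edge — ten
  capacitive time constants, leaving < 1 pA of transient on the largest
  steps — and ends half a smoothing window before the next edge so the
  smoother cannot smear the off-edge transient in.
* **Fit initialization.** All fits use deterministic data-driven starts
  (e.g. $V_\mathrm{rev}$ from the interpolated zero crossing of the
  positive limb, $V_{0.5}$ from the half-maximal inward current), so
  identical data give identical estimates; Levenberg–Marquardt with box
  bounds does the optimization.
* **Degenerate inputs.** SSI inputs with essentially no inactivation
  (ratio range < 0.05) are flagged non-converged rather than fit; r-value
  extraction refuses traces whose peak is below five baseline noise SDs.
* **P/4 correction.** Because main and subsweeps share the holding level,
  `main − Σ subsweeps` overestimates the leak by a constant equal to three
  times the holding-level leak current; that constant is estimated on the
  pre-step baseline and restored, making the correction exact for linear
  membranes and referencing corrected traces to zero. The offline method
  estimates $g_\mathrm{leak}$ and $E_\mathrm{leak}$ from the −80/−90-mV
  reference step; it leaves the (peak-window-excluded) capacitive
  transients in place and picks up the sub-pA channel current present at
  −80 mV, a ≲0.05 mV effect on fitted midpoints.

## What the simulations do and do not show

Because the generator and the estimators share the same current model, the
recovery tests demonstrate that the analysis chain is unbiased and
correctly implemented *given* that model — they cannot validate the model
against real cells. Features of real recordings that are deliberately not
emulated: Ca$^{2+}$-dependent inactivation, GHK rectification of the open-
channel current, rundown over the 30-s intersweep intervals, seal
degradation, series-resistance voltage errors, and 1/f or line noise.
Under the default 5 pA noise the extreme-value nature of peak picking
inflates peak magnitudes slightly and shifts recovered cohort-mean
$V_{0.5}$ by about +0.3 mV — half a typical cohort SEM; real
peak-cursor measurements share this property. The r-value pipeline reads
decay relative to the measured (slightly post-onset, slightly decayed)
peak, as cursor-based analysis does, which raises r-values ~1–2% above the
underlying decay curve.

## Cohort sizes used in the tests

The bundled tests recover each tabulated cohort with its published n
(25/18/44 activation cells, 28 kinetics cells, 21 + 13 SSI cells), ten
seeded replicates for the single-cohort targets and three replicate pairs
for the mutant-minus-wildtype gating shifts; smaller 2–6-cell cohorts are
used where only plumbing is exercised. These sizes make the whole suite a
few minutes of CPU while keeping cohort-mean sampling error at the level
the published SEMs imply.

## A worked example

```{r, eval = FALSE}
library(cavgating)

## a 12-cell cohort of the exon-11-containing short variant
spec <- reference_cohort_spec("8b-11-43S", n_cells = 12, seed = 42)
recs <- simulate_cohort(spec, default_protocols()[c("iv", "ssi")],
                        leak = "offline")
results <- analyze_cohort(recs)
summarize_groups(results)

## compare two constructs
spec_wt <- reference_cohort_spec("8b-11-43S", n_cells = 12, seed = 1)
spec_mut <- reference_cohort_spec("S652L-8b-11-43S", n_cells = 12, seed = 2)
recs <- c(simulate_cohort(spec_wt, default_protocols()["iv"]),
          simulate_cohort(spec_mut, default_protocols()["iv"]))
results <- analyze_cohort(recs)
cmp <- compare_constructs(results, "v_half_act", reference = "8b-11-43S")
render_group_table(summarize_groups(results), cmp)
```

## Known limitations

* The linear driving force overestimates outward currents above
  $V_\mathrm{rev}$ relative to GHK behaviour; fitted $V_\mathrm{rev}$ is
  an extrapolated, model-dependent quantity, as it is in the underlying
  fit equation.
* Inactivation kinetics are voltage-independent above threshold; only the
  six tabulated time points constrain them, so $\tau$ values are
  under-determined and should not be interpreted mechanistically.
* The SSI ratio uses peak (not mean) pulse currents; with 20-ms pulses and
  the default kinetics the distinction is ≪1%.
* ABF (binary amplifier) files are not parsed; the tab-separated text
  dialect written by `write_recording()` is the interchange format.
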