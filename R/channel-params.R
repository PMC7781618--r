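#' Activation gating parameters
#'
#' Parameter set describing voltage-dependent activation of an L-type
#' Ca2+ conductance with a linear (ohmic) driving force. The steady-state
#' open fraction follows a Boltzmann function of membrane potential,
#' \eqn{m_\infty(V) = 1/(1 + \exp(-(V - V_{0.5})/k))}, and activation relaxes
#' mono-exponentially towards it.
#'
#' @param v_half Half-maximal activation voltage \eqn{V_{0.5}} (mV).
#' @param slope Boltzmann slope factor \eqn{k} (mV, > 0); smaller values mean
#'   a steeper voltage dependence.
#' @param g_max Maximal conductance (nS, >= 0; zero gives a channel-free
#'   cell, useful for leak-subtraction checks).
#' @param v_rev Reversal potential of the channel current (mV).
#' @param tau_act Activation time constant (ms, > 0). Fast relative to the
#'   20-ms test pulses used for current-voltage families.
#' @return An object of class `activation_params`.
#' @seealso [steady_state_activation()], [channel_params()]
#' @export
activation_params <- function(v_half, slope, g_max, v_rev, tau_act = 0.5) {
  stopifnot(
    is.numeric(v_half), length(v_half) == 1L, is.finite(v_half),
    is.numeric(slope), length(slope) == 1L, is.finite(slope), slope > 0,
    is.numeric(g_max), length(g_max) == 1L, is.finite(g_max), g_max >= 0,
    is.numeric(v_rev), length(v_rev) == 1L, is.finite(v_rev),
    is.numeric(tau_act), length(tau_act) == 1L, tau_act > 0
  )
  structure(
    list(v_half = v_half, slope = slope, g_max = g_max,
         v_rev = v_rev, tau_act = tau_act),
    class = "activation_params"
  )
}

#' Inactivation gating parameters
#'
#' Voltage-dependent inactivation with a non-inactivating plateau: the
#' steady-state availability is
#' \eqn{h_\infty(V) = (1 - p)/(1 + \exp((V - V_{0.5,inact})/k_{inact})) + p},
#' where `plateau` (\eqn{p}) is the fraction of current that never
#' inactivates (tabulated as "non-inactivating \%" when multiplied by 100).
#' Availability relaxes bi-exponentially towards \eqn{h_\infty} with a fast
#' and a slow component.
#'
#' @param v_half Half-maximal inactivation voltage (mV).
#' @param slope Inactivation slope factor (mV, > 0).
#' @param plateau Non-inactivating fraction, in `[0, 1]`.
#' @param tau_fast,tau_slow Fast/slow inactivation time constants (ms, > 0,
#'   `tau_fast <= tau_slow`; `Inf` disables the component's relaxation).
#' @param frac_fast Weight of the fast component, in `[0, 1]`.
#' @return An object of class `inactivation_params`.
#' @seealso [steady_state_availability()]
#' @export
inactivation_params <- function(v_half, slope, plateau,
                                tau_fast = 80, tau_slow = 1000,
                                frac_fast = 0.55) {
  stopifnot(
    is.numeric(v_half), length(v_half) == 1L, is.finite(v_half),
    is.numeric(slope), length(slope) == 1L, is.finite(slope), slope > 0,
    is.numeric(plateau), length(plateau) == 1L, is.finite(plateau),
    is.numeric(tau_fast), length(tau_fast) == 1L, tau_fast > 0,
    is.numeric(tau_slow), length(tau_slow) == 1L, tau_slow > 0,
    is.numeric(frac_fast), length(frac_fast) == 1L,
    frac_fast >= 0, frac_fast <= 1
  )
  if (plateau < 0 || plateau > 1) {
    stop("`plateau` must lie in [0, 1], got ", plateau)
  }
  if (tau_fast > tau_slow) {
    stop("`tau_fast` must not exceed `tau_slow`")
  }
  structure(
    list(v_half = v_half, slope = slope, plateau = plateau,
         tau_fast = tau_fast, tau_slow = tau_slow, frac_fast = frac_fast),
    class = "inactivation_params"
  )
}

#' Passive membrane and recording parameters
#'
#' Linear (non-gated) properties of the simulated cell and patch: ohmic seal
#' leak, membrane capacitance, the time constant of the capacitive charging
#' transient at voltage-step edges, and the standard deviation of white
#' Gaussian recording noise.
#'
#' @param g_leak Leak conductance (nS, >= 0).
#' @param e_leak Leak reversal potential (mV).
#' @param c_m Cell membrane capacitance (pF, > 0); used both for the
#'   capacitive transient amplitude and for pA/pF current normalization.
#' @param tau_cap Capacitive transient decay time constant (ms, > 0).
#' @param noise_sd Recording noise SD (pA, >= 0).
#' @return An object of class `passive_params`.
#' @export
passive_params <- function(g_leak = 1, e_leak = 0, c_m = 20,
                           tau_cap = 0.2, noise_sd = 5) {
  stopifnot(
    is.numeric(g_leak), length(g_leak) == 1L, is.finite(g_leak), g_leak >= 0,
    is.numeric(e_leak), length(e_leak) == 1L, is.finite(e_leak),
    is.numeric(c_m), length(c_m) == 1L, is.finite(c_m), c_m > 0,
    is.numeric(tau_cap), length(tau_cap) == 1L, is.finite(tau_cap), tau_cap > 0,
    is.numeric(noise_sd), length(noise_sd) == 1L, is.finite(noise_sd),
    noise_sd >= 0
  )
  structure(
    list(g_leak = g_leak, e_leak = e_leak, c_m = c_m,
         tau_cap = tau_cap, noise_sd = noise_sd),
    class = "passive_params"
  )
}

#' Full channel/cell parameter set
#'
#' @param act [activation_params()].
#' @param inact [inactivation_params()].
#' @param passive [passive_params()].
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(act, inact, passive = passive_params()) {
  stopifnot(inherits(act, "activation_params"),
            inherits(inact, "inactivation_params"),
            inherits(passive, "passive_params"))
  structure(list(act = act, inact = inact, passive = passive),
            class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat("<channel_params>\n")
  cat(sprintf("  activation:   V0.5 %.2f mV, k %.2f mV, Gmax %.2f nS, Vrev %.2f mV, tau %.2f ms\n",
              x$act$v_half, x$act$slope, x$act$g_max, x$act$v_rev, x$act$tau_act))
  cat(sprintf("  inactivation: V0.5 %.2f mV, k %.2f mV, plateau %.3f, tau %.0f/%.0f ms (f %.2f)\n",
              x$inact$v_half, x$inact$slope, x$inact$plateau,
              x$inact$tau_fast, x$inact$tau_slow, x$inact$frac_fast))
  cat(sprintf("  passive:      g_leak %.2f nS (E %.1f mV), Cm %.1f pF, tau_cap %.2f ms, noise %.1f pA\n",
              x$passive$g_leak, x$passive$e_leak, x$passive$c_m,
              x$passive$tau_cap, x$passive$noise_sd))
  invisible(x)
}

#' Steady-state activation (Boltzmann)
#'
#' Normalized steady-state open fraction
#' \eqn{m_\infty(V) = 1/(1 + \exp(-(V - V_{0.5})/k))}; this is the curve a
#' conductance-voltage (G-V) fit estimates.
#'
#' @param v Membrane potential(s), mV. Must be finite.
#' @param act [activation_params()].
#' @return Fraction(s) in (0, 1), strictly increasing in `v`.
#' @examples
#' act <- activation_params(v_half = -10, slope = 8.5, g_max = 8, v_rev = 65)
#' steady_state_activation(-10, act)  # 0.5 at V0.5
#' @export
steady_state_activation <- function(v, act) {
  stopifnot(inherits(act, "activation_params"), is.numeric(v))
  if (any(!is.finite(v))) stop("`v` must be finite")
  1 / (1 + exp(-(v - act$v_half) / act$slope))
}

#' Steady-state availability (modified Boltzmann with plateau)
#'
#' Fraction of channels available after equilibration at potential `v`:
#' \eqn{h_\infty(V) = (1 - p)/(1 + \exp((V - V_{0.5,inact})/k_{inact})) + p}.
#' Tends to 1 at strongly hyperpolarized and to `plateau` at strongly
#' depolarized potentials.
#'
#' @param v Membrane potential(s), mV.
#' @param inact [inactivation_params()].
#' @return Fraction(s) in (0, 1].
#' @export
steady_state_availability <- function(v, inact) {
  stopifnot(inherits(inact, "inactivation_params"), is.numeric(v))
  if (any(!is.finite(v))) stop("`v` must be finite")
  p <- inact$plateau
  if (p < 0 || p > 1) stop("`plateau` must lie in [0, 1]")
  (1 - p) / (1 + exp((v - inact$v_half) / inact$slope)) + p
}
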