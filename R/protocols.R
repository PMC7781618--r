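# Voltage-clamp protocol descriptions and the sweep waveforms they expand to.
# All voltages are true membrane potentials (i.e. already corrected for the
# liquid junction potential); use correct_ljp() when importing nominal values.

#' Declare a voltage-clamp protocol
#'
#' @param kind One of `"IV"` (current-voltage family of short depolarizing
#'   steps), `"SSI"` (steady-state inactivation: control pulse, long
#'   conditioning step, test pulse) or `"INACT5S"` (a single 5-s
#'   depolarization used for inactivation time-course r-values).
#' @param holding_potential Holding potential between steps (mV).
#' @param step_increment Voltage increment between sweeps (mV, > 0).
#' @param step_duration Test/control pulse duration (ms).
#' @param voltage_range Length-2 numeric, `c(min, max)` of the stepped
#'   voltage (test voltages for IV, conditioning voltages for SSI).
#' @param conditioning_duration Conditioning step duration (ms; SSI only).
#' @param intersweep_interval Interval between sweeps (s); metadata only, the
#'   simulator assumes full recovery at the holding potential between sweeps.
#' @param dt Sampling interval (ms). 0.05 ms corresponds to 20 kHz.
#' @param pre_ms,post_ms Holding-potential padding simulated before/after the
#'   stepped part of each sweep (ms).
#' @param gap_ms SSI only: holding-potential gap between the control pulse
#'   and the conditioning step (ms).
#' @return An object of class `voltage_protocol`.
#' @seealso [default_protocols()]
#' @export
voltage_protocol <- function(kind = c("IV", "SSI", "INACT5S"),
                             holding_potential = -89,
                             step_increment = 5,
                             step_duration = 20,
                             voltage_range = c(-89, 71),
                             conditioning_duration = NA_real_,
                             intersweep_interval = 30,
                             dt = 0.05,
                             pre_ms = 10, post_ms = 10, gap_ms = 30) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(voltage_range), length(voltage_range) == 2L,
            voltage_range[1] < voltage_range[2],
            is.numeric(step_increment), step_increment > 0,
            is.numeric(step_duration), step_duration > 0,
            is.numeric(dt), dt > 0)
  if (kind == "SSI" && (is.na(conditioning_duration) ||
                        conditioning_duration <= 0)) {
    stop("SSI protocols require a positive `conditioning_duration`")
  }
  structure(
    list(kind = kind, holding_potential = holding_potential,
         step_increment = step_increment, step_duration = step_duration,
         voltage_range = voltage_range,
         conditioning_duration = conditioning_duration,
         intersweep_interval = intersweep_interval, dt = dt,
         pre_ms = pre_ms, post_ms = post_ms, gap_ms = gap_ms),
    class = "voltage_protocol"
  )
}

#' Standard protocol triple for Cav1.3 gating characterization
#'
#' The three protocols used throughout: an I-V family of 20-ms depolarizing
#' square pulses from a holding potential of -89 mV in 5-mV increments
#' (-89 to +71 mV); a steady-state inactivation protocol with 20-ms control
#' and test pulses to the voltage of maximal inward current separated by a
#' 5-s conditioning step (-119 to +1 mV, 10-mV increments, 30-s intersweep
#' interval); and a single 5-s depolarization to the voltage of maximal
#' inward current for the inactivation time course.
#'
#' @param iv_step_duration I-V pulse length, 20 or 50 ms.
#' @param dt Sampling interval (ms) applied to all three protocols.
#' @return Named list with elements `iv`, `ssi` and `inact5s`.
#' @export
default_protocols <- function(iv_step_duration = 20, dt = 0.05) {
  list(
    iv = voltage_protocol("IV", holding_potential = -89, step_increment = 5,
                          step_duration = iv_step_duration,
                          voltage_range = c(-89, 71), dt = dt),
    ssi = voltage_protocol("SSI", holding_potential = -89,
                           step_increment = 10, step_duration = 20,
                           voltage_range = c(-119, 1),
                           conditioning_duration = 5000,
                           intersweep_interval = 30, dt = dt),
    inact5s = voltage_protocol("INACT5S", holding_potential = -89,
                               step_increment = 5, step_duration = 5000,
                               voltage_range = c(-89, 71), dt = dt)
  )
}

# Stepped voltages of a protocol
protocol_step_voltages <- function(protocol) {
  seq(protocol$voltage_range[1], protocol$voltage_range[2],
      by = protocol$step_increment)
}

# Expand a protocol into the per-sweep segment tables the simulator consumes.
# For IV: one sweep per test voltage. For SSI: one sweep per conditioning
# voltage (control pulse / gap / conditioning / test pulse). For INACT5S: a
# single 5-s step to v_max. Returns a list of lists with fields
# `segments`, `role`, and the voltage being stepped.
protocol_sweep_plan <- function(protocol, v_max = NULL) {
  hp <- protocol$holding_potential
  pre <- protocol$pre_ms
  post <- protocol$post_ms
  switch(
    protocol$kind,
    IV = lapply(protocol_step_voltages(protocol), function(v) {
      list(segments = sweep_segments(c(hp, v, hp),
                                     c(pre, protocol$step_duration, post)),
           role = "main", test_v = v, step_segment = 2L)
    }),
    SSI = {
      if (is.null(v_max)) stop("SSI sweeps require `v_max`")
      lapply(protocol_step_voltages(protocol), function(vc) {
        list(segments = sweep_segments(
               c(hp, v_max, hp, vc, v_max, hp),
               c(pre, protocol$step_duration, protocol$gap_ms,
                 protocol$conditioning_duration, protocol$step_duration,
                 post)),
             role = "main", cond_v = vc, test_v = v_max,
             control_segment = 2L, test_segment = 5L)
      })
    },
    INACT5S = {
      if (is.null(v_max)) stop("INACT5S sweeps require `v_max`")
      list(list(segments = sweep_segments(c(hp, v_max, hp),
                                          c(pre, 5000, post)),
                role = "main", test_v = v_max, step_segment = 2L))
    },
    stop("unknown protocol kind: ", protocol$kind)
  )
}

# Reference sweep for offline leak subtraction: a 50-ms hyperpolarizing step
# from -80 to -90 mV, where the channel is closed and only leak flows.
leakref_sweep_plan <- function(dt, pre_ms = 20, post_ms = 10) {
  list(segments = sweep_segments(c(-80, -90, -80), c(pre_ms, 50, post_ms)),
       role = "leakref", step_segment = 2L)
}

# Quarter-amplitude P/4 subsweep for a main sweep stepping hp -> v_test.
p4_sub_plan <- function(protocol, v_test) {
  hp <- protocol$holding_potential
  list(segments = sweep_segments(
         c(hp, hp + (v_test - hp) / 4, hp),
         c(protocol$pre_ms, protocol$step_duration, protocol$post_ms)),
       role = "p4sub", test_v = v_test)
}
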