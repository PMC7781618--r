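# Forward simulation of whole-cell current for piecewise-constant command
# voltage. Gating states have closed-form exponential relaxations within each
# segment, so traces are computed segment-wise and fully vectorized.

# Run `expr` with a private RNG stream; the caller's .Random.seed survives.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed streams (all below 2^31).
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Build a voltage-step segment table
#'
#' @param v Segment command voltages (mV).
#' @param dur Segment durations (ms), same length as `v`.
#' @return A data.frame with columns `v` and `dur` describing a
#'   piecewise-constant command waveform.
#' @export
sweep_segments <- function(v, dur) {
  stopifnot(is.numeric(v), is.numeric(dur), length(v) == length(dur),
            length(v) >= 1L, all(is.finite(v)), all(is.finite(dur)),
            all(dur > 0))
  data.frame(v = as.numeric(v), dur = as.numeric(dur))
}

# Sample counts per segment at step dt; errors if dt does not resolve a segment
segment_samples <- function(segments, dt) {
  n <- as.integer(round(segments$dur / dt))
  if (any(segments$dur <= dt) || any(n < 1L)) {
    stop("`dt` (", dt, " ms) must be smaller than the shortest segment")
  }
  n
}

#' Reconstruct the command-voltage trace of a segment table
#'
#' @param segments A segment table from [sweep_segments()].
#' @param dt Sampling interval (ms).
#' @return Numeric vector of command voltage at sample times `dt, 2*dt, ...`.
#' @export
segment_voltage_trace <- function(segments, dt) {
  rep(segments$v, segment_samples(segments, dt))
}

#' Simulate one voltage-clamp sweep
#'
#' Forward-models the whole-cell current elicited by a piecewise-constant
#' command waveform. The channel current is
#' \eqn{I_{chan}(t) = G_{max}\, m(t)\, h(t)\, (V(t) - V_{rev})} with
#' `m` relaxing mono-exponentially to [steady_state_activation()] (time
#' constant `tau_act`) and `h` relaxing as the weighted sum of two
#' exponential pools (`tau_fast`, `tau_slow`) towards
#' [steady_state_availability()]. On top of the channel current the model
#' adds ohmic leak \eqn{g_{leak}(V - E_{leak})}, a capacitive transient
#' \eqn{C_m \Delta V/\tau_{cap}\, e^{-t/\tau_{cap}}} at every step edge, and
#' i.i.d. Gaussian noise of SD `noise_sd` (omitted when zero).
#'
#' The initial gating state is the steady state at the first segment's
#' voltage (the cell is assumed to have been held there). Identical
#' arguments and seed give a bit-identical trace.
#'
#' @param segments Segment table ([sweep_segments()]).
#' @param params [channel_params()].
#' @param dt Sampling interval (ms); must be smaller than every segment.
#' @param seed Optional integer seed for the noise stream; the global RNG
#'   state is left untouched. With `seed = NULL` the current RNG stream is
#'   consumed.
#' @return Numeric current trace (pA) at times `dt, 2*dt, ...`, with
#'   attributes `dt` and `segments`.
#' @export
simulate_sweep <- function(segments, params, dt, seed = NULL) {
  stopifnot(inherits(params, "channel_params"),
            is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  if (!is.data.frame(segments) || !all(c("v", "dur") %in% names(segments))) {
    stop("`segments` must be a data.frame with columns `v` and `dur`")
  }
  if (any(!is.finite(segments$v))) stop("segment voltages must be finite")
  n_seg <- segment_samples(segments, dt)

  act <- params$act
  inact <- params$inact
  pas <- params$passive

  m <- steady_state_activation(segments$v[1], act)
  h0 <- steady_state_availability(segments$v[1], inact)
  hf <- h0
  hs <- h0
  v_prev <- segments$v[1]

  out <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    v <- segments$v[i]
    tau <- seq_len(n_seg[i]) * dt
    m_inf <- steady_state_activation(v, act)
    h_inf <- steady_state_availability(v, inact)

    m_t <- m_inf + (m - m_inf) * exp(-tau / act$tau_act)
    hf_t <- h_inf + (hf - h_inf) * exp(-tau / inact$tau_fast)
    hs_t <- h_inf + (hs - h_inf) * exp(-tau / inact$tau_slow)
    h_t <- inact$frac_fast * hf_t + (1 - inact$frac_fast) * hs_t

    cur <- act$g_max * m_t * h_t * (v - act$v_rev) +
      pas$g_leak * (v - pas$e_leak)
    dv <- v - v_prev
    if (dv != 0) {
      cur <- cur + pas$c_m * dv / pas$tau_cap * exp(-tau / pas$tau_cap)
    }

    m <- m_t[n_seg[i]]
    hf <- hf_t[n_seg[i]]
    hs <- hs_t[n_seg[i]]
    v_prev <- v
    out[[i]] <- cur
  }

  trace <- unlist(out, use.names = FALSE)
  if (pas$noise_sd > 0) {
    trace <- trace + with_local_seed(seed, rnorm(length(trace), 0, pas$noise_sd))
  }
  attr(trace, "dt") <- dt
  attr(trace, "segments") <- segments
  trace
}
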