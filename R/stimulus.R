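#' Stimulus protocols
#'
#' Declarative description of the external drive applied to the compartment:
#' either a rectangular bath-agonist (DHPG) pulse or a presynaptic glutamate
#' spike train. Each presynaptic spike produces an instantaneous jump of
#' `glu_max` (~200 uM) in the perisynaptic glutamate concentration, which then
#' decays first-order with rate `k_glu` (1/6.25 ms), absorbing receptor
#' binding and reuptake into a single clearance constant.
#'
#' @param kind `"agonist_pulse"` or `"glutamate_train"`.
#' @param agonist_uM Agonist (DHPG) concentration during the pulse, uM.
#' @param onset_s Pulse/train onset, s.
#' @param duration_s Pulse or train duration, s.
#' @param rate_hz Spike rate for trains, Hz (0.4-100 matches the sweep the
#'   model is characterized over; other positive rates are allowed).
#' @param timing `"regular"` (default) or `"poisson"` spike timing.
#' @param glu_max Glutamate jump per spike, uM.
#' @param k_glu Glutamate clearance rate, 1/s.
#' @param glu_base Baseline glutamate, uM.
#' @return An object of class `stimulus_protocol`.
#' @export
#' @examples
#' stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 1,
#'                   duration_s = 2)
#' stimulus_protocol("glutamate_train", rate_hz = 10, onset_s = 0.5,
#'                   duration_s = 11)
stimulus_protocol <- function(kind = c("agonist_pulse", "glutamate_train"),
                              agonist_uM = 100, onset_s = 0.5,
                              duration_s = 2, rate_hz = 10,
                              timing = c("regular", "poisson"),
                              glu_max = 200, k_glu = 160, glu_base = 0) {
  kind <- match.arg(kind)
  timing <- match.arg(timing)
  stopifnot(onset_s >= 0, duration_s > 0, glu_max > 0, k_glu > 0,
            glu_base >= 0)
  if (kind == "glutamate_train" && rate_hz <= 0)
    stop("spike rate must be positive")
  if (kind == "agonist_pulse" && agonist_uM < 0)
    stop("agonist concentration must be non-negative")
  structure(list(kind = kind, agonist_uM = agonist_uM, onset_s = onset_s,
                 duration_s = duration_s, rate_hz = rate_hz, timing = timing,
                 glu_max = glu_max, k_glu = k_glu, glu_base = glu_base),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  if (x$kind == "agonist_pulse") {
    cat(sprintf("DHPG pulse: %g uM, onset %g s, duration %g s\n",
                x$agonist_uM, x$onset_s, x$duration_s))
  } else {
    cat(sprintf(
      "Glutamate train: %g Hz (%s), onset %g s, duration %g s, %g uM jump, tau %.3g ms\n",
      x$rate_hz, x$timing, x$onset_s, x$duration_s, x$glu_max,
      1000 / x$k_glu))
  }
  invisible(x)
}

#' Presynaptic spike times for a train protocol
#'
#' Regular mode places spikes at `onset + k/rate` for `k = 0, 1, ...` within
#' the train duration; Poisson mode draws exponential inter-spike intervals
#' at the same rate (uses the current R random-number stream).
#'
#' @param protocol A `stimulus_protocol` of kind `"glutamate_train"`.
#' @return Strictly increasing numeric vector of spike times, s.
#' @export
spike_times <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (protocol$kind != "glutamate_train")
    stop("spike_times() requires a glutamate_train protocol")
  if (protocol$rate_hz <= 0) stop("spike rate must be positive")
  t_end <- protocol$onset_s + protocol$duration_s
  if (protocol$timing == "regular") {
    ts <- seq(protocol$onset_s, t_end, by = 1 / protocol$rate_hz)
    ts <- ts[ts < t_end]
  } else {
    ts <- numeric(0)
    t <- protocol$onset_s
    repeat {
      t <- t + stats::rexp(1, rate = protocol$rate_hz)
      if (t >= t_end) break
      ts <- c(ts, t)
    }
  }
  ts
}

#' Glutamate concentration time course
#'
#' Evaluates the perisynaptic glutamate concentration at the requested times
#' for a given set of spike times: an impulse increment of `glu_max` at each
#' spike followed by exponential decay at rate `k_glu` toward `glu_base`.
#' Because the decay is linear and first order, the trace is exactly the
#' superposition of single-spike responses.
#'
#' @param protocol A `stimulus_protocol` (supplies `glu_max`, `k_glu`,
#'   `glu_base`).
#' @param times Numeric vector of query times, s.
#' @param spikes Spike times, s; defaults to `spike_times(protocol)` for
#'   train protocols and none otherwise.
#' @return Numeric vector of glutamate concentrations (uM), same length as
#'   `times`.
#' @export
glutamate_trace <- function(protocol, times, spikes = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (is.null(spikes)) {
    spikes <- if (protocol$kind == "glutamate_train")
      spike_times(protocol) else numeric(0)
  }
  g <- rep(0, length(times))
  for (ts in spikes) {
    on <- times >= ts
    g[on] <- g[on] + protocol$glu_max * exp(-protocol$k_glu * (times[on] - ts))
  }
  g + protocol$glu_base
}

#' Advance a glutamate state by one time step
#'
#' Step-wise counterpart of [glutamate_trace()] for use inside fixed-step
#' simulation: decays the current concentration toward baseline over `dt`
#' (exact exponential update) and applies the impulse of any pending spike
#' falling inside the step.
#'
#' @param state List with `time` (s), `glu` (uM) and `pending` (spike times,
#'   s), as created by `glutamate_state()`.
#' @param protocol A `stimulus_protocol`.
#' @param dt Time step, s.
#' @return Updated state list.
#' @export
glutamate_step <- function(state, protocol, dt) {
  stopifnot(dt > 0, state$glu >= 0)
  base <- protocol$glu_base
  g <- base + (state$glu - base) * exp(-protocol$k_glu * dt)
  t1 <- state$time + dt
  # a spike exactly at the current time is still pending (first step)
  due <- state$pending[state$pending >= state$time & state$pending <= t1]
  if (length(due)) {
    # decay each impulse from its spike time to the end of the step
    g <- g + sum(protocol$glu_max * exp(-protocol$k_glu * (t1 - due)))
  }
  list(time = t1, glu = g,
       pending = state$pending[state$pending > t1])
}

#' @rdname glutamate_step
#' @param spikes Spike times for the pending queue, s.
#' @export
glutamate_state <- function(protocol, spikes = NULL) {
  if (is.null(spikes)) {
    spikes <- if (protocol$kind == "glutamate_train")
      spike_times(protocol) else numeric(0)
  }
  list(time = 0, glu = protocol$glu_base, pending = sort(spikes))
}

#' Bath agonist concentration at a given time
#'
#' Rectangular pulse: the stated concentration inside
#' `[onset, onset + duration)`, zero outside.
#'
#' @param protocol A `stimulus_protocol` of kind `"agonist_pulse"`.
#' @param t Numeric vector of times, s.
#' @return Agonist concentration (uM) at each time.
#' @export
agonist_concentration <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (protocol$kind != "agonist_pulse") return(rep(0, length(t)))
  ifelse(t >= protocol$onset_s & t < protocol$onset_s + protocol$duration_s,
         protocol$agonist_uM, 0)
}

# Glutamate trace sampled on the fixed simulation grid (step starts), used
# to drive the compiled trial loop. Spikes are snapped to the step on whose
# start they would first act. Uses a recursive filter, so cost is O(n).
glutamate_grid <- function(protocol, n_steps, dt, spikes = NULL) {
  if (is.null(spikes)) {
    spikes <- if (protocol$kind == "glutamate_train")
      spike_times(protocol) else numeric(0)
  }
  x <- numeric(n_steps)
  if (length(spikes)) {
    idx <- pmin(n_steps, floor(spikes / dt) + 1L)
    for (i in idx) x[i] <- x[i] + protocol$glu_max
  }
  d <- exp(-protocol$k_glu * dt)
  g <- as.numeric(stats::filter(x, d, method = "recursive"))
  g + protocol$glu_base
}
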