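#' Instantaneous state of the compartment
#'
#' Bundles the continuous variables of the signaling core (all in uM) with
#' the categorical per-subunit IP3R states.
#'
#' @param time Time, s.
#' @param ca_cyt Cytosolic free Ca, uM.
#' @param ca_er ER free Ca, uM.
#' @param ip3 IP3, uM.
#' @param b_cyt Buffer-bound Ca in the cytosol, uM.
#' @param b_er Buffer-bound Ca in the ER, uM.
#' @param subunits Integer vector of IP3R subunit states (0..7), length
#'   `n_ip3r * n_subunits`, or `NULL` for a state without channels attached.
#' @return Object of class `compartment_state`.
#' @export
compartment_state <- function(time = 0, ca_cyt, ca_er, ip3,
                              b_cyt = 0, b_er = 0, subunits = NULL) {
  conc <- c(ca_cyt = ca_cyt, ca_er = ca_er, ip3 = ip3,
            b_cyt = b_cyt, b_er = b_er)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  if (!is.null(subunits) &&
      (any(subunits < 0L) || any(subunits > 7L)))
    stop("subunit states must lie in 0..7")
  structure(list(time = time, ca_cyt = ca_cyt, ca_er = ca_er, ip3 = ip3,
                 b_cyt = b_cyt, b_er = b_er,
                 subunits = if (is.null(subunits)) NULL else as.integer(subunits)),
            class = "compartment_state")
}

#' @export
print.compartment_state <- function(x, ...) {
  cat(sprintf(
    "compartment state @ t = %.4g s: Ca_cyt %.4g uM, Ca_ER %.4g uM, IP3 %.4g uM\n",
    x$time, x$ca_cyt, x$ca_er, x$ip3))
  if (!is.null(x$subunits))
    cat(sprintf("  %d IP3R subunits, %d active\n", length(x$subunits),
                sum(x$subunits == IP3R_ACTIVE_STATE)))
  invisible(x)
}

#' Deterministic flux terms of the signaling core
#'
#' Evaluates every labeled flux contribution at the given state (uM/s):
#' IP3R channel flux (scaled by the open-channel count), passive ER leak,
#' SERCA uptake, PMCA extrusion, constant plasma-membrane leak, kinetic
#' buffer exchange in cytosol and ER, mGluR-driven and PLCdelta-driven IP3
#' production, and 5-phosphatase / 3-kinase IP3 degradation. Ca bookkeeping
#' is exact: whatever leaves the ER enters the cytosol, scaled by the
#' ER/cytosol volume ratio on the ER side.
#'
#' @param state A `compartment_state`; negative concentrations are rejected.
#' @param params An `astro_params` object.
#' @param glu Extracellular glutamate, uM.
#' @param agonist Bath agonist (DHPG), uM. Both drive the same mGluR
#'   dose-response term; their sum is the effective agonist concentration.
#' @param n_open Open-channel count; defaults to the count implied by
#'   `state$subunits` (0 if the state has no channels attached).
#' @return List with `fluxes` (named, uM/s) and `deriv` (named derivative
#'   of `ca_cyt`, `ca_er`, `ip3`, `b_cyt`, `b_er`, uM/s).
#' @export
flux_terms <- function(state, params, glu = 0, agonist = 0, n_open = NULL) {
  with_state <- c(state$ca_cyt, state$ca_er, state$ip3, state$b_cyt, state$b_er)
  if (any(with_state < 0)) stop("negative concentration in input state")
  if (is.null(n_open)) {
    n_open <- if (is.null(state$subunits)) 0L
              else n_open_channels(state$subunits, params)
  }
  ca <- state$ca_cyt; er <- state$ca_er; ip3 <- state$ip3
  drive <- glu + agonist
  hill <- function(x, k, n) if (x <= 0) 0 else x^n / (x^n + k^n)

  J_ip3r    <- params$v_ip3r * n_open * (er - ca)
  J_er_leak <- params$v_er_leak * (er - ca)
  J_serca   <- params$v_serca * hill(ca, params$k_serca, 2)
  J_pmca    <- params$v_pmca * params$pmca_kf * ca /
                 (params$pmca_kf * ca + params$pmca_kb)
  J_pm_leak <- params$v_pm_leak
  J_buf_cyt <- params$kon_cyt * (params$bt_cyt - state$b_cyt) * ca -
                 params$koff_cyt * state$b_cyt
  J_buf_er  <- params$kon_er * (params$bt_er - state$b_er) * er -
                 params$koff_er * state$b_er
  J_mglur   <- params$v_mglur * hill(drive, params$k_mglur, params$n_mglur)
  J_plcd    <- params$v_plcd * hill(ca, params$k_plcd, 2)
  J_5p      <- params$k_5p * ip3
  J_3k      <- params$v_3k * hill(ca, params$k_3k, 2) * ip3

  deriv <- c(
    ca_cyt = J_ip3r + J_er_leak - J_serca - J_pmca + J_pm_leak - J_buf_cyt,
    ca_er  = (-J_ip3r - J_er_leak + J_serca) / params$er_cyt_ratio - J_buf_er,
    ip3    = J_mglur + J_plcd - J_5p - J_3k,
    b_cyt  = J_buf_cyt,
    b_er   = J_buf_er
  )
  list(fluxes = c(ip3r = J_ip3r, er_leak = J_er_leak, serca = J_serca,
                  pmca = J_pmca, pm_leak = J_pm_leak, buf_cyt = J_buf_cyt,
                  buf_er = J_buf_er, mglur = J_mglur, plcd = J_plcd,
                  ip3_5p = J_5p, ip3_3k = J_3k),
       deriv = deriv)
}

# right-hand side of the deterministic (mean-field) model for deSolve:
# y = (ca, er, ip3, bc, be, x0..x7) with x the subunit state occupancy.
meanfield_rhs <- function(t, y, parms) {
  params <- parms$params
  x <- y[6:13]
  p_active <- x[IP3R_ACTIVE_STATE + 1L]
  n_open_mean <- params$n_ip3r * p_active^params$n_subunits
  st <- compartment_state(time = t, ca_cyt = max(y[1], 0),
                          ca_er = max(y[2], 0), ip3 = max(y[3], 0),
                          b_cyt = max(y[4], 0), b_er = max(y[5], 0))
  ft <- flux_terms(st, params,
                   glu = parms$glu_fun(t), agonist = parms$agonist_fun(t),
                   n_open = n_open_mean)
  Q <- ip3r_rate_matrix(st$ca_cyt, st$ip3, params)
  dx <- as.numeric(t(Q) %*% x)
  list(c(ft$deriv, dx))
}

#' Deterministic (mean-field) simulation of the signaling core
#'
#' Integrates the compartment equations with the stochastic channel gating
#' replaced by its subunit master equation, so the open-channel count is
#' the cluster size times the active-state probability to the power of the
#' subunit number. Used for resting-state computation, dose-response
#' characterization and as the noise-free limit of the simulator.
#'
#' @param params An `astro_params` object.
#' @param protocol Optional `stimulus_protocol`. Agonist pulses are applied
#'   exactly; glutamate trains are applied through the analytic trace of
#'   [glutamate_trace()] (deterministic spike times only).
#' @param duration Total simulated time, s.
#' @param init Optional `compartment_state` to start from; defaults to the
#'   parameter file's resting targets with buffers equilibrated.
#' @param method `"lsoda"` (adaptive, default) or `"euler"` (fixed step
#'   `dt`, the deterministic limit of the stochastic integrator).
#' @param dt Fixed step for `method = "euler"` and output resolution for
#'   both methods, s.
#' @param dt_out Output sampling interval, s.
#' @return Data frame with columns `time`, `ca_cyt`, `ca_er`, `ip3`,
#'   `b_cyt`, `b_er`, `p_open` (per-channel open probability).
#' @export
simulate_deterministic <- function(params, protocol = NULL, duration,
                                   init = NULL,
                                   method = c("lsoda", "euler"),
                                   dt = 5e-5, dt_out = 1e-3) {
  method <- match.arg(method)
  if (is.null(init)) init <- default_init_state(params)
  agonist_fun <- function(t) 0
  glu_fun <- function(t) 0
  if (!is.null(protocol)) {
    if (protocol$kind == "agonist_pulse") {
      agonist_fun <- function(t) agonist_concentration(protocol, t)
    } else {
      if (protocol$timing != "regular")
        stop("deterministic simulation requires regular spike timing")
      sp <- spike_times(protocol)
      glu_fun <- function(t) glutamate_trace(protocol, t, spikes = sp)
    }
  }
  x0 <- subunit_occupancy_init(init, params)
  y0 <- c(init$ca_cyt, init$ca_er, init$ip3, init$b_cyt, init$b_er, x0)
  parms <- list(params = params, glu_fun = glu_fun, agonist_fun = agonist_fun)

  if (method == "lsoda") {
    times <- seq(0, duration, by = dt_out)
    sol <- deSolve::lsoda(y0, times, meanfield_rhs, parms,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
    out <- as.data.frame(sol)
  } else {
    n_steps <- ceiling(duration / dt)
    keep <- max(1L, round(dt_out / dt))
    n_out <- floor(n_steps / keep) + 1L
    out <- matrix(NA_real_, n_out, 14)
    y <- y0
    out[1, ] <- c(0, y)
    row <- 2L
    for (s in seq_len(n_steps)) {
      t <- (s - 1) * dt
      dy <- meanfield_rhs(t, y, parms)[[1]]
      y <- y + dt * dy
      y[y < 0 & seq_along(y) <= 5] <- 0
      if (s %% keep == 0L) { out[row, ] <- c(s * dt, y); row <- row + 1L }
    }
    out <- as.data.frame(out[seq_len(row - 1L), , drop = FALSE])
  }
  names(out) <- c("time", "ca_cyt", "ca_er", "ip3", "b_cyt", "b_er",
                  paste0("x", 0:7))
  out$p_open <- out[[paste0("x", IP3R_ACTIVE_STATE)]]^params$n_subunits
  out[c("time", "ca_cyt", "ca_er", "ip3", "b_cyt", "b_er", "p_open")]
}

# initial state from the parameter file's resting targets, with buffers at
# their binding equilibrium for those targets
default_init_state <- function(params) {
  ca <- params$ca_cyt_rest; er <- params$ca_er_rest
  bc <- params$bt_cyt * ca / (ca + params$koff_cyt / params$kon_cyt)
  be <- params$bt_er * er / (er + params$koff_er / params$kon_er)
  compartment_state(0, ca, er, params$ip3_rest, bc, be)
}

# subunit occupancy vector used to seed the mean-field integration
subunit_occupancy_init <- function(state, params) {
  if (!is.null(state$subunits)) {
    tabulate(state$subunits + 1L, nbins = 8) / length(state$subunits)
  } else {
    ip3r_stationary(state$ca_cyt, state$ip3, params)
  }
}

#' Resting state of the compartment
#'
#' Finds the state at which all net deterministic fluxes vanish by relaxing
#' the mean-field model with no stimulus, and attaches IP3R subunit states
#' drawn from the stationary distribution at the resting Ca/IP3 (uses the
#' current R random-number stream when `sample_channels = TRUE`).
#'
#' @param params An `astro_params` object.
#' @param init Optional starting `compartment_state`; when all fluxes are
#'   zero at `init` (e.g. pumps disabled and no ER gradient) it is a fixed
#'   point and is returned unchanged.
#' @param t_relax Relaxation horizon, s.
#' @param tol Convergence tolerance on the relative derivative
#'   `|dy/dt| / max(|y|, 1e-3)` of each continuous variable, 1/s.
#' @param sample_channels Attach sampled subunit states?
#' @return A `compartment_state` at rest, with attribute
#'   `"stationary"` (the subunit stationary distribution).
#' @export
resting_state <- function(params, init = NULL, t_relax = 600,
                          tol = 1e-5, sample_channels = TRUE) {
  if (is.null(init)) init <- default_init_state(params)
  for (attempt in 1:2) {
    sol <- simulate_deterministic(params, protocol = NULL,
                                  duration = t_relax, init = init,
                                  dt_out = t_relax / 50)
    last <- sol[nrow(sol), ]
    st <- compartment_state(0, max(last$ca_cyt, 0), max(last$ca_er, 0),
                            max(last$ip3, 0), max(last$b_cyt, 0),
                            max(last$b_er, 0))
    pi <- ip3r_stationary(st$ca_cyt, st$ip3, params)
    n_open_mean <- params$n_ip3r * pi[IP3R_ACTIVE_STATE + 1L]^params$n_subunits
    ft <- flux_terms(st, params, n_open = n_open_mean)
    rel <- abs(ft$deriv) / pmax(abs(c(st$ca_cyt, st$ca_er, st$ip3,
                                      st$b_cyt, st$b_er)), 1e-3)
    if (max(rel) < tol) {
      if (sample_channels)
        st$subunits <- sample_ip3r_states(st$ca_cyt, st$ip3, params)
      attr(st, "stationary") <- pi
      return(st)
    }
    init <- st
    t_relax <- t_relax * 4
  }
  stop("resting-state relaxation did not converge: unstable parameter set ",
       "(max relative derivative ", signif(max(rel), 3), " 1/s)")
}

#' Advance the full compartment state by one fixed step
#'
#' One step of the hybrid integrator: continuous variables advance by
#' explicit Euler on [flux_terms()] (concentrations clipped at zero with a
#' warning if an excursion occurs), then the IP3R subunits advance by
#' [ip3r_transition_step()]. The open-channel count entering the fluxes is
#' the one at the start of the step.
#'
#' @param state A `compartment_state` with `subunits` attached.
#' @param params An `astro_params` object.
#' @param glu Extracellular glutamate during the step, uM.
#' @param agonist Bath agonist during the step, uM.
#' @param dt Time step, s (fixed for the whole run; 5e-5 by default).
#' @return The advanced `compartment_state` (time increased by `dt`).
#' @export
step_compartment <- function(state, params, glu = 0, agonist = 0, dt = 5e-5) {
  stopifnot(inherits(state, "compartment_state"), !is.null(state$subunits))
  ft <- flux_terms(state, params, glu = glu, agonist = agonist)
  y <- c(state$ca_cyt, state$ca_er, state$ip3, state$b_cyt, state$b_er) +
    dt * ft$deriv
  if (any(!is.finite(y))) {
    stop("non-finite state after step at t = ", state$time,
         "; fluxes: ", paste(names(ft$fluxes), signif(ft$fluxes, 3),
                             sep = "=", collapse = ", "))
  }
  if (any(y < 0)) {
    warning("concentration clipped at zero during step at t = ", state$time)
    y[y < 0] <- 0
  }
  new <- compartment_state(state$time + dt, y[1], y[2], y[3], y[4], y[5],
                           subunits = state$subunits)
  ip3r_transition_step(new, params, dt)
}
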