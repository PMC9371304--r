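#' Gliotransmitter release machinery state
#'
#' Pool-level (mean-field) occupancy of the two Ca sensors plus integer
#' vesicle counts. Syt4, the fast low-affinity sensor of docked vesicles,
#' has a single Ca site; its occupancy is the expected bound fraction of
#' docked-vesicle sensors. Syt7, the slow high-affinity sensor of mobile
#' vesicles, has five sequential sites; its occupancy is a distribution over
#' 0..5 bound Ca ions, with fusion only from the fully bound state. Vesicles
#' live in four pools: docked, mobile, KR-endocytosed (post kiss-and-run,
#' awaiting recycling) and FF-endocytosed (post full-fusion). Total vesicle
#' number is conserved exactly at every step.
#'
#' @param params An `astro_params` object (supplies initial pool sizes).
#' @return Object of class `release_state` with fields `time`, `p4`
#'   (Syt4 bound fraction), `occ7` (Syt7 occupancy distribution over 0..5),
#'   `pools` (named integer vector `docked`, `mobile`, `kr_endo`,
#'   `ff_endo`) and `events` (data frame `time`, `mode`).
#' @export
release_machinery_state <- function(params) {
  structure(list(
    time = 0,
    p4 = 0,
    occ7 = c(1, 0, 0, 0, 0, 0),
    pools = c(docked = as.integer(params$n_docked),
              mobile = as.integer(params$n_mobile),
              kr_endo = 0L, ff_endo = 0L),
    events = data.frame(time = numeric(0), mode = character(0),
                        stringsAsFactors = FALSE)),
    class = "release_state")
}

#' @export
print.release_state <- function(x, ...) {
  cat(sprintf(
    "release machinery @ t = %.4g s: Syt4 bound %.3f, Syt7 fully bound %.3g\n",
    x$time, x$p4, x$occ7[6]))
  cat("  pools:", paste(names(x$pools), x$pools, sep = "=", collapse = " "),
      sprintf(" (%d events logged)\n", nrow(x$events)))
  invisible(x)
}

# generator of the Syt7 sequential binding chain (6 states, 0..5 bound).
# forward i -> i+1: (5 - i) * kon * ca; backward i -> i-1: i * koff * b^(i-1),
# with b < 1 slowing each successive unbinding (bound-state stabilization).
syt7_rate_matrix <- function(ca, params) {
  n <- params$syt7_sites
  Q <- matrix(0, n + 1, n + 1)
  for (i in 0:(n - 1))
    Q[i + 1, i + 2] <- (n - i) * params$syt7_kon * ca
  for (i in 1:n)
    Q[i + 1, i] <- i * params$syt7_koff * params$syt7_b^(i - 1)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Advance the sensor occupancies by one step
#'
#' Integrates the Syt4 two-state and Syt7 six-state mass-action master
#' equations at the instantaneous (constant within the step) Ca
#' concentration, using an explicit Runge-Kutta step that internally
#' subdivides so the fastest rate times the substep stays below 0.05.
#' Occupancies remain valid distributions.
#'
#' @param state A `release_state`.
#' @param ca Cytosolic Ca, uM.
#' @param params An `astro_params` object.
#' @param dt Time step, s.
#' @return The state with updated `p4` and `occ7` (time unchanged; the
#'   release step owns the clock).
#' @export
sensor_update <- function(state, ca, params, dt) {
  stopifnot(inherits(state, "release_state"), ca >= 0, dt > 0)
  out <- cpp_sensor_update(state$p4, state$occ7, ca, dt, params)
  p4 <- out[[1]]; occ7 <- out[[2]]
  if (p4 < -1e-9 || p4 > 1 + 1e-9 || any(occ7 < -1e-9) ||
      abs(sum(occ7) - 1) > 1e-8)
    stop("sensor occupancy left [0, 1]; dt too large for the binding rates")
  state$p4 <- min(max(p4, 0), 1)
  occ7[occ7 < 0] <- 0
  state$occ7 <- occ7 / sum(occ7)
  state
}

#' Instantaneous release rates of the two fusion modes
#'
#' Kiss-and-run rate: Syt4 fusion rate x Syt4 bound fraction x docked
#' count. Full-fusion rate: Syt7 fusion rate x fully bound probability x
#' mobile count. Both are zero when the corresponding pool is empty.
#'
#' @param state A `release_state`.
#' @param params An `astro_params` object.
#' @return Named numeric vector `c(kr = , ff = )`, 1/s.
#' @export
release_rates <- function(state, params) {
  c(kr = params$syt4_gamma * state$p4 * state$pools[["docked"]],
    ff = params$syt7_gamma * state$occ7[params$syt7_sites + 1] *
      state$pools[["mobile"]])
}

#' Draw release events for one step
#'
#' For each mode independently, one vesicle is released iff
#' `rate * dt > U(0,1)`. A kiss-and-run release moves a docked vesicle to
#' the KR-endocytosed pool; a full fusion moves a mobile vesicle to the
#' FF-endocytosed pool. Events are appended to the log. Uses the current R
#' random-number stream.
#'
#' @param state A `release_state`.
#' @param rates Named vector from [release_rates()].
#' @param dt Time step, s; `rate * dt` must stay below 1 for both modes.
#' @return Updated `release_state` with `time` advanced by `dt`.
#' @export
sample_release_events <- function(state, rates, dt) {
  if (any(rates * dt >= 1)) stop("release probability per step >= 1")
  u <- stats::runif(2)
  t_ev <- state$time
  if (state$pools[["docked"]] > 0 && u[1] < rates[["kr"]] * dt) {
    state$pools[["docked"]] <- state$pools[["docked"]] - 1L
    state$pools[["kr_endo"]] <- state$pools[["kr_endo"]] + 1L
    state$events <- rbind(state$events,
                          data.frame(time = t_ev, mode = "KR"))
  }
  if (state$pools[["mobile"]] > 0 && u[2] < rates[["ff"]] * dt) {
    state$pools[["mobile"]] <- state$pools[["mobile"]] - 1L
    state$pools[["ff_endo"]] <- state$pools[["ff_endo"]] + 1L
    state$events <- rbind(state$events,
                          data.frame(time = t_ev, mode = "FF"))
  }
  state$time <- state$time + dt
  state
}

#' Stochastic vesicle pool transitions for one step
#'
#' Binomial per-step transitions: KR-endocytosed -> mobile at the KR
#' recycling rate, FF-endocytosed -> mobile at the FF recycling rate, and
#' mobile -> docked at the docking rate, limited by the free docking sites.
#' Total vesicle number is conserved exactly. Uses the current R
#' random-number stream.
#'
#' @param state A `release_state`.
#' @param params An `astro_params` object.
#' @param dt Time step, s.
#' @return Updated `release_state`.
#' @export
pool_kinetics_step <- function(state, params, dt) {
  p_kr <- -expm1(-params$kr_recycle * dt)
  p_ff <- -expm1(-params$ff_recycle * dt)
  p_dk <- -expm1(-params$k_dock * dt)
  pools <- state$pools
  kr_mv <- stats::rbinom(1, pools[["kr_endo"]], p_kr)
  ff_mv <- stats::rbinom(1, pools[["ff_endo"]], p_ff)
  free <- as.integer(params$docked_max) - pools[["docked"]]
  dk_mv <- min(stats::rbinom(1, pools[["mobile"]], p_dk), max(free, 0L))
  pools[["kr_endo"]] <- pools[["kr_endo"]] - kr_mv
  pools[["ff_endo"]] <- pools[["ff_endo"]] - ff_mv
  pools[["mobile"]] <- pools[["mobile"]] + kr_mv + ff_mv - dk_mv
  pools[["docked"]] <- pools[["docked"]] + dk_mv
  state$pools <- pools
  state
}

# expected-rate ODE for clamped-Ca characterization: sensor occupancies plus
# depleting pools, no recycling (isolates the release time course)
clamped_release_rhs <- function(t, y, parms) {
  p <- parms$params; ca <- parms$ca
  p4 <- y[1]; occ <- y[2:7]; nd <- y[8]; nm <- y[9]
  dp4 <- p$syt4_kon * ca * (1 - p4) - p$syt4_koff * p4
  docc <- as.numeric(t(syt7_rate_matrix(ca, p)) %*% occ)
  rate_kr <- p$syt4_gamma * p4 * nd
  rate_ff <- p$syt7_gamma * occ[p$syt7_sites + 1] * nm
  list(c(dp4, docc, -rate_kr, -rate_ff))
}

#' Clamped-calcium characterization of the release machinery
#'
#' Deterministic expected release-rate time courses at a set of clamped
#' steady-state Ca concentrations, starting from fully unbound sensors and
#' full pools, with recycling disabled so the curves isolate binding and
#' depletion. Peak rate and time to peak are extracted per level; fitting
#' the peak-rate curves with [fit_hill()] recovers the operational Ca
#' affinity of each sensor.
#'
#' @param params An `astro_params` object.
#' @param ca_levels Positive Ca concentrations (uM) spanning sub- to
#'   supra-affinity values.
#' @param t_max Time horizon per level, s.
#' @param dt_out Output sampling, s.
#' @return List of class `clamped_characterization`: `time`, matrices
#'   `rate_kr` and `rate_ff` (levels x time, 1/s), and `peaks`
#'   (data frame `ca`, `peak_kr`, `ttp_kr`, `peak_ff`, `ttp_ff`).
#' @export
characterize_clamped <- function(params, ca_levels, t_max = 3,
                                 dt_out = 5e-4) {
  if (length(ca_levels) == 0) stop("ca_levels must be non-empty")
  if (any(ca_levels <= 0)) stop("ca_levels must be positive")
  times <- seq(0, t_max, by = dt_out)
  rate_kr <- rate_ff <- matrix(NA_real_, length(ca_levels), length(times))
  for (i in seq_along(ca_levels)) {
    y0 <- c(0, c(1, 0, 0, 0, 0, 0), params$n_docked, params$n_mobile)
    sol <- deSolve::lsoda(y0, times, clamped_release_rhs,
                          list(params = params, ca = ca_levels[i]),
                          rtol = 1e-8, atol = 1e-10)
    rate_kr[i, ] <- params$syt4_gamma * sol[, 2] * sol[, 9]
    rate_ff[i, ] <- params$syt7_gamma * sol[, 8] * sol[, 10]
  }
  peaks <- data.frame(
    ca = ca_levels,
    peak_kr = apply(rate_kr, 1, max),
    ttp_kr = times[apply(rate_kr, 1, which.max)],
    peak_ff = apply(rate_ff, 1, max),
    ttp_ff = times[apply(rate_ff, 1, which.max)]
  )
  structure(list(time = times, rate_kr = rate_kr, rate_ff = rate_ff,
                 peaks = peaks),
            class = "clamped_characterization")
}

#' @export
print.clamped_characterization <- function(x, ...) {
  cat("Clamped-Ca release characterization over",
      nrow(x$peaks), "levels\n")
  print(x$peaks, digits = 3)
  invisible(x)
}
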