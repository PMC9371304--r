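#' Amyloid-beta condition specification
#'
#' The two experimentally motivated amyloid-beta perturbations are pure
#' parameter transforms: enhanced mGluR signaling (half-activation halved,
#' maximal IP3 production doubled) and impaired PMCA function (backward
#' rate scaled so the pump's fitted Ca affinity falls by about 50%). The
#' four flag combinations map to the control / Abeta-mGluR / Abeta-PMCA /
#' combined conditions.
#'
#' @param mglur Apply the mGluR transform?
#' @param pmca Apply the PMCA transform?
#' @return Object of class `condition_spec`.
#' @export
#' @examples
#' condition_spec(mglur = TRUE)
condition_spec <- function(mglur = FALSE, pmca = FALSE) {
  structure(list(mglur = isTRUE(mglur), pmca = isTRUE(pmca)),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("condition:", condition_label(x), "\n")
  invisible(x)
}

#' @rdname condition_spec
#' @param x A `condition_spec`.
#' @export
condition_label <- function(x) {
  if (x$mglur && x$pmca) "both"
  else if (x$mglur) "mglur"
  else if (x$pmca) "pmca"
  else "control"
}

#' Apply an amyloid-beta condition to a parameter set
#'
#' mGluR flag: the half-activation agonist concentration is halved and the
#' maximal IP3 production rate doubled. PMCA flag: the backward reaction
#' rate is scaled by a factor found by a one-dimensional search so that the
#' Hill-fitted Ca affinity of the steady-state pump flux falls by 50%
#' relative to control (the experimental observation fixes the outcome, not
#' the factor). All other parameters are untouched. The transform is
#' guarded: applying a condition to already-transformed parameters is an
#' error.
#'
#' @param params Control `astro_params`.
#' @param spec A `condition_spec`.
#' @return Transformed `astro_params` with attribute `"abeta_condition"`.
#' @export
apply_condition <- function(params, spec) {
  stopifnot(inherits(params, "astro_params"), inherits(spec, "condition_spec"))
  prior <- attr(params, "abeta_condition")
  if (!is.null(prior) && prior != "control")
    stop("parameters already carry condition '", prior,
         "'; apply conditions to control parameters only")
  out <- params
  if (spec$mglur) {
    out$k_mglur <- out$k_mglur / 2
    out$v_mglur <- out$v_mglur * 2
  }
  if (spec$pmca) {
    ca_levels <- exp(seq(log(0.01), log(20), length.out = 12))
    kd0 <- fitted_pmca_affinity(params, ca_levels)
    fac <- stats::uniroot(function(s) {
      p2 <- params
      p2$pmca_kb <- p2$pmca_kb * s
      fitted_pmca_affinity(p2, ca_levels) / kd0 - 2
    }, interval = c(1.05, 8), tol = 1e-6)$root
    out$pmca_kb <- out$pmca_kb * fac
  }
  attr(out, "abeta_condition") <- condition_label(spec)
  out
}

fitted_pmca_affinity <- function(params, ca_levels) {
  dr <- pmca_dose_response(params, ca_levels)
  coef(fit_hill(dr$ca, dr$flux))[["kd"]]
}

#' Hill fit of a dose-response curve
#'
#' Least-squares fit of `y = Vmax * x^n / (x^n + kd^n)` with `Vmax`, `kd`
#' and `n` free, via Levenberg-Marquardt.
#'
#' @param x Dose or concentration values (uM), at least 4 points spanning
#'   the transition.
#' @param y Non-negative responses.
#' @return Object of class `hill_fit` with `coef` (Vmax, kd, n), the
#'   residual norm, and the underlying `nls` fit.
#' @export
#' @examples
#' x <- c(0.5, 1, 2, 4, 8, 16)
#' fit_hill(x, 10 * x^1.5 / (x^1.5 + 2^1.5))
fit_hill <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (any(y < 0)) stop("responses must be non-negative")
  if (diff(range(y)) <= max(1e-12, 1e-8 * max(abs(y))))
    stop("flat response: Hill parameters unidentifiable")
  vmax0 <- max(y)
  kd0 <- stats::approx(y, x, xout = vmax0 / 2, ties = "ordered")$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(x)
  fit <- minpack.lm::nlsLM(
    y ~ Vmax * x^n / (x^n + kd^n),
    start = list(Vmax = vmax0, kd = kd0, n = 1),
    lower = c(Vmax = 1e-12, kd = 1e-9, n = 0.05),
    control = minpack.lm::nls.lm.control(maxiter = 200),
    data = data.frame(x = x, y = y))
  cf <- stats::coef(fit)
  structure(list(coef = cf,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fit = fit),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coef

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: Vmax = %.4g, kd = %.4g uM, n = %.3g (resid %.3g)\n",
              x$coef[["Vmax"]], x$coef[["kd"]], x$coef[["n"]],
              x$residual_norm))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  cf <- object$coef
  if (is.null(newdata)) return(stats::fitted(object$fit))
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  cf[["Vmax"]] * x^cf[["n"]] / (x^cf[["n"]] + cf[["kd"]]^cf[["n"]])
}

#' DHPG dose-response of peak IP3
#'
#' Noise-free (mean-field) simulation of the standard agonist pulse at each
#' dose; the peak IP3 over the run is recorded. The curve is monotone
#' non-decreasing in dose; Hill-fitting it gives the operational
#' half-activation of the mGluR-to-IP3 pathway (halved under the
#' Abeta-mGluR condition, with peak production roughly doubled).
#'
#' @param params An `astro_params` object.
#' @param doses DHPG concentrations, uM, sorted ascending; a dose of 0
#'   returns the resting IP3.
#' @param pulse_s Pulse duration, s.
#' @param onset_s Pulse onset, s.
#' @param follow_s Extra simulated time after the pulse, s.
#' @return Data frame with columns `dose` and `peak_ip3` (uM).
#' @export
ip3_dose_response <- function(params, doses, pulse_s = 2, onset_s = 0.5,
                              follow_s = 2) {
  stopifnot(all(doses >= 0), !is.unsorted(doses))
  rest <- resting_state(params, sample_channels = FALSE)
  peak <- vapply(doses, function(d) {
    if (d == 0) return(rest$ip3)
    prot <- stimulus_protocol("agonist_pulse", agonist_uM = d,
                              onset_s = onset_s, duration_s = pulse_s)
    sol <- simulate_deterministic(params, prot,
                                  duration = onset_s + pulse_s + follow_s,
                                  init = rest, dt_out = 2e-3)
    max(sol$ip3)
  }, numeric(1))
  data.frame(dose = doses, peak_ip3 = peak)
}

#' Steady-state PMCA flux versus clamped cytosolic Ca
#'
#' The pump follows a one-site cycle with forward rate `pmca_kf * ca` and
#' backward rate `pmca_kb`, so the steady-state extrusion flux is
#' `v_pmca * kf * ca / (kf * ca + kb)` and the operational affinity is
#' `kb / kf`. Scaling the backward rate shifts the curve rightward
#' (affinity reduction) without changing the saturating flux.
#'
#' @param params An `astro_params` object.
#' @param ca_levels Positive clamped Ca concentrations, uM.
#' @return Data frame with columns `ca` and `flux` (uM/s).
#' @export
pmca_dose_response <- function(params, ca_levels) {
  stopifnot(all(ca_levels >= 0))
  flux <- params$v_pmca * params$pmca_kf * ca_levels /
    (params$pmca_kf * ca_levels + params$pmca_kb)
  data.frame(ca = ca_levels, flux = flux)
}
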