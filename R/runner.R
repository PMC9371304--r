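#' Simulation configuration
#'
#' Bundles everything a seeded batch needs: parameters, stimulus protocol,
#' amyloid-beta condition, trial count, base seed, step size and duration.
#' Per-trial random streams are derived as `base_seed + trial_index`, so a
#' batch is reproducible and trials are order-independent.
#'
#' @param params An `astro_params` object (control values; the condition is
#'   applied when the batch runs).
#' @param protocol A `stimulus_protocol`.
#' @param condition A `condition_spec`.
#' @param n_trials Number of independent trials (>= 1).
#' @param base_seed Integer root seed.
#' @param dt Integration step, s (5e-5 by default; fixed for the run).
#' @param duration Total simulated time, s; must exceed the stimulus
#'   extent. Defaults to the stimulus extent plus 1 s.
#' @param record_every Output decimation: one sample every this many steps
#'   (default 20, i.e. 1 ms at the default step).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(params, protocol,
                              condition = condition_spec(),
                              n_trials = 100, base_seed = 1,
                              dt = 5e-5, duration = NULL,
                              record_every = 20L) {
  stopifnot(inherits(params, "astro_params"),
            inherits(protocol, "stimulus_protocol"),
            inherits(condition, "condition_spec"),
            n_trials >= 1, dt > 0, record_every >= 1)
  extent <- protocol$onset_s + protocol$duration_s
  if (is.null(duration)) duration <- extent + 1
  if (duration <= extent)
    stop("duration must exceed the stimulus extent (", extent, " s)")
  structure(list(params = params, protocol = protocol,
                 condition = condition, n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed), dt = dt,
                 duration = duration,
                 record_every = as.integer(record_every)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation config: %d trials x %.3g s at dt = %g s, seed %d, condition %s\n",
    x$n_trials, x$duration, x$dt, x$base_seed, condition_label(x$condition)))
  print(x$protocol)
  invisible(x)
}

# effective parameters with the condition applied (no-op for control)
effective_params <- function(config) {
  if (config$condition$mglur || config$condition$pmca)
    apply_condition(config$params, config$condition)
  else config$params
}

#' Run a single seeded trial
#'
#' Deterministic given `(config, base_seed, trial_index)`: the trial seed
#' is `base_seed + trial_index`, and two runs produce bit-identical traces
#' and event logs. The compartment starts from the deterministic resting
#' state with IP3R subunits sampled from their stationary distribution, and
#' is stepped at `dt` with the stimulus and the release machinery coupled
#' to the instantaneous cytosolic Ca.
#'
#' @param config A `simulation_config`.
#' @param trial_index Trial number (>= 1).
#' @param rest Optional precomputed [resting_state()] for the effective
#'   parameters (avoids recomputing it per trial).
#' @param validate Validate the parameter set first?
#' @return Object of class `astro_trial`: `series` (data frame sampled
#'   every `record_every` steps: time, ca_cyt, ca_er, ip3, b_cyt, b_er,
#'   glu, n_open, docked, mobile, kr_endo, ff_endo), `release_events`
#'   (data frame time, mode in KR/FF), `seed`, `trial`, `n_clip` (zero
#'   clippings, warned about when non-zero) and `final` (end state).
#' @export
run_trial <- function(config, trial_index, rest = NULL, validate = TRUE) {
  stopifnot(inherits(config, "simulation_config"), trial_index >= 1)
  params <- effective_params(config)
  if (validate) validate_parameters(params)
  seed <- config$base_seed + as.integer(trial_index)
  if (is.null(rest)) rest <- resting_state(params, sample_channels = FALSE)
  set.seed(seed)
  subunits <- sample_ip3r_states(rest$ca_cyt, rest$ip3, params)
  prot <- config$protocol
  n_steps <- ceiling(config$duration / config$dt)
  if (prot$kind == "glutamate_train") {
    spikes <- spike_times(prot)  # poisson timing draws from the trial stream
    glu <- glutamate_grid(prot, n_steps, config$dt, spikes = spikes)
    dhpg <- 0; dhpg_on <- 0; dhpg_dur <- 0
  } else {
    glu <- rep(prot$glu_base, n_steps)
    dhpg <- prot$agonist_uM; dhpg_on <- prot$onset_s
    dhpg_dur <- prot$duration_s
  }
  out <- cpp_simulate_trial(
    params, glu, dhpg, dhpg_on, dhpg_dur, config$dt, n_steps,
    config$record_every,
    c(rest$ca_cyt, rest$ca_er, rest$ip3, rest$b_cyt, rest$b_er),
    subunits, 0, c(1, 0, 0, 0, 0, 0),
    c(as.integer(params$n_docked), as.integer(params$n_mobile), 0L, 0L),
    TRUE, TRUE, TRUE)
  if (out$n_clip > 0)
    warning("trial ", trial_index, ": ", out$n_clip,
            " zero-clipped concentration excursions")
  if (out$n_bigp > 0)
    warning("trial ", trial_index, ": ", out$n_bigp,
            " gating steps with transition probability > 0.1; dt too large")
  series <- data.frame(out[c("time", "ca_cyt", "ca_er", "ip3", "b_cyt",
                             "b_er", "glu", "n_open", "docked", "mobile",
                             "kr_endo", "ff_endo")])
  rel <- data.frame(time = out$rel_time,
                    mode = c("KR", "FF")[out$rel_mode],
                    stringsAsFactors = FALSE)
  structure(list(series = series, release_events = rel, seed = seed,
                 trial = trial_index, n_clip = out$n_clip,
                 final = out$final, condition = condition_label(config$condition)),
            class = "astro_trial")
}

#' @export
print.astro_trial <- function(x, ...) {
  cat(sprintf(
    "trial %d (seed %d, %s): %.3g s, %d release events (%d KR, %d FF)\n",
    x$trial, x$seed, x$condition, max(x$series$time),
    nrow(x$release_events), sum(x$release_events$mode == "KR"),
    sum(x$release_events$mode == "FF")))
  invisible(x)
}

#' @export
plot.astro_trial <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  s <- x$series
  graphics::plot(s$time, s$ca_cyt, type = "l", xlab = "time (s)",
                 ylab = expression(Ca^{"2+"} ~ "(uM)"), ...)
  graphics::abline(h = 0.3, lty = 3)
  graphics::plot(s$time, s$ip3, type = "l", xlab = "time (s)",
                 ylab = "IP3 (uM)")
  graphics::plot(s$time, s$docked, type = "s", ylim = c(0, max(s$docked,
                 s$mobile)), xlab = "time (s)", ylab = "vesicles")
  graphics::lines(s$time, s$mobile, type = "s", lty = 2)
  if (nrow(x$release_events))
    graphics::rug(x$release_events$time)
  graphics::legend("topright", legend = c("docked", "mobile"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Run a seeded batch of independent trials
#'
#' Executes `n_trials` independently seeded trials (seeds
#' `base_seed + 1 .. base_seed + n_trials`), detects Ca events in every
#' trial, and consolidates per-class event matrices together with mean
#' time series across trials. Trials are independent, so the consolidated
#' statistics do not depend on execution order. A failing trial is
#' reported and skipped without discarding completed trials.
#'
#' @param config A `simulation_config`.
#' @param keep_series Keep every trial's full time series? (memory-hungry;
#'   means are always kept).
#' @param threshold Ca event detection threshold, uM.
#' @param progress Print per-trial progress to stderr?
#' @return Object of class `astro_batch`: `config`, `ca_events`
#'   (`event_record` rows across trials), event matrices `ca_matrix`,
#'   `kr_matrix`, `ff_matrix`, `rel_matrix` (all release events),
#'   `mean_series` (trial-mean traces), `trial_seeds`, `failed` (indices),
#'   and a `provenance` list (config hash, seeds, package version).
#' @export
run_batch <- function(config, keep_series = FALSE, threshold = 0.3,
                      progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  params <- effective_params(config)
  validate_parameters(params)
  rest <- resting_state(params, sample_channels = FALSE)
  ca_list <- kr_list <- ff_list <- rel_list <- vector("list", config$n_trials)
  ev_list <- vector("list", config$n_trials)
  series_list <- if (keep_series) vector("list", config$n_trials) else NULL
  mean_acc <- NULL
  failed <- integer(0)
  n_ok <- 0L
  for (i in seq_len(config$n_trials)) {
    tr <- tryCatch(
      run_trial(config, i, rest = rest, validate = FALSE),
      error = function(e) {
        message("trial ", i, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(tr)) { failed <- c(failed, i); next }
    n_ok <- n_ok + 1L
    ev <- detect_ca_events(tr$series$ca_cyt, times = tr$series$time,
                           threshold = threshold, trial = i)
    ev_list[[i]] <- ev
    ca_list[[i]] <- ev$t_peak
    kr_list[[i]] <- tr$release_events$time[tr$release_events$mode == "KR"]
    ff_list[[i]] <- tr$release_events$time[tr$release_events$mode == "FF"]
    rel_list[[i]] <- tr$release_events$time
    num <- tr$series[setdiff(names(tr$series), "time")]
    mean_acc <- if (is.null(mean_acc)) num else mean_acc + num
    if (keep_series) series_list[[i]] <- tr$series
    if (progress) message("trial ", i, "/", config$n_trials, " done")
  }
  if (n_ok == 0) stop("all trials failed")
  tr_time <- seq(0, by = config$dt * config$record_every,
                 length.out = nrow(mean_acc))
  mean_series <- data.frame(time = tr_time, mean_acc / n_ok)
  freq <- if (config$protocol$kind == "glutamate_train")
    config$protocol$rate_hz else NA_real_
  ca_events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, TRUE)])
  prov <- list(config_hash = config_hash(config),
               base_seed = config$base_seed,
               trial_seeds = config$base_seed + seq_len(config$n_trials),
               condition = condition_label(config$condition),
               package_version = as.character(utils::packageVersion("gliosim")))
  structure(list(config = config, ca_events = ca_events,
                 ca_matrix = event_matrix(ca_list[!vapply(ca_list, is.null, TRUE)], freq),
                 kr_matrix = event_matrix(kr_list[!vapply(kr_list, is.null, TRUE)], freq),
                 ff_matrix = event_matrix(ff_list[!vapply(ff_list, is.null, TRUE)], freq),
                 rel_matrix = event_matrix(rel_list[!vapply(rel_list, is.null, TRUE)], freq),
                 mean_series = mean_series, rest = rest,
                 series = series_list, failed = failed,
                 provenance = prov),
            class = "astro_batch")
}

#' @export
print.astro_batch <- function(x, ...) {
  n <- length(x$ca_matrix)
  cat(sprintf(
    "batch of %d trials (%s): %d Ca events, %d KR + %d FF releases\n",
    n, x$provenance$condition,
    if (is.null(x$ca_events)) 0L else nrow(x$ca_events),
    sum(lengths(x$kr_matrix)), sum(lengths(x$ff_matrix))))
  invisible(x)
}

#' @export
summary.astro_batch <- function(object, ...) {
  ev <- object$ca_events
  n <- length(object$ca_matrix)
  dur <- object$config$duration
  out <- list(
    n_trials = n,
    condition = object$provenance$condition,
    ca_event_rate_hz = if (is.null(ev)) 0 else nrow(ev) / (n * dur),
    mean_amplitude_uM = if (is.null(ev) || !nrow(ev)) NA_real_
                        else mean(ev$amplitude),
    mean_rise_s = if (is.null(ev) || !nrow(ev)) NA_real_
                  else mean(ev$rise_s, na.rm = TRUE),
    mean_fwhm_s = if (is.null(ev) || !nrow(ev)) NA_real_
                  else mean(ev$fwhm_s, na.rm = TRUE),
    mean_decay_s = if (is.null(ev) || !nrow(ev)) NA_real_
                   else mean(ev$decay_s, na.rm = TRUE),
    kr_per_trial = sum(lengths(object$kr_matrix)) / n,
    ff_per_trial = sum(lengths(object$ff_matrix)) / n)
  class(out) <- "summary.astro_batch"
  out
}

#' @export
print.summary.astro_batch <- function(x, ...) {
  cat(sprintf("condition %s, %d trials\n", x$condition, x$n_trials))
  cat(sprintf("  Ca events: %.3g /s, amplitude %.3g uM, rise %.3g s, fwhm %.3g s, decay %.3g s\n",
              x$ca_event_rate_hz, x$mean_amplitude_uM, x$mean_rise_s,
              x$mean_fwhm_s, x$mean_decay_s))
  cat(sprintf("  releases per trial: %.3g KR, %.3g FF\n",
              x$kr_per_trial, x$ff_per_trial))
  invisible(x)
}

# small stable FNV-1a hash of the configuration (no external digest
# dependency; provenance only, not cryptographic)
config_hash <- function(config) {
  txt <- paste(deparse(list(unclass(config$params),
                            unclass(config$protocol),
                            unclass(config$condition),
                            config$n_trials, config$base_seed, config$dt,
                            config$duration, config$record_every)),
               collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor and multiply in 16-bit halves: every intermediate stays exact
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    lo_p <- lo * 16777619
    hi_p <- (hi * 16777619) %% 65536
    h <- (hi_p * 65536 + lo_p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Export batch results to plain-text files
#'
#' Writes `release_events.csv` (trial, time_s, mode), `ca_events.csv`
#' (trial, time_s, amplitude_uM, rise_s, fwhm_s, decay_s),
#' `mean_series.csv` and `summary.json` (provenance: config hash, seeds,
#' condition, protocol, package version) into `dir`. The round trip
#' through [import_results()] reproduces the in-memory event matrices
#' exactly.
#'
#' @param batch An `astro_batch`.
#' @param dir Output directory (created if needed).
#' @param format Output format; `"csv"` is supported.
#' @return `dir`, invisibly.
#' @export
export_results <- function(batch, dir, format = "csv") {
  stopifnot(inherits(batch, "astro_batch"))
  if (!identical(format, "csv"))
    stop("unsupported format '", format, "'; supported formats: csv")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rel <- data.frame(
    trial = rep(seq_along(batch$kr_matrix),
                lengths(batch$kr_matrix) + lengths(batch$ff_matrix)),
    time_s = unlist(mapply(c, batch$kr_matrix, batch$ff_matrix,
                           SIMPLIFY = FALSE)),
    mode = unlist(mapply(function(a, b) c(rep("KR", length(a)),
                                          rep("FF", length(b))),
                         batch$kr_matrix, batch$ff_matrix,
                         SIMPLIFY = FALSE)))
  utils::write.csv(rel, file.path(dir, "release_events.csv"),
                   row.names = FALSE)
  ev <- batch$ca_events
  if (is.null(ev)) {
    ev <- data.frame(trial = integer(0), t_peak = numeric(0),
                     amplitude = numeric(0), rise_s = numeric(0),
                     fwhm_s = numeric(0), decay_s = numeric(0),
                     class = character(0))
  }
  utils::write.csv(as.data.frame(ev), file.path(dir, "ca_events.csv"),
                   row.names = FALSE)
  utils::write.csv(batch$mean_series, file.path(dir, "mean_series.csv"),
                   row.names = FALSE)
  prov <- batch$provenance
  prov$n_trials <- length(batch$ca_matrix)
  prov$duration_s <- batch$config$duration
  prov$dt_s <- batch$config$dt
  prov$protocol <- unclass(batch$config$protocol)
  jsonlite::write_json(prov, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname export_results
#' @return `import_results()` returns a list with `kr_matrix`,
#'   `ff_matrix`, `rel_matrix`, `ca_matrix` and the provenance list.
#' @export
import_results <- function(dir) {
  rel <- utils::read.csv(file.path(dir, "release_events.csv"),
                         stringsAsFactors = FALSE)
  ca <- utils::read.csv(file.path(dir, "ca_events.csv"),
                        stringsAsFactors = FALSE)
  prov <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  n <- prov$n_trials
  split_times <- function(df, keep, col) {
    d <- df[keep, , drop = FALSE]
    lapply(seq_len(n), function(i) sort(d[[col]][d$trial == i]))
  }
  list(kr_matrix = event_matrix(split_times(rel, rel$mode == "KR", "time_s")),
       ff_matrix = event_matrix(split_times(rel, rel$mode == "FF", "time_s")),
       rel_matrix = event_matrix(split_times(rel, rep(TRUE, nrow(rel)),
                                             "time_s")),
       ca_matrix = event_matrix(lapply(seq_len(n), function(i)
         sort(ca$t_peak[ca$trial == i]))),
       provenance = prov)
}
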