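#' Event matrix (events x trials)
#'
#' Ordered per-trial event-time lists with an optional stimulation
#' frequency label.
#'
#' @param times_list List of numeric vectors, one per trial; each is sorted
#'   internally.
#' @param freq_hz Stimulation frequency label, Hz.
#' @return Object of class `event_matrix`.
#' @export
event_matrix <- function(times_list, freq_hz = NA_real_) {
  stopifnot(is.list(times_list))
  times_list <- lapply(times_list, function(v) sort(as.numeric(v)))
  structure(times_list, freq_hz = freq_hz, class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  n_ev <- vapply(x, length, 0L)
  cat(sprintf("event matrix: %d trials, %d events total", length(x),
              sum(n_ev)))
  if (!is.na(attr(x, "freq_hz")))
    cat(sprintf(" (stimulation %g Hz)", attr(x, "freq_hz")))
  cat("\n")
  invisible(x)
}

#' Pinsky-Rinzel synchrony of event times across trials
#'
#' For every reference event (each event time `t0` of each trial) and
#' inter-event order `m`, the vector of inter-event intervals from the
#' reference to the `m`-th following event of every trial is computed and
#' normalized by the reference trial's own `m`-spanning interval (the
#' maximum, interval-defining element of the vector):
#' `phi_j = (t_j^{(m)} - t0) / (t0^{(m)} - t0)`. The phases are projected
#' to the complex plane, `Z = exp(2*pi*i*phi)`, and synchrony is
#' `s = 1 - Var(Z)` with `Var(Z)` the circular variance
#' `mean(|Z - mean(Z)|^2) = 1 - |mean(Z)|^2`, so `s` is the squared
#' resultant length across trials. Perfectly aligned trains give `phi = 1`
#' for every trial and `s = 1`; for completely random trains the ratios
#' decohere around the circle and `s` is near 0 at every order. Values are
#' averaged over reference events per order.
#'
#' The `"within_trial"` mode is the alternative reading of the recipe: the
#' `m`-spaced intervals are formed within each trial at the same event
#' index and normalized by the maximum across trials.
#'
#' @param mat An `event_matrix` with at least 2 trials of at least 2 events.
#' @param max_order Largest inter-event order `m` evaluated.
#' @param mode `"pooled"` (default) or `"within_trial"`.
#' @return Object of class `synchrony_result`: data frame with columns
#'   `order`, `s` (in [0, 1] or `NA` when undefined) and `n_ref`, plus the
#'   grand mean as attribute `"s_mean"` and the frequency label.
#' @export
pinsky_rinzel_synchrony <- function(mat, max_order = 10,
                                    mode = c("pooled", "within_trial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "event_matrix"))
  n_trials <- length(mat)
  if (n_trials < 2 || sum(vapply(mat, length, 0L) >= 2) < 2)
    stop("need at least 2 trials with at least 2 events each")
  acc <- matrix(0, max_order, 2)  # sum of s, count
  if (mode == "pooled") {
    for (j0 in seq_len(n_trials)) {
      tj <- mat[[j0]]
      for (k in seq_along(tj)) {
        t0 <- tj[k]
        for (m in seq_len(max_order)) {
          if (k + m > length(tj)) break
          L <- tj[k + m] - t0
          if (L <= 0) next
          phi <- vapply(seq_len(n_trials), function(j) {
            after <- mat[[j]][mat[[j]] > t0]
            if (length(after) < m) return(NA_real_)
            (after[m] - t0) / L
          }, numeric(1))
          phi <- phi[!is.na(phi)]
          if (length(phi) < 2) next
          z <- exp(2i * pi * phi)
          s <- Mod(mean(z))^2
          acc[m, 1] <- acc[m, 1] + s
          acc[m, 2] <- acc[m, 2] + 1
        }
      }
    }
  } else {
    n_ev <- vapply(mat, length, 0L)
    for (k in seq_len(max(n_ev) - 1L)) {
      for (m in seq_len(max_order)) {
        iv <- vapply(seq_len(n_trials), function(j) {
          tn <- mat[[j]]
          if (k + m > length(tn)) return(NA_real_)
          tn[k + m] - tn[k]
        }, numeric(1))
        iv <- iv[!is.na(iv) & iv > 0]
        if (length(iv) < 2) next
        phi <- iv / max(iv)
        z <- exp(2i * pi * phi)
        s <- Mod(mean(z))^2
        acc[m, 1] <- acc[m, 1] + s
        acc[m, 2] <- acc[m, 2] + 1
      }
    }
  }
  s_vals <- ifelse(acc[, 2] > 0, acc[, 1] / acc[, 2], NA_real_)
  out <- data.frame(order = seq_len(max_order), s = s_vals,
                    n_ref = acc[, 2])
  attr(out, "s_mean") <- mean(s_vals, na.rm = TRUE)
  attr(out, "freq_hz") <- attr(mat, "freq_hz")
  class(out) <- c("synchrony_result", "data.frame")
  out
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("Pinsky-Rinzel synchrony: mean s = %.3f over %d orders\n",
              attr(x, "s_mean"), nrow(x)))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Cross-correlation of two event trains via the joint PSTH
#'
#' Bins both event matrices on the stimulation-aligned window, forms the
#' shuffle-corrected (trial-mean subtracted) joint peristimulus time
#' histogram normalized by the bin-wise standard deviations, and reads the
#' correlation profile along the diagonal band of lags within the fixed
#' window. The peak over the analysis duration is returned: 1 for
#' identical trains, about 0 for independent ones.
#'
#' @param ca_events,rel_events `event_matrix` objects with matched trial
#'   counts.
#' @param window Maximum lag, s.
#' @param duration Analysis duration from `t0`, s.
#' @param bin Bin width, s (default `window / 10`).
#' @param t0 Window start (stimulation onset), s.
#' @return List of class `jpsth_result`: `peak` (peak diagonal
#'   correlation), `peak_lag_s`, `lags_s`, `profile` (mean normalized
#'   correlation per lag) and `n_trials`.
#' @export
jpsth_cross_correlation <- function(ca_events, rel_events, window = 0.1,
                                    duration = 11, bin = window / 10,
                                    t0 = 0) {
  stopifnot(inherits(ca_events, "event_matrix"),
            inherits(rel_events, "event_matrix"))
  n_trials <- length(ca_events)
  if (length(rel_events) != n_trials)
    stop("trial counts differ between the two event matrices")
  if (sum(vapply(ca_events, length, 0L)) == 0 ||
      sum(vapply(rel_events, length, 0L)) == 0)
    stop("empty event set: cross-correlation undefined")
  edges <- seq(t0, t0 + duration, by = bin)
  nb <- length(edges) - 1L
  count_mat <- function(mat) {
    t(vapply(mat, function(tt) {
      tt <- tt[tt >= t0 & tt < t0 + duration]
      tabulate(findInterval(tt, edges, rightmost.closed = FALSE),
               nbins = nb)
    }, numeric(nb)))
  }
  n1 <- count_mat(ca_events)
  n2 <- count_mat(rel_events)
  m1 <- colMeans(n1); m2 <- colMeans(n2)
  v1 <- apply(n1, 2, stats::var) * (n_trials - 1) / n_trials
  v2 <- apply(n2, 2, stats::var) * (n_trials - 1) / n_trials
  w <- round(window / bin)
  lags <- -w:w
  profile <- vapply(lags, function(d) {
    u <- seq_len(nb)
    v <- u + d
    ok <- v >= 1 & v <= nb
    u <- u[ok]; v <- v[ok]
    raw <- colMeans(n1[, u, drop = FALSE] * n2[, v, drop = FALSE])
    num <- raw - m1[u] * m2[v]
    den <- sqrt(v1[u] * v2[v])
    good <- den > 0
    if (!any(good)) return(NA_real_)
    mean(num[good] / den[good])
  }, numeric(1))
  peak_i <- which.max(profile)
  structure(list(peak = profile[peak_i],
                 peak_lag_s = lags[peak_i] * bin,
                 lags_s = lags * bin, profile = profile,
                 n_trials = n_trials),
            class = "jpsth_result")
}

#' @export
print.jpsth_result <- function(x, ...) {
  cat(sprintf(
    "JPSTH cross-correlation: peak %.3f at lag %g ms (%d trials)\n",
    x$peak, 1000 * x$peak_lag_s, x$n_trials))
  invisible(x)
}

#' Bootstrap standard error of a statistic
#'
#' Standard deviation of the statistic over resamples drawn with
#' replacement (uses the current R random-number stream).
#'
#' @param samples Non-empty numeric vector (or list) of per-trial values.
#' @param statistic Function applied to each resample (default `mean`).
#' @param n_boot Number of resamples.
#' @param sample_size Size of each resample; defaults to `length(samples)`.
#' @return The bootstrap s.e. (0, with a warning, when `n_boot = 1`).
#' @export
bootstrap_sem <- function(samples, statistic = mean, n_boot = 100,
                          sample_size = NULL) {
  n <- length(samples)
  if (n == 0) stop("samples must be non-empty")
  if (is.null(sample_size)) sample_size <- n
  stats_v <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, sample_size, replace = TRUE)
    statistic(if (is.list(samples)) unlist(samples[idx]) else samples[idx])
  }, numeric(1))
  if (n_boot == 1) {
    warning("n_boot = 1: bootstrap s.e. is degenerate (0)")
    return(0)
  }
  stats::sd(stats_v)
}
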