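#' Detect calcium events in a trace
#'
#' Finds local maxima whose peak value crosses the detection threshold
#' (300 nM by default, the physiological minimum for evoking glutamate
#' release from astrocytes), measures the full width at half
#' prominence-referenced height with linear interpolation between samples,
#' and measures rise (20% to 80% of the peak deflection) and decay (peak to
#' 36.8% of the deflection) times. Overlapping events are split at the
#' minimum between peaks.
#'
#' @param trace Uniformly sampled Ca concentrations, uM (at least 3
#'   samples).
#' @param times Sample times, s; alternatively give `dt`.
#' @param dt Sampling interval, s (used when `times` is `NULL`).
#' @param threshold Peak detection threshold, uM.
#' @param min_prominence Minimum peak prominence, uM (default half the
#'   threshold): stochastic channel flicker riding on a large event is not
#'   counted as separate events; an event must rise this far above its
#'   surroundings.
#' @param trial Trial index stored with each event.
#' @return Data frame of class `event_record` with columns `trial`,
#'   `t_peak` (s), `amplitude` (peak value, uM), `rise_s`, `fwhm_s`,
#'   `decay_s` (s; `NA` when the corresponding crossing is unresolved) and
#'   `class` (`"Ca"`).
#' @export
detect_ca_events <- function(trace, times = NULL, dt = NULL,
                             threshold = 0.3,
                             min_prominence = threshold / 2,
                             trial = NA_integer_) {
  if (length(trace) < 3) stop("trace must contain at least 3 samples")
  if (is.null(times)) {
    if (is.null(dt)) stop("supply either times or dt")
    times <- (seq_along(trace) - 1) * dt
  }
  peaks <- find_peaks(trace)
  peaks <- peaks[trace[peaks] >= threshold]
  empty <- data.frame(trial = integer(0), t_peak = numeric(0),
                      amplitude = numeric(0), rise_s = numeric(0),
                      fwhm_s = numeric(0), decay_s = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("event_record", "data.frame")
  if (length(peaks) == 0) return(empty)

  prom <- peak_prominences(trace, peaks)
  keep <- prom$prominence >= min_prominence
  peaks <- peaks[keep]
  prom <- lapply(prom, `[`, keep)
  if (length(peaks) == 0) return(empty)
  # segment boundaries: split overlapping events at the minimum between
  # adjacent detected peaks, otherwise use the prominence bases
  lb <- prom$left_base
  rb <- prom$right_base
  if (length(peaks) > 1) {
    for (i in seq_len(length(peaks) - 1)) {
      valley <- peaks[i] + which.min(trace[peaks[i]:peaks[i + 1]]) - 1L
      rb[i] <- min(rb[i], valley)
      lb[i + 1] <- max(lb[i + 1], valley)
    }
  }
  rows <- lapply(seq_along(peaks), function(i) {
    w <- peak_width(trace, times, peaks[i], prom$prominence[i],
                    prom$left_base[i], prom$right_base[i])
    kin <- event_kinetics(trace, times, peaks[i], lb[i], rb[i])
    data.frame(trial = trial, t_peak = times[peaks[i]],
               amplitude = trace[peaks[i]], rise_s = kin[["rise_s"]],
               fwhm_s = w, decay_s = kin[["decay_s"]], class = "Ca",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("event_record", "data.frame")
  out
}

# strict local maxima; flat-topped peaks contribute their middle sample
find_peaks <- function(y) {
  n <- length(y)
  d <- diff(y)
  # positions where the derivative sign changes + -> - across a
  # possibly-flat top
  s <- sign(d)
  idx <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (s[i] > 0) {
      j <- i + 1L
      while (j <= n - 1L && s[j] == 0) j <- j + 1L
      if (j <= n - 1L && s[j] < 0) {
        # peak samples run from i+1 to j; take the middle of a flat top
        idx <- c(idx, i + (j - i + 1L) %/% 2L)
      }
      i <- j
    } else i <- i + 1L
  }
  idx + 0L
}

# prominence of each peak: height above the higher of the two base minima,
# where each base is the minimum between the peak and the nearest
# higher-or-equal point (or the trace end) on that side
peak_prominences <- function(y, peaks) {
  prom <- numeric(length(peaks))
  lb <- rb <- integer(length(peaks))
  for (pi in seq_along(peaks)) {
    p <- peaks[pi]
    h <- y[p]
    j <- p; lmin <- p
    while (j > 1L && y[j - 1L] <= h) {
      j <- j - 1L
      if (y[j] < y[lmin]) lmin <- j
    }
    j <- p; rmin <- p
    while (j < length(y) && y[j + 1L] <= h) {
      j <- j + 1L
      if (y[j] < y[rmin]) rmin <- j
    }
    prom[pi] <- h - max(y[lmin], y[rmin])
    lb[pi] <- lmin; rb[pi] <- rmin
  }
  list(prominence = prom, left_base = lb, right_base = rb)
}

# full width at the prominence-referenced half height, with linear
# interpolation between samples, bounded by the peak's bases
peak_width <- function(y, x, p, prominence, lb, rb) {
  h <- y[p] - 0.5 * prominence
  xl <- x[lb]
  for (j in seq(p, lb)) {
    if (y[j] < h) {
      xl <- x[j] + (x[j + 1L] - x[j]) * (h - y[j]) / (y[j + 1L] - y[j])
      break
    }
  }
  xr <- x[rb]
  for (j in seq(p, rb)) {
    if (y[j] < h) {
      xr <- x[j - 1L] + (x[j] - x[j - 1L]) * (y[j - 1L] - h) / (y[j - 1L] - y[j])
      break
    }
  }
  xr - xl
}

#' Rise and decay times of a single event
#'
#' Rise time is the time between the 20% and 80% crossings of the peak
#' deflection on the ascending limb; decay time is the time from the peak
#' to the 36.8% crossing on the descending limb (the e-fold point, so an
#' ideal exponential decay returns its time constant). Deflections are
#' measured above the local baseline, the minimum of the event segment.
#' Crossings are located by linear interpolation; if a crossing is not
#' contained in the segment the corresponding value is `NA` (the event is
#' unresolved and excluded from kinetic averages).
#'
#' @param trace Ca trace, uM.
#' @param times Sample times, s.
#' @param peak Index of the peak sample.
#' @param left,right Indices bounding the event segment.
#' @return Named vector `c(rise_s = , decay_s = )`.
#' @export
event_kinetics <- function(trace, times, peak, left = 1L,
                           right = length(trace)) {
  stopifnot(peak >= left, peak <= right)
  base <- min(trace[left:right])
  amp <- trace[peak] - base
  if (amp <= 0) return(c(rise_s = NA_real_, decay_s = NA_real_))
  cross_up <- function(level) {
    # last upward crossing of `level` before the peak
    seg <- left:peak
    below <- which(trace[seg] < level)
    if (length(below) == 0 || max(below) == length(seg)) return(NA_real_)
    j <- seg[max(below)]
    times[j] + (times[j + 1L] - times[j]) *
      (level - trace[j]) / (trace[j + 1L] - trace[j])
  }
  cross_down <- function(level) {
    seg <- peak:right
    below <- which(trace[seg] < level)
    if (length(below) == 0) return(NA_real_)
    j <- seg[min(below)]
    times[j - 1L] + (times[j] - times[j - 1L]) *
      (trace[j - 1L] - level) / (trace[j - 1L] - trace[j])
  }
  t20 <- cross_up(base + 0.2 * amp)
  t80 <- cross_up(base + 0.8 * amp)
  t_decay <- cross_down(base + exp(-1) * amp)
  c(rise_s = t80 - t20, decay_s = t_decay - times[peak])
}

#' Percentage calcium response
#'
#' Ratio of the area under the Ca trace during the stimulation window to
#' the area during the equally long pre-stimulus window (trapezoidal
#' integration): `r = int[t0, t0+t_stim] Ca dt / int[t0-t_stim, t0] Ca dt`.
#' Multiplied by 100 this is the percentage response. The ratio is
#' invariant under uniform rescaling of the trace and equals 1 for a
#' constant trace.
#'
#' @param trace Ca trace, uM.
#' @param times Sample times, s; must cover `[t0 - t_stim, t0 + t_stim]`.
#' @param t0 Stimulation onset, s.
#' @param t_stim Stimulation duration, s.
#' @return The ratio `r` (dimensionless; multiply by 100 for percent).
#' @export
percent_response <- function(trace, times, t0, t_stim) {
  if (min(times) > t0 - t_stim || max(times) < t0 + t_stim)
    stop("trace must cover [t0 - t_stim, t0 + t_stim]")
  pre <- trapz_window(trace, times, t0 - t_stim, t0)
  post <- trapz_window(trace, times, t0, t0 + t_stim)
  if (pre <= 0) stop("pre-stimulus integral is zero; ratio undefined")
  post / pre
}

trapz_window <- function(y, x, a, b) {
  ya <- stats::approx(x, y, xout = a, ties = "ordered")$y
  yb <- stats::approx(x, y, xout = b, ties = "ordered")$y
  inside <- x > a & x < b
  xs <- c(a, x[inside], b)
  ys <- c(ya, y[inside], yb)
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}
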