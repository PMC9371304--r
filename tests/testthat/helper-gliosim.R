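# shared fixtures: default parameters are loaded once; short-trial helper
# keeps stochastic tests cheap.

params_default <- astro_parameters()

rest_default <- local({
  set.seed(1)
  resting_state(params_default, sample_channels = FALSE, tol = 1e-5)
})

# run a short seeded trial with the default parameters
short_trial <- function(protocol, duration, seed = 1, params = params_default,
                        rest = NULL, trial = 1) {
  if (is.null(rest) && identical(params, params_default)) rest <- rest_default
  cfg <- simulation_config(params, protocol, n_trials = 1, base_seed = seed,
                           duration = duration)
  suppressWarnings(run_trial(cfg, trial, rest = rest, validate = FALSE))
}

# independent straight-line construction of the subunit generator, used as
# an oracle against the package's rate matrix
oracle_subunit_Q <- function(ca, ip3, p) {
  b <- c(p$ip3r_a1 * p$ip3r_d1, p$ip3r_a2 * p$ip3r_d2, p$ip3r_a3 * p$ip3r_d3,
         p$ip3r_a4 * p$ip3r_d4, p$ip3r_a5 * p$ip3r_d5)
  Q <- matrix(0, 8, 8)
  for (s in 0:7) {
    i <- s %/% 4; j <- (s %/% 2) %% 2; k <- s %% 2
    # IP3 site
    if (i == 0) Q[s + 1, s + 5] <- ip3 * (if (k == 0) p$ip3r_a1 else p$ip3r_a3)
    else        Q[s + 1, s - 3] <- if (k == 0) b[1] else b[3]
    # activating Ca site
    if (j == 0) Q[s + 1, s + 3] <- ca * p$ip3r_a5
    else        Q[s + 1, s - 1] <- b[5]
    # inhibitory Ca site
    if (k == 0) Q[s + 1, s + 2] <- ca * (if (i == 1) p$ip3r_a2 else p$ip3r_a4)
    else        Q[s + 1, s    ] <- if (i == 1) b[2] else b[4]
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# independent generator of the Syt7 chain for the matrix-exponential oracle
oracle_syt7_Q <- function(ca, p) {
  n <- p$syt7_sites
  Q <- matrix(0, n + 1, n + 1)
  for (i in 0:(n - 1)) Q[i + 1, i + 2] <- (n - i) * p$syt7_kon * ca
  for (i in 1:n) Q[i + 1, i] <- i * p$syt7_koff * p$syt7_b^(i - 1)
  diag(Q) <- -rowSums(Q)
  Q
}

# brute-force synchrony oracle sharing the documented reading of the recipe
# (intervals from each reference event to the m-th following event in every
# trial, normalized by the reference trial's m-spanning interval): loops
# only, no vectorized shortcuts
oracle_synchrony <- function(times_list, max_order) {
  n_trials <- length(times_list)
  s_sum <- s_n <- numeric(max_order)
  for (j0 in seq_len(n_trials)) {
    tj <- times_list[[j0]]
    for (k in seq_along(tj)) {
      for (m in seq_len(max_order)) {
        if (k + m > length(tj)) next
        L <- tj[k + m] - tj[k]
        if (L <= 0) next
        phis <- c()
        for (j in seq_len(n_trials)) {
          after <- c()
          for (tt in times_list[[j]]) if (tt > tj[k]) after <- c(after, tt)
          if (length(after) < m) next
          phis <- c(phis, (after[m] - tj[k]) / L)
        }
        if (length(phis) < 2) next
        zr <- mean(cos(2 * pi * phis))
        zi <- mean(sin(2 * pi * phis))
        s_sum[m] <- s_sum[m] + zr^2 + zi^2
        s_n[m] <- s_n[m] + 1
      }
    }
  }
  ifelse(s_n > 0, s_sum / s_n, NA_real_)
}
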