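test_that("subunit rate matrix matches an independent construction", {
  p <- params_default
  for (cc in list(c(0.05, 0.01), c(0.3, 0.3), c(5, 1))) {
    Q <- ip3r_rate_matrix(cc[1], cc[2], p)
    expect_equal(unname(Q), oracle_subunit_Q(cc[1], cc[2], p),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(Q)), rep(0, 8), tolerance = 1e-10)
  }
})

test_that("stationary distribution solves the balance equations and is a pmf", {
  p <- params_default
  pi <- ip3r_stationary(0.3, 0.3, p)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_true(all(pi >= 0))
  expect_equal(as.numeric(pi %*% ip3r_rate_matrix(0.3, 0.3, p)),
               rep(0, 8), tolerance = 1e-10)
})

test_that("empirical gating occupancy converges to the analytic stationary law", {
  p <- params_default
  ca <- 0.3; ip3 <- 0.3
  pi <- ip3r_stationary(ca, ip3, p)
  set.seed(7)
  init <- sample(0:7, 30, replace = TRUE, prob = pi)
  counts <- gliosim:::cpp_gate_clamped(p, ca, ip3, 2e6, 2e-4, init)
  emp <- counts / sum(counts)
  tv <- 0.5 * sum(abs(emp - pi))
  expect_lt(tv, 0.02)
})

test_that("unliganded relaxation empties all binding sites", {
  p <- params_default
  st <- compartment_state(0, 0, 0, 0, 0, 0,
                          subunits = rep(6L, p$n_ip3r * p$n_subunits))
  set.seed(1)
  for (i in 1:16000) st <- ip3r_transition_step(st, p, 5e-4)
  expect_true(all(st$subunits == 0L))
})

test_that("per-step gating probabilities above 0.1 are rejected", {
  p <- params_default
  st <- compartment_state(0, 10, 100, 10, 0, 0,
                          subunits = rep(0L, p$n_ip3r * p$n_subunits))
  expect_error(ip3r_transition_step(st, p, 0.01), "dt too large")
})

test_that("pump fluxes vanish with nothing to pump and reject bad input", {
  p <- params_default
  st <- compartment_state(0, 0, 400, 0.02, 0, 600)
  ft <- flux_terms(st, p)
  expect_equal(ft$fluxes[["pmca"]], 0)
  expect_equal(ft$fluxes[["serca"]], 0)
  bad <- compartment_state(0, 0.1, 400, 0.02, 0, 600)
  bad$ca_cyt <- -1
  expect_error(flux_terms(bad, p), "negative")
})

test_that("the resting state is a fixed point of the deterministic fluxes", {
  p <- params_default
  rest <- rest_default
  pi <- attr(rest, "stationary")
  n_open_mean <- p$n_ip3r * pi[7]^p$n_subunits
  ft <- flux_terms(rest, p, n_open = n_open_mean)
  rel <- abs(ft$deriv) / pmax(abs(c(rest$ca_cyt, rest$ca_er, rest$ip3,
                                    rest$b_cyt, rest$b_er)), 1e-3)
  expect_lt(max(rel), 1e-4)
  # control rest sits below the 300 nM event threshold
  expect_lt(rest$ca_cyt, 0.3)
  # mean-field run of 10 s drifts < 1% in every variable
  sol <- simulate_deterministic(p, NULL, duration = 10, init = rest,
                                dt_out = 1)
  first <- unlist(sol[1, c("ca_cyt", "ca_er", "ip3", "b_cyt", "b_er")])
  last <- unlist(sol[nrow(sol), c("ca_cyt", "ca_er", "ip3", "b_cyt", "b_er")])
  expect_true(all(abs(last - first) / first < 0.01))
})

test_that("with all fluxes disabled any state is returned unchanged", {
  p <- astro_parameters(v_ip3r = 1e-300, v_er_leak = 1e-300,
                        v_serca = 1e-300, v_pmca = 1e-300, v_pm_leak = 0,
                        v_mglur = 1e-300, v_plcd = 1e-300, k_5p = 1e-300,
                        v_3k = 1e-300, kon_cyt = 1e-300, koff_cyt = 1e-300,
                        kon_er = 1e-300, koff_er = 1e-300)
  init <- compartment_state(0, 0.25, 0.25, 0.07, 1, 2)
  out <- resting_state(p, init = init, t_relax = 5, sample_channels = FALSE)
  expect_equal(out$ca_cyt, init$ca_cyt, tolerance = 1e-9)
  expect_equal(out$ca_er, init$ca_er, tolerance = 1e-9)
  expect_equal(out$ip3, init$ip3, tolerance = 1e-9)
})

test_that("Abeta-PMCA raises both resting cytosolic and ER calcium", {
  pb <- apply_condition(params_default, condition_spec(pmca = TRUE))
  rb <- resting_state(pb, sample_channels = FALSE, tol = 1e-5)
  expect_gt(rb$ca_cyt, rest_default$ca_cyt)
  expect_gt(rb$ca_er, rest_default$ca_er)
})

test_that("fixed-step deterministic peak IP3 matches the adaptive reference", {
  p <- params_default
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 0.2,
                            duration_s = 2)
  ref <- simulate_deterministic(p, prot, duration = 3, init = rest_default,
                                method = "lsoda", dt_out = 2e-3)
  fix <- simulate_deterministic(p, prot, duration = 3, init = rest_default,
                                method = "euler", dt = 5e-5, dt_out = 2e-3)
  expect_lt(abs(max(fix$ip3) - max(ref$ip3)) / max(ref$ip3), 0.01)
})

test_that("peak IP3 is non-decreasing in the clamped agonist dose", {
  dr <- ip3_dose_response(params_default, c(5, 20, 60, 150, 400),
                          pulse_s = 2, follow_s = 1)
  expect_true(all(diff(dr$peak_ip3) >= -1e-9))
})

test_that("total calcium is conserved when membrane fluxes are off", {
  p <- params_default
  rest <- rest_default
  set.seed(3)
  sub <- sample_ip3r_states(rest$ca_cyt, rest$ip3, p)
  out <- gliosim:::cpp_simulate_trial(
    p, rep(0, 40000), 100, 0.2, 1.5, 5e-5, 40000, 20,
    c(rest$ca_cyt, rest$ca_er, rest$ip3, rest$b_cyt, rest$b_er),
    sub, 0, c(1, 0, 0, 0, 0, 0), c(9L, 16L, 0L, 0L),
    TRUE, FALSE, FALSE)  # stochastic gating, membrane off, release off
  expect_equal(out$n_clip, 0)
  r <- p$er_cyt_ratio
  total <- out$ca_cyt + out$b_cyt + r * (out$ca_er + out$b_er)
  expect_lt(diff(range(total)) / total[1], 1e-6)
})

test_that("compiled and R flux arithmetic agree with channels frozen", {
  p <- params_default
  rest <- rest_default
  n <- 400
  out <- gliosim:::cpp_simulate_trial(
    p, rep(0, n), 50, 0.002, 1, 5e-5, n, 1,
    c(rest$ca_cyt, rest$ca_er, rest$ip3, rest$b_cyt, rest$b_er),
    rep(0L, p$n_ip3r * p$n_subunits), 0, c(1, 0, 0, 0, 0, 0),
    c(9L, 16L, 0L, 0L), FALSE, TRUE, FALSE)
  y <- c(rest$ca_cyt, rest$ca_er, rest$ip3, rest$b_cyt, rest$b_er)
  for (s in seq_len(n)) {
    t <- (s - 1) * 5e-5
    ag <- if (t >= 0.002 && t < 1.002) 50 else 0
    st <- compartment_state(t, y[1], y[2], y[3], y[4], y[5])
    y <- y + 5e-5 * flux_terms(st, p, glu = 0, agonist = ag, n_open = 0)$deriv
  }
  expect_equal(out$ca_cyt[n + 1], unname(y[1]), tolerance = 1e-12)
  expect_equal(out$ca_er[n + 1], unname(y[2]), tolerance = 1e-12)
  expect_equal(out$ip3[n + 1], unname(y[3]), tolerance = 1e-12)
})

test_that("suprathreshold events concentrate inside the DHPG window", {
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 0.5,
                            duration_s = 2)
  n_in <- n_out <- 0
  for (seed in 1:4) {
    tr <- short_trial(prot, duration = 6, seed = seed, trial = seed)
    ev <- detect_ca_events(tr$series$ca_cyt, times = tr$series$time)
    # allow the tail of an in-window event to peak shortly after offset
    n_in <- n_in + sum(ev$t_peak >= 0.5 & ev$t_peak <= 3.0)
    n_out <- n_out + sum(ev$t_peak < 0.5 | ev$t_peak > 3.0)
  }
  expect_gt(n_in, 0)
  expect_gt(n_in, 3 * n_out)
})

test_that("event statistics are stable when the step is halved", {
  p <- params_default
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 0.2,
                            duration_s = 2)
  count_events <- function(dt, seeds) {
    cfg <- simulation_config(p, prot, n_trials = length(seeds),
                             base_seed = 100, dt = dt, duration = 3.5,
                             record_every = max(1L, as.integer(1e-3 / dt)))
    vapply(seeds, function(i) {
      tr <- suppressWarnings(run_trial(cfg, i, rest = rest_default,
                                       validate = FALSE))
      nrow(detect_ca_events(tr$series$ca_cyt, times = tr$series$time))
    }, numeric(1))
  }
  c50 <- count_events(5e-5, 1:10)
  c25 <- count_events(2.5e-5, 1:10)
  se <- sqrt(stats::var(c50) / 10 + stats::var(c25) / 10)
  expect_lt(abs(mean(c50) - mean(c25)), 3.2 * se)
})
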