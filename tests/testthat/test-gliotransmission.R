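test_that("sensors fully unbind at zero calcium and fusion rates vanish", {
  p <- params_default
  st <- release_machinery_state(p)
  st$p4 <- 0.8
  st$occ7 <- c(0, 0, 0, 0, 0, 1)
  for (i in 1:400) st <- sensor_update(st, 0, p, 0.005)
  expect_lt(st$p4, 1e-6)
  expect_gt(st$occ7[1], 1 - 1e-6)
  expect_equal(unname(release_rates(st, p)), c(0, 0), tolerance = 1e-4)
})

test_that("Syt4 equilibrates to half occupancy at its 22 uM affinity", {
  p <- params_default
  st <- release_machinery_state(p)
  for (i in 1:2000) st <- sensor_update(st, 22, p, 0.001)
  expect_equal(st$p4, 0.5, tolerance = 1e-3)
})

test_that("sensor occupancies match the matrix-exponential master-equation solution", {
  skip_if_not_installed("Matrix")
  p <- params_default
  for (ca in c(2, 22, 80)) {
    dt <- 5e-5
    steps <- 2000  # 100 ms of clamped exposure
    st <- release_machinery_state(p)
    occ_path <- matrix(NA_real_, steps, 7)
    for (s in seq_len(steps)) {
      st <- sensor_update(st, ca, p, dt)
      occ_path[s, ] <- c(st$p4, st$occ7)
    }
    # two-state closed form for Syt4
    lam <- p$syt4_kon * ca + p$syt4_koff
    peq <- p$syt4_kon * ca / lam
    tt <- dt * seq_len(steps)
    p4_exact <- peq * (1 - exp(-lam * tt))
    expect_lt(max(abs(occ_path[, 1] - p4_exact)), 1e-4)
    # matrix exponential for the Syt7 chain at a few checkpoints
    Q <- oracle_syt7_Q(ca, p)
    for (chk in c(200, 1000, 2000)) {
      ex <- as.numeric(Matrix::expm(Matrix::Matrix(t(Q) * chk * dt)) %*%
                         c(1, 0, 0, 0, 0, 0))
      expect_lt(max(abs(occ_path[chk, 2:7] - ex)), 1e-4)
    }
  }
})

test_that("release rates are proportional to pool occupancy and zero for empty pools", {
  p <- params_default
  st <- release_machinery_state(p)
  st$p4 <- 0.4
  st$occ7 <- c(0, 0, 0, 0, 0.2, 0.8)
  r <- release_rates(st, p)
  expect_equal(r[["kr"]], p$syt4_gamma * 0.4 * p$n_docked)
  expect_equal(r[["ff"]], p$syt7_gamma * 0.8 * p$n_mobile)
  st$pools[["docked"]] <- 0L
  expect_equal(release_rates(st, p)[["kr"]], 0)
})

test_that("release sampling is Bernoulli thinning at the requested rate", {
  p <- astro_parameters(kr_recycle = 1e-300, ff_recycle = 1e-300,
                        k_dock = 1e-300, n_docked = 9, n_mobile = 16)
  # hold the Syt4 rate constant by pinning occupancy and a large pool
  rate <- 40  # 1/s
  dt <- 5e-4
  n_steps <- 2000
  set.seed(5)
  counts <- vapply(1:40, function(i) {
    st <- release_machinery_state(p)
    st$pools[["docked"]] <- 100000L
    n0 <- st$pools[["docked"]]
    for (s in seq_len(n_steps))
      st <- sample_release_events(st, c(kr = rate, ff = 0), dt)
    n0 - st$pools[["docked"]]
  }, numeric(1))
  expected <- rate * dt * n_steps
  se <- sqrt(expected * (1 - rate * dt) / 40)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  expect_error(sample_release_events(release_machinery_state(p),
                                     c(kr = 1e5, ff = 0), dt), ">= 1")
})

test_that("zero rates leave the machinery unchanged", {
  st <- release_machinery_state(params_default)
  set.seed(1)
  st2 <- sample_release_events(st, c(kr = 0, ff = 0), 5e-5)
  expect_equal(st2$pools, st$pools)
  expect_equal(nrow(st2$events), 0)
})

test_that("pool kinetics conserve vesicles and fix the fully docked state", {
  p <- params_default
  st <- release_machinery_state(p)
  st$pools <- c(docked = 9L, mobile = 0L, kr_endo = 0L, ff_endo = 0L)
  set.seed(2)
  st2 <- pool_kinetics_step(st, p, 5e-5)
  expect_equal(st2$pools, st$pools)
  # random occupancy: conservation holds across many stochastic steps
  st$pools <- c(docked = 3L, mobile = 7L, kr_endo = 8L, ff_endo = 7L)
  total <- sum(st$pools)
  for (i in 1:2000) {
    st <- pool_kinetics_step(st, p, 1e-3)
    expect_true(all(st$pools >= 0L))
    if (sum(st$pools) != total) break
  }
  expect_equal(sum(st$pools), total)
  # docking never overfills the docked pool
  expect_lte(st$pools[["docked"]], p$docked_max)
})

test_that("whole-trial simulation conserves the total vesicle count", {
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 0.3,
                            duration_s = 2)
  tr <- short_trial(prot, duration = 4, seed = 9)
  tot <- tr$series$docked + tr$series$mobile + tr$series$kr_endo +
    tr$series$ff_endo
  expect_true(all(tot == tot[1]))
})

test_that("clamped characterization separates the two sensors as fast/slow", {
  p <- params_default
  ch <- characterize_clamped(p, c(5, 20, 50, 100), t_max = 3)
  # Syt4 (kiss-and-run) peaks before Syt7 (full fusion) at every level
  expect_true(all(ch$peaks$ttp_kr < ch$peaks$ttp_ff))
  # Syt4 time-to-peak shrinks with calcium
  expect_true(all(diff(ch$peaks$ttp_kr) <= 1e-9))
  # Syt7 peak rates stay well below Syt4 peak rates at matched calcium
  expect_true(all(ch$peaks$peak_ff < ch$peaks$peak_kr))
  # full-fusion rise is hundreds of milliseconds
  expect_gt(ch$peaks$ttp_ff[ch$peaks$ca == 20], 0.1)
  expect_error(characterize_clamped(p, numeric(0)), "non-empty")
  # zero calcium level is rejected, a flat-zero curve is returned for tiny ca
  expect_error(characterize_clamped(p, c(0, 1)), "positive")
})

test_that("Hill fits of clamped peak rates recover the stated affinities", {
  p <- params_default
  ch <- characterize_clamped(p, c(1, 2, 5, 8, 12, 15, 20, 30, 50, 100, 200))
  f4 <- fit_hill(ch$peaks$ca, ch$peaks$peak_kr)
  f7 <- fit_hill(ch$peaks$ca, ch$peaks$peak_ff)
  expect_equal(coef(f4)[["kd"]], 22, tolerance = 0.1)
  expect_equal(coef(f7)[["kd"]], 15, tolerance = 0.1)
})

test_that("docked pool depletes under DHPG and recovers within tens of seconds", {
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 0.5,
                            duration_s = 2)
  cfg <- simulation_config(params_default, prot, n_trials = 12,
                           base_seed = 40, duration = 24)
  docked <- mobile <- NULL
  for (i in seq_len(12)) {
    tr <- suppressWarnings(run_trial(cfg, i, rest = rest_default,
                                     validate = FALSE))
    docked <- if (is.null(docked)) tr$series$docked
              else docked + tr$series$docked
    mobile <- if (is.null(mobile)) tr$series$mobile
              else mobile + tr$series$mobile
  }
  docked <- docked / 12; mobile <- mobile / 12
  tm <- cfg$dt * cfg$record_every * (seq_along(docked) - 1)
  stim <- tm > 0.5 & tm < 4
  expect_lt(min(docked[stim]), 0.8 * docked[1])
  recovered <- tm[docked >= 0.95 * docked[1] & tm > 4]
  expect_lte(min(recovered), 20)
  # mobile pool rises above its initial level and stays elevated after offset
  expect_gt(mean(mobile[tm > 3 & tm < 8]), mobile[1])
})
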