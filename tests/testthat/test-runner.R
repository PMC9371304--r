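test_that("parameter files round-trip and invariants are enforced", {
  p <- params_default
  expect_silent(validate_parameters(p))
  tmp <- tempfile(fileext = ".json")
  write_parameters(p, tmp)
  p2 <- astro_parameters(file = tmp)
  expect_equal(unclass(p2)[names(p)], unclass(p)[names(p)])
  expect_error(astro_parameters(nonexistent_key = 1), "unknown parameter")
  expect_error(validate_parameters(astro_parameters(er_cyt_ratio = 1.5)),
               "er_cyt_ratio")
  expect_error(validate_parameters(astro_parameters(n_ip3r = 0)), "n_ip3r")
  expect_error(validate_parameters(astro_parameters(v_serca = -1)),
               "strictly positive")
})

test_that("a trial is bit-reproducible under its seed", {
  prot <- stimulus_protocol("glutamate_train", rate_hz = 20, onset_s = 0.2,
                            duration_s = 1, timing = "poisson")
  cfg <- simulation_config(params_default, prot, n_trials = 2,
                           base_seed = 77, duration = 1.5)
  t1 <- suppressWarnings(run_trial(cfg, 1, rest = rest_default,
                                   validate = FALSE))
  t1b <- suppressWarnings(run_trial(cfg, 1, rest = rest_default,
                                    validate = FALSE))
  expect_identical(t1$series, t1b$series)
  expect_identical(t1$release_events, t1b$release_events)
  # a different trial index gives a different stream
  t2 <- suppressWarnings(run_trial(cfg, 2, rest = rest_default,
                                   validate = FALSE))
  expect_false(identical(t1$series$ca_cyt, t2$series$ca_cyt))
})

test_that("trials are independent of execution order", {
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 0.2,
                            duration_s = 1)
  cfg <- simulation_config(params_default, prot, n_trials = 2,
                           base_seed = 5, duration = 1.6)
  fwd <- lapply(1:2, function(i)
    suppressWarnings(run_trial(cfg, i, rest = rest_default,
                               validate = FALSE)))
  rev <- lapply(2:1, function(i)
    suppressWarnings(run_trial(cfg, i, rest = rest_default,
                               validate = FALSE)))
  expect_identical(fwd[[1]]$series, rev[[2]]$series)
  expect_identical(fwd[[2]]$release_events, rev[[1]]$release_events)
})

test_that("batches consolidate events and survive an export round trip", {
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 0.2,
                            duration_s = 1)
  cfg <- simulation_config(params_default, prot, n_trials = 3,
                           base_seed = 19, duration = 2)
  b <- suppressWarnings(run_batch(cfg))
  expect_s3_class(b, "astro_batch")
  expect_equal(length(b$ca_matrix), 3)
  expect_equal(b$provenance$trial_seeds, 19 + 1:3)
  dir <- tempfile("batch")
  export_results(b, dir)
  expect_error(export_results(b, dir, format = "hdf5"), "supported formats")
  back <- import_results(dir)
  expect_equal(unclass(back$kr_matrix), unclass(b$kr_matrix),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(back$ff_matrix), unclass(b$ff_matrix),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(back$ca_matrix),
               lapply(b$ca_matrix, identity),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$provenance$config_hash, b$provenance$config_hash)
})

test_that("empty batches export valid files with intact headers", {
  # stimulus too weak to evoke anything: expect zero event rows
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 1e-6,
                            onset_s = 0.2, duration_s = 0.2)
  cfg <- simulation_config(params_default, prot, n_trials = 2,
                           base_seed = 3000, duration = 0.6)
  b <- suppressWarnings(run_batch(cfg))
  dir <- tempfile("emptybatch")
  export_results(b, dir)
  rel <- utils::read.csv(file.path(dir, "release_events.csv"))
  expect_equal(names(rel), c("trial", "time_s", "mode"))
  back <- import_results(dir)
  expect_equal(sum(lengths(back$rel_matrix)), sum(lengths(b$rel_matrix)))
})

test_that("the batch summary reports the headline statistics", {
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 0.2,
                            duration_s = 1)
  cfg <- simulation_config(params_default, prot, n_trials = 2,
                           base_seed = 23, duration = 2)
  b <- suppressWarnings(run_batch(cfg))
  s <- summary(b)
  expect_equal(s$n_trials, 2)
  expect_true(is.finite(s$kr_per_trial))
  expect_output(print(s), "condition control")
})

test_that("configs validate their stimulus extent", {
  prot <- stimulus_protocol("agonist_pulse", agonist_uM = 100, onset_s = 1,
                            duration_s = 2)
  expect_error(simulation_config(params_default, prot, duration = 2.5),
               "exceed the stimulus extent")
})
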