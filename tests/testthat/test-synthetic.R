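test_that("generation is deterministic under a fixed seed", {
  s1 <- simulate_experiment(scenario_preset("sulfide_rate", seed = 9))
  s2 <- simulate_experiment(scenario_preset("sulfide_rate", seed = 9))
  expect_identical(s1$animals, s2$animals)
  expect_identical(s1$scans, s2$scans)
  expect_identical(s1$tissue, s2$tissue)
  s3 <- simulate_experiment(scenario_preset("sulfide_rate", seed = 10))
  expect_false(identical(s1$scans, s3$scans))
})

test_that("true fixation rates decay geometrically along the stack", {
  cfg <- scenario_config(n_animals_per_genus = c(Alviniconcha = 5),
                         positional_attenuation = 0.5, base_c_inc = 1,
                         seed = 2)
  truth <- gen_cohort(cfg)$truth_animals
  expect_equal(truth$true_c_inc, c(1, 0.5, 0.25, 0.125, 0.0625))

  flat <- scenario_config(n_animals_per_genus = c(Alviniconcha = 5),
                          positional_attenuation = 0, base_c_inc = 1,
                          seed = 2)
  expect_equal(gen_cohort(flat)$truth_animals$true_c_inc, rep(1, 5))

  # uptake is tied to fixation through the molar ratio
  expect_equal(truth$true_uptake, truth$true_c_inc * 6.21)
})

test_that("steady-state effluent follows the aquarium mass balance", {
  expect_equal(steady_state_effluent(349, 250, 1), 99)
  expect_equal(steady_state_effluent(100, 0, 2), 100)
  expect_warning(out <- steady_state_effluent(100, 500, 1), "floored")
  expect_equal(out, 0)
})

test_that("an empty control aquarium passes input water through within noise", {
  sim <- simulate_experiment(scenario_preset("sulfide_rate", seed = 12))
  cfg <- sim$config
  ctrl <- sim$scans[sim$scans$channel == "control" &
                      sim$scans$analyte == "sulfide" &
                      sim$scans$time_s > 15 * 3600 &
                      sim$scans$time_s %% 1800 > 40, ] # drop switch transients
  expect_gt(nrow(ctrl), 100)
  expect_lt(abs(mean(ctrl$concentration_uM) - cfg$input_concentration_uM),
            3 * cfg$noise_sd_uM / sqrt(nrow(ctrl)) + 0.1)
})

test_that("the sulfur-free scenario censors every sulfur scan", {
  sim <- simulate_experiment(scenario_preset("sulfur_free", seed = 3))
  expect_true(all(sim$scans$censored == 1L))
})

test_that("scan series honours the burst structure and schedule", {
  sim <- simulate_experiment(scenario_preset("sulfide_rate", seed = 4))
  sched <- sim$schedule
  one <- sim$scans[sim$scans$time_s < 1800 & sim$scans$analyte == "sulfide", ]
  expect_equal(nrow(one), 42L)
  expect_equal(unique(one$channel), sched$channels[[1L]])
  # two bursts: 21 scans from minute 0, 21 from minute 15, 2 s cadence
  expect_equal(one$time_s, c((0:20) * 2, 900 + (0:20) * 2))
  expect_equal(sched$reference_channel, "control")
})

test_that("channel-switch transients relax toward the channel's own level", {
  cfg <- scenario_preset("sulfide_variation", seed = 6, noise_sd_uM = 0)
  sim <- simulate_experiment(cfg)
  s <- sim$scans[sim$scans$analyte == "sulfide", ]
  # late interval, after the ramp: compare head and tail of one interval
  iv <- s[s$time_s >= 20 * 3600 & s$time_s < 20 * 3600 + 1800, ]
  head10 <- iv$concentration_uM[1:10]
  settled <- mean(iv$concentration_uM[11:42])
  # monotone relaxation from the previous channel's level
  expect_true(all(diff(abs(head10 - settled)) <= 1e-9))
  expect_gt(abs(head10[1] - settled), abs(head10[10] - settled))
  # the discard rule removes exactly the affected scans
  cc <- interval_concentration(iv, "sulfide")
  expect_equal(cc$mean_uM, settled, tolerance = 1e-9)
})

test_that("tissue generation inverts the tracer chain exactly at zero noise", {
  cfg <- scenario_preset("sulfide_variation", seed = 7, isotope_noise_A_pct = 0)
  cohort <- gen_cohort(cfg)
  tissue <- gen_isotope_samples(cfg, cohort)
  out <- c_inc_pipeline(tissue)
  expect_rel_equal(out$wet_rate, cohort$truth_animals$true_c_inc, 1e-9)

  # a rate too hot for the label strength is unphysical
  hot <- scenario_preset("sulfide_variation", seed = 7, base_c_inc = 500)
  expect_error(gen_isotope_samples(hot, gen_cohort(hot)), "label strength")
})

test_that("scenario files round-trip through CSV with the seed in the header", {
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(scenario_preset("sulfide_rate", seed = 8,
                                             duration_h = 12))
  write_scenario(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "scans.csv", "animals.csv", "tissue.csv", "truth_animals.csv",
    "truth_aquaria.csv", "config.json")))))
  expect_equal(readLines(file.path(dir, "scans.csv"), n = 1), "# seed=8")
  back <- readr::read_csv(file.path(dir, "animals.csv"), comment = "#",
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sim$animals))
  expect_equal(back$gill_wet_g, signif(sim$animals$gill_wet_g, 6))
})
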