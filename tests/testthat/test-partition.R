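# Cascade partition: sum rule, attribution, tracer linearity.

test_that("a single-element photo-only system has one channel equal to f", {
  comp <- target_composition(c(C = 6), density_g_cm3 = 0.5)
  pulse <- pulse_profile(6, 5e11, fwhm_fs = 10)
  pol <- test_policy(ee = FALSE, tbr = FALSE)
  sys <- build_system(comp, pulse, pol, channels = TRUE)
  # keep only photoionization: rebuild with decay/eii removed via process
  # toggles is not exposed; instead use a fresh system and verify the sum
  # rule and that the carbon channels carry all density
  traj <- run_simulation(comp, pulse, pol, t_start_fs = -10, t_end_fs = 10,
                         channels = TRUE)
  tot <- rowSums(traj$channel_density)
  expect_equal(tot, traj$free_density_cm3, tolerance = 1e-8)
  expect_true(all(vapply(strsplit(traj$channel_names, " "), `[`, "", 1) == "C"))
})

test_that("the partition sum rule holds through a multi-element run", {
  comp <- fixture_composition("cno")
  pulse <- pulse_profile(9, 5e11, fwhm_fs = 10)
  traj <- cached_run("cno_part", run_simulation(
    comp, pulse, test_policy(), t_start_fs = -12, t_end_fs = 12,
    channels = TRUE))
  nt <- length(traj$time_fs)
  tot <- rowSums(traj$channel_density)
  # pointwise-in-time sum rule at the density level
  expect_equal(tot[-1], traj$free_density_cm3[-1],
               tolerance = 1e-6)
  # all channel densities essentially non-negative
  expect_true(all(traj$channel_density > -1e-8 * max(tot)))
  # oxygen seeds the largest light-atom share (K-shell cross-section)
  fin <- traj$channel_density[nt, ]
  by_el <- tapply(fin, vapply(strsplit(colnames(traj$channel_density), " "),
                              `[`, "", 1), sum)
  expect_gt(by_el[["O"]], by_el[["N"]])
})

test_that("tracer channels are linear in the injected density", {
  comp <- fixture_composition("cno")
  pulse <- pulse_profile(9, 5e11, fwhm_fs = 10)
  pol <- test_policy()
  dens <- c()
  for (frac in c(1e-8, 3e-8)) {
    traj <- run_simulation(comp, pulse, pol, t_start_fs = -12, t_end_fs = 0,
                           channels = TRUE,
                           tracers = list(tracer_impulse(2000, -5, frac)))
    k <- grep("tracer", traj$channel_names)
    dens <- c(dens, unname(traj$channel_density[length(traj$time_fs), k]))
  }
  expect_equal(dens[2] / dens[1], 3, tolerance = 0.01)
})

test_that("zero injected density leaves the tracer channel empty", {
  comp <- target_composition(c(C = 6), density_g_cm3 = 0.5)
  pulse <- pulse_profile(6, 5e11, fwhm_fs = 10)
  traj <- run_simulation(comp, pulse, test_policy(), t_start_fs = -6,
                         t_end_fs = 0, channels = TRUE,
                         tracers = list(tracer_impulse(2000, -3, 0)))
  k <- grep("tracer", traj$channel_names)
  expect_true(all(abs(traj$channel_density[, k]) <
                    1e-12 * max(traj$free_density_cm3, 1)))
})

test_that("tracer injection outside the energy grid demands a regrid", {
  comp <- target_composition(c(C = 6), density_g_cm3 = 0.5)
  pulse <- pulse_profile(6, 5e11, fwhm_fs = 10)
  sys <- build_system(comp, pulse, test_policy(), channels = TRUE)
  expect_error(inject_tracer(sys, 50000), "outside|regrid")
})
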