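# Coupled-system integration: analytic limits, conservation, convergence,
# thermalization, and physical monotonicities. Problem sizes here use the
# routine-suite resolutions documented in the methods vignette.

test_that("a zero-fluence run leaves every charge at zero", {
  comp <- target_composition(c(C = 6, O = 2), density_g_cm3 = 0.5)
  pulse <- pulse_profile(5, 0, fwhm_fs = 10)
  traj <- run_simulation(comp, pulse, test_policy(), t_start_fs = -5,
                         t_end_fs = 5, out_dt_fs = 1)
  expect_true(all(abs(traj$charge) < 1e-12))
  expect_true(all(abs(traj$f_coef) < 1e-20))
  cons <- conservation_report(traj)
  expect_equal(cons$max_electron_drift, 0, tolerance = 1e-12)
})

test_that("elements beyond the supported range are rejected at build", {
  comp <- target_composition(c(C = 6, U = 1), density_g_cm3 = 1)
  comp$Z[2] <- 93  # force an unsupported element past composition checks
  pulse <- pulse_profile(5, 1e10, fwhm_fs = 10)
  expect_error(build_system(comp, pulse, test_policy()), "unsupported|93")
})

test_that("pure photoionization follows the closed-form exponential decay", {
  comp <- target_composition(c(H = 1), density_g_cm3 = 1e-3)
  pulse <- pulse_profile(1, 1e10, shape = "square", fwhm_fs = 100)
  pol <- test_policy(ee = FALSE, tbr = FALSE, rtol = 1e-7)
  traj <- run_simulation(comp, pulse, pol, t_start_fs = -50, t_end_fs = -20,
                         out_dt_fs = 1)
  m <- crplasma:::get_element_model(1, 1000, pol$alpha_x)
  sg <- m$st$sigma[1, m$cs$ground]
  J_au <- 1e10 / crplasma:::UM2_AU / 100 / crplasma:::AU_PER_FS
  rate_fs <- sg * J_au * crplasma:::AU_PER_FS
  tt <- traj$time_fs - traj$time_fs[1]
  expect_equal(1 - traj$charge[, 1], exp(-rate_fs * tt), tolerance = 1e-4)
})

test_that("bound + free electrons and the energy ledger are conserved", {
  comp <- fixture_composition("cno")
  pulse <- pulse_profile(9, 5e11, fwhm_fs = 10)
  traj <- cached_run("cno_9kev_5e11", run_simulation(
    comp, pulse, test_policy(), t_start_fs = -12, t_end_fs = 12))
  cons <- conservation_report(traj)
  expect_lt(cons$max_electron_drift, 1e-6)
  expect_lt(cons$max_energy_residual, 1e-3)
  # populations stay normalized per element
  st <- system_state(traj$system)
  for (P in st$P) expect_equal(sum(P), 1, tolerance = 1e-8)
})

test_that("halving the tolerance barely changes the carbon charge", {
  comp <- target_composition(c(C = 6, N = 2, O = 2), density_g_cm3 = 1.2)
  pulse <- pulse_profile(8, 8e11, fwhm_fs = 10)
  q10 <- sapply(c(1e-4, 5e-5), function(rt) {
    traj <- run_simulation(comp, pulse, test_policy(rtol = rt),
                           t_start_fs = -12, t_end_fs = 12)
    tr <- average_charge_trace(traj, "C")
    stats::approx(tr$time_fs, tr$charge, 10)$y
  })
  expect_lt(abs(q10[2] - q10[1]) / q10[1], 0.01)
})

test_that("with only EE active, any distribution relaxes to a Maxwellian", {
  comp <- target_composition(c(H = 1), density_g_cm3 = 1e-9)
  pulse <- pulse_profile(1, 0, fwhm_fs = 10)
  pol <- test_policy(ee = TRUE, tbr = FALSE, hydrogen_ionization = FALSE,
                     n_log = 55, emin_ev = 0.08, dt_max_fs = 0.05)
  sys <- build_system(comp, pulse, pol)
  au <- crplasma:::basis_au_mirror(sys$basis)
  n1 <- 5e21
  fq <- maxwellian_cm3_ev(au$qx * HA, n1, 3) + maxwellian_cm3_ev(au$qx * HA, n1, 9)
  cf <- solve(au$mass, drop(t(au$Bq) %*% (au$qw * fq * CM3AU * HA)))
  st <- system_state(sys)
  crplasma:::cpp_sys_set_state(sys$ptr, 0, cf, st$G, st$P, st$ledger)
  sys$t_fs <- 0
  n0 <- sum(au$mvec * cf)
  E0 <- sum(au$evec * cf)
  Texp <- 2 * E0 / (3 * n0)  # energy conservation fixes the final T
  step_system(sys, 120)
  st2 <- system_state(sys)
  # number and energy conserved through the relaxation
  expect_equal(sum(au$mvec * st2$c) / n0, 1, tolerance = 1e-9)
  expect_equal(sum(au$evec * st2$c) / E0, 1, tolerance = 1e-9)
  fM <- 2 / sqrt(pi) * n0 * Texp^-1.5 * sqrt(au$qx) * exp(-au$qx / Texp)
  fnow <- drop(au$Bq %*% st2$c)
  l2 <- sqrt(sum(au$qw * (fnow - fM)^2) / sum(au$qw * fM^2))
  expect_lt(l2, 0.01)
  expect_equal(2 * sum(au$evec * st2$c) / (3 * n0) / Texp, 1, tolerance = 0.01)
})

test_that("doubling the fluence strictly increases the final carbon charge", {
  comp <- fixture_composition("cno")
  qf <- sapply(c(2.5e11, 5e11, 1e12), function(f) {
    pulse <- pulse_profile(9, f, fwhm_fs = 10)
    traj <- run_simulation(comp, pulse, test_policy(), t_start_fs = -12,
                           t_end_fs = 12, out_dt_fs = 2)
    traj$charge[nrow(traj$charge), "C"]
  })
  expect_true(all(diff(qf) > 0))
})

test_that("step-size underflow raises a stiffness diagnostic", {
  comp <- target_composition(c(C = 6), density_g_cm3 = 1)
  pulse <- pulse_profile(5, 1e12, fwhm_fs = 10)
  sys <- build_system(comp, pulse, test_policy(dt_min_fs = 0.05, rtol = 1e-13))
  sys$t_fs <- -5
  st <- system_state(sys)
  crplasma:::cpp_sys_set_state(sys$ptr, crplasma:::fs_to_au(-5), st$c, st$G,
                               st$P, st$ledger)
  expect_error(step_system(sys, 5), "underflow|stiff")
})

test_that("trajectories expose distribution snapshots consistent with ledgers", {
  comp <- fixture_composition("cno")
  pulse <- pulse_profile(9, 5e11, fwhm_fs = 10)
  traj <- cached_run("cno_9kev_5e11", run_simulation(
    comp, pulse, test_policy(), t_start_fs = -12, t_end_fs = 12))
  # before any ionization: identically zero
  s0 <- distribution_snapshot(traj, traj$time_fs[1])
  expect_true(all(abs(s0$f) < 1e-12))
  sp <- distribution_snapshot(traj, 10)
  expect_equal(attr(sp, "density"),
               traj$free_density_cm3[match(10, traj$time_fs)],
               tolerance = 1e-6)
  expect_error(distribution_snapshot(traj, 99), "outside")
})
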