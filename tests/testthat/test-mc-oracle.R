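# Cross-validation of the deterministic EII cascade against an independent
# particle Monte Carlo with identical cross-sections (one-subshell hydrogen
# gas, 2 keV seed electrons, no fields / EE / recombination).

test_that("time-resolved cascade ionization matches the particle MC", {
  B <- 13.6057
  n_a <- 2e21          # atoms/cm3: a few ionizations per seed in the window
  t_end <- 8
  tsamp <- c(2, 4, 8)

  # deterministic run: H gas, seed electrons injected as an impulse
  comp <- target_composition(c(H = 1), density_g_cm3 = 1)
  comp$ndens_cm3[] <- n_a   # exact atom density
  pulse <- pulse_profile(2.3, 0, fwhm_fs = 10)
  pol <- test_policy(ee = FALSE, tbr = FALSE, rtol = 1e-6, n_log = 50)
  sys <- build_system(comp, pulse, pol)
  m <- sys$models[[1]]
  # model threshold for the MC (identical inputs)
  occ2 <- m$cs$occ[m$cs$ground, ]; occ2[1] <- 0L
  B_model <- (m$st$E[crplasma:::config_index(m$cs, occ2)] -
                m$st$E[m$cs$ground]) * HA
  U_model <- m$st$U[1, m$cs$ground] * HA
  n_e0 <- 1e-4 * n_a   # negligible depletion in both routes
  st <- system_state(sys)
  st$c <- st$c + n_e0 * CM3AU *
    crplasma:::cpp_sys_project_point(sys$ptr, crplasma:::ev_to_au(2000))
  crplasma:::cpp_sys_set_state(sys$ptr, 0, st$c, st$G, st$P, st$ledger)
  sys$t_fs <- 0
  det <- numeric(length(tsamp))
  for (k in seq_along(tsamp)) {
    step_system(sys, tsamp[k] - sys$t_fs)
    led <- system_state(sys)$ledger
    det[k] <- led[5] / CM3AU / n_e0     # EII events per seed electron
  }

  mc <- mc_cascade(2000, n_a, B_model, U_model, 1, t_end,
                   n_rep = 250, dt_fs = 0.02, seed = 42, sample_times = tsamp)
  for (k in seq_along(tsamp)) {
    expect_lt(abs(det[k] - mc$mean[k]), 3 * mc$se[k] + 0.02 * mc$mean[k])
  }
})
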