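# Particle Monte Carlo oracle for electron-impact-ionization cascades.
# Uses the same BEB total cross-section and secondary spectrum as the
# solver, but as an independent stochastic particle simulation: electrons
# collide with a fixed gas of one-subshell atoms; each event removes B + w
# from the impactor and spawns a secondary of energy w drawn from the
# normalized SDCS. No fields, no EE, no recombination.

mc_cascade <- function(e0_ev, n_atoms_cm3, B_ev, U_ev, N_occ, t_end_fs,
                       n_rep = 200, dt_fs = 0.02, seed = 1,
                       sample_times = t_end_fs) {
  set.seed(seed)
  v_cm_fs <- function(e_ev) 5.93097e7 * sqrt(e_ev) * 1e-15  # cm/fs
  sig <- function(e_ev) eii_cross_section(B_ev, U_ev, N_occ, e_ev)
  # secondary sampling by inverse CDF on a log-mapped grid
  draw_w <- function(T_ev) {
    half <- (T_ev - B_ev) / 2
    ug <- seq(0, log(1 + half / B_ev), length.out = 101)
    wg <- B_ev * (exp(ug) - 1)
    pdf <- eii_sdcs(B_ev, U_ev, N_occ, T_ev, wg) * (wg + B_ev)
    cdf <- cumsum(pdf)
    cdf <- cdf / cdf[length(cdf)]
    u <- stats::runif(1)
    i <- findInterval(u, cdf) + 1
    wg[min(i, length(wg))]
  }
  counts <- matrix(0, n_rep, length(sample_times))
  for (r in seq_len(n_rep)) {
    E <- e0_ev
    n_ion <- 0
    t <- 0
    k <- 1
    while (t < t_end_fs) {
      t <- t + dt_fs
      live <- E > B_ev
      if (any(live)) {
        p <- 1 - exp(-n_atoms_cm3 * sig(E[live]) * v_cm_fs(E[live]) * dt_fs)
        hit <- stats::runif(length(p)) < p
        if (any(hit)) {
          idx <- which(live)[hit]
          for (i in idx) {
            w <- draw_w(E[i])
            E[i] <- E[i] - B_ev - w
            E <- c(E, w)
            n_ion <- n_ion + 1
          }
        }
      }
      while (k <= length(sample_times) && t >= sample_times[k] - 1e-9) {
        counts[r, k] <- n_ion
        k <- k + 1
      }
    }
    if (k <= length(sample_times)) counts[r, k:length(sample_times)] <- n_ion
  }
  list(mean = colMeans(counts),
       se = apply(counts, 2, stats::sd) / sqrt(n_rep),
       times = sample_times)
}
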