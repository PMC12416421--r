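# Coupled solver: configuration populations dP/dt = Gamma(f, J) P per element
# and the free-electron distribution df/dt = Q[P, f] on the spline basis.
# The C++ backend integrates with an adaptive embedded Runge-Kutta scheme for
# the non-stiff couplings and an operator-split linearly implicit update for
# the stiff electron-electron collisions.

#' Solver policy
#'
#' Numerical controls and process toggles for [build_system()] /
#' [run_simulation()].
#'
#' @param rtol relative local error tolerance of the adaptive stepper
#' @param atol_p absolute tolerance on configuration populations
#' @param dt_max_fs maximum step (also bounds the electron-electron splitting
#'   error)
#' @param dt_min_fs step-size underflow threshold (stiffness failure)
#' @param ee,tbr enable electron-electron collisions / three-body
#'   recombination
#' @param heavy_processes processes modeled for heavy atoms (Z > heavy_z):
#'   "all", "primary" (photoionization, Auger, fluorescence only) or "none"
#' @param heavy_z heavy-atom threshold (the field's convention: Z > 10)
#' @param hydrogen_ionization model ionization of hydrogen
#' @param n_log number of logarithmic knots of the energy grid
#' @param emin_ev thermal resolution scale (first interior knot)
#' @param order spline order
#' @param eii_bin_rel relative binning width of EII operator caching in B
#' @param u_bin_rel relative binning width in U
#' @param n_node size of the deposit-node grid for monoenergetic sources
#' @param n_tbr three-body recombination quadrature nodes per dimension
#' @param tbr_emin_ev,tbr_emax_ev TBR quadrature energy range
#' @param lnl_floor Coulomb-logarithm floor
#' @param expand_threshold population at which a lazily handled heavy-element
#'   configuration is expanded (its outgoing transitions computed)
#' @param chunk_fs orchestration interval: output sampling, lazy expansion and
#'   tracer injection happen at these boundaries
#' @param lazy_threshold configuration-set size above which an element is
#'   handled lazily
#' @param alpha_x Slater exchange coefficient of the mean field
#' @return object of class `solver_policy`
#' @export
solver_policy <- function(rtol = 1e-6, atol_p = 1e-12, dt_max_fs = 0.2,
                          dt_min_fs = 1e-9, ee = TRUE, tbr = TRUE,
                          heavy_processes = c("all", "primary", "none"),
                          heavy_z = 10, hydrogen_ionization = TRUE,
                          n_log = 60, emin_ev = 0.15, order = 4,
                          eii_bin_rel = 0.03, u_bin_rel = 0.25,
                          n_node = 800, n_tbr = 41, tbr_emin_ev = 0.003,
                          tbr_emax_ev = 1200, lnl_floor = 2,
                          expand_threshold = 1e-10, chunk_fs = 0.25,
                          lazy_threshold = 3000, alpha_x = 0.8) {
  heavy_processes <- match.arg(heavy_processes)
  stopifnot(rtol > 0, atol_p > 0, dt_max_fs > 0, dt_min_fs > 0)
  structure(as.list(environment()), class = "solver_policy")
}

# per-session cache of element models keyed by (Z, omega, collapse, alpha)
.model_cache <- new.env(parent = emptyenv())

get_element_model <- function(Z, omega_ev, alpha_x, use_cache = TRUE) {
  key <- sprintf("%d|%.6g|%.4g", Z, omega_ev, alpha_x)
  if (use_cache && !is.null(.model_cache[[key]])) return(.model_cache[[key]])
  m <- element_model(Z, omega_ev, alpha_x = alpha_x)
  if (use_cache) .model_cache[[key]] <- m
  m
}

#' Build a simulation system
#'
#' Assembles element models (configurations, rates, cross-sections), the
#' energy grid, and the discrete operators, and returns a live system ready
#' for [step_system()] / [run_simulation()].
#'
#' @param target a [target_composition()]
#' @param pulse a [pulse_profile()]
#' @param policy a [solver_policy()]
#' @param channels `FALSE`, or `TRUE` to track the cascade partition by
#'   (element x primary process) channels
#' @param tracers list of tracer specifications ([tracer_impulse()] /
#'   [tracer_flux()])
#' @param use_model_cache reuse per-session atomic models
#' @return object of class `cr_system`
#' @export
build_system <- function(target, pulse, policy = solver_policy(),
                         channels = FALSE, tracers = list(),
                         use_model_cache = TRUE) {
  stopifnot(inherits(target, "target_composition"),
            inherits(pulse, "pulse_profile"),
            inherits(policy, "solver_policy"))
  if (any(target$Z > 92)) stop("unsupported element: Z > 92 in target")
  omega_ev <- pulse$energy_ev
  syms <- names(target$counts)
  nel <- length(syms)

  # element models + process sets
  models <- vector("list", nel)
  procs <- vector("list", nel)
  for (i in seq_len(nel)) {
    Z <- target$Z[i]
    models[[i]] <- get_element_model(Z, omega_ev, policy$alpha_x, use_model_cache)
    p <- c("photo", "decay", "eii")
    if (Z == 1 && !policy$hydrogen_ionization) p <- character()
    if (Z > policy$heavy_z) {
      p <- switch(policy$heavy_processes,
                  all = c("photo", "decay", "eii"),
                  primary = c("photo", "decay"),
                  none = character())
    }
    procs[[i]] <- p
  }

  # primary photo peaks of the ground configurations (for knot clustering);
  # only shells carrying a meaningful share of the element's cross-section
  peaks_ev <- numeric()
  for (i in seq_len(nel)) {
    if (!("photo" %in% procs[[i]])) next
    m <- models[[i]]
    g <- m$cs$ground
    model_ensure_photo(m, g)
    occ <- m$cs$occ[g, ]
    sg_tot <- sum(m$st$sigma[, g], na.rm = TRUE)
    for (s in which(occ > 0)) {
      sg <- m$st$sigma[s, g]
      if (!is.finite(sg) || sg < 0.05 * sg_tot) next
      occ2 <- occ; occ2[s] <- occ2[s] - 1L
      j <- config_index(m$cs, occ2)
      dE <- au_to_ev(m$st$E[j] - m$st$E[g])
      if (is.finite(dE) && dE > 0 && dE < omega_ev) {
        peaks_ev <- c(peaks_ev, omega_ev - dE)
      }
    }
  }
  peaks_ev <- sort(unique(round(peaks_ev, 1)))
  if (length(peaks_ev) > 1) {
    keep <- c(TRUE, diff(peaks_ev) / peaks_ev[-length(peaks_ev)] > 0.01)
    peaks_ev <- peaks_ev[keep]
  }
  emax_ev <- omega_ev * 1.02
  basis <- build_basis(emax_ev, peaks_ev = peaks_ev,
                       n_log = policy$n_log, emin_ev = policy$emin_ev,
                       order = policy$order)

  # deposit-node and TBR grids (a.u.)
  node_ev <- exp(seq(log(policy$emin_ev / 2), log(emax_ev * 0.999),
                     length.out = policy$n_node))
  ntbr <- policy$n_tbr
  if (ntbr %% 2 == 0) ntbr <- ntbr + 1
  xt <- seq(log(policy$tbr_emin_ev), log(min(policy$tbr_emax_ev, emax_ev / 2)),
            length.out = ntbr)
  tbr_ev <- exp(xt)
  swt <- c(1, rep(c(4, 2), length.out = ntbr - 2), 1)
  swt[ntbr] <- 1
  tbr_w_ev <- (xt[2] - xt[1]) / 3 * swt * tbr_ev

  # channel layout
  chan_names <- character()
  chan_of <- function(i, proc) -1L
  if (isTRUE(channels)) {
    cmap <- list()
    for (i in seq_len(nel)) {
      if (!length(procs[[i]])) next
      for (pr in intersect(c("photo", "decay"), procs[[i]])) {
        nm <- paste(syms[i], if (pr == "photo") "photo" else "auger")
        cmap[[nm]] <- length(cmap)
        chan_names <- c(chan_names, nm)
      }
    }
    for (k in seq_along(tracers)) {
      nm <- paste0("tracer@", tracers[[k]]$e0_ev, "eV")
      cmap[[nm]] <- length(cmap)
      chan_names <- c(chan_names, nm)
    }
    chan_of <- function(i, proc) {
      nm <- paste(syms[i], if (proc == 0) "photo" else "auger")
      v <- cmap[[nm]]
      if (is.null(v)) -1L else as.integer(v)
    }
  }
  nch <- length(chan_names)

  pulse_au <- list(shape = pulse$shape,
                   fluence_au = pulse$fluence_um2 / UM2_AU,
                   t0_au = fs_to_au(pulse$t0_fs),
                   par_au = if (pulse$shape == "gaussian")
                     fs_to_au(pulse$sigma_fs) else fs_to_au(pulse$fwhm_fs),
                   omega_au = ev_to_au(omega_ev))
  pol_au <- list(rtol = policy$rtol, atol_P = policy$atol_p,
                 atol_c = 1e-7 * sum(percm3_to_au(target$ndens_cm3)) / ev_to_au(1),
                 dt_min_au = fs_to_au(policy$dt_min_fs),
                 dt_max_au = fs_to_au(policy$dt_max_fs),
                 ee_on = policy$ee, tbr_on = policy$tbr,
                 lnL_floor = policy$lnl_floor)

  ptr <- cpp_sys_new(ev_to_au(basis$knots), basis$order, ev_to_au(node_ev),
                     ev_to_au(tbr_ev), ev_to_au(tbr_w_ev), pulse_au, pol_au,
                     as.integer(nch))

  sys <- new.env(parent = emptyenv())
  sys$ptr <- ptr
  sys$basis <- basis
  sys$target <- target
  sys$pulse <- pulse
  sys$policy <- policy
  sys$models <- models
  sys$procs <- procs
  sys$symbols <- syms
  sys$ndens_au <- percm3_to_au(target$ndens_cm3)
  sys$chan_names <- chan_names
  sys$nch <- nch
  sys$chan_of <- chan_of
  sys$t_fs <- 0
  sys$bins <- new.env(parent = emptyenv())  # bin key -> id
  sys$nbin <- 0
  sys$tracers <- tracers
  # per-element bookkeeping
  sys$local_of <- vector("list", nel)   # global cfg -> local slot (1-based)
  sys$active <- vector("list", nel)     # local slot -> global cfg
  sys$expanded <- vector("list", nel)   # global cfg -> transitions registered
  class(sys) <- "cr_system"

  for (i in seq_len(nel)) {
    m <- models[[i]]
    cpp_sys_add_element(ptr, sys$ndens_au[i], as.integer(m$nsh))
    sys$local_of[[i]] <- integer(m$cs$n)
    sys$active[[i]] <- integer(0)
    sys$expanded[[i]] <- logical(m$cs$n)
    eager <- m$cs$n <= policy$lazy_threshold
    if (eager && length(procs[[i]])) {
      register_configs(sys, i, seq_len(m$cs$n), p0_ground = TRUE)
      expand_configs(sys, i, seq_len(m$cs$n))
    } else {
      register_configs(sys, i, m$cs$ground, p0_ground = TRUE)
      if (length(procs[[i]])) expand_configs(sys, i, m$cs$ground)
    }
  }
  # tracers (flux-proportional ones need ground photo rates)
  for (k in seq_along(tracers)) {
    tr <- tracers[[k]]
    chan <- if (nch > 0) nch - length(tracers) + k - 1L else -1L
    if (tr$mode == "flux") {
      coef <- 0
      for (i in seq_len(nel)) {
        if (!("photo" %in% procs[[i]])) next
        m <- models[[i]]
        g <- m$cs$ground
        psc <- if (is.null(m$st$photo_scale)) 1 else m$st$photo_scale
        sg <- sum(m$st$sigma[, g] * psc, na.rm = TRUE)
        coef <- coef + sys$ndens_au[i] * sg
      }
      cpp_sys_add_tracer(sys$ptr, ev_to_au(tr$e0_ev), tr$multiple * coef,
                         as.integer(chan))
      tr$chan <- chan
    } else {
      tr$chan <- chan
    }
    sys$tracers[[k]] <- tr
  }
  sys
}

#' @export
print.cr_system <- function(x, ...) {
  cat("<cr_system>", length(x$symbols), "elements (",
      paste(x$symbols, collapse = " "), "), K =", x$basis$K,
      ", t =", signif(x$t_fs, 4), "fs\n")
  invisible(x)
}

# register configurations (populations) in the C++ system
register_configs <- function(sys, i, global_idx, p0_ground = FALSE) {
  global_idx <- global_idx[sys$local_of[[i]][global_idx] == 0]
  if (length(global_idx) == 0) return(invisible(NULL))
  m <- sys$models[[i]]
  model_ensure_scf(m, global_idx)
  occ <- t(m$cs$occ[global_idx, , drop = FALSE])
  nb <- colSums(occ)
  E <- m$st$E[global_idx]
  P0 <- numeric(length(global_idx))
  if (p0_ground) P0[global_idx == m$cs$ground] <- 1
  base <- cpp_sys_add_configs(sys$ptr, i - 1L, nb, E, occ, P0)
  sys$local_of[[i]][global_idx] <- base + seq_along(global_idx)
  sys$active[[i]] <- c(sys$active[[i]], global_idx)
  invisible(NULL)
}

# fetch (or create) an EII operator bin for (B, U) in a.u.
fetch_bin <- function(sys, B, U) {
  key <- paste0(round(log(B) / sys$policy$eii_bin_rel), "_",
                round(log(U) / sys$policy$u_bin_rel))
  id <- sys$bins[[key]]
  if (!is.null(id)) return(id)
  id <- cpp_sys_add_bin(sys$ptr, B, U)
  sys$bins[[key]] <- id
  sys$nbin <- sys$nbin + 1
  id
}

# compute and register the outgoing transitions of a set of configurations
expand_configs <- function(sys, i, global_idx) {
  global_idx <- global_idx[!sys$expanded[[i]][global_idx]]
  if (length(global_idx) == 0) return(invisible(NULL))
  m <- sys$models[[i]]
  tr <- model_transitions(m, global_idx, processes = sys$procs[[i]])
  sys$expanded[[i]][global_idx] <- TRUE
  if (nrow(tr) == 0) return(invisible(NULL))
  register_configs(sys, i, sort(unique(c(tr$src, tr$dst))))
  loc <- sys$local_of[[i]]
  bins <- integer(nrow(tr))
  bins[] <- -1L
  is_eii <- tr$type == 3
  if (any(is_eii)) {
    for (r in which(is_eii)) bins[r] <- fetch_bin(sys, tr$B[r], tr$U[r])
  }
  chan <- integer(nrow(tr))
  chan[] <- -1L
  if (sys$nch > 0) {
    for (r in seq_len(nrow(tr))) {
      if (tr$type[r] %in% c(0, 1)) chan[r] <- sys$chan_of(i, tr$type[r])
    }
  }
  cpp_sys_add_transitions(sys$ptr, i - 1L, as.integer(tr$type),
                          as.integer(loc[tr$src] - 1L),
                          as.integer(loc[tr$dst] - 1L),
                          tr$a, tr$dE, as.integer(bins), tr$gr,
                          as.integer(chan), tr$edep)
  invisible(NULL)
}

# lazy expansion sweep: expand any populated-but-unexpanded configuration
expand_populated <- function(sys) {
  st <- cpp_sys_get_state(sys$ptr)
  for (i in seq_along(sys$models)) {
    if (!length(sys$procs[[i]])) next
    P <- st$P[[i]]
    act <- sys$active[[i]]
    hot <- act[P > sys$policy$expand_threshold]
    hot <- hot[!sys$expanded[[i]][hot]]
    if (length(hot)) expand_configs(sys, i, hot)
  }
  invisible(NULL)
}

#' Advance a system by one interval
#'
#' Adaptive integration to `t + dt_fs`; local truncation error is controlled
#' by the policy tolerance. Step-size underflow raises a stiffness error.
#'
#' @param sys a [build_system()] object
#' @param dt_fs interval length (fs)
#' @export
step_system <- function(sys, dt_fs) {
  stopifnot(dt_fs > 0)
  res <- cpp_sys_advance(sys$ptr, fs_to_au(sys$t_fs + dt_fs))
  if (!isTRUE(res$ok)) {
    stop("propagation failure: ", res$msg)
  }
  sys$t_fs <- au_to_fs(res$t)
  invisible(sys)
}

# apply an impulsive tracer injection
apply_impulse <- function(sys, tr) {
  st <- cpp_sys_get_state(sys$ptr)
  ntot <- sum(sys$ndens_au)
  dens <- tr$density_frac * ntot
  p <- cpp_sys_project_point(sys$ptr, ev_to_au(tr$e0_ev))
  st$c <- st$c + dens * p
  if (sys$nch > 0 && tr$chan >= 0) {
    st$G[, tr$chan + 1] <- st$G[, tr$chan + 1] + dens * p
  }
  st$ledger[7] <- st$ledger[7] + dens
  st$ledger[8] <- st$ledger[8] + dens * ev_to_au(tr$e0_ev)
  cpp_sys_set_state(sys$ptr, st$t, st$c, st$G, st$P, st$ledger)
  invisible(NULL)
}

#' Run a full simulation
#'
#' Integrates the coupled system over the pulse, sampling the trajectory on a
#' regular output grid. The default window follows the convention of running
#' from -1.2 to +1.2 pulse FWHM around the peak.
#'
#' @inheritParams build_system
#' @param t_start_fs,t_end_fs simulation window relative to the pulse peak
#' @param out_dt_fs output sampling interval
#' @param sys optionally, a prebuilt [build_system()] object
#' @return object of class `cr_trajectory`
#' @export
run_simulation <- function(target, pulse, policy = solver_policy(),
                           t_start_fs = -1.2 * pulse$fwhm_fs,
                           t_end_fs = 1.2 * pulse$fwhm_fs,
                           out_dt_fs = 0.25, channels = FALSE,
                           tracers = list(), sys = NULL,
                           use_model_cache = TRUE) {
  if (t_start_fs >= t_end_fs) stop("t_start must precede t_end")
  if (is.null(sys)) {
    sys <- build_system(target, pulse, policy, channels = channels,
                        tracers = tracers, use_model_cache = use_model_cache)
  }
  sys$t_fs <- t_start_fs
  st0 <- cpp_sys_get_state(sys$ptr)
  cpp_sys_set_state(sys$ptr, fs_to_au(t_start_fs), st0$c, st0$G, st0$P,
                    st0$ledger)

  times <- seq(t_start_fs, t_end_fs, by = out_dt_fs)
  if (times[length(times)] < t_end_fs) times <- c(times, t_end_fs)
  nt <- length(times)
  nel <- length(sys$symbols)
  K <- sys$basis$K

  rec <- list(
    charge = matrix(NA_real_, nt, nel, dimnames = list(NULL, sys$symbols)),
    bound = matrix(NA_real_, nt, nel, dimnames = list(NULL, sys$symbols)),
    shell_occ = lapply(seq_len(nel), function(i)
      matrix(NA_real_, nt, sys$models[[i]]$nsh,
             dimnames = list(NULL, sys$models[[i]]$shells$label))),
    f_coef = matrix(NA_real_, nt, K),
    ledger = matrix(NA_real_, nt, 8, dimnames = list(NULL,
      c("absorbed_e", "radiated_e", "photo", "auger", "eii", "tbr",
        "injected", "injected_e"))),
    channel_density = if (sys$nch > 0)
      matrix(NA_real_, nt, sys$nch, dimnames = list(NULL, sys$chan_names)),
    bound_energy = numeric(nt),
    free_density = numeric(nt), free_energy = numeric(nt))

  record <- function(k) {
    st <- cpp_sys_get_state(sys$ptr)
    for (i in seq_len(nel)) {
      m <- sys$models[[i]]
      P <- st$P[[i]]
      act <- sys$active[[i]]
      nb <- rowSums(m$cs$occ[act, , drop = FALSE])
      bnd <- sum(P * nb)
      rec$charge[k, i] <<- m$Z - bnd
      rec$bound[k, i] <<- bnd
      rec$shell_occ[[i]][k, ] <<- drop(t(m$cs$occ[act, , drop = FALSE]) %*% P)
      rec$bound_energy[k] <<- rec$bound_energy[k] +
        sys$ndens_au[i] * sum(P * m$st$E[act])
    }
    rec$f_coef[k, ] <<- st$c
    rec$ledger[k, ] <<- st$ledger
    rec$free_density[k] <<- sum(basis_au_vec(sys)$m * st$c)
    rec$free_energy[k] <<- sum(basis_au_vec(sys)$e * st$c)
    if (sys$nch > 0) {
      rec$channel_density[k, ] <<- drop(basis_au_vec(sys)$m %*% st$G)
    }
  }

  # pending impulse tracers sorted by time
  impulses <- Filter(function(t) t$mode == "impulse", sys$tracers)
  imp_done <- logical(length(impulses))

  record(1)
  tprev <- times[1]
  for (k in 2:nt) {
    # impulses due within this interval fire at the interval start
    for (q in seq_along(impulses)) {
      if (!imp_done[q] && impulses[[q]]$time_fs <= tprev + 1e-9) {
        apply_impulse(sys, impulses[[q]])
        imp_done[q] <- TRUE
      }
    }
    tb <- times[k]
    while (sys$t_fs < tb - 1e-9) {
      tnext <- min(tb, sys$t_fs + sys$policy$chunk_fs)
      res <- cpp_sys_advance(sys$ptr, fs_to_au(tnext))
      if (!isTRUE(res$ok)) {
        traj <- finalize_trajectory(sys, times[seq_len(k - 1)], rec)
        stop(structure(class = c("cr_propagation_error", "error", "condition"),
                       list(message = paste0("propagation failure at t = ",
                                             signif(sys$t_fs, 5), " fs: ",
                                             res$msg),
                            call = sys.call(), partial = traj)))
      }
      sys$t_fs <- au_to_fs(res$t)
      expand_populated(sys)
      repair_channel_sum(sys)
    }
    record(k)
    tprev <- tb
  }
  finalize_trajectory(sys, times, rec)
}

# cached a.u. moment vectors of the system basis
basis_au_vec <- function(sys) {
  if (is.null(sys$au_m)) {
    au <- basis_au_mirror(sys$basis)
    sys$au_m <- list(m = au$mvec, e = au$evec)
  }
  sys$au_m
}

# enforce sum(g_n) = f exactly at orchestration boundaries
repair_channel_sum <- function(sys) {
  if (sys$nch == 0) return(invisible(NULL))
  st <- cpp_sys_get_state(sys$ptr)
  resid <- st$c - rowSums(st$G)
  if (max(abs(resid)) == 0) return(invisible(NULL))
  wsum <- rowSums(abs(st$G))
  share <- abs(st$G) / ifelse(wsum > 0, wsum, 1)
  share[wsum == 0, ] <- 1 / sys$nch
  st$G <- st$G + share * resid
  cpp_sys_set_state(sys$ptr, st$t, st$c, st$G, st$P, st$ledger)
  invisible(NULL)
}

finalize_trajectory <- function(sys, times, rec) {
  nt <- length(times)
  keep <- seq_len(nt)
  fau <- CM3_AU * HARTREE_EV
  structure(list(
    time_fs = times,
    basis = sys$basis,
    f_coef = rec$f_coef[keep, , drop = FALSE] / fau,  # cm^-3 eV^-1
    charge = rec$charge[keep, , drop = FALSE],
    bound = rec$bound[keep, , drop = FALSE],
    shell_occ = lapply(rec$shell_occ, function(x) x[keep, , drop = FALSE]),
    ledger = rec$ledger[keep, , drop = FALSE],
    channel_density = if (!is.null(rec$channel_density))
      rec$channel_density[keep, , drop = FALSE] / CM3_AU,
    channel_names = sys$chan_names,
    bound_energy_au = rec$bound_energy[keep],
    free_density_cm3 = rec$free_density[keep] / CM3_AU,
    free_energy_ev_cm3 = rec$free_energy[keep] * HARTREE_EV / CM3_AU,
    elements = data.frame(symbol = sys$symbols,
                          Z = sapply(sys$models, `[[`, "Z"),
                          ndens_cm3 = as.numeric(sys$target$ndens_cm3),
                          stringsAsFactors = FALSE),
    target = sys$target, pulse = sys$pulse, policy = sys$policy,
    system = sys), class = "cr_trajectory")
}

#' @export
print.cr_trajectory <- function(x, ...) {
  nt <- length(x$time_fs)
  cat("<cr_trajectory>", nt, "samples over [", x$time_fs[1], ",",
      x$time_fs[nt], "] fs\n  final charges:",
      paste(sprintf("%s %+0.2f", x$elements$symbol, x$charge[nt, ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Conservation ledger summary of a trajectory
#'
#' Reports the relative drift of the total (bound + free - injected) electron
#' count and the closure of the energy ledger: absorbed photon energy + any
#' injected energy against the change in bound-state energy, the free kinetic
#' energy and the radiated fluorescence energy.
#'
#' @param traj a [run_simulation()] trajectory
#' @return list with per-sample drift series and summary maxima
#' @export
conservation_report <- function(traj) {
  if (length(traj$time_fs) == 0) stop("empty trajectory")
  nel <- nrow(traj$elements)
  ndens <- traj$elements$ndens_cm3
  bound_cm3 <- drop(traj$bound %*% ndens)
  free_cm3 <- traj$free_density_cm3
  inj_cm3 <- traj$ledger[, "injected"] / CM3_AU
  total <- bound_cm3 + free_cm3 - inj_cm3
  n_drift <- (total - total[1]) / total[1]
  # energy (eV / cm^3)
  conv <- HARTREE_EV / CM3_AU
  absorbed <- traj$ledger[, "absorbed_e"] * conv
  radiated <- traj$ledger[, "radiated_e"] * conv
  injectedE <- traj$ledger[, "injected_e"] * conv
  dbound <- (traj$bound_energy_au - traj$bound_energy_au[1]) * conv
  freeE <- traj$free_energy_ev_cm3
  closure <- absorbed + injectedE - (dbound + freeE - freeE[1] + radiated)
  scale <- pmax(absorbed + injectedE, max(absorbed + injectedE) * 1e-3 + 1e-300)
  e_resid <- closure / scale
  e_resid[absorbed + injectedE == 0] <- 0
  list(time_fs = traj$time_fs,
       electron_drift = n_drift,
       energy_residual = e_resid,
       max_electron_drift = max(abs(n_drift)),
       max_energy_residual = max(abs(e_resid)),
       events = traj$ledger[length(traj$time_fs),
                            c("photo", "auger", "eii", "tbr")] / CM3_AU)
}

#' Tracer: impulsive monoenergetic injection
#'
#' A negligibly small electron density added at one time and energy, tracked
#' as its own cascade-partition channel.
#'
#' @param e0_ev injection energy (eV)
#' @param time_fs injection time (fs)
#' @param density_frac injected density as a fraction of the total atom
#'   density (default keeps the tracer in the linear-response regime)
#' @export
tracer_impulse <- function(e0_ev, time_fs, density_frac = 1e-8) {
  list(mode = "impulse", e0_ev = e0_ev, time_fs = time_fs,
       density_frac = density_frac, chan = -1L)
}

#' Tracer: intensity-proportional injection
#'
#' Electrons added at a rate proportional to the instantaneous photon flux,
#' scaled to `multiple` times the photoionization rate of the undamaged
#' target.
#'
#' @param e0_ev injection energy (eV)
#' @param multiple rate multiple of the undamaged-target photoionization rate
#' @export
tracer_flux <- function(e0_ev, multiple = 3) {
  list(mode = "flux", e0_ev = e0_ev, multiple = multiple, chan = -1L)
}
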