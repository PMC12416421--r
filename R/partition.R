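# Cascade partition: auxiliary distributions g_n(eps, t) that decompose the
# free-electron density by the primary process that seeded each electron's
# lineage. Channels evolve under the same kernels as f: photo/Auger sources
# feed their own channels, EII secondaries are credited to the impactor's
# channel in proportion to its share of the impacting density, and TBR flux
# between two channels is split evenly between them. The partition is
# advanced alongside f by [run_simulation()] with `channels = TRUE`.

#' Channel densities of a partitioned run
#'
#' @param traj trajectory from `run_simulation(..., channels = TRUE)`
#' @return data.frame: time_fs plus one density column (cm^-3) per channel
#' @export
cascade_channels <- function(traj) {
  if (is.null(traj$channel_density)) {
    stop("trajectory was not run with channels = TRUE")
  }
  data.frame(time_fs = traj$time_fs, traj$channel_density, check.names = FALSE)
}

#' Fraction of the free-electron density seeded by given channels
#'
#' @param traj partitioned trajectory
#' @param channels channel names (e.g. "Gd photo"), or element symbols to
#'   select all their channels
#' @param t_fs evaluation time (defaults to all samples)
#' @return data.frame with time_fs and fraction
#' @export
channel_fraction <- function(traj, channels, t_fs = NULL) {
  if (is.null(traj$channel_density)) {
    stop("trajectory was not run with channels = TRUE")
  }
  nm <- traj$channel_names
  pick <- nm %in% channels |
    vapply(strsplit(nm, " "), `[`, "", 1) %in% channels
  if (!any(pick)) stop("no matching channels")
  tot <- rowSums(traj$channel_density)
  frac <- rowSums(traj$channel_density[, pick, drop = FALSE]) /
    ifelse(tot > 0, tot, 1)
  out <- data.frame(time_fs = traj$time_fs, fraction = frac)
  if (!is.null(t_fs)) {
    k <- which.min(abs(out$time_fs - t_fs))
    out <- out[k, , drop = FALSE]
  }
  out
}

#' Inject a tracer electron population into a live system
#'
#' Adds a labelled channel fed either by a one-off impulse (negligibly small
#' density at a single time, applied immediately) or at a rate proportional
#' to the pulse intensity. The tracer evolves under the same kernels as every
#' other channel; its induced ionization is read off the channel density.
#'
#' @param sys a [build_system()] object built with `channels = TRUE` and the
#'   tracer declared, or any system for an immediate impulse without its own
#'   channel
#' @param e0_ev injection energy (eV); must lie inside the energy grid
#' @param schedule a [tracer_impulse()] or [tracer_flux()]
#' @export
inject_tracer <- function(sys, e0_ev, schedule = tracer_impulse(e0_ev, 0)) {
  if (e0_ev <= sys$basis$emin || e0_ev >= sys$basis$emax) {
    stop("tracer energy outside the energy grid; regrid needed")
  }
  schedule$e0_ev <- e0_ev
  if (schedule$mode == "impulse") {
    apply_impulse(sys, schedule)
  } else {
    coef <- 0
    for (i in seq_along(sys$models)) {
      if (!("photo" %in% sys$procs[[i]])) next
      m <- sys$models[[i]]
      psc <- if (is.null(m$st$photo_scale)) 1 else m$st$photo_scale
      coef <- coef + sys$ndens_au[i] *
        sum(m$st$sigma[, m$cs$ground] * psc, na.rm = TRUE)
    }
    cpp_sys_add_tracer(sys$ptr, ev_to_au(e0_ev), schedule$multiple * coef,
                       -1L)
  }
  invisible(sys)
}

#' Per-injected-electron ionization of a tracer cascade
#'
#' Ratio of the tracer channel's density to the injected density; values
#' above 1 measure the secondary ionization produced by the cascade (reduced
#' at late times by recombination).
#'
#' @param traj partitioned trajectory with a tracer channel
#' @param pulse pulse for intensity averaging (defaults to trajectory pulse)
#' @return list with the trace and its intensity average
#' @export
tracer_yield <- function(traj, pulse = traj$pulse) {
  k <- grep("^tracer@", traj$channel_names)
  if (length(k) != 1) stop("expected exactly one tracer channel")
  inj <- traj$ledger[, "injected"] / CM3_AU
  dens <- traj$channel_density[, k]
  yield <- ifelse(inj > 0, dens / inj, 0)
  ia <- intensity_averaged(
    data.frame(time_fs = traj$time_fs, x = yield), pulse)
  list(trace = data.frame(time_fs = traj$time_fs, yield = yield),
       intensity_averaged = ia)
}
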