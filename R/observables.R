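# Observables computed from trajectories: charge traces, intensity-averaged
# charges, electron density ratios (EDR), ionization contrast, and snapshots
# of the free-electron energy distribution.

#' Average charge trace of an element
#'
#' Z minus the expected bound-electron count under the configuration
#' populations P(t).
#'
#' @param traj a [run_simulation()] trajectory
#' @param element element symbol
#' @return data.frame with time_fs and charge
#' @export
average_charge_trace <- function(traj, element) {
  i <- match(element, traj$elements$symbol)
  if (is.na(i)) stop("element ", element, " not present in trajectory")
  data.frame(time_fs = traj$time_fs, charge = traj$charge[, i])
}

#' Stoichiometry-weighted mean charge of a set of elements
#'
#' The "protein light atom" observable: abundance-weighted mean charge of
#' C, N and O by default.
#'
#' @param traj trajectory
#' @param elements element symbols
#' @return data.frame with time_fs and charge
#' @export
light_atom_charge_trace <- function(traj, elements = c("C", "N", "O")) {
  idx <- match(elements, traj$elements$symbol)
  if (any(is.na(idx))) {
    stop("elements not in trajectory: ",
         paste(elements[is.na(idx)], collapse = ", "))
  }
  w <- traj$elements$ndens_cm3[idx]
  q <- drop(traj$charge[, idx, drop = FALSE] %*% w) / sum(w)
  data.frame(time_fs = traj$time_fs, charge = q)
}

#' Pulse-intensity-weighted time average of a trace
#'
#' integral Phi(t) x(t) dt with the normalized temporal profile Phi of the
#' pulse; the average is normalized over the covered window.
#'
#' @param trace data.frame with columns time_fs and a value column (second
#'   column used), or a numeric vector paired with `time_fs`
#' @param pulse a [pulse_profile()] supplying Phi
#' @param time_fs sample times if `trace` is a bare vector
#' @return scalar
#' @export
intensity_averaged <- function(trace, pulse, time_fs = NULL) {
  if (is.data.frame(trace)) {
    tt <- trace$time_fs
    x <- trace[[setdiff(names(trace), "time_fs")[1]]]
  } else {
    tt <- time_fs
    x <- trace
  }
  if (is.null(tt) || length(tt) != length(x)) stop("trace times missing")
  # coverage check: the window must contain the bulk of Phi
  if (pulse$shape == "gaussian") {
    lo <- pulse$t0_fs - 2.5 * pulse$sigma_fs
    hi <- pulse$t0_fs + 2.5 * pulse$sigma_fs
  } else {
    lo <- pulse$t0_fs - pulse$fwhm_fs / 2
    hi <- pulse$t0_fs + pulse$fwhm_fs / 2
  }
  if (min(tt) > lo + 1e-6 || max(tt) < hi - 1e-6) {
    stop("trace does not cover the pulse support [", signif(lo, 4), ", ",
         signif(hi, 4), "] fs")
  }
  phi <- pulse_flux(pulse, tt) / pulse$fluence_um2
  dt <- diff(tt)
  wts <- c(dt / 2, 0) + c(0, dt / 2)   # trapezoid
  sum(wts * phi * x) / sum(wts * phi)
}

#' Electron density ratio (EDR)
#'
#' Probe-intensity-averaged bound-electron count of one heavy atom over the
#' intensity-averaged total bound count of a light-atom reference region.
#'
#' @param traj trajectory
#' @param heavy heavy-site element symbol
#' @param reference named vector of reference-region atom counts
#'   (default C20 N10 O10)
#' @param probe pulse profile used for the intensity weighting (defaults to
#'   the trajectory's pulse)
#' @return list with numerator, denominator, undamaged values and the ratio
#' @export
compute_edr <- function(traj, heavy = "Gd",
                        reference = c(C = 20, N = 10, O = 10),
                        probe = traj$pulse) {
  ih <- match(heavy, traj$elements$symbol)
  if (is.na(ih)) stop("heavy element ", heavy, " not simulated")
  ir <- match(names(reference), traj$elements$symbol)
  if (any(is.na(ir))) stop("reference elements not simulated")
  num <- intensity_averaged(
    data.frame(time_fs = traj$time_fs, x = traj$bound[, ih]), probe)
  den_trace <- drop(traj$bound[, ir, drop = FALSE] %*% reference)
  den <- intensity_averaged(
    data.frame(time_fs = traj$time_fs, x = den_trace), probe)
  if (den <= 0) stop("reference region has no bound electrons")
  Zh <- traj$elements$Z[ih]
  Zr <- sum(reference * traj$elements$Z[ir])
  list(numerator = num, denominator = den, ratio = num / den,
       undamaged_ratio = Zh / Zr, heavy = heavy, reference = reference)
}

#' Heavy-atom ionization contrast between two exposures
#'
#' Difference in intensity-averaged heavy-atom charge between a high- and a
#' low-fluence trajectory. Uncorrected: the actual simulated charge
#' difference (equivalent to assuming an undamaged reference region in the
#' EDR). Corrected: inferred from the EDR difference with the simulated
#' time-dependent reference occupancies in the denominator, which lowers the
#' apparent contrast whenever the light atoms ionize.
#'
#' @param traj_high,traj_low trajectories of the two exposures (same target)
#' @param heavy heavy element symbol
#' @param reference reference-region composition
#' @param correct_light apply the light-atom-ionization correction
#' @return electrons per heavy atom (scalar)
#' @export
ionization_contrast <- function(traj_high, traj_low, heavy = "Gd",
                                reference = c(C = 20, N = 10, O = 10),
                                correct_light = FALSE) {
  if (!identical(traj_high$elements$symbol, traj_low$elements$symbol)) {
    stop("trajectories have mismatched targets")
  }
  eh <- compute_edr(traj_high, heavy, reference, probe = traj_high$pulse)
  el <- compute_edr(traj_low, heavy, reference, probe = traj_low$pulse)
  if (correct_light) {
    ref0 <- sum(reference * traj_high$elements$Z[
      match(names(reference), traj_high$elements$symbol)])
    (el$ratio - eh$ratio) * ref0
  } else {
    el$numerator - eh$numerator
  }
}

#' Snapshot of the free-electron energy distribution
#'
#' @param traj trajectory
#' @param t_fs snapshot time (must lie inside the trajectory)
#' @param e_ev optional reporting energies (default: log grid over the basis
#'   domain)
#' @param clip_negative clip small negative spline undershoots in the report
#' @return data.frame with e_ev, f (cm^-3 eV^-1) and energy density e*f;
#'   attributes `density` and `energy` carry the totals
#' @export
distribution_snapshot <- function(traj, t_fs, e_ev = NULL,
                                  clip_negative = TRUE) {
  tt <- traj$time_fs
  if (t_fs < tt[1] - 1e-9 || t_fs > tt[length(tt)] + 1e-9) {
    stop("snapshot time outside trajectory range")
  }
  # linear interpolation of coefficients in time
  k <- findInterval(t_fs, tt, all.inside = TRUE)
  w <- (t_fs - tt[k]) / max(tt[k + 1] - tt[k], 1e-12)
  coef <- (1 - w) * traj$f_coef[k, ] + w * traj$f_coef[k + 1, ]
  bas <- traj$basis
  if (is.null(e_ev)) {
    e_ev <- exp(seq(log(max(bas$emin, 0.05)), log(bas$emax), length.out = 400))
  }
  f <- drop(cpp_bspline_design(bas$knots, bas$order, e_ev) %*% coef)
  dens <- sum(bas$mvec * coef)
  ener <- sum(bas$evec * coef)
  if (clip_negative) {
    neg <- -sum(pmin(f, 0))
    if (neg > 1e-6 * max(sum(pmax(f, 0)), 1e-300)) {
      warning("negative spline density ", signif(neg, 3),
              " clipped in snapshot")
    }
    f <- pmax(f, 0)
  }
  out <- data.frame(e_ev = e_ev, f = f, ef = e_ev * f)
  attr(out, "density") <- dens
  attr(out, "energy") <- ener
  out
}
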