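# Atomic-structure module: electronic configurations and the per-element
# atomic data driving the kinetics (binding energies, photoionization
# cross-sections, Auger/fluorescence decay rates, BEB impact-ionization
# cross-sections and their microreversible recombination kernels).
#
# Mean field: configuration-average SCF with Slater local exchange and the
# Latter tail correction on a logarithmic radial grid (C++ backend).
# Ionization thresholds and transition energies are total-energy differences
# between configurations (Delta-SCF), so per-event energy bookkeeping closes.

#' Enumerate the ionization-reachable configurations of an element
#'
#' All subshell occupancy vectors with each occupancy between 0 and its
#' ground-state value. Recombination never raises an occupancy above the
#' ground state, so this set is closed under every modeled process. For heavy
#' elements (`collapse = TRUE`, default for Z >= 30) all subshells of a
#' principal shell are merged into a single level with the summed ground
#' occupancy, which keeps the combinatorics tractable (e.g. Gd: 400140
#' configurations on 6 collapsed shells instead of ~1e9 on subshells).
#'
#' @param Z atomic number (1..92)
#' @param collapse merge each principal shell into one level (default for
#'   Z >= 30)
#' @return an object of class `config_set`: shell table, occupancy matrix
#'   (configurations x shells), ground-state index
#' @examples
#' cs <- enumerate_configurations(6)
#' nrow(cs$occ)  # 27
#' @export
enumerate_configurations <- function(Z, collapse = Z >= 30) {
  gs <- ground_subshells(Z)
  if (collapse) {
    agg <- stats::aggregate(cbind(cap, occ) ~ n, data = gs, FUN = sum)
    shells <- data.frame(n = agg$n, l = 0L, label = paste0("n", agg$n),
                         cap = pmin(agg$cap, 2 * agg$n^2), occ = agg$occ,
                         stringsAsFactors = FALSE)
  } else {
    shells <- gs
  }
  nsh <- nrow(shells)
  grid <- lapply(shells$occ, function(g) 0:g)
  occ <- as.matrix(rev(expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE)))
  dimnames(occ) <- list(NULL, shells$label)
  storage.mode(occ) <- "integer"
  key <- as.numeric(occ %*% 32^(seq_len(nsh) - 1))
  ground <- which(key == sum(shells$occ * 32^(seq_len(nsh) - 1)))
  ord <- order(key)
  structure(list(Z = Z, collapse = collapse, shells = shells, occ = occ,
                 key = key, key_sorted = key[ord], ord = ord,
                 ground = ground, n = nrow(occ)),
            class = "config_set")
}

#' @export
print.config_set <- function(x, ...) {
  cat("<config_set> Z =", x$Z, if (x$collapse) "(collapsed shells)" else "",
      "\n  shells:", paste(x$shells$label, collapse = " "),
      "\n  configurations:", x$n, "\n")
  invisible(x)
}

# index of an occupancy vector within a config_set (0 if absent)
config_index <- function(cs, occvec) {
  key <- sum(as.numeric(occvec) * 32^(seq_along(occvec) - 1))
  pos <- cpp_key_lookup(cs$key_sorted, key)
  if (pos >= 1) cs$ord[pos] else 0L
}

# log statistical weight of a configuration: sum log C(cap, occ)
config_log_g <- function(shells, occvec) {
  sum(lchoose(shells$cap, occvec))
}

#' Self-consistent mean field for one configuration
#'
#' Configuration-average SCF with Slater (X-alpha) exchange and Latter tail
#' correction. Returns orbital binding energies B = -eps (eV), mean orbital
#' kinetic energies U (eV), and the total electronic energy (eV). Bare nuclei
#' give a zero-orbital result; one-electron ions are solved exactly.
#'
#' @param Z atomic number
#' @param occ occupancy vector over the element's (possibly collapsed) shells,
#'   or a configuration index together with `shells` from
#'   [enumerate_configurations()]
#' @param shells shell table (data.frame with n, l, cap); defaults to the
#'   neutral ground-state structure
#' @param alpha_x Slater exchange coefficient
#' @return list with B (eV), U (eV), E_total (eV), and the radial solution
#' @export
solve_mean_field <- function(Z, occ, shells = NULL, alpha_x = 0.8) {
  if (is.null(shells)) {
    shells <- ground_subshells(Z)
  }
  stopifnot(length(occ) == nrow(shells), all(occ >= 0), all(occ <= shells$cap))
  res <- cpp_scf(as.integer(Z), as.integer(shells$n), as.integer(shells$l),
                 as.numeric(occ), alpha_x)
  if (!isTRUE(res$converged)) {
    stop("SCF did not converge for Z = ", Z, " occ = ",
         paste(occ, collapse = ","), " (last residual ", res$residual, ")")
  }
  list(B = -res$eps * HARTREE_EV, U = res$U * HARTREE_EV,
       E_total = res$Etot * HARTREE_EV, scf = res)
}

#' Photoionization cross-section of a subshell
#'
#' Numeric dipole matrix element between the SCF bound orbital and a
#' continuum wave in the same mean-field potential. The threshold is the
#' total-energy difference to the ionized configuration (Delta-SCF), so the
#' cross-section is zero below the per-configuration edge.
#'
#' @param Z atomic number
#' @param occ occupancy vector
#' @param subshell index into the shell table
#' @param photon_energy_ev photon energy (eV)
#' @param shells optional shell table
#' @return cross-section in cm^2 (includes the subshell occupancy)
#' @export
photoionization_cross_section <- function(Z, occ, subshell, photon_energy_ev,
                                          shells = NULL) {
  if (photon_energy_ev < 0) stop("photon energy must be non-negative")
  if (is.null(shells)) shells <- ground_subshells(Z)
  if (occ[subshell] <= 0) return(0)
  src <- solve_mean_field(Z, occ, shells)
  occ2 <- occ
  occ2[subshell] <- occ2[subshell] - 1
  dst <- solve_mean_field(Z, occ2, shells)
  dE <- (dst$E_total - src$E_total) / HARTREE_EV
  if (dE <= 0) return(0)
  sg <- cpp_photo_xs(src$scf$r, src$scf$V, src$scf$P[, subshell],
                     as.integer(shells$l[subshell]), dE, occ[subshell],
                     photon_energy_ev / HARTREE_EV)
  au_to_cm2(sg)
}

#' BEB electron-impact ionization cross-section
#'
#' Binary-encounter-Bethe total cross-section
#' \deqn{\sigma = \frac{S}{t+u+1}\left[\frac{\ln t}{2}\left(1-\frac{1}{t^2}\right)
#'   + 1 - \frac{1}{t} - \frac{\ln t}{t+1}\right]}
#' with t = T/B, u = U/B, S = 4 pi a0^2 N (R/B)^2.
#'
#' @param B binding energy (eV, > 0)
#' @param U mean orbital kinetic energy (eV, > 0)
#' @param N subshell occupancy
#' @param T_ev incident electron energy (eV); vectorized
#' @return cross-section (cm^2); zero at and below threshold
#' @export
eii_cross_section <- function(B, U, N, T_ev) {
  if (B <= 0 || U <= 0) stop("B and U must be positive")
  au_to_cm2(cpp_beb_sigma(ev_to_au(B), ev_to_au(U), N, ev_to_au(T_ev)))
}

#' BEB singly differential ionization cross-section
#'
#' dsigma/dW at secondary energy W; symmetric under exchange of the two
#' outgoing electrons (W <-> T - B - W) and integrating over the slower
#' branch [0, (T-B)/2] recovers [eii_cross_section()].
#'
#' @inheritParams eii_cross_section
#' @param W_ev secondary electron energy (eV); vectorized
#' @return differential cross-section (cm^2 / eV)
#' @export
eii_sdcs <- function(B, U, N, T_ev, W_ev) {
  if (B <= 0 || U <= 0) stop("B and U must be positive")
  au_to_cm2(cpp_beb_sdcs(ev_to_au(B), ev_to_au(U), N, ev_to_au(T_ev),
                         ev_to_au(W_ev))) / HARTREE_EV
}

#' Microreversible three-body recombination kernel
#'
#' Constructed from the BEB differential cross-section by detailed balance,
#' so that with a Maxwellian electron distribution and Saha-balanced
#' populations the net EII - TBR flux vanishes. Returned in atomic units
#' (recombination rate = g_ratio * integral f(e1) f(e2) K de1 de2 per ion).
#'
#' @inheritParams eii_cross_section
#' @param e1_ev,e2_ev energies of the two incoming free electrons (eV)
#' @param g_ratio statistical-weight ratio g(recombined)/g(ionized)
#' @return kernel value (atomic units), >= 0
#' @export
tbr_kernel <- function(B, U, N, e1_ev, e2_ev, g_ratio = 1) {
  if (B <= 0 || U <= 0) stop("B and U must be positive")
  if (N <= 0) return(numeric(length(e1_ev)))
  g_ratio * N * cpp_tbr_kernel0(ev_to_au(B), ev_to_au(U), 1,
                                ev_to_au(e1_ev), ev_to_au(e2_ev))
}

#' Auger and fluorescence decay channels of a configuration
#'
#' A shell is a hole when its occupancy is below the ground-state value and
#' some higher shell is occupied. Total per-hole widths are scaled tabulated
#' level widths split between Auger and fluorescence by the fluorescence
#' yield; Auger channels are weighted by available electron pairs and channels
#' with non-positive ejection energy are suppressed.
#'
#' @param Z atomic number
#' @param occ occupancy vector
#' @param shells optional shell table
#' @param energies optional precomputed total energies (eV) keyed by
#'   configuration (internal use)
#' @return data.frame: type ("auger"/"fluor"), destination occupancies,
#'   rate (fs^-1), energy (eV; ejected electron or photon)
#' @export
decay_rates <- function(Z, occ, shells = NULL) {
  if (is.null(shells)) shells <- ground_subshells(Z)
  ground <- shells$occ
  src <- solve_mean_field(Z, occ, shells)
  nsh <- nrow(shells)
  out <- list()
  for (h in seq_len(nsh)) {
    nh <- ground[h] - occ[h]
    if (nh <= 0) next
    above <- seq_len(nsh)[seq_len(nsh) > h]
    if (length(above) == 0 || sum(occ[above]) == 0) next
    width_au <- ev_to_au(hole_width_ev(Z, shells$n[h])) * nh
    wfl <- fluor_yield(Z, shells$n[h])
    # Auger pair weights
    pairs <- list()
    wsum <- 0
    for (j in above) for (k in above[above >= j]) {
      w <- if (j == k) occ[j] * (occ[j] - 1) / 2 else occ[j] * occ[k]
      if (w > 0) {
        pairs[[length(pairs) + 1]] <- c(j, k, w)
        wsum <- wsum + w
      }
    }
    # reference pair count: ground occupancies above h
    g_above <- ground[above]
    wmax <- sum(outer(g_above, g_above)[upper.tri(diag(length(above)), diag = FALSE)]) +
      sum(g_above * (g_above - 1) / 2)
    wmax <- max(wmax, wsum, 1)
    if (wsum > 0) {
      rate_auger_tot <- width_au * (1 - wfl) * min(1, wsum / wmax)
      for (p in pairs) {
        j <- p[1]; k <- p[2]; w <- p[3]
        occ2 <- occ
        occ2[h] <- occ2[h] + 1
        occ2[j] <- occ2[j] - 1
        occ2[k] <- occ2[k] - 1
        if (any(occ2 < 0)) next
        dst <- solve_mean_field(Z, occ2, shells)
        eA <- src$E_total - dst$E_total
        if (eA <= 0) next
        out[[length(out) + 1]] <- data.frame(
          type = "auger", dst = I(list(occ2)),
          rate_fs = rate_auger_tot * (w / wsum) / FS_PER_AU,
          energy_ev = eA, stringsAsFactors = FALSE)
      }
    }
    # fluorescence
    ne_above <- sum(occ[above])
    if (ne_above > 0) {
      rate_fl_tot <- width_au * wfl * min(1, ne_above / max(sum(g_above), 1))
      for (j in above) {
        if (occ[j] <= 0) next
        occ2 <- occ
        occ2[h] <- occ2[h] + 1
        occ2[j] <- occ2[j] - 1
        dst <- solve_mean_field(Z, occ2, shells)
        eF <- src$E_total - dst$E_total
        if (eF <= 0) next
        out[[length(out) + 1]] <- data.frame(
          type = "fluor", dst = I(list(occ2)),
          rate_fs = rate_fl_tot * (occ[j] / ne_above) / FS_PER_AU,
          energy_ev = eF, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(type = character(), dst = I(list()),
                      rate_fs = numeric(), energy_ev = numeric()))
  }
  do.call(rbind, out)
}
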