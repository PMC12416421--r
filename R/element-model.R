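# Internal per-element model: cached configuration-resolved atomic data for a
# run at fixed photon energy. Light elements are solved eagerly; elements with
# large (collapsed) configuration sets are solved lazily as population first
# reaches a configuration.

element_model <- function(Z, omega_ev, collapse = Z >= 30, alpha_x = 0.8,
                          lazy = NULL) {
  cs <- enumerate_configurations(Z, collapse)
  if (is.null(lazy)) lazy <- cs$n > 3000
  nsh <- nrow(cs$shells)
  st <- new.env(parent = emptyenv())
  st$E <- rep(NA_real_, cs$n)          # total energy (a.u.)
  st$eps <- matrix(NA_real_, nsh, cs$n)
  st$U <- matrix(NA_real_, nsh, cs$n)
  st$sigma <- matrix(NA_real_, nsh, cs$n)  # photoionization at omega (a.u.)
  st$scf_done <- logical(cs$n)
  st$photo_done <- logical(cs$n)
  st$warmV <- NULL
  st$warmE <- NULL
  m <- structure(list(Z = Z, symbol = ELEMENT_SYMBOLS[Z], cs = cs,
                      shells = cs$shells, nsh = nsh,
                      omega_au = ev_to_au(omega_ev),
                      alpha_x = alpha_x, lazy = lazy, st = st),
                 class = "element_model")
  if (collapse) {
    model_collapse_anchor(m)
    model_fit_surrogate(m)
  }
  if (!lazy) {
    model_ensure_scf(m, seq_len(cs$n))
    model_ensure_photo(m, seq_len(cs$n))
  }
  m
}

# Quadratic configuration-energy surrogate for collapsed heavy elements.
# With frozen orbitals the configuration-average mean-field energy is exactly
# quadratic in the occupancies,
#   E(n) = sum_s eps_s n_s + 1/2 sum_st J_st n_s (n_t - delta_st),
# so a least-squares fit of that form to a few hundred SCF samples (ionization
# ladders plus their single-removal neighbourhoods) gives closed-form energies
# for the whole configuration set; orbital relaxation enters only as a small
# residual. Per-shell sigma and U come from the anchored ground configuration,
# scaled by occupancy.
model_fit_surrogate <- function(m) {
  sh <- m$shells
  nsh <- m$nsh
  g <- sh$occ
  # sample set: outermost-first ionization ladder + single removals
  ladder <- list(g)
  occ <- g
  while (sum(occ) > 0) {
    s <- max(which(occ > 0))
    occ[s] <- occ[s] - 1L
    ladder[[length(ladder) + 1]] <- occ
  }
  samples <- ladder
  for (occ in ladder) {
    if (sum(occ) < 1) next
    for (s in which(occ > 0)) {
      o2 <- occ
      o2[s] <- o2[s] - 1L
      samples[[length(samples) + 1]] <- o2
      # double removals: the Auger-cycling region (a couple of inner holes
      # on top of any outer-ionization stage)
      for (t in which(o2 > 0)) {
        o3 <- o2
        o3[t] <- o3[t] - 1L
        samples[[length(samples) + 1]] <- o3
      }
    }
  }
  keys <- sapply(samples, function(o) sum(as.numeric(o) * 32^(seq_len(nsh) - 1)))
  samples <- samples[!duplicated(keys)]
  feat <- function(o) {
    o <- as.numeric(o)
    di <- o * (o - 1) / 2
    cross <- outer(o, o)[upper.tri(diag(nsh))]
    c(o, di, cross)
  }
  X <- t(vapply(samples, feat, numeric(nsh + nsh + nsh * (nsh - 1) / 2)))
  y <- numeric(length(samples))
  warmV <- NULL; warmE <- NULL
  for (i in seq_along(samples)) {
    o <- samples[[i]]
    if (sum(o) == 0) { y[i] <- 0; next }
    r <- cpp_scf(as.integer(m$Z), as.integer(sh$n), as.integer(sh$l),
                 as.numeric(o), m$alpha_x, ngrid = 420L,
                 V_init = warmV, eps_init = warmE)
    if (!isTRUE(r$converged)) {
      r <- cpp_scf(as.integer(m$Z), as.integer(sh$n), as.integer(sh$l),
                   as.numeric(o), m$alpha_x, ngrid = 420L)
    }
    if (!isTRUE(r$converged)) stop("surrogate sample SCF failed for Z=", m$Z)
    y[i] <- r$Etot
    if (sum(o) > 1) { warmV <- r$V; warmE <- r$eps }
  }
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  resid <- X %*% beta - y
  m$st$surrogate <- list(beta = beta, rms_ev = sqrt(mean(resid^2)) * HARTREE_EV)
  m$st$surrogate$feat <- feat
  # per-electron photoionization along the ionization ladder: at fixed photon
  # energy the cross-section grows as ionization pushes the edge towards the
  # photon line, so sigma per electron is tabulated against the threshold and
  # interpolated for off-ladder configurations
  skip <- m$st$photo_skip
  lad_tab <- vector("list", nsh)
  warmV <- NULL; warmE <- NULL
  for (occ in ladder) {
    if (sum(occ) == 0) next
    r <- cpp_scf(as.integer(m$Z), as.integer(sh$n), as.integer(sh$l),
                 as.numeric(occ), m$alpha_x, ngrid = 420L,
                 V_init = warmV, eps_init = warmE)
    if (!isTRUE(r$converged)) next
    if (sum(occ) > 1) { warmV <- r$V; warmE <- r$eps }
    for (s2 in seq_len(nsh)) {
      if (occ[s2] <= 0 || (!is.null(skip) && skip[s2])) next
      o2 <- occ; o2[s2] <- o2[s2] - 1L
      i2 <- config_index(m$cs, o2)
      dE <- surrogate_energy(m, i2) - surrogate_energy(m, config_index(m$cs, occ))
      if (!is.finite(dE) || dE <= 0 || m$omega_au <= dE) next
      sg <- cpp_photo_xs(r$r, r$V, r$P[, s2], as.integer(sh$l[s2]), dE, 1.0,
                         m$omega_au)
      lad_tab[[s2]] <- rbind(lad_tab[[s2]], c(dE, sg))
    }
  }
  m$st$sigma_ladder <- lapply(lad_tab, function(tb) {
    if (is.null(tb) || nrow(tb) < 2) return(NULL)
    tb <- tb[order(tb[, 1]), , drop = FALSE]
    tb[!duplicated(tb[, 1]), , drop = FALSE]
  })
  invisible(m)
}

surrogate_energy <- function(m, idx) {
  sg <- m$st$surrogate
  occ <- m$cs$occ[idx, , drop = FALSE]
  nsh <- m$nsh
  X <- t(apply(occ, 1, sg$feat))
  if (length(idx) == 1) X <- matrix(X, nrow = 1)
  drop(X %*% sg$beta)
}

# Anchor collapsed-shell photoionization cross-sections and orbital kinetic
# energies to a subshell-resolved SCF of the neutral ground configuration.
# A single l = 0 level per principal shell reproduces shell energetics well
# but overestimates the dipole coupling of the merged p/d/f electrons, so
# per-shell scale factors are derived once and applied to every
# configuration. U follows the occupancy-weighted mean of the merged
# subshells, per the collapse policy.
model_collapse_anchor <- function(m) {
  gs <- ground_subshells(m$Z)
  res <- cpp_scf(as.integer(m$Z), as.integer(gs$n), as.integer(gs$l),
                 as.numeric(gs$occ), m$alpha_x)
  if (!isTRUE(res$converged)) {
    stop("subshell-resolved anchor SCF failed for Z = ", m$Z)
  }
  # subshell-resolved thresholds: Delta-SCF per subshell
  sig_sub <- numeric(m$nsh)
  U_sub <- numeric(m$nsh)
  for (k in seq_len(m$nsh)) {
    nsh_n <- m$shells$n[k]
    subs <- which(gs$n == nsh_n)
    if (length(subs) == 0) next
    U_sub[k] <- sum(gs$occ[subs] * res$U[subs]) / sum(gs$occ[subs])
    for (s in subs) {
      occ2 <- gs$occ
      occ2[s] <- occ2[s] - 1
      r2 <- cpp_scf(as.integer(m$Z), as.integer(gs$n), as.integer(gs$l),
                    as.numeric(occ2), m$alpha_x,
                    V_init = res$V, eps_init = res$eps)
      dE <- if (isTRUE(r2$converged)) r2$Etot - res$Etot else -res$eps[s]
      if (dE <= 0 || m$omega_au <= dE) next
      sig_sub[k] <- sig_sub[k] +
        cpp_photo_xs(res$r, res$V, res$P[, s], as.integer(gs$l[s]), dE,
                     gs$occ[s], m$omega_au)
    }
  }
  # collapsed ground values
  g <- m$cs$ground
  model_ensure_photo(m, g)
  sig_col <- m$st$sigma[, g]
  U_col <- m$st$U[, g]
  ps <- rep(1, m$nsh)
  us <- rep(1, m$nsh)
  for (k in seq_len(m$nsh)) {
    if (is.finite(sig_col[k]) && sig_col[k] > 0) ps[k] <- sig_sub[k] / sig_col[k]
    if (is.finite(U_col[k]) && U_col[k] > 0 && U_sub[k] > 0)
      us[k] <- U_sub[k] / U_col[k]
  }
  m$st$photo_scale <- ps
  m$st$u_scale <- us
  # shells contributing < 0.5% of the element's photoabsorption are skipped
  # in per-configuration cross-section evaluation (their outer orbitals make
  # the continuum integrals disproportionately expensive)
  tot <- sum(sig_sub)
  m$st$photo_skip <- if (tot > 0) sig_sub < 0.005 * tot else rep(FALSE, m$nsh)
  invisible(m)
}

#' @export
print.element_model <- function(x, ...) {
  cat("<element_model>", x$symbol, "Z =", x$Z, "|", x$cs$n, "configurations",
      if (x$lazy) "(lazy)" else "(eager)", "\n")
  invisible(x)
}

# one SCF of a configuration with warm start from the element's last solve
model_scf_one <- function(m, i) {
  sh <- m$shells
  occ <- m$cs$occ[i, ]
  ng <- if (m$cs$collapse) 420L else 650L
  res <- cpp_scf(as.integer(m$Z), as.integer(sh$n), as.integer(sh$l),
                 as.numeric(occ), m$alpha_x, ngrid = ng,
                 V_init = m$st$warmV, eps_init = m$st$warmE)
  if (!isTRUE(res$converged)) {
    # retry cold
    res <- cpp_scf(as.integer(m$Z), as.integer(sh$n), as.integer(sh$l),
                   as.numeric(occ), m$alpha_x, ngrid = ng)
    if (!isTRUE(res$converged)) {
      stop("SCF failed for ", m$symbol, " configuration ",
           paste(occ, collapse = ","), " (residual ", res$residual, ")")
    }
  }
  if (sum(occ) > 1) {
    m$st$warmV <- res$V
    m$st$warmE <- res$eps
  }
  m$st$E[i] <- res$Etot
  m$st$eps[, i] <- res$eps
  m$st$U[, i] <- res$U
  m$st$scf_done[i] <- TRUE
  res
}

# energy-only SCF for a set of configuration indices
model_ensure_scf <- function(m, idx) {
  idx <- idx[!m$st$scf_done[idx]]
  if (length(idx) == 0) return(invisible(NULL))
  if (!is.null(m$st$surrogate)) {
    g <- m$cs$ground
    if (!m$st$scf_done[g]) model_scf_one(m, g)
    idx <- idx[idx != g]
    if (length(idx)) {
      m$st$E[idx] <- surrogate_energy(m, idx)
      m$st$eps[, idx] <- m$st$eps[, g]
      m$st$U[, idx] <- m$st$U[, g]
      m$st$scf_done[idx] <- TRUE
    }
    return(invisible(NULL))
  }
  # ascending electron count: smooth warm starts
  idx <- idx[order(rowSums(m$cs$occ[idx, , drop = FALSE]))]
  for (i in idx) model_scf_one(m, i)
  invisible(NULL)
}

# photoionization cross-sections at the run photon energy; one SCF per
# configuration, processed in ascending electron count so that ionization
# destinations (thresholds) are already available
model_ensure_photo <- function(m, idx) {
  idx <- idx[!m$st$photo_done[idx]]
  if (length(idx) == 0) return(invisible(NULL))
  sh <- m$shells
  if (!is.null(m$st$surrogate)) {
    # per-electron cross-sections from the anchored ground configuration,
    # scaled by occupancy, with per-configuration surrogate thresholds;
    # destinations resolved in batch via key arithmetic
    g <- m$cs$ground
    if (!m$st$photo_done[g] || anyNA(m$st$sigma[, g])) {
      surr <- m$st$surrogate
      m$st$surrogate <- NULL  # ground goes through the full route once
      model_ensure_photo(m, g)
      m$st$surrogate <- surr
      idx <- idx[idx != g]
      if (length(idx) == 0) return(invisible(NULL))
    }
    model_ensure_scf(m, idx)
    sig_e0 <- m$st$sigma[, g] / pmax(m$cs$occ[g, ], 1)   # per electron, ground
    occ_idx <- m$cs$occ[idx, , drop = FALSE]
    sig_new <- matrix(0, length(idx), m$nsh)
    for (s in seq_len(m$nsh)) {
      sel <- which(occ_idx[, s] > 0)
      if (length(sel) == 0) next
      jpos <- cpp_key_lookup_vec(m$cs$key_sorted,
                                 m$cs$key[idx[sel]] - 32^(s - 1))
      j <- m$cs$ord[jpos]
      model_ensure_scf(m, unique(j))
      dE <- m$st$E[j] - m$st$E[idx[sel]]
      ok <- is.finite(dE) & dE > 0 & m$omega_au > dE
      tb <- m$st$sigma_ladder[[s]]
      sig_e <- if (!is.null(tb)) {
        stats::approx(tb[, 1], tb[, 2], xout = dE[ok], rule = 2)$y
      } else rep(sig_e0[s], sum(ok))
      sig_new[sel[ok], s] <- sig_e * occ_idx[sel[ok], s]
    }
    m$st$sigma[, idx] <- t(sig_new)
    m$st$photo_done[idx] <- TRUE
    return(invisible(NULL))
  }
  # destinations needed for thresholds
  dests <- integer(0)
  for (i in idx) {
    occ <- m$cs$occ[i, ]
    for (s in which(occ > 0)) {
      occ2 <- occ; occ2[s] <- occ2[s] - 1L
      dests <- c(dests, config_index(m$cs, occ2))
    }
  }
  dests <- setdiff(unique(dests), idx)
  model_ensure_scf(m, dests)
  idx <- idx[order(rowSums(m$cs$occ[idx, , drop = FALSE]))]
  for (i in idx) {
    occ <- m$cs$occ[i, ]
    if (sum(occ) == 0) {
      m$st$scf_done[i] <- TRUE
      m$st$E[i] <- 0
      m$st$photo_done[i] <- TRUE
      next
    }
    res <- model_scf_one(m, i)
    skip <- m$st$photo_skip
    for (s in which(occ > 0)) {
      if (!is.null(skip) && skip[s]) { m$st$sigma[s, i] <- 0; next }
      occ2 <- occ; occ2[s] <- occ2[s] - 1L
      j <- config_index(m$cs, occ2)
      dE <- m$st$E[j] - m$st$E[i]
      m$st$sigma[s, i] <- if (is.finite(dE) && dE > 0 && m$omega_au > dE) {
        cpp_photo_xs(res$r, res$V, res$P[, s], as.integer(sh$l[s]), dE,
                     occ[s], m$omega_au)
      } else 0
    }
    m$st$photo_done[i] <- TRUE
  }
  invisible(NULL)
}

# Transition table for a set of configurations.
# processes: subset of c("photo", "decay", "eii")
# Returns a data.frame in atomic units with columns:
#   src, dst (config indices), type (0 photo / 1 auger / 2 fluor / 3 eii),
#   a (sigma_ph | rate | N_occ), dE, edep (free-electron deposit energy,
#   -1 if none), B, U (for eii bins), gr (stat-weight ratio for TBR)
model_transitions <- function(m, idx, processes = c("photo", "decay", "eii")) {
  sh <- m$shells
  ground <- sh$occ
  nsh <- m$nsh
  rows <- vector("list", 4096)
  nr <- 0
  add <- function(src, dst, type, a, dE, edep, B = 0, U = 0, gr = 0) {
    nr <<- nr + 1
    if (nr > length(rows)) rows <<- c(rows, vector("list", length(rows)))
    rows[[nr]] <<- c(src, dst, type, a, dE, edep, B, U, gr)
  }
  want_photo <- "photo" %in% processes
  want_decay <- "decay" %in% processes
  want_eii <- "eii" %in% processes

  if (want_photo) model_ensure_photo(m, idx) else model_ensure_scf(m, idx)

  # collect SCF of all destinations first
  dests <- integer(0)
  for (i in idx) {
    occ <- m$cs$occ[i, ]
    if (want_eii || want_photo) {
      for (s in which(occ > 0)) {
        occ2 <- occ; occ2[s] <- occ2[s] - 1L
        dests <- c(dests, config_index(m$cs, occ2))
      }
    }
    if (want_decay) {
      for (h in seq_len(nsh)) {
        if (ground[h] - occ[h] <= 0) next
        above <- seq_len(nsh)[seq_len(nsh) > h]
        for (j in above) for (k in above[above >= j]) {
          w <- if (j == k) occ[j] * (occ[j] - 1) / 2 else occ[j] * occ[k]
          if (w <= 0) next
          occ2 <- occ
          occ2[h] <- occ2[h] + 1L; occ2[j] <- occ2[j] - 1L; occ2[k] <- occ2[k] - 1L
          dests <- c(dests, config_index(m$cs, occ2))
        }
        for (j in above) {
          if (occ[j] <= 0) next
          occ2 <- occ
          occ2[h] <- occ2[h] + 1L; occ2[j] <- occ2[j] - 1L
          dests <- c(dests, config_index(m$cs, occ2))
        }
      }
    }
  }
  model_ensure_scf(m, unique(dests[dests > 0]))

  pscale <- if (is.null(m$st$photo_scale)) rep(1, nsh) else m$st$photo_scale
  uscale <- if (is.null(m$st$u_scale)) rep(1, nsh) else m$st$u_scale
  for (i in idx) {
    occ <- m$cs$occ[i, ]
    Ei <- m$st$E[i]
    lgi <- config_log_g(sh, occ)
    # --- photo and EII share destinations
    for (s in which(occ > 0)) {
      occ2 <- occ; occ2[s] <- occ2[s] - 1L
      j <- config_index(m$cs, occ2)
      dE <- m$st$E[j] - Ei
      if (dE <= 0) next
      if (want_photo) {
        sg <- m$st$sigma[s, i] * pscale[s]
        if (!is.na(sg) && sg > 0 && m$omega_au > dE) {
          add(i, j, 0, sg, dE, m$omega_au - dE)
        }
      }
      if (want_eii) {
        U <- m$st$U[s, i] * uscale[s]
        if (is.finite(U) && U > 0) {
          gr <- exp(lgi - config_log_g(sh, occ2))
          add(i, j, 3, occ[s], dE, -1, dE, U, gr)
        }
      }
    }
    # --- decay
    if (want_decay) {
      for (h in seq_len(nsh)) {
        nh <- ground[h] - occ[h]
        if (nh <= 0) next
        above <- seq_len(nsh)[seq_len(nsh) > h]
        if (length(above) == 0 || sum(occ[above]) == 0) next
        width_au <- ev_to_au(hole_width_ev(m$Z, sh$n[h])) * nh
        wfl <- fluor_yield(m$Z, sh$n[h])
        pairs <- list(); wsum <- 0
        for (j in above) for (k in above[above >= j]) {
          w <- if (j == k) occ[j] * (occ[j] - 1) / 2 else occ[j] * occ[k]
          if (w > 0) { pairs[[length(pairs) + 1]] <- c(j, k, w); wsum <- wsum + w }
        }
        g_above <- ground[above]
        np <- length(above)
        wmax <- if (np > 1) sum(outer(g_above, g_above)[upper.tri(matrix(0, np, np))]) else 0
        wmax <- wmax + sum(g_above * (g_above - 1) / 2)
        wmax <- max(wmax, wsum, 1)
        if (wsum > 0) {
          rtot <- width_au * (1 - wfl) * min(1, wsum / wmax)
          for (p in pairs) {
            occ2 <- occ
            occ2[h] <- occ2[h] + 1L; occ2[p[1]] <- occ2[p[1]] - 1L
            occ2[p[2]] <- occ2[p[2]] - 1L
            jdx <- config_index(m$cs, occ2)
            eA <- Ei - m$st$E[jdx]
            if (!is.finite(eA) || eA <= 0) next
            add(i, jdx, 1, rtot * p[3] / wsum, eA, eA)
          }
        }
        ne_above <- sum(occ[above])
        if (ne_above > 0 && wfl > 0) {
          rtot <- width_au * wfl * min(1, ne_above / max(sum(g_above), 1))
          for (j in above) {
            if (occ[j] <= 0) next
            occ2 <- occ
            occ2[h] <- occ2[h] + 1L; occ2[j] <- occ2[j] - 1L
            jdx <- config_index(m$cs, occ2)
            eF <- Ei - m$st$E[jdx]
            if (!is.finite(eF) || eF <= 0) next
            add(i, jdx, 2, rtot * occ[j] / ne_above, eF, -1)
          }
        }
      }
    }
  }
  if (nr == 0) {
    return(data.frame(src = integer(), dst = integer(), type = integer(),
                      a = numeric(), dE = numeric(), edep = numeric(),
                      B = numeric(), U = numeric(), gr = numeric()))
  }
  tab <- do.call(rbind, rows[seq_len(nr)])
  colnames(tab) <- c("src", "dst", "type", "a", "dE", "edep", "B", "U", "gr")
  as.data.frame(tab)
}

#' Export an element's atomic tables for inspection
#'
#' Writes a TSV with one row per configuration (occupancies, total energy,
#' orbital binding energies) for whatever part of the configuration set has
#' been solved.
#'
#' @param model an element model (internal builder)
#' @param path output file
#' @keywords internal
dump_atomic_tables <- function(model, path) {
  done <- which(model$st$scf_done)
  df <- data.frame(config = done, model$cs$occ[done, , drop = FALSE],
                   E_total_ev = au_to_ev(model$st$E[done]))
  for (s in seq_len(model$nsh)) {
    df[[paste0("B_", model$shells$label[s], "_ev")]] <-
      -au_to_ev(model$st$eps[s, done])
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
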