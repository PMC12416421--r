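# Shared helpers: unit shorthands, Maxwellian initialization of a live
# system, and memoised expensive runs shared across test files.

HA <- crplasma:::HARTREE_EV
CM3AU <- crplasma:::CM3_AU

maxwellian_cm3_ev <- function(e_ev, n_cm3, T_ev) {
  n_cm3 * 2 / sqrt(pi) * T_ev^-1.5 * sqrt(e_ev) * exp(-e_ev / T_ev)
}

# set the free-electron distribution of a live system to a Maxwellian
set_system_maxwellian <- function(sys, n_cm3, T_ev, P = NULL) {
  au <- crplasma:::basis_au_mirror(sys$basis)
  fq <- maxwellian_cm3_ev(au$qx * HA, n_cm3, T_ev) * CM3AU * HA
  cf <- solve(au$mass, drop(t(au$Bq) %*% (au$qw * fq)))
  st <- crplasma:::cpp_sys_get_state(sys$ptr)
  if (!is.null(P)) st$P <- P
  crplasma:::cpp_sys_set_state(sys$ptr, crplasma:::fs_to_au(sys$t_fs), cf,
                               st$G, st$P, st$ledger)
  invisible(sys)
}

system_state <- function(sys) crplasma:::cpp_sys_get_state(sys$ptr)

au_moments <- function(sys, coef) {
  au <- crplasma:::basis_au_mirror(sys$basis)
  c(n = sum(au$mvec * coef), e = sum(au$evec * coef))
}

# memoised expensive trajectories shared between test files
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# moderate-resolution policy used by most integration tests (documented in
# the methods vignette: problem sizes chosen for the routine test suite)
test_policy <- function(...) {
  args <- utils::modifyList(list(n_log = 45, rtol = 1e-5, n_tbr = 31,
                                 n_node = 500), list(...))
  do.call(solver_policy, args)
}
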