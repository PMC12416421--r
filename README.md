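# crplasma

Zero-dimensional, non-thermal collisional–radiative plasma modelling of the
electronic damage suffered by biomolecular targets under femtosecond X-ray
free-electron-laser (XFEL) pulses.

## The problem

In serial femtosecond crystallography the diffraction signal is collected
while the sample is being destroyed. Photoionization and Auger decay eject
primary electrons; these seed electron-impact-ionization (EII) cascades that
become the dominant source of ionization well before the pulse ends. The
resulting time-dependent charge states degrade the scattered signal, and
trace heavy elements (native S, added Gd/Se, salt ions) seed a
disproportionate share of the cascades. Quantifying this requires following
both the ionic states and a strongly non-Maxwellian free-electron spectrum —
keV photoelectron peaks coexisting with an eV-scale thermal bulk — through
the pulse.

`crplasma` is for researchers modelling or planning such experiments:
it predicts charge-state dynamics, free-electron spectra, cascade
attribution, and derived observables (intensity-averaged charges, electron
density ratios) for arbitrary element compositions and pulse parameters.

## The model

Per element, populations $P_\xi(t)$ over ionic configurations $\xi$ evolve by
a master equation, coupled to the free-electron energy distribution
$f(\varepsilon,t)$ (cm⁻³ eV⁻¹) expanded in cubic B-splines:

$$\dot P_\xi = \sum_\eta \Gamma_{\eta\to\xi}[f,J]P_\eta - \Gamma_{\xi\to\eta}[f,J]P_\xi,
\qquad
\dot f = Q_{\rm photo} + Q_{\rm Auger} + Q_{\rm EII} + Q_{\rm TBR} + Q_{\rm EE}.$$

Processes: photoionization (flux $J(t)$), Auger/fluorescent decay,
electron-impact ionization, three-body recombination (microreverse of EII,
verified against Saha equilibrium), and electron–electron Coulomb collisions
(isotropic Landau/Rosenbluth form, treated linearly implicitly). All atomic
data are generated internally from a configuration-average self-consistent
mean field (Slater exchange, Latter correction): $\Delta$SCF thresholds,
numeric-dipole photoionization cross-sections (validated against
Cromer–Liberman tabulations to a few %), binary-encounter-Bethe impact
ionization, and scaled tabulated core-hole widths. Heavy elements
($Z \ge 30$) use collapsed principal shells with a fitted quadratic
configuration-energy surrogate and lazily activated configurations (Gd:
400140 configurations). The methods vignette
(`vignettes/methods.Rmd`) documents every model choice.

Particle and energy bookkeeping are enforced structurally: full runs
conserve bound+free electrons to ~10⁻¹⁴ relative and close the energy
ledger (absorbed = Δbinding + free kinetic + radiated) to a few 10⁻⁴.

## Worked example

A pure light-atom target (C₆₁₃N₂₀₃O₁₈₅ at 1.2 g cm⁻³) under a 9 keV,
10¹² photons µm⁻², 15 fs FWHM Gaussian pulse:

```r
library(crplasma)

target <- fixture_composition("cno")
pulse  <- pulse_profile(9, 1e12, fwhm_fs = 15)
traj   <- run_simulation(target, pulse, solver_policy(),
                         t_start_fs = -18, t_end_fs = 18)
traj
#> <cr_trajectory> 145 samples over [ -18 , 18 ] fs
#>   final charges: C +0.73, N +0.71, O +0.73

trC <- average_charge_trace(traj, "C")
intensity_averaged(trC, pulse)
#> [1] 0.211645

cons <- conservation_report(traj)
c(cons$max_electron_drift, cons$max_energy_residual)
#> [1] 1.115045e-15 9.649173e-05

snap <- distribution_snapshot(traj, 0)   # spectrum at the pulse peak
attr(snap, "density")                    # free electrons / cm^3
#> [1] 9.243268e+21
```

The final charges are the pulse-end average charge per element; the
intensity-averaged carbon charge (+0.21) is the damage measure most relevant
to diffraction, weighting the charge trace by the instantaneous pulse
intensity. The conservation report confirms the particle ledger closes to
rounding and the energy ledger to ~10⁻⁴.

Cascade attribution and tracer injection:

```r
traj <- run_simulation(target, pulse, solver_policy(),
                       t_start_fs = -18, t_end_fs = 18, channels = TRUE,
                       tracers = list(tracer_impulse(2000, -7.5)))
tracer_yield(traj)$intensity_averaged   # electrons per injected electron
#> [1] 51.07817
```

Command-line use (after installation):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "crplasma", package = "crplasma"))') \
    fixtures --name lysozyme_water --out work
# edit work/lysozyme_water.yaml, then
Rscript .../crplasma simulate --config work/lysozyme_water.yaml --out work/run
```

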