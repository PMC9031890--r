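---
title: "Hydration dynamics from broad-band depolarized light scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration dynamics from broad-band depolarized light scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edlshyd)
```

## The measurement and the model

Extended frequency-range depolarized light scattering (EDLS) measures the
spectrum of collective polarizability-anisotropy fluctuations in a liquid
over roughly five decades of frequency (0.6 to 36,000 GHz). The measured
depolarized intensity $I(\omega)$ is reduced to the imaginary part of the
dynamic susceptibility via the Bose--Einstein occupation number,

$$\chi''(\omega) \propto \frac{I(\omega)}{n_B(\omega) + 1},
\qquad n_B(\omega) = \frac{1}{e^{\hbar\omega/k_B T} - 1}.$$

For an aqueous peptide solution, `edlshyd` decomposes $\chi''$ into a sum
of closed-form components:

* a **Debye** relaxation $\chi'' = \Im\,\{-\Delta_D/(1 + i\omega\tau_D)\}$
  for the rotational diffusion of the solute (peaking at a few GHz);
* a **Cole--Davidson** (CD) relaxation
  $\chi'' = \Im\,\{-\Delta_{CD}/(1 + i\omega\tau_{CD})^{\beta}\}$ for the
  structural relaxation of *hydration* water (peak near 30 GHz) and a
  second CD for *bulk-like* water (near 200 GHz in solution, 270 GHz in
  pure water), both with the shape parameter fixed at $\beta = 0.6$;
* **damped harmonic oscillators** (DHO)
  $\chi'' = A\,\Omega_0^2\Gamma_0\omega\,/\,[(\Omega_0^2-\omega^2)^2 +
  (\Gamma_0\omega)^2]$ for the solute's THz vibrational modes, the two
  intermolecular (bending/stretching) modes of water near 1,800 and
  5,400 GHz, and the librational band near 15,000 GHz. The same
  functional form serves the under- and overdamped ("Brownian
  oscillator") regimes; in the overdamped limit it tends to a Debye
  profile with $\tau_{\rm eff} = \Gamma_0/\Omega_0^2$.

The mean relaxation time of a CD component is $\langle\tau\rangle =
\beta\,\tau_{CD}$, and its susceptibility peak sits at
$\omega_{\max}\tau_{CD} = \tan[\pi/(2(1+\beta))]$, so that at $\beta=0.6$
the ratio $\langle\tau\rangle/\tau_{\max} = \beta\tan[\pi/(2(1+\beta))] =
0.90$.

Two headline quantities follow from the fitted solution decomposition:

* the **retardation factor** $\xi = \tau_{\rm hydr}/\tau_{\rm bulk}$,
  the slow-down of hydration-water relaxation relative to the bulk-like
  component of the *same* solution fit (using the in-solution bulk
  component, not pure water, is what places $\xi$ in the observed 6--8
  range);
* the **hydration number**
  $N_h = \dfrac{\Delta_{\rm hydr}}{\Delta_{\rm hydr}+\Delta_{\rm bulk}}
  \cdot \dfrac{1}{f}$,
  the number of dynamically perturbed waters per solute, where $f$ is the
  solute/water mole ratio. The product $N_h f$ is identically the
  hydration amplitude share, hence never exceeds 1.

The solute rotation time extrapolated to infinite dilution,
$\tau_{sm}$, connects to the hydrodynamic volume through the
Stokes--Einstein--Debye relation $\tau_{sm} = V_h\,\eta/(k_B T)$ with the
neat-water viscosity $\eta$ (1.002 mPa s at 20 °C, 0.890 at 25 °C,
linearly interpolated in between).

## Workflow

```{r pipeline, eval = FALSE}
meta <- solution_meta("NAGMA", 130.15, 50, 293.15)   # 50 mg/mL of solvent
gen  <- solution_spectrum(meta, noise = noise_spec(0.02, seed = 1))
wat  <- water_spectrum(noise = noise_spec(0.02, seed = 2))
res  <- analyze_solution(gen$spectrum, wat$spectrum, meta)
res$hydration
```

`analyze_solution()` chains the full procedure: fit the pure-water
spectrum; normalize the solution spectrum to the water librational band
(default window 10,000--30,000 GHz, a band nearly insensitive to solute
and temperature); subtract to form the solvent-free (SF) spectrum; fit
the SF spectrum with Debye + hydration CD + two solute oscillators; then
fit the full solution spectrum with all eight components, seeded from the
SF and water fits.

## Fitting: objective, starts, and numerical choices

The spectra span about four decades in amplitude, so the objective is
least squares on *relative* residuals,
$(\chi''_{\rm model} - \chi''_{\rm data})/\max(|\chi''_{\rm data}|,
\varepsilon)$, with a floor $\varepsilon$ set to a small fraction of the
spectrum maximum (0.1% for positive solution/water spectra; 5% for SF
spectra, which cross zero). Uniform weighting would be dominated by the
librational band and ignore the GHz region the analysis is about.

Optimization is bounded Levenberg--Marquardt (`minpack.lm::nls.lm`) with
seeded multiplicative random restarts (default 8 for standalone fits, at
log-scale s.d. 0.3); the lowest residual wins and ties go to the first
occurrence. Two structural devices make the solution fit reliable rather
than lucky:

1. **Amplitude projection.** For fixed times, centers and dampings the
   model is *linear* in every amplitude-type parameter (component
   amplitudes and the water gain $s_w$), so each starting point is first
   projected onto its exact weighted linear least-squares amplitude
   section (negative solutions clamped to zero). This removes the most
   common failure mode, in which a grossly overscaled start drives a
   component amplitude to zero and strands the time parameter.
2. **Dual deterministic starts.** The full fit is started both from the
   SF-seeded parameters and from the canonical in-solution peak positions
   (hydration at 30 GHz, bulk-like at 200 GHz).

Further choices:

* $\beta$ is fixed at 0.6 for all CD components (configurable in
  `fit_config()`).
* In the full fit the water intermolecular and librational oscillators
  are held at their pure-water values up to one common floated gain
  $s_w$. The gain absorbs the residual unit mismatch left by
  librational-band normalization: the band integral is not perfectly
  solute-independent because the relaxation tails beneath it change with
  solute, so the normalization scale is close to, but not exactly, the
  true gain ratio. Without $s_w$ this few-percent mismatch biases the
  relaxation times.
* The SF fit uses only points with $f \le 8$ THz and positive values.
  Above a few THz the SF difference is cancellation noise between two
  large, nearly equal spectra; and because amplitude moves from the
  270 GHz pure-water peak to 30 GHz in solution, exact subtraction
  produces a *negative* excursion near a few hundred GHz that the
  non-negative SF model cannot (and should not) chase.
* The hydration CD must peak below the bulk CD; a fit that lands the
  other way is swapped back and flagged (`"role_swap"`). A Debye and CD
  peaking within a factor 1.5 of each other is flagged
  (`"degenerate_overlap"`).
* Parameter uncertainties come from the linearized Jacobian at the
  optimum; fits store enough data to re-evaluate their residuals
  (`fit_residual_rms()`).

## The water-sharing shell model

The concentration dependence of $N_h$ is modelled geometrically: solutes
are spheres of radius $r$ (3.0 Å for the hydrophilic peptide, 3.5 Å for
the amphiphilic one) placed uniformly at random -- *no* mutual excluded
volume, i.e. ideal random mixing, consistent with attributing the $N_h$
decrease to random contacts rather than aggregation -- in a periodic
cubic box containing ~27,000 uniform water points at bulk number density
$\rho = 0.0334$ Å$^{-3}$. Waters are excluded from solute cores
(distance > $r$), and the box side is chosen so the density refers to the
water-accessible volume; this keeps the dilute limit equal to the exact
shell-volume count $\rho\,\tfrac{4\pi}{3}[(r+h)^3 - r^3]$, which serves
as the closed-form oracle. A water is *hydration* water when its
minimum-image distance to the nearest solute center lies in $(r, r+h]$
with $h = 6.4$ Å; $N_h$ is the covered count divided by the number of
solutes, averaged over seeded realizations with a Monte-Carlo standard
error.

Distance evaluation is a vectorised per-solute minimum-image pass
(O($n_{\rm solute} n_{\rm water}$), at most a few hundred by 27,000
points), which at this scale outperforms an interpreted cell list while
counting identically.

At low mole ratio the covered fraction follows the Poisson-overlap limit
$1 - e^{-f N_{\rm iso}}$ within a few percent (`poisson_overlap_nh()`);
deviations grow at high $f$ where solute cores overlap. Note the
geometric dilute limit for the $r = 3.0$ Å sphere is ~112 waters, at the
low edge of the experimentally derived 125 ± 15 -- the sphere-plus-shell
idealization, not a tunable, sets this number.

## The synthetic-data generator

`water_spectrum()`, `solution_spectrum()` and `concentration_series()`
generate seeded spectra with complete truth records on the default
400-point log grid over 0.6--36,000 GHz. The presets are internally
consistent with the physics above:

* pure water: CD peaking at 270 GHz ($\beta = 0.6$), intermolecular DHOs
  at 1,800 and 5,400 GHz, libration at 15,000 GHz;
* solutes: molar masses 130.15 / 186.25 g/mol; infinite-dilution rotation
  times $\tau_{sm}$ = 28.5 ps (20 °C) and 34.6 ps (25 °C), SED-consistent
  with hydrodynamic volumes of 115 and 160 Å$^3$; exponential
  concentration law $\tau_D = \tau_{sm} e^{k x}$ with $k = 40$, chosen so
  $\tau_D$ roughly doubles across the 25--150 mg/mL ladder;
* hydration CD at 30 GHz ($\langle\tau\rangle \approx 4.8$ ps) and
  bulk-like CD at 200 GHz ($\approx 0.71$ ps), giving a truth retardation
  $\xi \approx 6.7$;
* the water relaxation amplitude is split between hydration and bulk so
  the hydration share equals $N_h(f)\,f$, with $N_h(f)$ from the
  shell-overlap model at the preset geometry. The deterministic
  Poisson-overlap closed form is the default (exact truth records, no
  Monte-Carlo noise in the generator); `nh_model = "simulate"` substitutes
  the Monte-Carlo curve;
* solute THz oscillators sit at 1,000 and 3,000 GHz with broad damping --
  placeholder values, not literature constants;
* noise is multiplicative log-normal (default 2% relative), matching the
  roughly constant relative uncertainty of photon-counting spectra.

What the generator does *not* emulate: instrument response, dark-count
statistics (a constant-offset subtraction helper is provided instead),
Brillouin doublets and their leakage (maskable via `fit_config(mask=)`),
temperature-dependent lineshape changes, and any deviation of real
hydration water from a single CD form. Passing recovery tests on these
synthetics therefore demonstrates that the *pipeline* is unbiased and
stable at realistic noise, not that the model is uniquely correct for
real spectra.

## Validation and problem sizes

The test suite checks, among others: analytic oracle equivalences
(CD$(\beta{=}1)$ = Debye to machine precision; numeric argmax vs analytic
peak position across $\beta$; overdamped DHO vs Debye), exact recovery of
noiseless generate-and-fit round trips at every ladder concentration,
10-seed recovery of the hydration (30 GHz, ±15%) and pure-water (270 GHz,
±10%) peaks at 2% noise, isolated-shell Monte Carlo vs the closed-form
count within 3 Monte-Carlo $\sigma$, monotone decrease of $N_h(f)$, and
the SED forward/inverse identity. Monte-Carlo checks use 27,000 waters
with 10--100 realizations; fitting checks use the 400-point default
grid -- sizes chosen so the whole suite completes in about a minute while
keeping Monte-Carlo standard errors near one water molecule.

## Known limitations

* $\xi$ and $N_h$ inherit the assumption that the water scattering cross
  section is the same in the shell and the bulk.
* The amplitude share identifies $N_h$ only through the two-CD
  decomposition; strongly overlapping relaxations at low concentration
  make $\Delta_{\rm hydr}$ the least certain fitted quantity.
* The shell model idealizes solutes as spheres and water as an ideal gas
  at bulk density; it has no dynamics, shapes, or water structure.
* The SF fit is a seeding device, deliberately misspecified (it ignores
  the negative redistribution dip); its parameters should not be
  interpreted on their own.
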