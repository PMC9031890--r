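# edlshyd

Hydration dynamics of small solutes from broad-band depolarized light
scattering (EDLS) susceptibility spectra.

EDLS measures collective polarizability-anisotropy fluctuations of a
liquid from 0.6 to 36,000 GHz. In an aqueous peptide solution that range
contains, at increasing frequency: the rotational diffusion of the solute
(a Debye peak at a few GHz), the structural relaxation of hydration water
(a Cole–Davidson peak near 30 GHz), the bulk-like water relaxation
(~200 GHz in solution, 270 GHz in pure water), the solute's THz
vibrations, the intermolecular bending/stretching modes of water, and the
librational band. `edlshyd` is for spectroscopists who want to turn such
spectra into two headline numbers per sample:

* the **retardation factor** ξ = τ_hydr/τ_bulk — how much the solute slows
  the relaxation of its solvation water relative to the bulk-like
  component of the same fit;
* the **hydration number**
  N_h = Δ_hydr / (Δ_hydr + Δ_bulk) / f — the average count of dynamically
  perturbed water molecules per solute, from the amplitude share of the
  hydration relaxation and the solute/water mole ratio f.

The package provides the full chain: Bose–Einstein reduction of raw
intensity, instrument-segment joining, librational-band normalization,
solvent-free subtraction, constrained multi-component least-squares fits
(Debye + Cole–Davidson with β fixed at 0.6 + damped harmonic
oscillators), Stokes–Einstein–Debye analysis of the solute rotation time
(τ_sm = V_h η / k_B T), a Monte-Carlo model of random hydration-shell
overlap explaining why N_h falls with concentration, and a seeded
synthetic-spectrum generator with exact truth records for validating the
whole pipeline.

## Worked example

Generate a 50 mg/mL peptide solution spectrum and a pure-water spectrum
at 2% noise, then run the analysis chain (water fit → normalization →
solvent-free subtraction → SF fit → full-spectrum fit):

```r
library(edlshyd)

meta <- solution_meta("NAGMA", 130.15, 50, 293.15)   # MW g/mol, mg/mL, K
gen  <- solution_spectrum(meta, noise = noise_spec(0.02, seed = 1))
wat  <- water_spectrum(noise = noise_spec(0.02, seed = 2))
res  <- analyze_solution(gen$spectrum, wat$spectrum, meta)
res$hydration
#> <hydration_result> f = 0.006921, N_h = 74.8, xi = 6.51, perturbed fraction = 0.52, tau_D = 37.6 ps
```

Read: at this concentration one peptide in every ~145 water molecules
perturbs ~75 waters each (the generator truth is 78, from shell overlap
at this mole ratio), together covering half of all water; hydration water
relaxes 6.5× slower than the bulk-like component (truth 6.7); the solute
rotates with a 38 ps Debye time. The recovered hydration component peaks
at

```r
peak_frequency(model_components(res$full_fit$model, "hydration_water")[[1]])
#> [1] 28.6   # GHz; generated at 30
```

The shell-overlap model, run at infinite dilution for a 3.5 Å solute
sphere with a 6.4 Å shell at bulk water density:

```r
shell_simulate_isolated(r = 3.5, h = 6.4, n_realizations = 50, seed = 42)
#> <shell_sim_result> N_h = 130.4 +/- 1.5, perturbed fraction = 0.005 +/- 0.000 (50 realizations)
```

A thin command-line wrapper over the same functions lives in
`inst/cli/edls-cli.R` (subcommands `synth`, `chi`, `join`, `sf`,
`shellsim`, `report`).

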