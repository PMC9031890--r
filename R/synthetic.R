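# Seeded generator of realistic broad-band EDLS susceptibility spectra
# (pure water and peptide solutions) with full ground-truth records, used
# for validation and parameter-recovery studies.

#' Pure-water spectral preset
#'
#' Default decomposition of the pure-water susceptibility: one bulk
#' Cole-Davidson relaxation peaking at 270 GHz (beta = 0.6), two damped
#' harmonic oscillators for the intermolecular bending and stretching modes
#' (~1,800 and ~5,400 GHz), and a broad librational band (~15,000 GHz).
#'
#' @param cd_peak_GHz bulk relaxation peak frequency, GHz.
#' @param cd_amplitude bulk relaxation amplitude (arbitrary units).
#' @param beta Cole-Davidson shape parameter.
#' @return A [spectral_model()] with water roles.
#' @export
water_preset <- function(cd_peak_GHz = 270, cd_amplitude = 1.0, beta = 0.6) {
  tau <- tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * cd_peak_GHz)
  spectral_model(
    cole_davidson(cd_amplitude, tau, beta, role = "bulk_water"),
    dho(0.35, 1800, 2500, role = "water_intermolecular"),
    dho(0.45, 5400, 5500, role = "water_intermolecular"),
    dho(0.80, 15000, 12000, role = "libration"))
}

#' Solute presets for the model peptides
#'
#' Internally consistent defaults for a hydrophilic (NAGMA-like) and an
#' amphiphilic (NALMA-like) model peptide: molar mass; infinite-dilution
#' rotation time tau_sm (SED-consistent with hydrodynamic volumes of 115
#' and 160 Angstrom^3 at the working temperatures) with exponential
#' concentration slope k; hydration-water relaxation peak (30 GHz);
#' in-solution bulk-like water peak (200 GHz); effective sphere radius for
#' the shell model; two broad THz vibrational modes (placeholder
#' parameters, not literature values).
#'
#' @param name `"NAGMA"` or `"NALMA"`.
#' @return A list of preset parameters (class `solute_preset`).
#' @export
solute_preset <- function(name = c("NAGMA", "NALMA")) {
  name <- match.arg(name)
  p <- switch(name,
    NAGMA = list(name = "NAGMA", molecular_weight = 130.15, T_K = 293.15,
                 tau_sm_ps = 28.5, k = 40, radius_A = 3.0),
    NALMA = list(name = "NALMA", molecular_weight = 186.25, T_K = 298.15,
                 tau_sm_ps = 34.6, k = 40, radius_A = 3.5))
  p$hydration_peak_GHz <- 30
  p$bulk_solution_peak_GHz <- 200
  p$beta <- 0.6
  p$shell_h_A <- 6.4
  p$debye_amp_per_f <- 90     # Delta_D = 90 * mole ratio
  p$osc1 <- list(amp_per_f = 10, center_GHz = 1000, damping_GHz = 1500)
  p$osc2 <- list(amp_per_f = 15, center_GHz = 3000, damping_GHz = 4000)
  class(p) <- "solute_preset"
  p
}

#' Multiplicative noise specification
#'
#' Log-normal multiplicative noise: each point is multiplied by
#' `exp(rnorm(1, 0, sigma))`, emulating the roughly constant relative
#' uncertainty of photon-counting spectra across decades.
#'
#' @param sigma relative noise level (default 0.02, i.e. 2%).
#' @param seed integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.02, seed = 1L) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "noise_spec")
}

apply_noise <- function(values, noise) {
  if (noise$sigma == 0) return(values)
  old <- .Random.seed_guard(noise$seed)
  on.exit(old(), add = TRUE)
  values * exp(stats::rnorm(length(values), 0, noise$sigma))
}

#' Generate a synthetic pure-water spectrum
#'
#' @param grid frequency grid, GHz, spanning 0.6-36,000 GHz.
#' @param preset a [water_preset()].
#' @param noise a [noise_spec()].
#' @param T_K temperature recorded in the spectrum metadata.
#' @return List with `spectrum` (an [spectrum()]) and `truth` (the
#'   noiseless generating [spectral_model()]).
#' @export
water_spectrum <- function(grid = default_grid(), preset = water_preset(),
                           noise = noise_spec(), T_K = 293.15) {
  if (min(grid) > 0.6 + 1e-9 || max(grid) < 36000 - 1e-6)
    stop("grid must span the full 0.6-36,000 GHz measurement range")
  clean <- model_chi(preset, grid)
  s <- spectrum(grid, apply_noise(clean, noise), kind = "susceptibility",
                sample = "water", T_K = T_K)
  list(spectrum = s, truth = preset)
}

#' Generate a synthetic peptide-solution spectrum
#'
#' The solution decomposition is: solute rotation Debye with
#' `tau_D = tau_sm * exp(k x)`; hydration-water Cole-Davidson at the preset
#' peak; bulk-like water Cole-Davidson shifted to ~200 GHz; two solute THz
#' modes; plus the water preset's intermolecular and librational modes.
#' The total water relaxation amplitude of the water preset is split
#' between hydration and bulk so that the hydration share equals
#' `N_h(f) * f`, with `N_h(f)` from the shell-overlap model at the preset
#' geometry (closed-form Poisson-overlap limit by default, Monte Carlo on
#' request).
#'
#' @param meta a [solution_meta()].
#' @param preset a [solute_preset()].
#' @param water a [water_preset()].
#' @param noise a [noise_spec()].
#' @param grid frequency grid, GHz.
#' @param nh_model `"poisson"` (deterministic closed form) or `"simulate"`
#'   (seeded Monte Carlo via [shell_simulate()]).
#' @return List with `spectrum`, `truth` (the generating [spectral_model()])
#'   and `truth_params` (named list of every generator parameter).
#' @export
solution_spectrum <- function(meta, preset = solute_preset("NAGMA"),
                              water = water_preset(), noise = noise_spec(),
                              grid = default_grid(),
                              nh_model = c("poisson", "simulate")) {
  stopifnot(inherits(meta, "solution_meta"), inherits(preset, "solute_preset"))
  nh_model <- match.arg(nh_model)
  f <- mole_ratio(meta)
  if (f <= 0 || f > 0.1) stop("mole ratio out of the model range (0, 0.1]")
  x <- f / (1 + f)  # mole fraction
  tau_D <- preset$tau_sm_ps * exp(preset$k * x)

  if (nh_model == "poisson") {
    nh <- poisson_overlap_nh(f, preset$radius_A, preset$shell_h_A)
  } else {
    res <- shell_simulate(shell_sim_config(
      r = preset$radius_A, h = preset$shell_h_A, f = f,
      n_water = 8000L, n_realizations = 4L, seed = noise$seed + 1000L))
    nh <- list(N_h = res$N_h, perturbed_fraction = res$perturbed_fraction)
  }
  share <- nh$perturbed_fraction

  wat_cd <- model_components(water, "bulk_water")[[1L]]
  beta <- preset$beta
  tau_h <- tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * preset$hydration_peak_GHz)
  tau_b <- tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * preset$bulk_solution_peak_GHz)

  comps <- c(
    list(debye(preset$debye_amp_per_f * f, tau_D, role = "solute_rotation"),
         cole_davidson(share * wat_cd$amplitude, tau_h, beta,
                       role = "hydration_water"),
         cole_davidson((1 - share) * wat_cd$amplitude, tau_b, beta,
                       role = "bulk_water"),
         dho(preset$osc1$amp_per_f * f, preset$osc1$center_GHz,
             preset$osc1$damping_GHz, role = "solute_vibration"),
         dho(preset$osc2$amp_per_f * f, preset$osc2$center_GHz,
             preset$osc2$damping_GHz, role = "solute_vibration")),
    model_components(water, "water_intermolecular"),
    model_components(water, "libration"))
  truth <- spectral_model(comps)

  clean <- model_chi(truth, grid)
  s <- spectrum(grid, apply_noise(clean, noise), kind = "susceptibility",
                sample = sprintf("%s_%gmg", preset$name, meta$conc_mg_per_mL),
                T_K = meta$T_K)
  list(spectrum = s, truth = truth,
       truth_params = list(f = f, x = x, tau_D_ps = tau_D,
                           delta_D = preset$debye_amp_per_f * f,
                           delta_hydr = share * wat_cd$amplitude,
                           delta_bulk = (1 - share) * wat_cd$amplitude,
                           tau_hydr_ps = tau_h, tau_bulk_ps = tau_b,
                           beta = beta, N_h = nh$N_h,
                           perturbed_fraction = share,
                           hydration_peak_GHz = preset$hydration_peak_GHz,
                           bulk_solution_peak_GHz = preset$bulk_solution_peak_GHz))
}

#' Generate a concentration series of solution spectra
#'
#' One spectrum per concentration on a shared water preset; per-member
#' noise seeds are derived deterministically from the master seed.
#'
#' @param preset a [solute_preset()].
#' @param concentrations mg per mL of solvent; the study ladder
#'   25, 50, 75, 100, 150 by default.
#' @param noise a [noise_spec()] (its seed is the master seed).
#' @param grid frequency grid, GHz.
#' @param nh_model as in [solution_spectrum()].
#' @return List of [solution_spectrum()] results, one per concentration.
#' @export
concentration_series <- function(preset = solute_preset("NAGMA"),
                                 concentrations = c(25, 50, 75, 100, 150),
                                 noise = noise_spec(), grid = default_grid(),
                                 nh_model = "poisson") {
  stopifnot(length(concentrations) >= 1L)
  lapply(seq_along(concentrations), function(i) {
    meta <- solution_meta(preset$name, preset$molecular_weight,
                          concentrations[i], preset$T_K)
    solution_spectrum(meta, preset = preset,
                      water = water_preset(), grid = grid,
                      noise = noise_spec(noise$sigma,
                                         noise$seed + 7919L * i),
                      nh_model = nh_model)
  })
}
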