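# End-to-end analysis: normalize, subtract, fit, extract hydration numbers.

#' Analyse a solution spectrum against a solvent reference
#'
#' Runs the full workflow on susceptibility spectra: (1) fit the pure-water
#' spectrum; (2) normalize the solution to the water librational band and
#' form the solvent-free difference; (3) fit the SF spectrum
#' (Debye + hydration CD + two solute oscillators); (4) fit the full
#' solution spectrum seeded from the SF and water fits; (5) derive the
#' hydration quantities (f, N_h, xi, perturbed fraction, tau_D).
#'
#' @param solution solution susceptibility [spectrum()].
#' @param water pure-water susceptibility [spectrum()].
#' @param meta the sample's [solution_meta()].
#' @param cfg a [fit_config()] shared by the three fits.
#' @param water_fit optional precomputed [fit_pure_water()] result (reused
#'   across a concentration series).
#' @param norm_window librational-band normalization window, GHz.
#' @return List with elements `water_fit`, `sf_spectrum`, `sf_fit`,
#'   `full_fit` and `hydration` (a [hydration_result()]).
#' @export
analyze_solution <- function(solution, water, meta, cfg = fit_config(),
                             water_fit = NULL, norm_window = c(10000, 30000)) {
  stopifnot(inherits(solution, "edls_spectrum"), inherits(water, "edls_spectrum"),
            inherits(meta, "solution_meta"))
  if (is.null(water_fit)) water_fit <- fit_pure_water(water, cfg)
  sol_n <- normalize_to_reference_band(solution, water, window = norm_window)
  sf <- solvent_free_subtract(sol_n, water)
  sf_cfg <- cfg
  sf_cfg$rel_floor_frac <- max(cfg$rel_floor_frac, 0.02)
  sf_fit <- fit_solvent_free(sf, sf_cfg)
  full_fit <- fit_full_spectrum(sol_n, water_fit, sf_fit, cfg,
                                s_w_start = attr(sol_n, "norm_scale"))
  list(water_fit = water_fit, sf_spectrum = sf, sf_fit = sf_fit,
       full_fit = full_fit, hydration = hydration_result(full_fit, meta))
}

#' Tabulate hydration results for a concentration series
#'
#' @param analyses list of [analyze_solution()] results.
#' @param metas list of matching [solution_meta()] objects.
#' @return data.frame with one row per sample: concentration, f, N_h, xi,
#'   perturbed fraction, tau_D.
#' @export
hydration_table <- function(analyses, metas) {
  stopifnot(length(analyses) == length(metas))
  do.call(rbind, lapply(seq_along(analyses), function(i) {
    h <- analyses[[i]]$hydration
    data.frame(sample = metas[[i]]$solute,
               conc_mg_per_mL = metas[[i]]$conc_mg_per_mL,
               f = h$f, N_h = h$N_h, xi = h$xi,
               perturbed_fraction = h$perturbed_fraction,
               tau_D_ps = h$tau_D_ps)
  }))
}
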