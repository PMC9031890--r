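# Headline hydration quantities from fitted relaxation parameters:
# solute/water mole ratio, hydration number N_h, retardation factor xi,
# infinite-dilution extrapolation of the solute rotation time, and the
# Stokes-Einstein-Debye hydrodynamic volume.

.WATER_MOLAR_MASS <- 18.015  # g/mol

# Van der Waals volumes (A^3), literature reference constants for reporting.
#' Reference van der Waals volumes of the model peptides
#' @format Named numeric vector (Angstrom^3): NAGMA 125, NALMA 192.
#' @export
vdw_volumes <- c(NAGMA = 125, NALMA = 192)

#' Solution metadata
#'
#' @param solute solute name.
#' @param molecular_weight solute molar mass, g/mol.
#' @param conc_mg_per_mL solute concentration in mg per mL of solvent
#'   (equivalently g per kg, water density ~ 1 g/mL as prepared by weight).
#' @param T_K temperature, K.
#' @param viscosity_mPas solvent shear viscosity, mPa s; defaults to the
#'   built-in neat-water table at `T_K`.
#' @return An object of class `solution_meta`.
#' @export
solution_meta <- function(solute, molecular_weight, conc_mg_per_mL, T_K,
                          viscosity_mPas = water_viscosity(T_K)) {
  stopifnot(molecular_weight > 0, conc_mg_per_mL >= 0, T_K > 0,
            viscosity_mPas > 0)
  structure(list(solute = solute, molecular_weight = molecular_weight,
                 conc_mg_per_mL = conc_mg_per_mL, T_K = T_K,
                 viscosity_mPas = viscosity_mPas),
            class = "solution_meta")
}

#' Solute/water mole ratio
#'
#' `f = (c / MW) / (1000 / 18.015)` with c in mg per mL (g per kg) of
#' solvent: moles of solute per mole of water.
#'
#' @param meta a [solution_meta()], or a concentration in mg/mL when
#'   `molecular_weight` is supplied directly.
#' @param molecular_weight solute molar mass, g/mol (scalar use).
#' @return Mole ratio f (dimensionless).
#' @export
mole_ratio <- function(meta, molecular_weight = NULL) {
  if (inherits(meta, "solution_meta")) {
    conc <- meta$conc_mg_per_mL; mw <- meta$molecular_weight
  } else {
    if (is.null(molecular_weight)) stop("supply a solution_meta or molecular_weight")
    conc <- meta; mw <- molecular_weight
  }
  stopifnot(conc >= 0, mw > 0)
  (conc / mw) / (1000 / .WATER_MOLAR_MASS)
}

#' Hydration number from relaxation amplitudes
#'
#' `N_h = Delta_hydr / (Delta_hydr + Delta_bulk) / f`: the amplitude share
#' of the hydration-water relaxation divided by the solute/water mole
#' ratio, i.e. the average number of dynamically perturbed water molecules
#' per solute. The perturbed fraction `N_h * f` equals the amplitude share
#' and cannot exceed 1; a violation (over-assigned hydration amplitude)
#' raises a warning.
#'
#' @param delta_hydr,delta_bulk hydration and bulk-like water relaxation
#'   amplitudes, >= 0, not both zero.
#' @param f solute/water mole ratio, > 0.
#' @return N_h (water molecules per solute).
#' @export
hydration_number <- function(delta_hydr, delta_bulk, f) {
  stopifnot(delta_hydr >= 0, delta_bulk >= 0)
  if (delta_hydr + delta_bulk <= 0) stop("both amplitudes are zero")
  if (f <= 0) stop("mole ratio must be positive")
  share <- delta_hydr / (delta_hydr + delta_bulk)
  nh <- share / f
  if (nh * f > 1 + 1e-12)
    warning("perturbed fraction N_h * f exceeds 1")
  nh
}

#' Retardation factor
#'
#' Ratio of the hydration-water to the bulk-like water mean relaxation
#' times from the same solution fit. At a common Cole-Davidson beta the
#' ratio of mean times equals the ratio of tau_CD values and of peak
#' periods alike.
#'
#' @param tau_hydr_ps,tau_bulk_ps mean relaxation times, ps, > 0.
#' @return xi = tau_hydr / tau_bulk.
#' @export
retardation <- function(tau_hydr_ps, tau_bulk_ps) {
  if (tau_hydr_ps <= 0 || tau_bulk_ps <= 0) stop("relaxation times must be positive")
  tau_hydr_ps / tau_bulk_ps
}

#' Extrapolate the solute rotation time to infinite dilution
#'
#' The rotational Debye time follows an exponential law in the solute mole
#' fraction, `tau_D(x) = tau_sm * exp(k x)`; a least-squares line through
#' `ln tau_D` vs `x` gives the infinite-dilution intercept `tau_sm`.
#'
#' @param x solute mole fractions (>= 3 distinct values).
#' @param tau_D_ps rotation times, ps, > 0.
#' @return List with `tau_sm_ps`, its standard error `tau_sm_se_ps`
#'   (delta-method), slope `k` and `k_se`.
#' @export
extrapolate_tau_dilution <- function(x, tau_D_ps) {
  if (length(x) != length(tau_D_ps)) stop("x and tau_D_ps lengths differ")
  if (length(unique(x)) < 3L) stop("need at least 3 distinct mole fractions")
  if (any(tau_D_ps <= 0)) stop("rotation times must be positive")
  fit <- stats::lm(log(tau_D_ps) ~ x)
  # noiseless inputs fit perfectly; summary()'s se warning is expected then
  cf <- suppressWarnings(summary(fit))$coefficients
  tau_sm <- exp(cf[1L, 1L])
  list(tau_sm_ps = tau_sm,
       tau_sm_se_ps = tau_sm * cf[1L, 2L],
       k = cf[2L, 1L], k_se = cf[2L, 2L])
}

#' Stokes-Einstein-Debye hydrodynamic volume
#'
#' Inverts the SED relation `tau_sm = V_h * eta / (kB * T)` for the
#' hydrodynamic volume of the rotating solute, `V_h = tau_sm * kB * T / eta`
#' (stick boundary conditions, neat-water viscosity).
#'
#' @param tau_sm_ps infinite-dilution rotation time, ps.
#' @param T_K temperature, K.
#' @param viscosity_mPas solvent viscosity, mPa s.
#' @return Hydrodynamic volume in Angstrom^3.
#' @export
sed_volume <- function(tau_sm_ps, T_K, viscosity_mPas) {
  stopifnot(tau_sm_ps > 0, T_K > 0, viscosity_mPas > 0)
  # ps * J / (mPa s) = 1e-12 s * J / (1e-3 Pa s) -> m^3; 1 m^3 = 1e30 A^3
  tau_sm_ps * 1e-12 * .kB * T_K / (viscosity_mPas * 1e-3) * 1e30
}

#' SED rotation time from a hydrodynamic volume
#'
#' Forward SED relation, the exact inverse of [sed_volume()].
#'
#' @param V_h_A3 hydrodynamic volume, Angstrom^3.
#' @param T_K temperature, K.
#' @param viscosity_mPas solvent viscosity, mPa s.
#' @return Rotation time in ps.
#' @export
sed_time <- function(V_h_A3, T_K, viscosity_mPas) {
  stopifnot(V_h_A3 > 0, T_K > 0, viscosity_mPas > 0)
  V_h_A3 * 1e-30 * viscosity_mPas * 1e-3 / (.kB * T_K) * 1e12
}

#' Hydration summary from a full-spectrum fit
#'
#' Combines the fitted solution decomposition with the sample metadata
#' into the headline quantities: mole ratio f, hydration number N_h,
#' perturbed-water fraction, retardation xi and the component times.
#'
#' @param fit an `edls_fit` from [fit_full_spectrum()].
#' @param meta the matching [solution_meta()].
#' @return An object of class `hydration_result` (also a list) with fields
#'   `f`, `N_h`, `xi`, `perturbed_fraction`, `tau_hydr_mean_ps`,
#'   `tau_bulk_mean_ps`, `tau_D_ps`.
#' @export
hydration_result <- function(fit, meta) {
  stopifnot(inherits(fit, "edls_fit"), inherits(meta, "solution_meta"))
  hyd <- model_components(fit$model, "hydration_water")[[1L]]
  blk <- model_components(fit$model, "bulk_water")[[1L]]
  rot <- model_components(fit$model, "solute_rotation")[[1L]]
  f <- mole_ratio(meta)
  structure(list(
    f = f,
    N_h = hydration_number(hyd$amplitude, blk$amplitude, f),
    xi = retardation(mean_relaxation_time(hyd), mean_relaxation_time(blk)),
    perturbed_fraction = hyd$amplitude / (hyd$amplitude + blk$amplitude),
    tau_hydr_mean_ps = mean_relaxation_time(hyd),
    tau_bulk_mean_ps = mean_relaxation_time(blk),
    tau_D_ps = rot$tau_ps), class = "hydration_result")
}

#' @export
print.hydration_result <- function(x, ...) {
  cat(sprintf(
    paste0("<hydration_result> f = %.4g, N_h = %.1f, xi = %.2f, ",
           "perturbed fraction = %.2f, tau_D = %.1f ps\n"),
    x$f, x$N_h, x$xi, x$perturbed_fraction, x$tau_D_ps))
  invisible(x)
}
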