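# Constrained multi-component least-squares fits of pure-water,
# solvent-free (SF) and full solution susceptibility spectra.
#
# The objective is least squares on relative residuals,
# (chi''_model - chi''_data) / w with w = max(|data|, floor): the spectra
# span ~4 decades in amplitude and uniform weighting would swamp the GHz
# relaxation region the analysis is about. Optimization is bounded
# Levenberg-Marquardt (minpack.lm::nls.lm) with seeded multiplicative
# random restarts; the best residual wins.

#' Fit configuration
#'
#' @param beta fixed Cole-Davidson shape parameter for all CD components
#'   (default 0.6).
#' @param weighting `"relative"` (default) or `"uniform"`.
#' @param rel_floor_frac floor of the relative-residual denominator as a
#'   fraction of the spectrum maximum; guards against near-zero data in
#'   SF spectra.
#' @param mask list of two-element frequency intervals (GHz) excluded from
#'   the fit (e.g. spurious Brillouin-leakage points).
#' @param n_restarts number of random multiplicative restarts around the
#'   starting point (the unperturbed start is always tried too).
#' @param restart_sigma log-scale s.d. of the restart perturbations.
#' @param seed integer seed for the restart stream.
#' @param maxiter maximum LM iterations per start.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(beta = 0.6, weighting = c("relative", "uniform"),
                       rel_floor_frac = 1e-3, mask = NULL, n_restarts = 8L,
                       restart_sigma = 0.3, seed = 1L, maxiter = 300L) {
  weighting <- match.arg(weighting)
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  structure(list(beta = beta, weighting = weighting,
                 rel_floor_frac = rel_floor_frac, mask = mask,
                 n_restarts = as.integer(n_restarts),
                 restart_sigma = restart_sigma, seed = as.integer(seed),
                 maxiter = as.integer(maxiter)),
            class = "fit_config")
}

mask_points <- function(f, mask) {
  keep <- rep(TRUE, length(f))
  for (iv in mask) keep <- keep & !(f >= iv[1L] & f <= iv[2L])
  keep
}

fit_weights <- function(y, cfg) {
  top <- max(abs(y))
  if (top == 0) return(rep(1, length(y)))   # degenerate (e.g. null SF) data
  if (cfg$weighting == "uniform") return(rep(top, length(y)))
  pmax(abs(y), cfg$rel_floor_frac * top)
}

# Bounded LM with seeded random restarts. `build` maps a named parameter
# vector to a spectral_model; returns the best nls.lm object plus its start.
lm_restarts <- function(par0, lower, upper, f, y, w, build, cfg) {
  resid_fn <- function(p) {
    names(p) <- names(par0)
    (model_chi(build(p), f) - y) / w
  }
  old <- .Random.seed_guard(cfg$seed)
  on.exit(old(), add = TRUE)
  ctrl <- minpack.lm::nls.lm.control(maxiter = cfg$maxiter,
                                     ftol = 1e-13, ptol = 1e-13)
  start_deviance <- sum(resid_fn(par0)^2)
  best <- NULL
  for (k in 0:cfg$n_restarts) {
    p_start <- par0
    if (k > 0L) {
      fac <- exp(stats::rnorm(length(par0), 0, cfg$restart_sigma))
      p_start <- pmin(pmax(par0 * fac, lower), upper)
      # keep zero starts perturbable
      p_start[par0 == 0] <- pmin(upper, pmax(lower, 0))[par0 == 0]
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p_start, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed to converge from any start; check data and bounds")
  attr(best, "start_deviance") <- start_deviance
  best
}

finish_fit <- function(best, par_names, build, f, y, w, cfg, lower, upper,
                       flags = character()) {
  p <- best$par
  names(p) <- par_names
  np <- length(p)
  n <- length(y)
  sigma2 <- best$deviance / max(1L, n - np)
  se <- rep(NA_real_, np)
  cov_try <- try(sigma2 * solve(best$hessian), silent = TRUE)
  if (!inherits(cov_try, "try-error")) {
    d <- diag(cov_try)
    se <- ifelse(d > 0, sqrt(d), NA_real_)
  }
  names(se) <- par_names
  at_bounds <- par_names[p <= lower + 1e-12 | p >= upper - 1e-12]
  structure(list(model = build(p), par = p, se = se,
                 rms = sqrt(best$deviance / n), ssr = best$deviance,
                 start_rms = sqrt(attr(best, "start_deviance") / n),
                 nobs = n, niter = best$niter,
                 data = list(f_GHz = f, values = y, weights = w),
                 at_bounds = at_bounds, flags = flags, seed = cfg$seed,
                 beta = cfg$beta),
            class = "edls_fit")
}

#' @export
print.edls_fit <- function(x, ...) {
  cat(sprintf("<edls_fit> %d parameters, %d points, weighted RMS = %.3g\n",
              length(x$par), x$nobs, x$rms))
  est <- format(signif(x$par, 5))
  sef <- format(signif(x$se, 3))
  for (i in seq_along(x$par))
    cat(sprintf("  %-12s %s +/- %s\n", names(x$par)[i], est[i], sef[i]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Recompute the weighted residual RMS of a fit
#'
#' Re-evaluates the stored best model against the stored data; equals
#' `fit$rms` up to floating-point noise.
#'
#' @param fit an `edls_fit`.
#' @return Weighted residual RMS.
#' @export
fit_residual_rms <- function(fit) {
  stopifnot(inherits(fit, "edls_fit"))
  r <- (model_chi(fit$model, fit$data$f_GHz) - fit$data$values) / fit$data$weights
  sqrt(mean(r^2))
}

prepare_fit_data <- function(s, cfg) {
  f <- s$f_GHz
  y <- s$values
  if (!is.null(cfg$mask)) {
    keep <- mask_points(f, cfg$mask)
    f <- f[keep]; y <- y[keep]
  }
  list(f = f, y = y, w = fit_weights(y, cfg))
}

#' Fit a pure-water susceptibility spectrum
#'
#' Model: one Cole-Davidson relaxation (beta fixed, default 0.6; pure water
#' peaks near 270 GHz) + two damped harmonic oscillators for the
#' intermolecular bending/stretching modes + one librational oscillator.
#'
#' @param s a susceptibility [spectrum()] covering at least 10-30,000 GHz.
#' @param cfg a [fit_config()].
#' @param start optional named start vector overriding the default
#'   (the standard water decomposition of [water_preset()]).
#' @return An `edls_fit` whose model carries roles `bulk_water`,
#'   `water_intermolecular` (x2) and `libration`.
#' @export
fit_pure_water <- function(s, cfg = fit_config(), start = NULL) {
  stopifnot(inherits(s, "edls_spectrum"))
  if (s$kind != "susceptibility") stop("need a susceptibility spectrum")
  if (min(s$f_GHz) > 10 || max(s$f_GHz) < 30000)
    stop("insufficient coverage of the relaxation: need the 10-30,000 GHz range")
  d <- prepare_fit_data(s, cfg)
  beta <- cfg$beta
  par0 <- c(d_cd = 1.0, t_cd = tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * 270),
            a1 = 0.35, w1 = 1800, g1 = 2500,
            a2 = 0.45, w2 = 5400, g2 = 5500,
            a3 = 0.80, w3 = 15000, g3 = 12000)
  if (!is.null(start)) par0[names(start)] <- start
  # scale amplitude starts to the data's overall level
  level <- max(d$y) # librational band dominates the default preset
  par0[c("d_cd", "a1", "a2", "a3")] <- par0[c("d_cd", "a1", "a2", "a3")] * level
  lower <- c(0, 0.05, 0, 400, 50, 0, 2000, 50, 0, 8000, 500)
  upper <- c(1e3 * level, 20, 1e3 * level, 3500, 5e4,
             1e3 * level, 8000, 5e4, 1e3 * level, 30000, 1e5)
  build <- function(p) spectral_model(
    cole_davidson(p[["d_cd"]], p[["t_cd"]], beta, role = "bulk_water"),
    dho(p[["a1"]], p[["w1"]], p[["g1"]], role = "water_intermolecular"),
    dho(p[["a2"]], p[["w2"]], p[["g2"]], role = "water_intermolecular"),
    dho(p[["a3"]], p[["w3"]], p[["g3"]], role = "libration"))
  best <- lm_restarts(par0, lower, upper, d$f, d$y, d$w, build, cfg)
  finish_fit(best, names(par0), build, d$f, d$y, d$w, cfg, lower, upper)
}

#' Fit a solvent-free spectrum
#'
#' Model: one Debye (solute rotation, peaking below 10 GHz) + one
#' Cole-Davidson (hydration water, beta fixed) + two broad Brownian
#' oscillators for the solute THz modes. Start values for the relaxations
#' are located from the low-frequency argmax of the data. A fit in which
#' the Debye and CD peaks come out within a factor 1.5 in frequency is
#' flagged `"degenerate_overlap"`; a Debye peaking above the CD is flagged
#' `"role_order"`.
#'
#' @param sf the solvent-free [spectrum()] from [solvent_free_subtract()].
#' @param cfg a [fit_config()]; the SF floor defaults to 5% of the maximum
#'   because SF spectra cross zero near the bulk-water peak.
#' @param start optional named start overrides.
#' @param fmax_GHz upper end of the fitted range; above a few THz the SF
#'   difference is dominated by the cancellation noise of the two large
#'   parent spectra and carries no solute information.
#' @return An `edls_fit` with roles `solute_rotation`, `hydration_water`,
#'   `solute_vibration` (x2).
#' @export
fit_solvent_free <- function(sf, cfg = fit_config(rel_floor_frac = 0.05),
                             start = NULL, fmax_GHz = 8000) {
  stopifnot(inherits(sf, "edls_spectrum"))
  # restrict to the informative range; also drop negative SF points (the
  # model is non-negative: sub-zero excursions come from over-subtraction
  # of the redistributed bulk-water relaxation, not from solute signal)
  keep <- sf$f_GHz <= fmax_GHz & sf$values > 0
  if (sum(keep) < 30L) keep <- sf$f_GHz <= fmax_GHz
  sf <- spectrum(sf$f_GHz[keep], sf$values[keep], kind = sf$kind,
                 sample = sf$sample, T_K = sf$T_K)
  d <- prepare_fit_data(sf, cfg)
  beta <- cfg$beta
  low <- d$f <= 100
  f_pk <- d$f[low][which.max(d$y[low])]
  amp_pk <- max(d$y[low])
  par0 <- c(d_D = 1.6 * amp_pk, t_D = 1000 / (2 * pi * f_pk),
            d_cd = 0.8 * amp_pk,
            t_cd = tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * 30),
            a1 = 0.05 * amp_pk, w1 = 1000, g1 = 1500,
            a2 = 0.08 * amp_pk, w2 = 3000, g2 = 4000)
  if (!is.null(start)) par0[names(start)] <- start
  big <- 100 * max(abs(d$y))
  lower <- c(0, 2, 0, 0.5, 0, 200, 50, 0, 1500, 50)
  upper <- c(big, 400, big, 40, big, 2500, 3e4, big, 8000, 5e4)
  build <- function(p) spectral_model(
    debye(p[["d_D"]], p[["t_D"]], role = "solute_rotation"),
    cole_davidson(p[["d_cd"]], p[["t_cd"]], beta, role = "hydration_water"),
    dho(p[["a1"]], p[["w1"]], p[["g1"]], role = "solute_vibration"),
    dho(p[["a2"]], p[["w2"]], p[["g2"]], role = "solute_vibration"))
  # project the start onto its exact weighted linear-LS amplitude section
  amp_idx <- match(c("d_D", "d_cd", "a1", "a2"), names(par0))
  X <- cbind(chi_values(debye(1, par0[["t_D"]]), d$f),
             chi_values(cole_davidson(1, par0[["t_cd"]], beta), d$f),
             chi_values(dho(1, par0[["w1"]], par0[["g1"]]), d$f),
             chi_values(dho(1, par0[["w2"]], par0[["g2"]]), d$f))
  a <- tryCatch(stats::lm.fit(X / d$w, d$y / d$w)$coefficients,
                error = function(e) NULL)
  if (!is.null(a) && !anyNA(a))
    par0[amp_idx] <- pmin(pmax(a, lower[amp_idx]), upper[amp_idx])
  best <- lm_restarts(par0, lower, upper, d$f, d$y, d$w, build, cfg)
  flags <- character()
  p <- best$par; names(p) <- names(par0)
  if (p[["d_D"]] > 0 && p[["d_cd"]] > 0) {
    f_D <- 1000 / (2 * pi * p[["t_D"]])
    f_CD <- tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * p[["t_cd"]])
    if (f_D > f_CD) flags <- c(flags, "role_order")
    if (abs(log(f_D / f_CD)) < log(1.5)) flags <- c(flags, "degenerate_overlap")
  }
  finish_fit(best, names(par0), build, d$f, d$y, d$w, cfg, lower, upper, flags)
}

#' Fit a full solution spectrum
#'
#' Model: solute-rotation Debye + hydration-water CD + bulk-like water CD
#' (both beta fixed) + two solute THz oscillators + the water
#' intermolecular and librational oscillators. The water oscillators are
#' held fixed at the pure-water fit values up to one floated common scale
#' `s_w` (absorbing residual gain mismatch between the solution and
#' solvent measurements, e.g. from librational-band normalization of
#' spectra whose relaxation tails differ); the bulk CD amplitude and time
#' float (in solution the bulk-like relaxation shifts from ~270 toward
#' ~200 GHz); the solute components are seeded from the SF fit and refined
#' (the SF spectrum also carries the bulk-water redistribution difference,
#' so its oscillator estimates are starting values only). If the refined
#' hydration CD ends up at a higher peak frequency than the bulk CD the
#' two roles are swapped back and the fit is flagged `"role_swap"`.
#'
#' @param s the solution susceptibility [spectrum()].
#' @param water_fit `edls_fit` from [fit_pure_water()].
#' @param sf_fit `edls_fit` from [fit_solvent_free()].
#' @param cfg a [fit_config()].
#' @param s_w_start starting value for the water gain factor; pass the
#'   librational normalization scale when the solution was rescaled onto
#'   the water reference after the water fit.
#' @return An `edls_fit` with all eight roles populated.
#' @export
fit_full_spectrum <- function(s, water_fit, sf_fit, cfg = fit_config(),
                              s_w_start = 1) {
  stopifnot(inherits(s, "edls_spectrum"), inherits(water_fit, "edls_fit"),
            inherits(sf_fit, "edls_fit"))
  if (s$kind != "susceptibility") stop("need a susceptibility spectrum")
  d <- prepare_fit_data(s, cfg)
  beta <- cfg$beta
  pw <- water_fit$par
  ps <- sf_fit$par
  # guard the hydration start against SF-fit collapse (zero amplitude or a
  # time pinned at a bound): fall back to a 30 GHz peak at moderate strength
  t_h0 <- unname(ps[["t_cd"]])
  d_h0 <- unname(ps[["d_cd"]])
  if (d_h0 < 0.05 * pw[["d_cd"]] || t_h0 > 35 || t_h0 < 2.5) {
    t_h0 <- tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * 30)
    d_h0 <- 0.4 * unname(pw[["d_cd"]])
  }
  par0 <- c(d_D = unname(ps[["d_D"]]), t_D = unname(ps[["t_D"]]),
            d_h = d_h0, t_h = t_h0,
            d_b = unname(max(pw[["d_cd"]] - d_h0, 0.05 * pw[["d_cd"]])),
            t_b = unname(pw[["t_cd"]] * 270 / 200),
            a_s1 = unname(ps[["a1"]]), w_s1 = unname(ps[["w1"]]),
            g_s1 = unname(ps[["g1"]]),
            a_s2 = unname(ps[["a2"]]), w_s2 = unname(ps[["w2"]]),
            g_s2 = unname(ps[["g2"]]),
            s_w = s_w_start)
  big <- 100 * max(d$y)
  lower <- c(0, 2, 0, 2, 0, 0.05, 0, 200, 50, 0, 1500, 50, 0.2)
  upper <- c(big, 400, big, 40, big, 5, big, 2500, 3e4, big, 8000, 5e4, 5)
  wat_osc <- c(model_components(water_fit$model, "water_intermolecular"),
               model_components(water_fit$model, "libration"))
  scale_osc <- function(o, s) { o$amplitude <- s * o$amplitude; o }
  build <- function(p) spectral_model(c(
    list(debye(p[["d_D"]], p[["t_D"]], role = "solute_rotation"),
         cole_davidson(p[["d_h"]], p[["t_h"]], beta, role = "hydration_water"),
         cole_davidson(p[["d_b"]], p[["t_b"]], beta, role = "bulk_water"),
         dho(p[["a_s1"]], p[["w_s1"]], p[["g_s1"]], role = "solute_vibration"),
         dho(p[["a_s2"]], p[["w_s2"]], p[["g_s2"]], role = "solute_vibration")),
    lapply(wat_osc, scale_osc, s = p[["s_w"]])))
  # the model is linear in the six amplitude-type parameters; given a set
  # of times/centers/dampings, the weighted linear least-squares amplitudes
  # are exact (clamped at zero) — used to project every start onto its best
  # amplitude section before Levenberg-Marquardt
  amp_names <- c("d_D", "d_h", "d_b", "a_s1", "a_s2", "s_w")
  wat_sum <- function(f) Reduce(`+`, lapply(wat_osc, chi_values, f_GHz = f))
  project_amplitudes <- function(p) {
    X <- cbind(chi_values(debye(1, p[["t_D"]]), d$f),
               chi_values(cole_davidson(1, p[["t_h"]], beta), d$f),
               chi_values(cole_davidson(1, p[["t_b"]], beta), d$f),
               chi_values(dho(1, p[["w_s1"]], p[["g_s1"]]), d$f),
               chi_values(dho(1, p[["w_s2"]], p[["g_s2"]]), d$f),
               wat_sum(d$f))
    a <- tryCatch(stats::lm.fit(X / d$w, d$y / d$w)$coefficients,
                  error = function(e) NULL)
    if (is.null(a) || anyNA(a)) return(p)
    p[amp_names] <- pmin(pmax(a, lower[match(amp_names, names(par0))]),
                         upper[match(amp_names, names(par0))])
    p
  }
  # second deterministic start at the canonical in-solution peak positions
  # (hydration ~30 GHz, bulk-like ~200 GHz); guards against a badly
  # contaminated SF seed
  par0b <- par0
  par0b[["t_h"]] <- tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * 30)
  par0b[["t_b"]] <- tan(pi / (2 * (1 + beta))) * 1000 / (2 * pi * 200)
  par0 <- project_amplitudes(par0)
  par0b <- project_amplitudes(par0b)
  best <- lm_restarts(par0, lower, upper, d$f, d$y, d$w, build, cfg)
  best_b <- lm_restarts(par0b, lower, upper, d$f, d$y, d$w, build, cfg)
  if (best_b$deviance < best$deviance) {
    attr(best_b, "start_deviance") <- attr(best, "start_deviance")
    best <- best_b
  }
  p <- best$par; names(p) <- names(par0)
  flags <- character()
  if (p[["t_h"]] < p[["t_b"]]) {     # hydration must be the slower (lower-peak) CD
    sw <- seq_along(par0)
    sw[3:6] <- c(5L, 6L, 3L, 4L)     # (d_h,t_h) <-> (d_b,t_b)
    best$par <- best$par[sw]
    best$hessian <- best$hessian[sw, sw]
    flags <- c(flags, "role_swap")
  }
  finish_fit(best, names(par0), build, d$f, d$y, d$w, cfg, lower, upper, flags)
}
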