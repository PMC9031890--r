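# Susceptibility lineshapes. All return the imaginary part chi'' evaluated
# on an ordinary-frequency grid in GHz; every shape is non-negative on a
# positive grid and vanishes as f -> 0.

check_grid <- function(f) {
  if (!is.numeric(f) || length(f) < 1L || anyNA(f))
    stop("frequency grid must be numeric and free of NA")
  if (any(f <= 0)) stop("frequency grid must be strictly positive")
  if (is.unsorted(f, strictly = TRUE)) stop("frequency grid must be strictly ascending")
  invisible(f)
}

#' Debye relaxation component
#'
#' Symmetric single-exponential relaxation, chi''(w) = Im{ -Delta/(1 + i w tau) }
#' = Delta * w*tau / (1 + (w*tau)^2), peaking at w*tau = 1.
#'
#' @param amplitude relaxation strength Delta (dimensionless susceptibility
#'   units), >= 0.
#' @param tau_ps relaxation time in ps, > 0.
#' @param role label for the component's place in a spectral decomposition
#'   (e.g. `"solute_rotation"`).
#' @return An object of class `c("debye", "edls_component")`.
#' @export
debye <- function(amplitude, tau_ps, role = "solute_rotation") {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0)
  if (!is.numeric(tau_ps) || length(tau_ps) != 1L || tau_ps <= 0)
    stop("tau_ps must be a single positive number")
  structure(list(amplitude = amplitude, tau_ps = tau_ps, role = role),
            class = c("debye", "edls_component"))
}

#' Cole-Davidson relaxation component
#'
#' Asymmetrically broadened relaxation chi''(w) = Im{ -Delta/(1 + i w tau)^beta }
#' = Delta * sin(beta * atan(w tau)) / (1 + (w tau)^2)^(beta/2).
#' Reduces to [debye()] at beta = 1. The mean relaxation time is
#' `beta * tau`.
#'
#' @param amplitude relaxation strength Delta, >= 0.
#' @param tau_ps Cole-Davidson time tau_CD in ps, > 0.
#' @param beta shape parameter in (0, 1].
#' @param role decomposition role label.
#' @return An object of class `c("cole_davidson", "edls_component")`.
#' @export
cole_davidson <- function(amplitude, tau_ps, beta = 0.6, role = "bulk_water") {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0)
  if (!is.numeric(tau_ps) || length(tau_ps) != 1L || tau_ps <= 0)
    stop("tau_ps must be a single positive number")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]")
  structure(list(amplitude = amplitude, tau_ps = tau_ps, beta = beta, role = role),
            class = c("cole_davidson", "edls_component"))
}

#' Damped harmonic oscillator component
#'
#' Resonant (possibly overdamped) vibrational mode,
#' chi''(w) = A * W0^2 * G0 * w / ((W0^2 - w^2)^2 + (G0 w)^2),
#' with W0 = 2*pi*center and G0 = 2*pi*damping angular quantities. The same
#' form serves both under- and overdamped ("Brownian oscillator") roles; in
#' the overdamped limit it approaches a Debye profile with
#' tau_eff = G0/W0^2.
#'
#' @param amplitude mode strength A, > 0 (or 0 for an absent mode).
#' @param center_GHz resonance frequency Omega as ordinary frequency, GHz.
#' @param damping_GHz damping Gamma as ordinary frequency, GHz.
#' @param role decomposition role label (e.g. `"solute_vibration"`,
#'   `"water_intermolecular"`, `"libration"`).
#' @return An object of class `c("dho", "edls_component")`.
#' @export
dho <- function(amplitude, center_GHz, damping_GHz, role = "water_intermolecular") {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0)
  if (!is.numeric(center_GHz) || length(center_GHz) != 1L || center_GHz <= 0)
    stop("center_GHz must be a single positive number")
  if (!is.numeric(damping_GHz) || length(damping_GHz) != 1L || damping_GHz <= 0)
    stop("damping_GHz must be a single positive number")
  structure(list(amplitude = amplitude, center_GHz = center_GHz,
                 damping_GHz = damping_GHz, role = role),
            class = c("dho", "edls_component"))
}

#' Evaluate a component's susceptibility on a frequency grid
#'
#' @param component an `edls_component` built by [debye()], [cole_davidson()]
#'   or [dho()].
#' @param f_GHz strictly positive ascending frequency grid, GHz.
#' @return Numeric vector of chi'' values, same length as `f_GHz`.
#' @export
chi_values <- function(component, f_GHz) UseMethod("chi_values")

#' @export
chi_values.debye <- function(component, f_GHz) {
  check_grid(f_GHz)
  wt <- omega_tau(f_GHz, component$tau_ps)
  component$amplitude * wt / (1 + wt^2)
}

#' @export
chi_values.cole_davidson <- function(component, f_GHz) {
  check_grid(f_GHz)
  wt <- omega_tau(f_GHz, component$tau_ps)
  b <- component$beta
  component$amplitude * sin(b * atan(wt)) / (1 + wt^2)^(b / 2)
}

#' @export
chi_values.dho <- function(component, f_GHz) {
  check_grid(f_GHz)
  w  <- 2 * pi * f_GHz
  w0 <- 2 * pi * component$center_GHz
  g0 <- 2 * pi * component$damping_GHz
  component$amplitude * w0^2 * g0 * w / ((w0^2 - w^2)^2 + (g0 * w)^2)
}

#' Mean relaxation time of a relaxation component
#'
#' For a Cole-Davidson shape the mean time is `beta * tau_CD`; a Debye shape
#' (beta = 1) returns `tau_D` itself.
#'
#' @param component a [debye()] or [cole_davidson()] component.
#' @return Mean relaxation time in ps.
#' @export
mean_relaxation_time <- function(component) {
  if (inherits(component, "debye")) return(component$tau_ps)
  if (inherits(component, "cole_davidson"))
    return(component$beta * component$tau_ps)
  stop("mean relaxation time is defined for relaxation components only")
}

#' Susceptibility peak frequency of a component
#'
#' Debye: `1/(2*pi*tau)`. Cole-Davidson: `tan(pi/(2*(1+beta))) / (2*pi*tau)`.
#' Damped oscillator: numeric argmax on a dense logarithmic grid around the
#' resonance, refined by [stats::optimize()].
#'
#' @param component an `edls_component` with positive amplitude.
#' @return Peak frequency f_max in GHz.
#' @export
peak_frequency <- function(component) {
  if (component$amplitude == 0)
    stop("peak frequency undefined for a zero-amplitude component")
  if (inherits(component, "debye"))
    return(1000 / (2 * pi * component$tau_ps))
  if (inherits(component, "cole_davidson")) {
    b <- component$beta
    return(tan(pi / (2 * (1 + b))) * 1000 / (2 * pi * component$tau_ps))
  }
  if (inherits(component, "dho")) {
    span <- c(component$center_GHz, component$damping_GHz^2 / component$center_GHz)
    lo <- min(span) / 100
    hi <- max(span) * 100
    f <- exp(seq(log(lo), log(hi), length.out = 4000L))
    i <- which.max(chi_values(component, f))
    opt <- stats::optimize(function(x) chi_values(component, x),
                           lower = f[max(1L, i - 1L)], upper = f[min(length(f), i + 1L)],
                           maximum = TRUE, tol = 1e-10)
    return(opt$maximum)
  }
  stop("unknown component type")
}

#' Additive spectral model
#'
#' An ordered collection of lineshape components whose susceptibilities add.
#' A solution-spectrum decomposition must contain exactly one
#' `hydration_water` and one `bulk_water` relaxation.
#'
#' @param ... `edls_component` objects.
#' @return An object of class `spectral_model`.
#' @export
spectral_model <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1L]]) &&
      !inherits(comps[[1L]], "edls_component"))
    comps <- comps[[1L]]
  if (length(comps) == 0L) stop("a spectral model needs at least one component")
  ok <- vapply(comps, inherits, logical(1L), what = "edls_component")
  if (!all(ok)) stop("all model members must be edls_component objects")
  roles <- vapply(comps, function(c) c$role, character(1L))
  for (r in c("hydration_water", "bulk_water"))
    if (sum(roles == r) > 1L) stop("at most one '", r, "' component allowed")
  structure(list(components = comps), class = "spectral_model")
}

#' Evaluate an additive spectral model
#'
#' @param model a [spectral_model()].
#' @param f_GHz strictly positive ascending frequency grid, GHz.
#' @return Pointwise sum of the component susceptibilities.
#' @export
model_chi <- function(model, f_GHz) {
  stopifnot(inherits(model, "spectral_model"))
  check_grid(f_GHz)
  Reduce(`+`, lapply(model$components, chi_values, f_GHz = f_GHz))
}

#' Extract the components of a model with a given role
#' @param model a [spectral_model()].
#' @param role role label to match.
#' @return List of matching components (possibly empty).
#' @export
model_components <- function(model, role) {
  stopifnot(inherits(model, "spectral_model"))
  Filter(function(c) identical(c$role, role), model$components)
}
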