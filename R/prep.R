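# Spectral reduction and assembly: Bose-Einstein susceptibility conversion,
# dark-count subtraction, two-segment joining, librational-band
# normalization, solvent-free subtraction.

#' Bose-Einstein occupation factor n_B + 1
#'
#' Returns `1/(1 - exp(-h f / kB T))`, the factor dividing the depolarized
#' intensity to obtain the susceptibility chi''. Strictly decreasing in f,
#' approaching 1 at high frequency and kB*T/(h f) in the classical limit.
#'
#' @param f_GHz frequency grid, GHz.
#' @param T_K temperature in kelvin, > 0.
#' @return Numeric vector of occupation factors (all > 1).
#' @export
bose_einstein_occupation <- function(f_GHz, T_K) {
  check_grid(f_GHz)
  if (!is.numeric(T_K) || length(T_K) != 1L || !is.finite(T_K) || T_K <= 0)
    stop("temperature must be a single positive number")
  x <- .h * f_GHz * 1e9 / (.kB * T_K)   # h f / kB T, dimensionless
  1 / (1 - exp(-x))
}

#' Reduce raw intensity to susceptibility
#'
#' Pointwise division of the measured depolarized intensity by the
#' Bose-Einstein occupation factor, chi'' = I / (n_B + 1), with unit
#' proportionality constant (arbitrary units).
#'
#' @param s a raw-intensity [spectrum()] carrying a temperature.
#' @return The susceptibility spectrum.
#' @export
intensity_to_susceptibility <- function(s) {
  stopifnot(inherits(s, "edls_spectrum"))
  if (s$kind != "raw_intensity") stop("input must be a raw_intensity spectrum")
  if (!is.finite(s$T_K)) stop("temperature missing; required for the reduction")
  fac <- bose_einstein_occupation(s$f_GHz, s$T_K)
  spectrum(s$f_GHz, s$values / fac, kind = "susceptibility",
           sample = s$sample, T_K = s$T_K)
}

#' Inverse reduction: susceptibility back to intensity
#'
#' @param s a susceptibility [spectrum()] carrying a temperature.
#' @return The raw-intensity spectrum (round-trips with
#'   [intensity_to_susceptibility()]).
#' @export
susceptibility_to_intensity <- function(s) {
  stopifnot(inherits(s, "edls_spectrum"))
  if (s$kind != "susceptibility") stop("input must be a susceptibility spectrum")
  if (!is.finite(s$T_K)) stop("temperature missing; required for the reduction")
  fac <- bose_einstein_occupation(s$f_GHz, s$T_K)
  spectrum(s$f_GHz, s$values * fac, kind = "raw_intensity",
           sample = s$sample, T_K = s$T_K)
}

#' Subtract a constant dark-count offset
#'
#' The offset is either supplied explicitly or estimated as the mean value
#' over a user-specified flat frequency window.
#'
#' @param s a raw-intensity [spectrum()].
#' @param offset constant to subtract; if `NULL`, estimated from `window`.
#' @param window two-element frequency interval (GHz) over which the signal
#'   is taken as dark-count dominated.
#' @return Spectrum with the offset removed.
#' @export
subtract_dark_counts <- function(s, offset = NULL, window = NULL) {
  stopifnot(inherits(s, "edls_spectrum"))
  if (is.null(offset)) {
    if (is.null(window) || length(window) != 2L)
      stop("supply either an explicit offset or a two-element window")
    sel <- s$f_GHz >= window[1L] & s$f_GHz <= window[2L]
    if (!any(sel)) stop("dark-count window contains no points")
    offset <- mean(s$values[sel])
  }
  spectrum(s$f_GHz, s$values - offset, kind = s$kind,
           sample = s$sample, T_K = s$T_K)
}

# Linear interpolation in (log f, value); grids here are log-dense, which
# makes this monotone-safe and overshoot-free.
interp_loglin <- function(f_from, v_from, f_to) {
  stats::approx(log(f_from), v_from, xout = log(f_to), rule = 1)$y
}

#' Join low- and high-frequency spectrum segments
#'
#' The two instrument segments overlap over roughly half a decade; the high
#' segment is rescaled by the least-squares factor that matches the low
#' segment over the overlap window (after interpolation to the low
#' segment's points there), then the segments are concatenated on a sorted,
#' deduplicated grid. Dark counts must already be subtracted.
#'
#' @param low,high [spectrum()] objects of the same kind.
#' @param overlap two-element frequency interval (GHz) contained in both
#'   segments; default 60-90 GHz.
#' @return The joined spectrum; the applied scale is attached as attribute
#'   `"join_scale"`.
#' @export
join_segments <- function(low, high, overlap = c(60, 90)) {
  stopifnot(inherits(low, "edls_spectrum"), inherits(high, "edls_spectrum"))
  if (low$kind != high$kind) stop("segments must have the same kind")
  if (length(overlap) != 2L || overlap[1L] >= overlap[2L])
    stop("overlap must be an increasing two-element interval")
  if (overlap[1L] < min(high$f_GHz) || overlap[2L] > max(low$f_GHz) ||
      overlap[1L] < min(low$f_GHz) || overlap[2L] > max(high$f_GHz))
    stop("overlap window not contained in both segments")
  sel <- low$f_GHz >= overlap[1L] & low$f_GHz <= overlap[2L]
  if (sum(sel) < 2L) stop("overlap window contains too few points")
  y_low <- low$values[sel]
  y_high <- interp_loglin(high$f_GHz, high$values, low$f_GHz[sel])
  # least-squares scale s minimizing sum (s*y_high - y_low)^2
  scale <- sum(y_low * y_high) / sum(y_high^2)
  f_all <- c(low$f_GHz, high$f_GHz)
  v_all <- c(low$values, scale * high$values)
  # below the overlap midpoint keep the low segment, above keep the high one
  mid <- sqrt(prod(overlap))
  keep <- c(low$f_GHz <= mid, high$f_GHz > mid)
  o <- order(f_all[keep])
  f_o <- f_all[keep][o]
  v_o <- v_all[keep][o]
  dup <- duplicated(f_o)
  out <- spectrum(f_o[!dup], v_o[!dup], kind = low$kind,
                  sample = low$sample, T_K = low$T_K)
  attr(out, "join_scale") <- scale
  out
}

#' Normalize a spectrum to a reference band
#'
#' Rescales `s` so that its trapezoidal integral over `window` on a log-f
#' abscissa equals the reference's. The water librational band
#' (default window 10,000-30,000 GHz) is used as an internal intensity
#' standard because it is nearly insensitive to temperature and solute
#' concentration.
#'
#' @param s spectrum to rescale.
#' @param ref reference spectrum (typically pure water).
#' @param window two-element frequency interval, GHz.
#' @return Rescaled copy of `s` with attribute `"norm_scale"`.
#' @export
normalize_to_reference_band <- function(s, ref, window = c(10000, 30000)) {
  stopifnot(inherits(s, "edls_spectrum"), inherits(ref, "edls_spectrum"))
  for (sp in list(s, ref))
    if (window[1L] < min(sp$f_GHz) || window[2L] > max(sp$f_GHz))
      stop("normalization window not covered by both spectra")
  band_integral <- function(sp) {
    sel <- sp$f_GHz >= window[1L] & sp$f_GHz <= window[2L]
    x <- log(sp$f_GHz[sel]); y <- sp$values[sel]
    sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
  }
  scale <- band_integral(ref) / band_integral(s)
  out <- spectrum(s$f_GHz, s$values * scale, kind = s$kind,
                  sample = s$sample, T_K = s$T_K)
  attr(out, "norm_scale") <- scale
  out
}

#' Solvent-free subtraction
#'
#' Subtracts the bulk-solvent susceptibility from the solution spectrum
#' (both previously normalized to the librational band), interpolating the
#' solvent onto the solution grid. Small negative excursions are expected
#' from noise and from the redistribution of the water relaxation; points
#' below -5% of the local solution value are flagged via the
#' `"negative_flagged"` attribute.
#'
#' @param solution,solvent susceptibility [spectrum()] objects.
#' @return The solvent-free (SF) spectrum on the solution grid.
#' @export
solvent_free_subtract <- function(solution, solvent) {
  stopifnot(inherits(solution, "edls_spectrum"), inherits(solvent, "edls_spectrum"))
  if (solution$kind != "susceptibility" || solvent$kind != "susceptibility")
    stop("both spectra must be susceptibility kind")
  keep <- solution$f_GHz >= min(solvent$f_GHz) & solution$f_GHz <= max(solvent$f_GHz)
  f <- solution$f_GHz[keep]
  v_solv <- interp_loglin(solvent$f_GHz, solvent$values, f)
  diff_v <- solution$values[keep] - v_solv
  out <- spectrum(f, diff_v, kind = "susceptibility",
                  sample = paste0(solution$sample, "_SF"), T_K = solution$T_K)
  attr(out, "negative_flagged") <- sum(diff_v < -0.05 * abs(solution$values[keep]))
  out
}
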