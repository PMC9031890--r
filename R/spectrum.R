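# Spectrum container and plain-text I/O.

#' Construct a spectrum
#'
#' A spectrum couples a strictly ascending positive frequency grid (GHz)
#' with per-point values that are either raw depolarized intensity or the
#' reduced susceptibility chi'', plus provenance metadata.
#'
#' @param f_GHz frequency grid, GHz, strictly positive and ascending.
#' @param values intensity or susceptibility values, finite, same length.
#' @param kind `"raw_intensity"` or `"susceptibility"`.
#' @param sample sample label.
#' @param T_K temperature in kelvin (needed for the Bose-Einstein reduction).
#' @return An object of class `edls_spectrum`.
#' @export
spectrum <- function(f_GHz, values, kind = c("susceptibility", "raw_intensity"),
                     sample = "unknown", T_K = NA_real_) {
  kind <- match.arg(kind)
  check_grid(f_GHz)
  if (length(values) != length(f_GHz))
    stop("values and grid must have the same length")
  if (!all(is.finite(values))) stop("spectrum values must be finite")
  structure(list(f_GHz = as.numeric(f_GHz), values = as.numeric(values),
                 kind = kind, sample = sample, T_K = T_K),
            class = "edls_spectrum")
}

#' @export
print.edls_spectrum <- function(x, ...) {
  cat(sprintf("<edls_spectrum> %s [%s], %d points, %.3g-%.3g GHz, T = %s K\n",
              x$sample, x$kind, length(x$f_GHz), min(x$f_GHz), max(x$f_GHz),
              format(x$T_K)))
  invisible(x)
}

#' Default logarithmic measurement grid
#'
#' @param n number of points.
#' @param fmin,fmax grid limits in GHz; defaults span the instrument range
#'   0.6 to 36,000 GHz.
#' @return Log-spaced frequency grid in GHz.
#' @export
default_grid <- function(n = 400L, fmin = 0.6, fmax = 36000) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Read a two-column spectral file
#'
#' Plain-text format: `#`-prefixed header lines carry `key: value` metadata
#' (`sample`, `T_K`, `kind`); data lines are `frequency_GHz value`.
#'
#' @param path file path.
#' @return An [spectrum()] object.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list(sample = "unknown", T_K = NA_real_, kind = "susceptibility")
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  dat <- utils::read.table(text = lines[!grepl("^\\s*#", lines) &
                                          nzchar(trimws(lines))],
                           col.names = c("f_GHz", "value"))
  o <- order(dat$f_GHz)
  spectrum(dat$f_GHz[o], dat$value[o], kind = meta$kind,
           sample = meta$sample, T_K = as.numeric(meta$T_K))
}

#' Write a spectrum to a two-column spectral file
#'
#' @param s an [spectrum()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "edls_spectrum"))
  hdr <- c(paste0("# sample: ", s$sample),
           paste0("# T_K: ", format(s$T_K, digits = 10)),
           paste0("# kind: ", s$kind))
  body <- sprintf("%.10e %.10e", s$f_GHz, s$values)
  writeLines(c(hdr, body), path)
  invisible(path)
}
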