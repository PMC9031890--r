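# Shared fixtures: everything is generated in code at test time.

dense_grid <- function(n = 20000L, fmin = 0.1, fmax = 1e5) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

# Brute-force peak location: argmax over a dense log grid.
argmax_freq <- function(component, grid = dense_grid()) {
  grid[which.max(chi_values(component, grid))]
}

nagma_meta <- function(conc = 50) solution_meta("NAGMA", 130.15, conc, 293.15)

quiet_cfg <- function(...) fit_config(n_restarts = 4L, ...)
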