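# Bose-Einstein reduction, segment joining, normalization, SF subtraction.

test_that("the occupation factor has the right limits and the kBT/h crossing value", {
  g <- default_grid()
  fac <- bose_einstein_occupation(g, 293.15)
  expect_true(all(fac > 1))
  expect_true(all(diff(fac) < 0))                 # strictly decreasing
  expect_equal(fac[length(fac)], 1, tolerance = 5e-3)
  # h f = kB T at f = 20.8366 GHz/K * T; factor = 1/(1 - 1/e)
  f_cross <- 293.15 * 1e-9 * 1.380649e-23 / 6.62607015e-34
  expect_equal(bose_einstein_occupation(c(1, f_cross), 293.15)[2L],
               1 / (1 - exp(-1)), tolerance = 1e-12)
  # classical limit ~ kB T / (h f)
  expect_equal(bose_einstein_occupation(c(0.6), 293.15),
               f_cross / 0.6, tolerance = 1e-3)
  expect_error(bose_einstein_occupation(g, -5), "positive")
})

test_that("intensity <-> susceptibility conversion is an exact bijection", {
  g <- default_grid()
  s_chi <- water_spectrum(noise = noise_spec(0))$spectrum
  # construct I = chi * (nB + 1), reduce, recover chi exactly
  I <- s_chi$values * bose_einstein_occupation(g, s_chi$T_K)
  s_raw <- spectrum(g, I, kind = "raw_intensity", T_K = s_chi$T_K)
  back <- intensity_to_susceptibility(s_raw)
  expect_equal(back$values, s_chi$values, tolerance = 1e-12)
  expect_identical(back$kind, "susceptibility")
  # round trip through the inverse operation
  rt <- susceptibility_to_intensity(back)
  expect_equal(rt$values, I, tolerance = 1e-12)
  # constant intensity maps to a strictly increasing susceptibility
  s_const <- spectrum(g, rep(2, length(g)), kind = "raw_intensity", T_K = 293.15)
  expect_true(all(diff(intensity_to_susceptibility(s_const)$values) > 0))
  s_noT <- spectrum(g, I, kind = "raw_intensity")
  expect_error(intensity_to_susceptibility(s_noT), "temperature")
})

test_that("dark-count subtraction removes a constant offset estimated from a flat window", {
  g <- default_grid()
  base <- chi_values(debye(1, 27), g) + 0.37
  s <- spectrum(g, base, kind = "raw_intensity", T_K = 293.15)
  out <- subtract_dark_counts(s, window = c(20000, 36000))
  sel <- g >= 20000
  expect_lt(max(abs(out$values[sel])), 1e-3)
  out2 <- subtract_dark_counts(s, offset = 0.37)
  expect_equal(out2$values, base - 0.37)
  expect_error(subtract_dark_counts(s), "window")
})

test_that("segment joining recovers exact gain ratios and is idempotent", {
  truth <- water_spectrum(noise = noise_spec(0))$spectrum
  g <- truth$f_GHz
  lo <- spectrum(g[g <= 90], truth$values[g <= 90], "susceptibility", T_K = 293.15)
  hi <- spectrum(g[g >= 60], 2 * truth$values[g >= 60], "susceptibility", T_K = 293.15)
  joined <- join_segments(lo, hi, overlap = c(62, 88))
  expect_equal(attr(joined, "join_scale"), 0.5, tolerance = 1e-12)
  expect_equal(interp_vals <- joined$values,
               truth$values[g %in% joined$f_GHz], tolerance = 1e-10)
  # identical segments: output equals input on the union grid
  j2 <- join_segments(truth, truth, overlap = c(62, 88))
  expect_equal(j2$f_GHz, g)
  expect_equal(j2$values, truth$values, tolerance = 1e-12)
  # idempotent on already-joined data
  j3 <- join_segments(j2, j2, overlap = c(62, 88))
  expect_equal(j3$values, j2$values, tolerance = 1e-12)
  expect_error(join_segments(lo, hi, overlap = c(5, 8)), "overlap")
})

test_that("joining noisy split segments reconstructs the underlying curve within 2% RMS", {
  truth <- water_spectrum(noise = noise_spec(0))$spectrum
  g <- truth$f_GHz
  set.seed(11)
  gain_lo <- 1.7; gain_hi <- 0.4
  lo <- spectrum(g[g <= 90],
                 gain_lo * truth$values[g <= 90] * exp(rnorm(sum(g <= 90), 0, 0.01)),
                 "susceptibility", T_K = 293.15)
  hi <- spectrum(g[g >= 60],
                 gain_hi * truth$values[g >= 60] * exp(rnorm(sum(g >= 60), 0, 0.01)),
                 "susceptibility", T_K = 293.15)
  joined <- join_segments(lo, hi, overlap = c(62, 88))
  ref <- gain_lo * truth$values[g %in% joined$f_GHz]
  rel_rms <- sqrt(mean((joined$values / ref - 1)^2))
  expect_lt(rel_rms, 0.02)
})

test_that("librational-band normalization equalizes band integrals", {
  w <- water_spectrum(noise = noise_spec(0))$spectrum
  s3 <- spectrum(w$f_GHz, 3 * w$values, "susceptibility", T_K = w$T_K)
  out <- normalize_to_reference_band(s3, w)
  expect_equal(attr(out, "norm_scale"), 1 / 3, tolerance = 1e-12)
  expect_equal(out$values, w$values, tolerance = 1e-12)
  same <- normalize_to_reference_band(w, w)
  expect_equal(attr(same, "norm_scale"), 1, tolerance = 1e-12)
  # two gains, same librational band -> curves agree after normalization
  meta <- nagma_meta(50)
  a <- solution_spectrum(meta, noise = noise_spec(0))$spectrum
  a_gain <- spectrum(a$f_GHz, 5.5 * a$values, "susceptibility", T_K = a$T_K)
  a_norm <- normalize_to_reference_band(a_gain, a)
  expect_equal(a_norm$values, a$values, tolerance = 1e-10)
  short <- spectrum(a$f_GHz[a$f_GHz < 5000], a$values[a$f_GHz < 5000],
                    "susceptibility")
  expect_error(normalize_to_reference_band(short, w), "window")
})

test_that("solvent-free subtraction is exact on shared grids and linear", {
  w <- water_spectrum(noise = noise_spec(0))$spectrum
  zero <- solvent_free_subtract(w, w)
  expect_equal(zero$values, rep(0, length(w$f_GHz)))
  # solution = solvent + Debye -> SF equals the Debye curve
  extra <- chi_values(debye(1, 27), w$f_GHz)
  sol <- spectrum(w$f_GHz, w$values + extra, "susceptibility", T_K = w$T_K)
  sf <- solvent_free_subtract(sol, w)
  expect_equal(sf$values, extra, tolerance = 1e-12)
  raw <- spectrum(w$f_GHz, w$values, "raw_intensity", T_K = w$T_K)
  expect_error(solvent_free_subtract(sol, raw), "susceptibility")
})

test_that("the synthetic 50 mg/mL solution minus water has its dominant SF peak below 10 GHz", {
  meta <- nagma_meta(50)
  sol <- solution_spectrum(meta, noise = noise_spec(0))$spectrum
  w <- water_spectrum(noise = noise_spec(0))$spectrum
  sf <- solvent_free_subtract(normalize_to_reference_band(sol, w), w)
  low <- sf$f_GHz <= 1000
  f_peak <- sf$f_GHz[low][which.max(sf$values[low])]
  expect_gt(f_peak, 3)
  expect_lt(f_peak, 10)
})

test_that("spectral files round-trip through the two-column text format", {
  s <- water_spectrum(noise = noise_spec(0.02, seed = 3))$spectrum
  path <- withr::local_tempfile(fileext = ".dat")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(back$f_GHz, s$f_GHz, tolerance = 1e-9)
  expect_equal(back$values, s$values, tolerance = 1e-9)
  expect_identical(back$sample, s$sample)
  expect_equal(back$T_K, s$T_K)
  expect_identical(back$kind, s$kind)
})
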