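# Closed-form lineshapes and the additive model.

test_that("Debye susceptibility has amplitude/2 maximum at omega*tau = 1 and vanishes at the ends", {
  tau <- 27
  f_at_wt1 <- 1000 / (2 * pi * tau)          # omega*tau = 1
  expect_equal(chi_values(debye(1, tau), c(f_at_wt1)), 0.5, tolerance = 1e-12)
  g <- dense_grid(2000L, 1e-3, 1e6)
  v <- chi_values(debye(1, tau), g)
  expect_true(all(v >= 0))
  expect_lt(v[1L], 1e-3)                     # f -> 0 limit
  expect_lt(v[length(v)], 1e-3)              # f -> infinity limit
  # brute-force argmax agrees with the analytic peak 1/(2 pi tau) ~ 5.9 GHz
  expect_equal(argmax_freq(debye(1, tau)), 5.8946, tolerance = 1e-3)
  expect_equal(peak_frequency(debye(1, tau)), 1000 / (2 * pi * tau))
  expect_error(debye(1, -3), "positive")
})

test_that("Cole-Davidson reduces to Debye at beta = 1 and peaks at the analytic position", {
  g <- dense_grid(5000L)
  expect_lt(max(abs(chi_values(cole_davidson(0.7, 12, 1), g) -
                    chi_values(debye(0.7, 12), g))), 1e-12)
  # omega_max * tau = tan(pi / (2 (1 + beta))) across the beta range
  for (b in seq(0.2, 1.0, by = 0.2)) {
    cd <- cole_davidson(1, 7.94, b)
    wt_max <- 2 * pi * argmax_freq(cd) * 7.94e-3
    expect_equal(wt_max, tan(pi / (2 * (1 + b))), tolerance = 2e-3)
    expect_equal(peak_frequency(cd) * 2 * pi * 7.94e-3,
                 tan(pi / (2 * (1 + b))), tolerance = 1e-12)
  }
  expect_equal(chi_values(cole_davidson(0, 5, 0.6), g), rep(0, length(g)))
  expect_error(cole_davidson(1, 5, 0), "beta")
  expect_error(cole_davidson(1, 5, 1.2), "beta")
  # beta = 0.6, tau = 7.94 ps peaks at ~30 GHz
  expect_equal(peak_frequency(cole_davidson(1, 7.94, 0.6)), 30, tolerance = 1e-3)
})

test_that("mean relaxation time is beta * tau and <tau>/tau_max = 0.90 at beta 0.6", {
  expect_identical(mean_relaxation_time(cole_davidson(1, 5, 1)), 5)
  expect_equal(mean_relaxation_time(cole_davidson(1, 7.94, 0.6)), 4.764)
  cd <- cole_davidson(1, 7.94, 0.6)
  tau_max <- 1000 / (2 * pi * peak_frequency(cd))
  expect_equal(mean_relaxation_time(cd) / tau_max, 0.90, tolerance = 0.005 / 0.90)
})

test_that("damped oscillator peaks at the resonance when underdamped and reduces to Debye when overdamped", {
  # weak damping: argmax within 1% of the center
  expect_equal(argmax_freq(dho(1, 1000, 50)), 1000, tolerance = 0.01)
  g <- dense_grid()
  v <- chi_values(dho(1, 1000, 50), g)
  expect_lt(v[1L], 1e-4)
  expect_true(all(v >= 0))
  # overdamped: matches a Debye with tau_eff = Gamma0/Omega0^2 below Omega/10
  om <- 10; gam <- 1000
  tau_eff <- (2 * pi * gam * 1e-3) / (2 * pi * om * 1e-3)^2
  f_lo <- dense_grid(300L, 0.101, om / 10)
  ratio <- chi_values(dho(1, om, gam), f_lo) / chi_values(debye(1, tau_eff), f_lo)
  expect_true(all(abs(ratio - 1) < 0.02))
  expect_error(dho(1, -5, 10), "positive")
  expect_error(dho(1, 5, 0), "positive")
})

test_that("peak_frequency rejects zero-amplitude components", {
  expect_error(peak_frequency(debye(0, 5)), "undefined")
})

test_that("the spectral model is additive and homogeneous in the amplitudes", {
  g <- default_grid()
  c1 <- debye(0.6, 27)
  c2 <- cole_davidson(0.5, 7.94, 0.6, role = "hydration_water")
  c3 <- dho(0.3, 1800, 2500)
  m <- spectral_model(c1, c2, c3)
  expect_equal(model_chi(spectral_model(c1), g), chi_values(c1, g))
  expect_equal(model_chi(m, g),
               chi_values(c1, g) + chi_values(c2, g) + chi_values(c3, g))
  m2 <- spectral_model(debye(1.2, 27), cole_davidson(1.0, 7.94, 0.6,
                                                     role = "hydration_water"),
                       dho(0.6, 1800, 2500))
  expect_equal(model_chi(m2, g), 2 * model_chi(m, g), tolerance = 1e-12)
  expect_error(spectral_model(), "at least one")
  expect_error(spectral_model(c2, c2), "hydration_water")
})

test_that("the default solution model shows the expected relaxation landscape", {
  meta <- nagma_meta(50)
  truth <- solution_spectrum(meta, noise = noise_spec(0))$truth
  g <- dense_grid(4000L, 0.6, 36000)
  v <- model_chi(truth, g)
  # local maxima from a numeric extrema scan
  loc_max <- which(diff(sign(diff(v))) == -2) + 1L
  f_max <- g[loc_max]
  # one local maximum in the solute-rotation region (Debye tau_D ~ 38 ps)
  expect_true(any(f_max > 3 & f_max < 10))
  # the librational band tops the THz region
  expect_true(any(f_max > 8000 & f_max < 30000))
  # hydration and bulk components peak at 30 and 200 GHz by construction
  expect_equal(peak_frequency(model_components(truth, "hydration_water")[[1L]]),
               30, tolerance = 1e-6)
  expect_equal(peak_frequency(model_components(truth, "bulk_water")[[1L]]),
               200, tolerance = 1e-6)
})
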