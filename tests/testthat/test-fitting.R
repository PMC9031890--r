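# Constrained multi-component fits: round trips, null components, seeding.

test_that("a noiseless water spectrum is recovered to within 0.1% in every parameter", {
  ws <- water_spectrum(noise = noise_spec(0))
  wf <- fit_pure_water(ws$spectrum, quiet_cfg())
  truth <- c(d_cd = 1, t_cd = tan(pi / 3.2) * 1000 / (2 * pi * 270),
             a1 = 0.35, w1 = 1800, g1 = 2500,
             a2 = 0.45, w2 = 5400, g2 = 5500,
             a3 = 0.80, w3 = 15000, g3 = 12000)
  expect_lt(max(abs(wf$par / truth - 1)), 1e-3)
  expect_lt(wf$rms, 1e-8)
  # stored residual metric is reproducible from the stored model
  expect_equal(fit_residual_rms(wf), wf$rms, tolerance = 1e-9)
})

test_that("a truncated spectrum is rejected for lack of relaxation coverage", {
  ws <- water_spectrum(noise = noise_spec(0))$spectrum
  keep <- ws$f_GHz >= 100
  trunc <- spectrum(ws$f_GHz[keep], ws$values[keep], "susceptibility",
                    T_K = ws$T_K)
  expect_error(fit_pure_water(trunc), "coverage")
})

test_that("water fitting at 2% noise recovers the relaxation peak within 10%", {
  ws <- water_spectrum(noise = noise_spec(0.02, seed = 7))
  wf <- fit_pure_water(ws$spectrum, quiet_cfg(seed = 7))
  pk <- peak_frequency(model_components(wf$model, "bulk_water")[[1L]])
  expect_lt(abs(pk / 270 - 1), 0.10)
})

test_that("fits are reproducible given data, config and seed", {
  ws <- water_spectrum(noise = noise_spec(0.02, seed = 3))
  f1 <- fit_pure_water(ws$spectrum, quiet_cfg(seed = 5))
  f2 <- fit_pure_water(ws$spectrum, quiet_cfg(seed = 5))
  expect_identical(f1$par, f2$par)
})

test_that("a noiseless SF spectrum built from the model family is recovered within 0.5%", {
  g <- default_grid()
  truth <- c(d_D = 0.62, t_D = 27, d_cd = 0.54, t_cd = 7.94,
             a1 = 0.07, w1 = 1000, g1 = 1500,
             a2 = 0.10, w2 = 3000, g2 = 4000)
  m <- spectral_model(
    debye(truth[["d_D"]], truth[["t_D"]]),
    cole_davidson(truth[["d_cd"]], truth[["t_cd"]], 0.6, role = "hydration_water"),
    dho(truth[["a1"]], truth[["w1"]], truth[["g1"]], role = "solute_vibration"),
    dho(truth[["a2"]], truth[["w2"]], truth[["g2"]], role = "solute_vibration"))
  sf <- spectrum(g, model_chi(m, g), "susceptibility", T_K = 293.15)
  fit <- fit_solvent_free(sf, quiet_cfg(rel_floor_frac = 0.05))
  expect_lt(max(abs(fit$par / truth - 1)), 5e-3)
  # linearity: scaling every amplitude by 10 scales the estimates, not the times
  sf10 <- spectrum(g, 10 * model_chi(m, g), "susceptibility", T_K = 293.15)
  fit10 <- fit_solvent_free(sf10, quiet_cfg(rel_floor_frac = 0.05))
  amps <- c("d_D", "d_cd", "a1", "a2")
  expect_equal(unname(fit10$par[amps] / fit$par[amps]), rep(10, 4L),
               tolerance = 1e-3)
  expect_equal(unname(fit10$par[c("t_D", "t_cd")]),
               unname(fit$par[c("t_D", "t_cd")]), tolerance = 1e-3)
})

test_that("a null Debye component is recovered as (near) zero amplitude", {
  g <- default_grid()
  m <- spectral_model(
    cole_davidson(0.54, 7.94, 0.6, role = "hydration_water"),
    dho(0.07, 1000, 1500, role = "solute_vibration"),
    dho(0.10, 3000, 4000, role = "solute_vibration"))
  sf <- spectrum(g, model_chi(m, g), "susceptibility", T_K = 293.15)
  fit <- fit_solvent_free(sf, quiet_cfg(rel_floor_frac = 0.05))
  expect_lt(fit$par[["d_D"]], 0.01 * fit$par[["d_cd"]])
})

test_that("the full-spectrum fit recovers a noiseless solution to machine-level accuracy", {
  meta <- nagma_meta(50)
  gen <- solution_spectrum(meta, noise = noise_spec(0))
  wat <- water_spectrum(noise = noise_spec(0))
  res <- analyze_solution(gen$spectrum, wat$spectrum, meta, quiet_cfg())
  tp <- gen$truth_params
  p <- res$full_fit$par
  sc <- p[["s_w"]]   # librational normalization gain absorbed by the fit
  expect_lt(abs(p[["d_D"]] / (sc * tp$delta_D) - 1), 5e-3)
  expect_lt(abs(p[["t_D"]] / tp$tau_D_ps - 1), 5e-3)
  expect_lt(abs(p[["t_h"]] / tp$tau_hydr_ps - 1), 5e-3)
  expect_lt(abs(p[["t_b"]] / tp$tau_bulk_ps - 1), 5e-3)
  share <- p[["d_h"]] / (p[["d_h"]] + p[["d_b"]])
  expect_lt(abs(share / tp$perturbed_fraction - 1), 0.01)
  # derived quantities
  expect_equal(res$hydration$N_h, tp$N_h, tolerance = 0.01)
  expect_equal(res$hydration$xi, tp$tau_hydr_ps / tp$tau_bulk_ps,
               tolerance = 0.01)
  # residual of the best model never exceeds that of its seeded start
  expect_lte(res$full_fit$rms, res$full_fit$start_rms + 1e-12)
  expect_lte(res$sf_fit$rms, res$sf_fit$start_rms + 1e-12)
})

test_that("feeding pure water through the solution fit leaves solute and hydration empty", {
  wat <- water_spectrum(noise = noise_spec(0))
  wf <- fit_pure_water(wat$spectrum, quiet_cfg())
  zero_sf <- spectrum(wat$spectrum$f_GHz,
                      rep(0, length(wat$spectrum$f_GHz)),
                      "susceptibility", T_K = 293.15)
  sff <- fit_solvent_free(zero_sf, quiet_cfg(rel_floor_frac = 0.05))
  ff <- fit_full_spectrum(wat$spectrum, wf, sff, quiet_cfg())
  expect_lt(ff$par[["d_D"]], 0.01 * ff$par[["d_b"]])
  expect_lt(ff$par[["d_h"]], 0.01 * ff$par[["d_b"]])
})

test_that("the noiseless concentration series returns xi within 2% of truth everywhere", {
  series <- concentration_series(noise = noise_spec(0))
  wat <- water_spectrum(noise = noise_spec(0))
  wf <- fit_pure_water(wat$spectrum, quiet_cfg())
  for (gen in series) {
    conc <- as.numeric(sub(".*_(\\d+)mg$", "\\1", gen$spectrum$sample))
    meta <- nagma_meta(conc)
    res <- analyze_solution(gen$spectrum, wat$spectrum, meta, quiet_cfg(),
                            water_fit = wf)
    truth_xi <- gen$truth_params$tau_hydr_ps / gen$truth_params$tau_bulk_ps
    expect_equal(res$hydration$xi, truth_xi, tolerance = 0.02)
    expect_equal(res$hydration$N_h, gen$truth_params$N_h, tolerance = 0.02)
  }
})
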