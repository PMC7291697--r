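test_that("absorption is linear in concentrations and zero for empty tissue", {
  grid <- combined_grid(5)
  empty <- tissue_composition()
  expect_equal(absorption_coefficient(empty, grid, test_chrom),
               rep(0, length(grid$wavelengths_nm)))
  set.seed(41)
  for (i in 1:20) {
    a <- tissue_composition(runif(1, 0, 40), runif(1, 0, 60),
                            runif(1, 0, 0.5), runif(1, 0, 0.5))
    b <- tissue_composition(runif(1, 0, 40), runif(1, 0, 60),
                            runif(1, 0, 0.5), runif(1, 0, 0.5))
    mu_a <- absorption_coefficient(a, grid, test_chrom)
    mu_b <- absorption_coefficient(b, grid, test_chrom)
    if (a$fat_frac_vol + b$fat_frac_vol +
        a$water_frac_vol + b$water_frac_vol <= 1) {
      ab <- tissue_composition(a$hb_conc + b$hb_conc,
                               a$hbo2_conc + b$hbo2_conc,
                               a$fat_frac_vol + b$fat_frac_vol,
                               a$water_frac_vol + b$water_frac_vol)
      expect_equal(absorption_coefficient(ab, grid, test_chrom), mu_a + mu_b,
                   tolerance = 1e-12)
    }
    if (2 * (a$fat_frac_vol + a$water_frac_vol) <= 1) {
      dbl <- tissue_composition(2 * a$hb_conc, 2 * a$hbo2_conc,
                                2 * a$fat_frac_vol, 2 * a$water_frac_vol)
      expect_equal(absorption_coefficient(dbl, grid, test_chrom), 2 * mu_a,
                   tolerance = 1e-12)
    }
    expect_true(all(mu_a >= 0))
  }
})

test_that("pure water reproduces the embedded water table at grid points", {
  tab <- read.csv(system.file("extdata", "chromophores", "water_synthetic.csv",
                              package = "drsfit"))
  wl <- c(970, 1200, 1450)  # points present in the 2 nm table
  comp <- tissue_composition(water_frac_vol = 1)
  mua <- absorption_coefficient(comp, wavelength_grid(wl), test_chrom)
  expect_equal(mua, tab$specific_absorption[match(wl, tab$wavelength_nm)],
               tolerance = 1e-12)
})

test_that("absorption refuses wavelengths outside the chromophore support", {
  expect_error(
    absorption_coefficient(tissue_composition(water_frac_vol = 0.5),
                           wavelength_grid(c(400, 500)), test_chrom),
    "outside chromophore support")
})

test_that("reduced scattering follows the 800 nm power law", {
  # amp = 16, b = 1 at 1600 nm: 16 * (2)^-1 = 8
  comp <- tissue_composition(scatter_amp_800 = 16, scatter_slope = 1)
  expect_equal(reduced_scattering(comp, wavelength_grid(c(800, 1600))),
               c(16, 8))
  flat <- tissue_composition(scatter_amp_800 = 12.5, scatter_slope = 0)
  expect_equal(reduced_scattering(flat, combined_grid(10)),
               rep(12.5, length(combined_grid(10)$wavelengths_nm)))
  set.seed(7)
  for (i in 1:25) {
    amp <- runif(1, 1, 40); b <- runif(1, 0, 4)
    comp <- tissue_composition(scatter_amp_800 = amp, scatter_slope = b)
    expect_identical(reduced_scattering(comp, wavelength_grid(c(800, 900)))[1],
                     amp)
  }
  expect_error(tissue_composition(scatter_amp_800 = 0), "positive")
})

test_that("diffusion reflectance matches the independent formula oracle", {
  set.seed(13)
  mua <- runif(120, 0.001, 50)
  musp <- runif(120, 2, 40)
  rho <- runif(120, 0.03, 0.3)
  for (i in seq_along(mua)) {
    got <- farrell_reflectance(mua[i], musp[i], rho[i])
    want <- farrell_oracle(mua[i], musp[i], rho[i])
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(farrell_reflectance(c(0, 1), c(0, 10), 0.1), "undefined")
})

test_that("reflectance decreases with chromophore concentration and distance", {
  set.seed(23)
  for (i in 1:10) {
    base <- random_composition(1000 + i)
    r0 <- forward_reflectance(base, test_inst, test_chrom)$reflectance
    for (field in c("hb_conc", "hbo2_conc", "fat_frac_vol", "water_frac_vol")) {
      up <- unclass(base)
      bump <- if (grepl("conc", field)) 1 else 0.05
      up[[field]] <- up[[field]] + bump
      if (up$fat_frac_vol + up$water_frac_vol > 1) next
      up <- do.call(tissue_composition, up)
      r1 <- forward_reflectance(up, test_inst, test_chrom)$reflectance
      expect_true(all(r1 < r0),
                  label = paste("monotone decreasing in", field))
    }
  }
  comp <- zone_median_composition("cancellous")
  near <- instrument_config(fiber_separation_mm = 0.5)
  far <- instrument_config(fiber_separation_mm = 1.042)
  expect_true(all(forward_reflectance(comp, far, test_chrom)$reflectance <
                    forward_reflectance(comp, near, test_chrom)$reflectance))
})

test_that("forward model is deterministic", {
  comp <- zone_median_composition("breach")
  a <- forward_reflectance(comp, test_inst, test_chrom)
  b <- forward_reflectance(comp, test_inst, test_chrom)
  expect_identical(a$reflectance, b$reflectance)
})

test_that("instrument noise is seeded, unbiased, and clips at zero", {
  comp <- zone_median_composition("cancellous")
  spec <- forward_reflectance(comp, test_inst, test_chrom)
  clean_inst <- instrument_config(noise = noise_model(0, 0, 0))
  expect_identical(add_instrument_noise(spec, clean_inst, 5)$reflectance,
                   spec$reflectance)
  n1 <- add_instrument_noise(spec, test_inst, 42)
  n2 <- add_instrument_noise(spec, test_inst, 42)
  expect_identical(n1$reflectance, n2$reflectance)
  expect_false(identical(add_instrument_noise(spec, test_inst, 43)$reflectance,
                         n1$reflectance))

  # Monte-Carlo unbiasedness at one wavelength: mean over 10000 replicates
  # within 3 standard errors of the noiseless value
  i1200 <- which(spec$grid$wavelengths_nm == 1200)
  one_wl <- drs_spectrum(wavelength_grid(c(1200, 1201)),
                         rep(spec$reflectance[i1200], 2))
  draws <- vapply(1:10000, function(s) {
    add_instrument_noise(one_wl, test_inst, s)$reflectance[1]
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - spec$reflectance[i1200]), 3 * se)

  # clipping: huge additive noise floors at zero and is counted
  loud <- instrument_config(noise = noise_model(0, 0, additive = 10))
  clipped <- add_instrument_noise(spec, loud, 7)
  expect_true(all(clipped$reflectance >= 0))
  expect_gt(clipped$meta$n_clipped, 0)
})
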