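test_that("zone draws converge to configured medians and respect truncation", {
  model <- zone_model()
  comps <- sample_zone_composition("cancellous", "low_pressure", model,
                                   n = 10000, seed = 1)
  ff <- vapply(comps, true_fat_fraction, numeric(1))
  blood <- vapply(comps, blood_content, numeric(1))
  expect_lt(abs(median(ff) - 26.4), 1)
  expect_lt(abs(median(blood) - 28.9), 1)
  expect_true(all(ff >= 11.9 - 1e-9 & ff <= 50.0 + 1e-9))
  expect_true(all(blood >= 21.4 - 1e-9 & blood <= 51.3 + 1e-9))
  amp <- vapply(comps, `[[`, numeric(1), "scatter_amp_800")
  expect_true(all(amp >= 14.6 & amp <= 17.2))
})

test_that("degenerate min = max = median collapses to a point mass", {
  model <- zone_model(zones = list(
    cancellous = list(blood = c(30, 30, 30), fat_fraction = c(20, 20, 20),
                      fw_total = 0.8)),
    scatter_amp_range = c(16, 16))
  comps <- sample_zone_composition("cancellous", "low_pressure", model,
                                   n = 50, seed = 3)
  expect_true(all(abs(vapply(comps, blood_content, numeric(1)) - 30) < 1e-9))
  expect_true(all(abs(vapply(comps, true_fat_fraction, numeric(1)) - 20) < 1e-9))
})

test_that("handling conditions shift the truth distributions as constructed", {
  model <- zone_model()
  ret <- sample_zone_composition("cancellous", "retracted", model,
                                 n = 5000, seed = 11)
  low <- sample_zone_composition("cancellous", "low_pressure", model,
                                 n = 5000, seed = 12)
  high <- sample_zone_composition("cancellous", "high_pressure", model,
                                  n = 5000, seed = 13)
  b_ret <- vapply(ret, blood_content, numeric(1))
  b_low <- vapply(low, blood_content, numeric(1))
  b_high <- vapply(high, blood_content, numeric(1))
  f_ret <- vapply(ret, true_fat_fraction, numeric(1))
  f_low <- vapply(low, true_fat_fraction, numeric(1))

  # retracted draws higher blood and lower fat fraction than low pressure;
  # high pressure draws lower blood than low pressure
  t1 <- wilcoxon_rank_sum(b_ret, b_low, alpha = 0.01)
  expect_true(t1$significant)
  expect_gt(median(b_ret), median(b_low))
  t2 <- wilcoxon_rank_sum(f_ret, f_low, alpha = 0.01)
  expect_true(t2$significant)
  expect_lt(median(f_ret), median(f_low))
  t3 <- wilcoxon_rank_sum(b_high, b_low, alpha = 0.01)
  expect_true(t3$significant)
  expect_lt(median(b_high), median(b_low))

  expect_error(sample_zone_composition("marrow", "low_pressure", model),
               "unknown zone")
  expect_error(sample_zone_composition("pcz", "shaken", model),
               "unknown handling condition")
})

test_that("insertion generation yields 30 spectra per position with true zones", {
  inst <- coarse_inst
  tr <- generate_insertion(c(-8), inst = inst, chrom = test_chrom, seed = 5)
  expect_length(tr$measurements, 30)
  conds <- vapply(tr$measurements, `[[`, character(1), "condition")
  expect_equal(unname(table(conds)[c("low_pressure", "high_pressure",
                                     "retracted")]),
               rep(10L, 3), ignore_attr = TRUE)
  # zone_true always agrees with the zone labeller (cross-module invariant)
  for (m in tr$measurements) {
    expect_identical(m$zone_true, label_zone(m$depth_mm))
  }
  expect_error(generate_insertion(c(1.5, -8), inst = inst, chrom = test_chrom),
               "nondecreasing")
})

test_that("the default six-insertion dataset holds 270 spectra", {
  geom <- default_insertion_geometry()
  expect_equal(vapply(geom, length, integer(1)), c(2L, 1L, 1L, 2L, 2L, 1L))
  inst <- coarse_inst
  ds <- generate_insertion_dataset(geom, inst = inst, chrom = test_chrom,
                                   seed = 2)
  expect_length(ds$measurements, 270)
  zones <- vapply(ds$measurements, `[[`, character(1), "zone_true")
  expect_setequal(unique(zones), c("cancellous", "pcz", "cortical", "breach"))
})

test_that("generated datasets are byte-identical for the same seed", {
  inst <- coarse_inst
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  ds_a <- generate_insertion_dataset(list(c(-8, 1.5)), inst = inst,
                                     chrom = test_chrom, seed = 9,
                                     n_per_condition = 2)
  ds_b <- generate_insertion_dataset(list(c(-8, 1.5)), inst = inst,
                                     chrom = test_chrom, seed = 9,
                                     n_per_condition = 2)
  ds_c <- generate_insertion_dataset(list(c(-8, 1.5)), inst = inst,
                                     chrom = test_chrom, seed = 10,
                                     n_per_condition = 2)
  write_insertion_dataset(ds_a, d1)
  write_insertion_dataset(ds_b, d2)
  write_insertion_dataset(ds_c, d3)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 0)
  for (f in files) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
  }
  expect_false(identical(readLines(file.path(d3, files[2])),
                         readLines(file.path(d1, files[2]))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("sacrifice truth matches its endpoints and decays monotonically", {
  tr <- sacrifice_truth(seq(0, 4200, length.out = 2020))
  expect_equal(tr$blood_pct[1], 18.9)
  expect_equal(tr$blood_pct[nrow(tr)], 8.1)
  expect_equal(tr$fat_fraction_pct[1], 35.5)
  expect_equal(tr$fat_fraction_pct[nrow(tr)], 32.3)
  expect_true(all(diff(tr$blood_pct) <= 0))
  expect_true(all(diff(tr$fat_fraction_pct) <= 0))
  expect_error(sacrifice_truth(-5), "time_s")
})

test_that("a noiseless sacrifice series starts at the configured blood content", {
  ser <- generate_sacrifice_series(n_samples = 3, inst = coarse_inst,
                                   chrom = test_chrom, seed = 0, noisy = FALSE)
  f0 <- fit_spectrum(ser$measurements[[1]]$spectrum, coarse_inst, test_chrom)
  expect_lt(abs(f0$blood_content_pct - 18.9), 0.05)
  # generated truth compositions track the configured trajectories
  b <- vapply(ser$measurements, function(m) blood_content(m$truth), numeric(1))
  expect_equal(b, ser$truth$blood_pct, tolerance = 1e-12)
})

test_that("end-to-end zone recovery: fitted low-pressure medians track the model", {
  inst <- coarse_inst
  ds <- generate_insertion_dataset(inst = inst, chrom = test_chrom, seed = 21,
                                   n_per_condition = 4)
  fits <- suppressWarnings(fit_dataset(ds, inst, test_chrom))
  lp <- fits[fits$condition == "low_pressure" & fits$converged, ]
  zs <- summarize_zones(lp)
  model <- zone_model()
  for (z in names(model$zones)) {
    med_ff <- zs$median[zs$zone == z & zs$parameter == "fat_fraction_pct"]
    med_bl <- zs$median[zs$zone == z & zs$parameter == "blood_pct"]
    expect_lt(abs(med_ff - model$zones[[z]]$fat_fraction[1]), 6)
    expect_lt(abs(med_bl - model$zones[[z]]$blood[1]), 6)
  }
})
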