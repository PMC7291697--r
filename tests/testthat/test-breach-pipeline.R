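test_that("zone labelling matches the anatomical geometry", {
  expect_identical(label_zone(-5), "cancellous")
  expect_identical(label_zone(-2), "pcz")
  expect_identical(label_zone(1), "breach")
  expect_identical(label_zone(0), "cortical")
  expect_identical(label_zone(-0.5), "cortical")
  expect_identical(label_zone(3), "breach")
  # with a zero-thickness cortex the boundary layer alone is cortical
  expect_identical(label_zone(-0.5, cortical_thickness_mm = 0), "pcz")
  expect_identical(label_zone(0, cortical_thickness_mm = 0), "cortical")
  expect_error(label_zone(3.2), "beyond the defined breach zone")
  expect_error(label_zone(NaN), "finite")
})

test_that("the pre-cortical zone is exactly 3 mm wide on a 0.1 mm trajectory", {
  depths <- seq(-8, 3, by = 0.1)
  zones <- label_zone(depths)
  expect_equal(sum(zones == "pcz") * 0.1, 3.0, tolerance = 1e-9)
  # zones appear in anatomical order along the insertion
  expect_identical(rle(zones)$values, c("cancellous", "pcz", "cortical",
                                        "breach"))
})

test_that("zone summaries agree with a sort-based oracle", {
  set.seed(31)
  n <- 40
  fits <- data.frame(
    zone_true = sample(c("cancellous", "pcz", "cortical", "breach"), n,
                       replace = TRUE),
    blood_pct = runif(n, 5, 90),
    fat_fraction_pct = runif(n, 0, 60),
    scatter_amp_800 = runif(n, 12, 20))
  zs <- summarize_zones(fits)
  sort_median <- function(v) {
    s <- sort(v)
    if (length(s) %% 2 == 1) s[(length(s) + 1) / 2]
    else mean(s[length(s) / 2 + 0:1])
  }
  for (i in seq_len(nrow(zs))) {
    v <- fits[[switch(zs$parameter[i], blood_pct = "blood_pct",
                      fat_fraction_pct = "fat_fraction_pct",
                      scatter_amp_800 = "scatter_amp_800")]][
      fits$zone_true == zs$zone[i]]
    expect_equal(zs$median[i], sort_median(v))
    expect_equal(zs$min[i], min(v))
    expect_equal(zs$max[i], max(v))
    expect_true(zs$min[i] <= zs$median[i] && zs$median[i] <= zs$max[i])
  }
  # single measurement: median = min = max
  one <- suppressWarnings(
    summarize_zones(data.frame(zone_true = "pcz", blood_pct = 33.3)))
  expect_equal(one$median, 33.3)
  expect_equal(one$min, one$max)
  three <- suppressWarnings(
    summarize_zones(data.frame(zone_true = rep("pcz", 3),
                               blood_pct = c(1, 2, 3))))
  expect_equal(three$median, 2)
  expect_warning(summarize_zones(data.frame(zone_true = "pcz",
                                            blood_pct = 1)),
                 "no measurements in zone")
})

test_that("breach calls follow the fat-fraction drop logic", {
  # constant fat fraction: every position is safe
  flat <- data.frame(position = 1:5, fat_fraction_pct = rep(25, 5),
                     blood_pct = rep(30, 5))
  expect_true(all(detect_breach_signal(flat)$call == "advance_safe"))

  # cancellous -> pcz -> cortical from generator truths: warning at the pcz
  model <- zone_model()
  set.seed(17)
  mk <- function(zone, pos) {
    comps <- sample_zone_composition(zone, "low_pressure", model, n = 10)
    data.frame(position = pos,
               fat_fraction_pct = vapply(comps, true_fat_fraction, numeric(1)),
               blood_pct = vapply(comps, blood_content, numeric(1)))
  }
  traj <- rbind(mk("cancellous", 1), mk("pcz", 2), mk("cortical", 3))
  calls <- detect_breach_signal(traj)
  expect_identical(calls$call[1], "advance_safe")
  expect_identical(calls$call[2], "impending_breach")

  # injected high-blood/low-fat measurement flags probe retraction
  inj <- rbind(mk("cancellous", 1),
               data.frame(position = 2, fat_fraction_pct = 2, blood_pct = 85),
               mk("cancellous", 3))
  expect_identical(detect_breach_signal(inj)$call[2], "retracted_suspect")

  # fat-fraction rebound with elevated blood after a warning: breached
  seq_tr <- data.frame(position = 1:4,
                       fat_fraction_pct = c(26, 4, 0.5, 11),
                       blood_pct = c(29, 28, 19, 49))
  expect_identical(detect_breach_signal(seq_tr)$call,
                   c("advance_safe", "impending_breach", "impending_breach",
                     "breached"))

  expect_error(detect_breach_signal(data.frame(position = 1,
                                               fat_fraction_pct = 1,
                                               blood_pct = 1)),
               "at least 2 positions")
  expect_error(detect_breach_signal(data.frame(position = 1:2,
                                               fat_fraction_pct = NA,
                                               blood_pct = 1)),
               "NA")
})

test_that("all-cancellous trajectories rarely raise a breach warning", {
  model <- zone_model()
  n_fp <- 0
  for (s in 1:100) {
    set.seed(s)
    traj <- do.call(rbind, lapply(1:4, function(pos) {
      comps <- unlist(lapply(c("low_pressure", "high_pressure", "retracted"),
                             function(cd) {
                               sample_zone_composition("cancellous", cd,
                                                       model, n = 10)
                             }), recursive = FALSE)
      data.frame(position = pos,
                 fat_fraction_pct = vapply(comps, true_fat_fraction,
                                           numeric(1)),
                 blood_pct = vapply(comps, blood_content, numeric(1)))
    }))
    if (any(detect_breach_signal(traj)$call == "impending_breach")) {
      n_fp <- n_fp + 1
    }
  }
  expect_lte(n_fp, 1)  # tolerated false-positive rate <= 1%
})

test_that("1200 nm normalization anchors, preserves shape, and is idempotent", {
  comp <- zone_median_composition("cancellous")
  spec <- forward_reflectance(comp, test_inst, test_chrom)
  norm <- normalize_at(spec)
  i1200 <- which(spec$grid$wavelengths_nm == 1200)
  expect_equal(norm$reflectance[i1200], 1)
  expect_equal(norm$reflectance / norm$reflectance[1],
               spec$reflectance / spec$reflectance[1], tolerance = 1e-12)
  expect_equal(normalize_at(norm)$reflectance, norm$reflectance)
  scaled <- drs_spectrum(spec$grid, 7 * spec$reflectance)
  expect_equal(normalize_at(scaled)$reflectance, norm$reflectance,
               tolerance = 1e-12)
  zero <- drs_spectrum(spec$grid, rep(0, length(spec$reflectance)))
  expect_error(normalize_at(zero), "positive")
  expect_error(normalize_at(spec, 2000), "outside the grid")
})

test_that("normalized sacrifice spectra overlap in the NIR but not at the blood bands", {
  ser <- generate_sacrifice_series(n_samples = 2, inst = test_inst,
                                   chrom = test_chrom, seed = 0,
                                   noisy = FALSE)
  a <- normalize_at(ser$measurements[[1]]$spectrum)  # t = 0
  b <- normalize_at(ser$measurements[[2]]$spectrum)  # t = 70 min
  wl <- a$grid$wavelengths_nm
  rel_diff <- abs(a$reflectance - b$reflectance) / a$reflectance
  nir <- wl >= 1000 & wl <= 1600
  blood_band <- wl >= 530 & wl <= 580
  expect_lt(max(abs(a$reflectance[nir] - b$reflectance[nir])), 0.15)
  expect_lt(max(rel_diff[nir]), 0.2)
  expect_gt(max(rel_diff[blood_band]), 2)
})
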