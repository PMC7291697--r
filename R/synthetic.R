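#' Per-zone tissue composition model
#'
#' Parameterizes the distributions from which ground-truth compositions are
#' drawn for each anatomical zone (cancellous bone, pre-cortical zone,
#' cortical bone, breach) and the probe-handling condition modifiers. Blood
#' content and fat fraction are each described by (median, min, max); draws
#' use a piecewise-uniform distribution with half its mass on either side of
#' the median so the sample median converges to the configured median while
#' respecting the truncation range. Defaults are the per-zone medians and
#' ranges observed during a typical in vivo vertebral insertion: cancellous
#' blood 28.9% \[21.4, 51.3\] with fat fraction 26.4% \[11.9, 50.0\], PCZ fat
#' fraction 5.3% \[0, 17.3\] with highly variable blood (median 28.8%,
#' \[21.0, 100\]), cortical blood 19.4% \[18.9, 20.5\] with fat fraction 0
#' \[0, 0.1\], and post-breach blood 48.9% \[48.1, 49.6\] with fat fraction
#' 11.2% \[10.9, 11.4\]. Scattering amplitude is uniform on \[14.6, 17.2\]
#' cm^-1.
#'
#' Handling-condition modifiers alter the drawn composition. High axial
#' pressure expels local blood relative to low pressure (`blood_scale`).
#' The retracted probe tip sits in a blood-filled pool: a mixing fraction
#' `m`, drawn uniformly from `pool_mix`, replaces part of the probed volume
#' with whole blood, raising blood content to `blood + m*(100 - blood)` and
#' diluting the fat fraction to `(1 - m)*ff`. The shared mixing fraction
#' couples the two effects, producing the characteristic trend of
#' decreasing fat fraction with increasing blood content under retraction.
#'
#' @param zones named list of per-zone parameter lists; each has `blood` and
#'   `fat_fraction` as `c(median, min, max)` (percent) and `fw_total`, the
#'   total fat+water volume fraction.
#' @param scatter_amp_range range (cm^-1) of the uniform scattering-amplitude
#'   draw.
#' @param scatter_slope scattering power-law exponent (held fixed).
#' @param so2 hemoglobin oxygen saturation used to split total hemoglobin
#'   into HbO2 and Hb.
#' @param conditions named list of per-condition modifiers with elements
#'   `blood_scale`, `ff_scale` and/or `pool_mix` (a `c(min, max)` range for
#'   the blood-pool mixing fraction).
#' @return An object of class `zone_model`.
#' @export
zone_model <- function(
    zones = list(
      cancellous = list(blood = c(28.9, 21.4, 51.3),
                        fat_fraction = c(26.4, 11.9, 50.0), fw_total = 0.80),
      pcz = list(blood = c(28.8, 21.0, 100),
                 fat_fraction = c(5.3, 0, 17.3), fw_total = 0.60),
      cortical = list(blood = c(19.4, 18.9, 20.5),
                      fat_fraction = c(0, 0, 0.1), fw_total = 0.30),
      breach = list(blood = c(48.9, 48.1, 49.6),
                    fat_fraction = c(11.2, 10.9, 11.4), fw_total = 0.70)),
    scatter_amp_range = c(14.6, 17.2),
    scatter_slope = 1.0,
    so2 = 0.7,
    conditions = list(
      low_pressure = list(blood_scale = 1.0, ff_scale = 1.0),
      high_pressure = list(blood_scale = 0.75, ff_scale = 1.0),
      retracted = list(blood_scale = 1.0, ff_scale = 1.0,
                       pool_mix = c(0.15, 0.75)))) {
  for (z in zones) {
    stopifnot(length(z$blood) == 3, length(z$fat_fraction) == 3,
              z$fw_total > 0, z$fw_total <= 1)
  }
  structure(list(zones = zones, scatter_amp_range = scatter_amp_range,
                 scatter_slope = scatter_slope, so2 = so2,
                 conditions = conditions),
            class = "zone_model")
}

# Piecewise-uniform draw with configured (median, min, max): half the mass on
# [min, median], half on [median, max]. min = max = median collapses to a
# point mass.
rmedian_range <- function(n, median, min, max) {
  u <- stats::runif(n)
  lo <- min + 2 * u * (median - min)
  hi <- median + (2 * u - 1) * (max - median)
  ifelse(u < 0.5, lo, hi)
}

scaled_triple <- function(triple, scale, cap = Inf) {
  pmin(triple * scale, cap)
}

#' Draw ground-truth compositions for a zone and handling condition
#'
#' @param zone one of `"cancellous"`, `"pcz"`, `"cortical"`, `"breach"`.
#' @param condition one of `"low_pressure"`, `"high_pressure"`, `"retracted"`.
#' @param model a [zone_model()].
#' @param n number of independent draws.
#' @param seed integer seed (draws are reproducible per seed).
#' @return A single [tissue_composition()] if `n = 1`, else a list of them.
#' @export
sample_zone_composition <- function(zone, condition = "low_pressure",
                                    model = zone_model(), n = 1,
                                    seed = NULL) {
  if (!zone %in% names(model$zones)) {
    stop("unknown zone '", zone, "'; expected one of ",
         paste(names(model$zones), collapse = ", "))
  }
  if (!condition %in% names(model$conditions)) {
    stop("unknown handling condition '", condition, "'")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  zp <- model$zones[[zone]]
  cond <- model$conditions[[condition]]
  blood_par <- scaled_triple(zp$blood, cond$blood_scale, cap = 100)
  ff_par <- scaled_triple(zp$fat_fraction, cond$ff_scale, cap = 100)

  blood <- rmedian_range(n, blood_par[1], blood_par[2], blood_par[3])
  ff <- rmedian_range(n, ff_par[1], ff_par[2], ff_par[3])
  if (!is.null(cond$pool_mix)) {
    m <- stats::runif(n, cond$pool_mix[1], cond$pool_mix[2])
    blood <- blood + m * (100 - blood)
    ff <- (1 - m) * ff
  }
  amp <- stats::runif(n, model$scatter_amp_range[1], model$scatter_amp_range[2])

  comps <- lapply(seq_len(n), function(i) {
    thb <- 150 * blood[i] / 100
    tissue_composition(
      hb_conc = thb * (1 - model$so2),
      hbo2_conc = thb * model$so2,
      fat_frac_vol = zp$fw_total * ff[i] / 100,
      water_frac_vol = zp$fw_total * (1 - ff[i] / 100),
      scatter_amp_800 = amp[i],
      scatter_slope = model$scatter_slope)
  })
  if (n == 1L) comps[[1]] else comps
}

#' Composition at a zone's configured median
#'
#' Deterministic counterpart of [sample_zone_composition()]: the composition
#' whose blood content and fat fraction sit exactly at the zone medians, with
#' the scattering amplitude at the midpoint of its range (or a supplied
#' value).
#'
#' @inheritParams sample_zone_composition
#' @param scatter_amp_800 optional scattering amplitude override, cm^-1.
#' @return A [tissue_composition()].
#' @export
zone_median_composition <- function(zone, model = zone_model(),
                                    scatter_amp_800 = NULL) {
  if (!zone %in% names(model$zones)) stop("unknown zone '", zone, "'")
  zp <- model$zones[[zone]]
  thb <- 150 * zp$blood[1] / 100
  amp <- if (is.null(scatter_amp_800)) mean(model$scatter_amp_range) else scatter_amp_800
  tissue_composition(
    hb_conc = thb * (1 - model$so2),
    hbo2_conc = thb * model$so2,
    fat_frac_vol = zp$fw_total * zp$fat_fraction[1] / 100,
    water_frac_vol = zp$fw_total * (1 - zp$fat_fraction[1] / 100),
    scatter_amp_800 = amp,
    scatter_slope = model$scatter_slope)
}

new_probe_measurement <- function(spectrum, depth_mm, zone_true, condition,
                                  time_s, truth, position = NA_integer_,
                                  insertion = NA_integer_) {
  structure(list(spectrum = spectrum, depth_mm = depth_mm,
                 zone_true = zone_true, condition = condition,
                 time_s = time_s, truth = truth, position = position,
                 insertion = insertion),
            class = "probe_measurement")
}

measurement_meta_row <- function(m) {
  data.frame(insertion = m$insertion, position = m$position,
             depth_mm = m$depth_mm, zone_true = m$zone_true,
             condition = m$condition, time_s = m$time_s,
             true_blood_pct = blood_content(m$truth),
             true_fat_fraction_pct = as.numeric(
               fat_fraction(m$truth$fat_frac_vol, m$truth$water_frac_vol)),
             true_scatter_amp = m$truth$scatter_amp_800,
             stringsAsFactors = FALSE)
}

as_measurement_list <- function(x) {
  if (inherits(x, "probe_measurement")) return(list(x))
  if (!is.null(x$measurements)) return(x$measurements)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "probe_measurement"))) {
    return(x)
  }
  if (is.list(x) && length(x) &&
      all(vapply(x, function(el) !is.null(el$measurements), logical(1)))) {
    return(do.call(c, lapply(x, `[[`, "measurements")))
  }
  stop("cannot interpret input as a list of probe measurements")
}

#' Simulate one probe insertion trajectory
#'
#' At every measurement position (a signed depth relative to the outer
#' cortical boundary, negative inside the vertebra) the three handling
#' conditions are applied in sequence, with `n_per_condition` independent
#' measurements each: a fresh ground-truth composition is drawn for the
#' position's zone and condition, propagated through the forward model and
#' degraded with instrument noise.
#'
#' @param depths_mm nondecreasing vector of measurement depths (mm, signed
#'   distance to the outer cortical boundary; negative = inside).
#' @param model a [zone_model()].
#' @param inst an [instrument_config()].
#' @param chrom a [load_chromophores()] set.
#' @param seed integer seed; the full trajectory is reproducible per seed.
#' @param n_per_condition measurements per handling condition per position.
#' @param insertion_id integer label stored on each measurement.
#' @param cortical_thickness_mm passed to [label_zone()].
#' @return An object of class `insertion_trajectory` with fields
#'   `measurements` (list of `probe_measurement`), `depths_mm`, `seed`,
#'   `insertion_id`.
#' @export
generate_insertion <- function(depths_mm, model = zone_model(),
                               inst = instrument_config(),
                               chrom = load_chromophores(),
                               seed = 1, n_per_condition = 10,
                               insertion_id = 1L,
                               cortical_thickness_mm = 1) {
  if (any(diff(depths_mm) < 0)) {
    stop("measurement depths must be nondecreasing along the insertion")
  }
  set.seed(as.integer(seed))
  conditions <- names(model$conditions)
  measurements <- list()
  t_s <- 0
  for (ipos in seq_along(depths_mm)) {
    d <- depths_mm[ipos]
    zone <- label_zone(d, cortical_thickness_mm = cortical_thickness_mm)
    for (cond in conditions) {
      comps <- sample_zone_composition(zone, cond, model, n = n_per_condition)
      if (n_per_condition == 1L) comps <- list(comps)
      for (comp in comps) {
        noise_seed <- sample.int(.Machine$integer.max, 1)
        spec <- forward_reflectance(comp, inst, chrom,
                                    meta = list(condition = cond,
                                                depth_mm = d))
        spec <- add_instrument_noise(spec, inst, noise_seed)
        measurements[[length(measurements) + 1L]] <- new_probe_measurement(
          spec, d, zone, cond, time_s = t_s, truth = comp,
          position = ipos, insertion = insertion_id)
        t_s <- t_s + 1
      }
    }
  }
  structure(list(measurements = measurements, depths_mm = depths_mm,
                 seed = as.integer(seed), insertion_id = insertion_id,
                 cortical_thickness_mm = cortical_thickness_mm),
            class = "insertion_trajectory")
}

#' Default insertion geometry of the simulated experiment
#'
#' Six insertions with position counts (2, 1, 1, 2, 2, 1) — nine positions in
#' total, so with three conditions of ten measurements each the default
#' dataset holds 270 spectra. Depths are chosen so that every zone
#' (cancellous, PCZ, cortical, breach) is visited by at least two positions.
#' The exact split of positions across insertions is a free design choice of
#' the generator.
#'
#' @return A list of depth vectors (mm), one per insertion.
#' @export
default_insertion_geometry <- function() {
  list(c(-8, -2), c(-0.5), c(1.5), c(-8, -0.5), c(-2, 1.5), c(-8))
}

#' Simulate the full multi-insertion dataset
#'
#' @param geometry list of per-insertion depth vectors,
#'   default [default_insertion_geometry()].
#' @inheritParams generate_insertion
#' @return An object of class `insertion_dataset`: list with `insertions`
#'   (list of `insertion_trajectory`), `measurements` (flattened), `seed`.
#' @export
generate_insertion_dataset <- function(geometry = default_insertion_geometry(),
                                       model = zone_model(),
                                       inst = instrument_config(),
                                       chrom = load_chromophores(),
                                       seed = 1, n_per_condition = 10,
                                       cortical_thickness_mm = 1) {
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, length(geometry))
  insertions <- lapply(seq_along(geometry), function(i) {
    generate_insertion(geometry[[i]], model, inst, chrom,
                       seed = sub_seeds[i], n_per_condition = n_per_condition,
                       insertion_id = i,
                       cortical_thickness_mm = cortical_thickness_mm)
  })
  structure(list(insertions = insertions,
                 measurements = do.call(c, lapply(insertions, `[[`,
                                                  "measurements")),
                 seed = as.integer(seed)),
            class = "insertion_dataset")
}

#' Ground-truth trajectories of the sacrifice time series
#'
#' Endpoint-matched exponential decay between the configured start and end
#' values: `x(t) = x_end + (x_0 - x_end) * (exp(-k t) - exp(-k T)) /
#' (1 - exp(-k T))`, which passes exactly through `x_0` at `t = 0` and
#' `x_end` at `t = T` and decreases monotonically. Defaults follow the
#' post-sacrifice recording: blood content 18.9 -> 8.1 % and fat fraction
#' 35.5 -> 32.3 % over 70 min.
#'
#' @param time_s time(s) in seconds, in `[0, duration_s]`.
#' @param duration_s total recording duration, default 4200 s (70 min).
#' @param blood_pct,fat_fraction_pct `c(start, end)` values in percent.
#' @param rate decay rate k in 1/s; default `3 / duration_s` (the curve
#'   covers ~95% of its drop by the end of the recording).
#' @return A data frame with columns `time_s`, `blood_pct`,
#'   `fat_fraction_pct`.
#' @export
sacrifice_truth <- function(time_s, duration_s = 4200,
                            blood_pct = c(18.9, 8.1),
                            fat_fraction_pct = c(35.5, 32.3),
                            rate = 3 / duration_s) {
  if (any(time_s < 0 | time_s > duration_s)) {
    stop("time_s must lie in [0, duration_s]")
  }
  shape <- (exp(-rate * time_s) - exp(-rate * duration_s)) /
    (1 - exp(-rate * duration_s))
  data.frame(
    time_s = time_s,
    blood_pct = blood_pct[2] + (blood_pct[1] - blood_pct[2]) * shape,
    fat_fraction_pct = fat_fraction_pct[2] +
      (fat_fraction_pct[1] - fat_fraction_pct[2]) * shape)
}

#' Simulate the continuous post-sacrifice recording
#'
#' Generates `n_samples` probe measurements uniformly spanning
#' `[0, duration_s]` from the time-varying ground truth of
#' [sacrifice_truth()], holding the probe in cancellous bone at the center of
#' the vertebral body. The fat+water volume total is held at `fw_total`
#' (fat fraction, not fat content, is the conserved trajectory).
#'
#' @inheritParams generate_insertion
#' @param duration_s recording length in seconds (default 70 min).
#' @param n_samples number of spectra over the recording (default 2020).
#' @param fw_total total fat+water volume fraction of the probed marrow.
#' @param scatter_amp_800 scattering amplitude, cm^-1.
#' @param noisy logical; FALSE yields noiseless spectra.
#' @param ... passed to [sacrifice_truth()] (endpoints, rate).
#' @return An object of class `sacrifice_series` with `measurements`,
#'   `truth` (data frame) and `seed`.
#' @export
generate_sacrifice_series <- function(duration_s = 4200, n_samples = 2020,
                                      model = zone_model(),
                                      inst = instrument_config(),
                                      chrom = load_chromophores(),
                                      seed = 1, fw_total = 0.95,
                                      scatter_amp_800 = 15.9,
                                      noisy = TRUE, ...) {
  stopifnot(duration_s > 0, n_samples >= 2)
  set.seed(as.integer(seed))
  time_s <- seq(0, duration_s, length.out = n_samples)
  truth <- sacrifice_truth(time_s, duration_s, ...)
  noise_seeds <- sample.int(.Machine$integer.max, n_samples)
  measurements <- lapply(seq_len(n_samples), function(i) {
    thb <- 150 * truth$blood_pct[i] / 100
    comp <- tissue_composition(
      hb_conc = thb * (1 - model$so2),
      hbo2_conc = thb * model$so2,
      fat_frac_vol = fw_total * truth$fat_fraction_pct[i] / 100,
      water_frac_vol = fw_total * (1 - truth$fat_fraction_pct[i] / 100),
      scatter_amp_800 = scatter_amp_800,
      scatter_slope = model$scatter_slope)
    spec <- forward_reflectance(comp, inst, chrom,
                                meta = list(time_s = time_s[i]))
    if (noisy) spec <- add_instrument_noise(spec, inst, noise_seeds[i])
    new_probe_measurement(spec, depth_mm = -10, zone_true = "cancellous",
                          condition = "stationary", time_s = time_s[i],
                          truth = comp)
  })
  structure(list(measurements = measurements, truth = truth,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "sacrifice_series")
}
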