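#' Anatomical zone from probe depth
#'
#' Depth is the signed distance (mm) of the probe tip to the outer cortical
#' boundary of the vertebra along the trajectory: negative inside the bone,
#' positive outside. With a cortical shell of thickness `t` the zones are
#' half-open intervals:
#' cancellous `(-Inf, -3 - t)`, pre-cortical zone `[-3 - t, -t)` (exactly
#' 3 mm wide, the region within 3 mm of the inner cortical wall), cortical
#' `[-t, 0]`, breach `(0, 3]` (the first 3 mm outside the vertebra). Depths
#' beyond +3 mm are outside the defined geometry and raise an error.
#'
#' @param depth_mm signed distance(s) to the outer cortical boundary, mm.
#' @param pcz_width_mm width of the pre-cortical zone (default 3).
#' @param breach_width_mm extent of the breach zone beyond the boundary
#'   (default 3).
#' @param cortical_thickness_mm thickness of the cortical shell (default 1;
#'   0 reduces "cortical" to the boundary layer itself).
#' @return Character vector of zone labels.
#' @export
label_zone <- function(depth_mm, pcz_width_mm = 3, breach_width_mm = 3,
                       cortical_thickness_mm = 1) {
  if (any(!is.finite(depth_mm))) stop("depth_mm must be finite")
  if (any(depth_mm > breach_width_mm)) {
    stop(sprintf("depth %.2f mm is beyond the defined breach zone (> %g mm)",
                 max(depth_mm), breach_width_mm))
  }
  t <- cortical_thickness_mm
  ifelse(depth_mm < -pcz_width_mm - t, "cancellous",
         ifelse(depth_mm < -t, "pcz",
                ifelse(depth_mm <= 0, "cortical", "breach")))
}

#' Per-zone summaries of fitted physiological parameters
#'
#' Median, minimum and maximum of blood content, fat fraction and scattering
#' amplitude per zone (the nonparametric summary used because vertebral DRS
#' parameters are not normally distributed). Medians follow the standard
#' even/odd-n rule (midpoint of the central pair for even n). Zones present
#' in the label set but without any measurement are omitted with a warning.
#'
#' @param fits data frame with one row per measurement, containing a zone
#'   column and the parameter columns.
#' @param zone_col name of the zone-label column.
#' @param params named character vector mapping summary names to columns of
#'   `fits`.
#' @return A data frame of class `drs_zone_summary`, one row per zone and
#'   parameter with columns `zone`, `parameter`, `n`, `median`, `min`, `max`.
#' @export
summarize_zones <- function(fits, zone_col = "zone_true",
                            params = c(blood_pct = "blood_pct",
                                       fat_fraction_pct = "fat_fraction_pct",
                                       scatter_amp_800 = "scatter_amp_800")) {
  stopifnot(is.data.frame(fits), zone_col %in% names(fits))
  params <- params[params %in% names(fits)]
  if (!length(params)) stop("none of the parameter columns found in fits")
  zone_order <- c("cancellous", "pcz", "cortical", "breach")
  zones_present <- unique(fits[[zone_col]])
  zones <- c(intersect(zone_order, zones_present),
             setdiff(zones_present, zone_order))
  missing_zones <- setdiff(zone_order, zones_present)
  if (length(missing_zones)) {
    warning("no measurements in zone(s): ",
            paste(missing_zones, collapse = ", "), "; omitted")
  }
  rows <- list()
  for (z in zones) {
    sub <- fits[fits[[zone_col]] == z, , drop = FALSE]
    for (i in seq_along(params)) {
      v <- sub[[params[[i]]]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        zone = z, parameter = names(params)[i], n = length(v),
        median = stats::median(v), min = min(v), max = max(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("drs_zone_summary", class(out))
  out
}

#' Breach-detection configuration
#'
#' @param ff_abs_threshold absolute fat-fraction floor (percentage points);
#'   a position whose fat fraction falls below it AND below
#'   `ff_rel_drop` times the running cancellous baseline raises
#'   `impending_breach`.
#' @param ff_rel_drop relative drop factor against the baseline.
#' @param retract_blood_threshold blood content (%) above which a
#'   simultaneous fat-fraction drop is attributed to probe retraction
#'   (blood-pool signature) rather than an impending breach.
#' @param breach_blood_threshold blood content (%) that, together with a
#'   fat-fraction rebound after a warning, marks the probe as breached.
#' @param ff_rebound_pp minimum fat-fraction rise (pp) over the post-warning
#'   minimum required for a `breached` call.
#' @return A list of class `breach_config`.
#' @export
breach_config <- function(ff_abs_threshold = 10, ff_rel_drop = 0.5,
                          retract_blood_threshold = 60,
                          breach_blood_threshold = 40,
                          ff_rebound_pp = 3) {
  structure(list(ff_abs_threshold = ff_abs_threshold,
                 ff_rel_drop = ff_rel_drop,
                 retract_blood_threshold = retract_blood_threshold,
                 breach_blood_threshold = breach_blood_threshold,
                 ff_rebound_pp = ff_rebound_pp),
            class = "breach_config")
}

#' Breach-signal extraction from an ordered fit trajectory
#'
#' Walks the per-position medians of fitted fat fraction and blood content
#' along an insertion and emits one call per position:
#' `advance_safe`, `impending_breach` (sharp fat-fraction drop against the
#' running cancellous baseline, the signature of the cancellous-to-PCZ
#' transition), `retracted_suspect` (high blood with low fat fraction, the
#' blood-pool signature of a retracted probe), or `breached` (fat-fraction
#' rebound with elevated blood after a warning). Calls are a deterministic
#' function of the fits and the configuration.
#'
#' @param fits data frame of fitted measurements, ordered along the
#'   insertion, with columns `position` (or one row per position),
#'   `fat_fraction_pct` and `blood_pct`.
#' @param config a [breach_config()].
#' @return A data frame with one row per position: `position`,
#'   `fat_fraction_pct`, `blood_pct`, `baseline_ff`, `drop_pp`, `call`.
#' @export
detect_breach_signal <- function(fits, config = breach_config()) {
  stopifnot(is.data.frame(fits))
  if (!all(c("fat_fraction_pct", "blood_pct") %in% names(fits))) {
    stop("fits must contain fat_fraction_pct and blood_pct columns")
  }
  if (all(is.na(fits$fat_fraction_pct))) stop("all fat fractions are NA")
  pos <- if ("position" %in% names(fits)) fits$position else seq_len(nrow(fits))
  upos <- unique(pos)
  if (length(upos) < 2) stop("breach detection needs at least 2 positions")
  ff <- vapply(upos, function(p) {
    stats::median(fits$fat_fraction_pct[pos == p], na.rm = TRUE)
  }, numeric(1))
  blood <- vapply(upos, function(p) {
    stats::median(fits$blood_pct[pos == p], na.rm = TRUE)
  }, numeric(1))

  calls <- character(length(upos))
  baseline <- numeric(length(upos))
  warned <- FALSE
  ff_min_since_warn <- Inf
  safe_ff <- numeric(0)
  for (i in seq_along(upos)) {
    baseline[i] <- if (length(safe_ff)) stats::median(safe_ff) else ff[i]
    dropped <- ff[i] < config$ff_abs_threshold &&
      ff[i] < config$ff_rel_drop * baseline[i]
    if (blood[i] > config$retract_blood_threshold && dropped) {
      calls[i] <- "retracted_suspect"
    } else if (warned && blood[i] > config$breach_blood_threshold &&
               ff[i] > ff_min_since_warn + config$ff_rebound_pp) {
      calls[i] <- "breached"
    } else if (dropped) {
      calls[i] <- "impending_breach"
      warned <- TRUE
    } else {
      calls[i] <- "advance_safe"
      safe_ff <- c(safe_ff, ff[i])
    }
    if (warned) ff_min_since_warn <- min(ff_min_since_warn, ff[i])
  }
  data.frame(position = upos, fat_fraction_pct = ff, blood_pct = blood,
             baseline_ff = baseline, drop_pp = baseline - ff, call = calls,
             stringsAsFactors = FALSE)
}

#' Normalize a spectrum at an anchor wavelength
#'
#' Divides the whole spectrum by its reflectance at the anchor wavelength
#' (1200 nm by default, in the flat region between the water bands), so the
#' output is exactly 1 there and ratios between wavelengths are preserved.
#' Used for shape comparison of spectra acquired under different perfusion
#' states. The anchor value is linearly interpolated if the anchor is not a
#' grid point.
#'
#' @param spec a [drs_spectrum()].
#' @param wavelength_nm anchor wavelength (must lie inside the grid).
#' @return A normalized [drs_spectrum()].
#' @export
normalize_at <- function(spec, wavelength_nm = 1200) {
  stopifnot(inherits(spec, "drs_spectrum"))
  wl <- spec$grid$wavelengths_nm
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl)) {
    stop("anchor wavelength ", wavelength_nm, " nm outside the grid")
  }
  anchor <- stats::approx(wl, spec$reflectance, xout = wavelength_nm)$y
  if (!is.finite(anchor) || anchor <= 0) {
    stop("reflectance at the anchor wavelength must be positive")
  }
  drs_spectrum(spec$grid, spec$reflectance / anchor,
               meta = c(spec$meta, list(normalized_at_nm = wavelength_nm)))
}
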