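#' Tissue composition
#'
#' Bundles the chromophore concentrations and scattering parameters that the
#' forward model maps to a reflectance spectrum: hemoglobin concentrations in
#' g/l, fat and water volume fractions, and a power-law reduced-scattering
#' spectrum anchored at 800 nm.
#'
#' @param hb_conc deoxyhemoglobin concentration, g/l.
#' @param hbo2_conc oxyhemoglobin concentration, g/l.
#' @param fat_frac_vol fat volume fraction in \[0, 1\].
#' @param water_frac_vol water volume fraction in \[0, 1\];
#'   `fat_frac_vol + water_frac_vol` must not exceed 1.
#' @param scatter_amp_800 reduced scattering coefficient at 800 nm, cm^-1
#'   (must be positive).
#' @param scatter_slope dimensionless scattering power-law exponent b in
#'   `mu_s'(lambda) = scatter_amp_800 * (lambda/800)^(-b)`.
#' @return An object of class `tissue_composition`.
#' @export
tissue_composition <- function(hb_conc = 0, hbo2_conc = 0,
                               fat_frac_vol = 0, water_frac_vol = 0,
                               scatter_amp_800 = 16, scatter_slope = 1) {
  vals <- c(hb_conc, hbo2_conc, fat_frac_vol, water_frac_vol,
            scatter_amp_800, scatter_slope)
  if (any(!is.finite(vals))) stop("composition parameters must be finite")
  if (hb_conc < 0 || hbo2_conc < 0) stop("hemoglobin concentrations must be >= 0")
  if (fat_frac_vol < 0 || water_frac_vol < 0) {
    stop("volume fractions must be >= 0")
  }
  if (fat_frac_vol + water_frac_vol > 1 + 1e-9) {
    stop("fat_frac_vol + water_frac_vol must not exceed 1")
  }
  if (scatter_amp_800 <= 0) stop("scatter_amp_800 must be positive")
  structure(list(hb_conc = hb_conc, hbo2_conc = hbo2_conc,
                 fat_frac_vol = fat_frac_vol, water_frac_vol = water_frac_vol,
                 scatter_amp_800 = scatter_amp_800,
                 scatter_slope = scatter_slope),
            class = "tissue_composition")
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat(sprintf(paste0("<tissue_composition> Hb %.2f g/l, HbO2 %.2f g/l, ",
                     "fat %.3f, water %.3f, mu_s'(800) %.2f cm^-1, slope %.2f\n"),
              x$hb_conc, x$hbo2_conc, x$fat_frac_vol, x$water_frac_vol,
              x$scatter_amp_800, x$scatter_slope))
  cat(sprintf("  blood content %.1f%%, fat fraction %.1f%%\n",
              blood_content(x), fat_fraction(100 * x$fat_frac_vol,
                                             100 * x$water_frac_vol)))
  invisible(x)
}

#' Bulk absorption coefficient of a tissue composition
#'
#' Linear chromophore mixing: `mu_a(lambda)` is the sum over chromophores of
#' concentration times specific absorption.
#'
#' @param comp a [tissue_composition()].
#' @param grid a [wavelength_grid()] (or plain wavelength vector in nm).
#' @param chrom a [load_chromophores()] set.
#' @return Numeric vector of absorption coefficients (cm^-1), one per grid
#'   wavelength.
#' @export
absorption_coefficient <- function(comp, grid, chrom) {
  stopifnot(inherits(comp, "tissue_composition"))
  wl <- grid_wavelengths(grid)
  basis <- chromophore_basis(chrom, wl)
  conc <- c(hbo2 = comp$hbo2_conc, hb = comp$hb_conc,
            fat = comp$fat_frac_vol, water = comp$water_frac_vol)
  as.numeric(basis %*% conc[colnames(basis)])
}

#' Reduced scattering coefficient of a tissue composition
#'
#' Power law normalized at 800 nm:
#' `mu_s'(lambda) = scatter_amp_800 * (lambda / 800)^(-scatter_slope)`.
#'
#' @inheritParams absorption_coefficient
#' @return Numeric vector of reduced scattering coefficients (cm^-1).
#' @export
reduced_scattering <- function(comp, grid) {
  stopifnot(inherits(comp, "tissue_composition"))
  if (comp$scatter_amp_800 <= 0) stop("scatter_amp_800 must be positive")
  wl <- grid_wavelengths(grid)
  comp$scatter_amp_800 * (wl / 800)^(-comp$scatter_slope)
}

#' Blood content as a percentage of whole blood
#'
#' Total hemoglobin (Hb + HbO2) expressed as a percentage of the hemoglobin
#' concentration of normal human whole blood, 150 g/l. Can exceed 100% for
#' supra-physiological concentrations.
#'
#' @param comp a [tissue_composition()], or a total hemoglobin concentration
#'   in g/l.
#' @param whole_blood_gl reference whole-blood hemoglobin concentration, g/l.
#' @return Blood content in percent.
#' @export
blood_content <- function(comp, whole_blood_gl = 150) {
  thb <- if (inherits(comp, "tissue_composition")) {
    comp$hb_conc + comp$hbo2_conc
  } else {
    as.numeric(comp)
  }
  if (any(thb < 0)) stop("hemoglobin concentration must be >= 0")
  100 * thb / whole_blood_gl
}

#' Fat fraction of the fat/water pool
#'
#' `Fat / (Fat + Water) * 100`, the breach-detection statistic. Invariant
#' under a common rescaling of fat and water, so content may be supplied in
#' any common unit (volume fraction or percent).
#'
#' For the degenerate input `fat + water == 0` the function returns 0 with
#' attribute `degenerate = TRUE` rather than NaN, keeping pipelines total.
#'
#' @param fat,water nonnegative fat and water content in a common unit.
#' @return Fat fraction in percent (vectorized); attribute `degenerate` marks
#'   entries where `fat + water == 0`.
#' @export
fat_fraction <- function(fat, water) {
  if (any(fat < 0) || any(water < 0)) stop("fat and water must be >= 0")
  tot <- fat + water
  degen <- tot == 0
  out <- ifelse(degen, 0, 100 * fat / ifelse(degen, 1, tot))
  if (any(degen)) attr(out, "degenerate") <- degen
  out
}
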