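#' Wavelength grids for the two-spectrometer instrument
#'
#' The instrument resolves light with a visible spectrometer (450--1100 nm)
#' and a near-infrared spectrometer (900--1600 nm); the two overlap in
#' 900--1100 nm. A combined spectrum uses the visible grid below the stitch
#' point (1000 nm by default) and the NIR grid from the stitch point up,
#' spanning 450--1600 nm.
#'
#' @param wavelengths_nm strictly increasing numeric vector of sampling
#'   wavelengths in nm.
#' @param band one of `"visible"`, `"nir"`, `"combined"`.
#' @return An object of class `wavelength_grid`: a list with elements
#'   `wavelengths_nm` and `band`.
#' @export
wavelength_grid <- function(wavelengths_nm, band = c("combined", "visible", "nir")) {
  band <- match.arg(band)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) < 2L) {
    stop("a wavelength grid needs at least two points")
  }
  if (any(!is.finite(wavelengths_nm)) || any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be finite and strictly increasing")
  }
  structure(list(wavelengths_nm = wavelengths_nm, band = band),
            class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param step_nm grid spacing in nm (default 1).
#' @export
visible_grid <- function(step_nm = 1) {
  wavelength_grid(seq(450, 1100, by = step_nm), band = "visible")
}

#' @rdname wavelength_grid
#' @export
nir_grid <- function(step_nm = 1) {
  wavelength_grid(seq(900, 1600, by = step_nm), band = "nir")
}

#' @rdname wavelength_grid
#' @param stitch_nm wavelength (nm) below which the visible grid is used and
#'   from which on the NIR grid is used.
#' @export
combined_grid <- function(step_nm = 1, stitch_nm = 1000) {
  vis <- seq(450, 1100, by = step_nm)
  nir <- seq(900, 1600, by = step_nm)
  wl <- c(vis[vis < stitch_nm], nir[nir >= stitch_nm])
  wavelength_grid(wl, band = "combined")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %s band, %d points, %.0f-%.0f nm\n",
              x$band, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

grid_wavelengths <- function(grid) {
  if (inherits(grid, "wavelength_grid")) grid$wavelengths_nm else as.numeric(grid)
}

#' Calibrated reflectance spectrum
#'
#' A spectrum couples a wavelength grid with dimensionless calibrated
#' reflectance values and free-form provenance metadata (seed, condition,
#' acquisition time, ...).
#'
#' @param grid a [wavelength_grid()].
#' @param reflectance numeric vector, same length as the grid, nonnegative.
#' @param meta named list of provenance fields.
#' @return An object of class `drs_spectrum`.
#' @export
drs_spectrum <- function(grid, reflectance, meta = list()) {
  wl <- grid_wavelengths(grid)
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(wl)
  reflectance <- as.numeric(reflectance)
  if (length(reflectance) != length(wl)) {
    stop("reflectance must have one value per grid wavelength")
  }
  if (any(!is.finite(reflectance))) stop("reflectance contains non-finite values")
  if (any(reflectance < 0)) stop("reflectance must be nonnegative")
  structure(list(grid = grid, reflectance = reflectance, meta = meta),
            class = "drs_spectrum")
}

#' @export
print.drs_spectrum <- function(x, ...) {
  wl <- x$grid$wavelengths_nm
  cat(sprintf("<drs_spectrum> %d points, %.0f-%.0f nm, reflectance %.3g-%.3g\n",
              length(wl), min(wl), max(wl),
              min(x$reflectance), max(x$reflectance)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stitch a visible-band and an NIR-band spectrum into a combined spectrum
#'
#' Takes the visible spectrum below the stitch point and the NIR spectrum at
#' and above it, producing one spectrum on the combined grid.
#'
#' @param visible,nir `drs_spectrum` objects on the visible and NIR grids.
#' @param stitch_nm single switch wavelength (nm), default 1000.
#' @return A `drs_spectrum` on the combined grid.
#' @export
stitch_spectra <- function(visible, nir, stitch_nm = 1000) {
  stopifnot(inherits(visible, "drs_spectrum"), inherits(nir, "drs_spectrum"))
  wv <- visible$grid$wavelengths_nm
  wn <- nir$grid$wavelengths_nm
  keep_v <- wv < stitch_nm
  keep_n <- wn >= stitch_nm
  if (!any(keep_v) || !any(keep_n)) {
    stop("stitch point ", stitch_nm, " nm not inside the overlap of the two bands")
  }
  wl <- c(wv[keep_v], wn[keep_n])
  if (any(diff(wl) <= 0)) stop("stitched grid is not strictly increasing")
  drs_spectrum(wavelength_grid(wl, band = "combined"),
               c(visible$reflectance[keep_v], nir$reflectance[keep_n]),
               meta = c(visible$meta[setdiff(names(visible$meta), "band")],
                        list(stitch_nm = stitch_nm)))
}
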