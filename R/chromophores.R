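#' Load the packaged chromophore absorption library
#'
#' Reads the packaged specific-absorption tables for the four fitted
#' chromophores: oxyhemoglobin and deoxyhemoglobin (cm^-1 per g/l of
#' hemoglobin), and pure fat and water (cm^-1 per unit volume fraction).
#' The packaged tables are synthetic parametric reconstructions of the
#' canonical literature band shapes (see the provenance file next to the
#' tables); they are internally consistent between simulation and fitting.
#'
#' @param path directory containing the chromophore CSV tables; defaults to
#'   the tables shipped with the package.
#' @return An object of class `chromophore_set`: a named list of data frames
#'   (`hbo2`, `hb`, `fat`, `water`), each with columns `wavelength_nm` and
#'   `specific_absorption`, plus attributes `support_nm` and `provenance`.
#' @export
load_chromophores <- function(path = system.file("extdata", "chromophores",
                                                 package = "drsfit")) {
  names <- c("hbo2", "hb", "fat", "water")
  curves <- lapply(names, function(nm) {
    f <- file.path(path, paste0(nm, "_synthetic.csv"))
    if (!file.exists(f)) stop("chromophore table not found: ", f)
    df <- utils::read.csv(f)
    stopifnot(all(c("wavelength_nm", "specific_absorption") %in% names(df)))
    if (any(df$specific_absorption < 0)) stop("negative absorption in ", f)
    df
  })
  names(curves) <- names
  support <- range(curves[[1]]$wavelength_nm)
  prov_file <- file.path(path, "provenance.yaml")
  prov <- if (file.exists(prov_file)) paste(readLines(prov_file), collapse = "\n") else ""
  structure(curves, support_nm = support, provenance = prov,
            class = "chromophore_set")
}

#' @export
print.chromophore_set <- function(x, ...) {
  s <- attr(x, "support_nm")
  cat(sprintf("<chromophore_set> %s; support %.0f-%.0f nm\n",
              paste(names(x), collapse = ", "), s[1], s[2]))
  invisible(x)
}

# Interpolate the four chromophore curves onto a wavelength vector, returning
# an n x 4 basis matrix with columns (hbo2, hb, fat, water). Extrapolation
# beyond the tabulated support is refused.
chromophore_basis <- function(chrom, wavelengths_nm) {
  stopifnot(inherits(chrom, "chromophore_set"))
  support <- attr(chrom, "support_nm")
  if (min(wavelengths_nm) < support[1] || max(wavelengths_nm) > support[2]) {
    stop(sprintf(
      "requested wavelengths %.1f-%.1f nm outside chromophore support %.0f-%.0f nm",
      min(wavelengths_nm), max(wavelengths_nm), support[1], support[2]))
  }
  basis <- vapply(chrom, function(df) {
    stats::approx(df$wavelength_nm, df$specific_absorption,
                  xout = wavelengths_nm, method = "linear")$y
  }, numeric(length(wavelengths_nm)))
  dim(basis) <- c(length(wavelengths_nm), length(chrom))
  colnames(basis) <- names(chrom)
  basis
}

# Single-slot cache so repeated fits on the same grid reuse the basis.
.basis_cache <- new.env(parent = emptyenv())

chromophore_basis_cached <- function(chrom, wavelengths_nm) {
  key <- .basis_cache$key
  if (!is.null(key) && identical(key$wl, wavelengths_nm) &&
      identical(key$chrom_id, attr(chrom, "provenance"))) {
    return(.basis_cache$basis)
  }
  basis <- chromophore_basis(chrom, wavelengths_nm)
  .basis_cache$key <- list(wl = wavelengths_nm,
                           chrom_id = attr(chrom, "provenance"))
  .basis_cache$basis <- basis
  basis
}
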