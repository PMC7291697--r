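#' Read and write spectrum CSV files
#'
#' The on-disk dialect is a CSV with header `wavelength_nm,reflectance`
#' preceded by `# key: value` metadata comment lines (seed, band, condition,
#' acquisition time, ...). `write_spectrum` followed by `read_spectrum`
#' reproduces values to better than 1e-12 and preserves metadata (as
#' strings/numbers).
#'
#' @param spec a [drs_spectrum()].
#' @param path file path.
#' @param band band tag stored in the grid of the re-read spectrum.
#' @return `read_spectrum` returns a [drs_spectrum()]; `write_spectrum`
#'   returns `path` invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "drs_spectrum"))
  meta <- spec$meta
  meta$band <- spec$grid$band
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, format(meta[[k]], digits = 17, scientific = FALSE))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("wavelength_nm,reflectance", con)
  writeLines(sprintf("%.10g,%.17g", spec$grid$wavelengths_nm,
                     spec$reflectance), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, band = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1] != "wavelength_nm,reflectance") {
    stop("missing 'wavelength_nm,reflectance' header in ", path)
  }
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  dat <- utils::read.csv(text = body)
  wl <- dat$wavelength_nm
  if (any(diff(wl) <= 0)) {
    stop("wavelengths in ", path, " are not strictly increasing")
  }
  if (is.null(band)) {
    band <- if (!is.null(meta$band) &&
                meta$band %in% c("visible", "nir", "combined")) {
      meta$band
    } else "combined"
  }
  meta$band <- NULL
  drs_spectrum(wavelength_grid(wl, band = band), dat$reflectance, meta = meta)
}

#' Read a visible-band and an NIR-band file and stitch them
#'
#' @param visible_path,nir_path spectrum CSV files for the two spectrometers.
#' @param stitch_nm switch wavelength, see [stitch_spectra()].
#' @return A combined-grid [drs_spectrum()].
#' @export
read_and_stitch <- function(visible_path, nir_path, stitch_nm = 1000) {
  stitch_spectra(read_spectrum(visible_path, band = "visible"),
                 read_spectrum(nir_path, band = "nir"),
                 stitch_nm = stitch_nm)
}

#' Write a simulated insertion dataset to disk
#'
#' One directory per insertion holding per-measurement spectrum CSVs, plus a
#' `manifest.json` recording geometry, seeds and ground truths.
#'
#' @param dataset an `insertion_dataset` from [generate_insertion_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_insertion_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "insertion_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = dataset$seed, insertions = list())
  for (tr in dataset$insertions) {
    sub <- file.path(dir, sprintf("insertion_%02d", tr$insertion_id))
    dir.create(sub, showWarnings = FALSE)
    entries <- list()
    for (i in seq_along(tr$measurements)) {
      m <- tr$measurements[[i]]
      fname <- sprintf("measurement_%03d.csv", i)
      write_spectrum(m$spectrum, file.path(sub, fname))
      entries[[i]] <- list(
        file = fname, position = m$position, depth_mm = m$depth_mm,
        zone_true = m$zone_true, condition = m$condition, time_s = m$time_s,
        truth = unclass(m$truth))
    }
    manifest$insertions[[length(manifest$insertions) + 1L]] <- list(
      insertion_id = tr$insertion_id, seed = tr$seed,
      depths_mm = tr$depths_mm,
      cortical_thickness_mm = tr$cortical_thickness_mm,
      measurements = entries)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run configuration
#'
#' All constants of a pipeline run live here with their defaults (fiber
#' separation 1.042 mm, 3 mm zone widths, 800 nm scattering anchor, 1200 nm
#' normalization anchor, 150 g/l whole-blood reference, alpha = 0.01), so a
#' run is fully reproducible from its serialized configuration plus seed.
#' Configurations round-trip losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed master seed for all simulation randomness.
#' @param geometry list of per-insertion depth vectors.
#' @param n_per_condition measurements per condition per position.
#' @param fiber_separation_mm,grid_step_nm,stitch_nm instrument constants.
#' @param noise_rel_visible,noise_rel_nir,noise_additive noise levels.
#' @param alpha significance level of the statistical comparisons.
#' @param weighting fit residual weighting, see [fit_options()].
#' @param normalize_nm spectral normalization anchor, nm.
#' @param schema_version config format version tag.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       geometry = default_insertion_geometry(),
                       n_per_condition = 10,
                       fiber_separation_mm = 1.042,
                       grid_step_nm = 1,
                       stitch_nm = 1000,
                       noise_rel_visible = noise_model()$rel_visible,
                       noise_rel_nir = noise_model()$rel_nir,
                       noise_additive = 0,
                       alpha = 0.01,
                       weighting = "relative",
                       normalize_nm = 1200,
                       schema_version = 1) {
  structure(list(seed = as.integer(seed), geometry = geometry,
                 n_per_condition = n_per_condition,
                 fiber_separation_mm = fiber_separation_mm,
                 grid_step_nm = grid_step_nm, stitch_nm = stitch_nm,
                 noise_rel_visible = noise_rel_visible,
                 noise_rel_nir = noise_rel_nir,
                 noise_additive = noise_additive,
                 alpha = alpha, weighting = weighting,
                 normalize_nm = normalize_nm,
                 schema_version = schema_version),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), "schema_version")])
  cfg$schema_version <- raw$schema_version
  cfg
}
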