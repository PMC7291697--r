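#' Options for the spectral inverse fit
#'
#' @param weighting `"relative"` (default) fits fractional residuals
#'   `(model - data)/model`, matching the multiplicative instrument noise and
#'   the several-decade dynamic range between the visible blood bands and the
#'   NIR; `"absolute"` fits plain reflectance residuals.
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol convergence tolerances passed to the optimizer.
#' @param starts list of [tissue_composition()] starting points; the default
#'   multistart covers a lipid-rich, a blood-rich and a water-rich corner of
#'   the parameter space and the best final objective wins.
#' @param lower,upper named bounds on the raw parameter vector
#'   (hbo2, hb g/l; fat, water volume fractions; amp cm^-1; slope).
#' @return A list of class `drs_fit_options`.
#' @export
fit_options <- function(weighting = c("relative", "absolute"),
                        max_iter = 300, ftol = 1e-12, ptol = 1e-12,
                        starts = default_fit_starts(),
                        lower = c(hbo2 = 0, hb = 0, fat = 0, water = 0,
                                  amp = 0.1, slope = 0),
                        upper = c(hbo2 = 300, hb = 300, fat = 1, water = 1,
                                  amp = 100, slope = 5)) {
  structure(list(weighting = match.arg(weighting), max_iter = max_iter,
                 ftol = ftol, ptol = ptol, starts = starts,
                 lower = lower, upper = upper),
            class = "drs_fit_options")
}

#' @rdname fit_options
#' @export
default_fit_starts <- function() {
  list(
    lipid_rich = tissue_composition(hb_conc = 5, hbo2_conc = 10,
                                    fat_frac_vol = 0.5, water_frac_vol = 0.3,
                                    scatter_amp_800 = 16, scatter_slope = 1),
    blood_rich = tissue_composition(hb_conc = 30, hbo2_conc = 40,
                                    fat_frac_vol = 0.1, water_frac_vol = 0.6,
                                    scatter_amp_800 = 16, scatter_slope = 1),
    water_rich = tissue_composition(hb_conc = 5, hbo2_conc = 10,
                                    fat_frac_vol = 0.05, water_frac_vol = 0.8,
                                    scatter_amp_800 = 16, scatter_slope = 1)
  )
}

comp_to_par <- function(comp) {
  c(hbo2 = comp$hbo2_conc, hb = comp$hb_conc, fat = comp$fat_frac_vol,
    water = comp$water_frac_vol, amp = comp$scatter_amp_800,
    slope = comp$scatter_slope)
}

par_to_comp <- function(p) {
  tissue_composition(hb_conc = p[["hb"]], hbo2_conc = p[["hbo2"]],
                     fat_frac_vol = min(p[["fat"]], 1),
                     water_frac_vol = min(p[["water"]], 1),
                     scatter_amp_800 = p[["amp"]],
                     scatter_slope = p[["slope"]])
}

# Model evaluation and full-parameter Jacobian on a fixed grid.
# ctx carries precomputed quantities shared by all evaluations of one fit.
fit_context <- function(spec, inst, chrom) {
  wl <- spec$grid$wavelengths_nm
  list(wl = wl,
       y = spec$reflectance,
       basis = chromophore_basis_cached(chrom, wl),
       log_ratio = log(wl / 800),
       rho_cm = inst$fiber_separation_mm / 10,
       n_tissue = inst$n_tissue)
}

model_eval <- function(p, ctx) {
  mua <- as.numeric(ctx$basis %*% p[1:4])
  pow <- exp(-p[[6]] * ctx$log_ratio)
  musp <- p[[5]] * pow
  list(f = farrell_reflectance(mua, musp, ctx$rho_cm, ctx$n_tissue),
       mua = mua, musp = musp, pow = pow)
}

model_jacobian <- function(p, ctx, ev = NULL) {
  if (is.null(ev)) ev <- model_eval(p, ctx)
  g <- farrell_reflectance_grad(ev$mua, ev$musp, ctx$rho_cm, ctx$n_tissue)
  J <- cbind(g$dmua * ctx$basis[, 1], g$dmua * ctx$basis[, 2],
             g$dmua * ctx$basis[, 3], g$dmua * ctx$basis[, 4],
             g$dmusp * ev$pow,
             g$dmusp * (-p[[5]] * ctx$log_ratio * ev$pow))
  colnames(J) <- c("hbo2", "hb", "fat", "water", "amp", "slope")
  J
}

residual_fn <- function(p, ctx, weighting) {
  f <- model_eval(p, ctx)$f
  if (weighting == "relative") 1 - ctx$y / f else f - ctx$y
}

residual_jac <- function(p, ctx, weighting) {
  ev <- model_eval(p, ctx)
  J <- model_jacobian(p, ctx, ev)
  if (weighting == "relative") J * (ctx$y / ev$f^2) else J
}

#' Fit a measured spectrum to the tissue model
#'
#' Bounded Levenberg-Marquardt least squares recovering hemoglobin
#' concentrations, fat and water volume fractions and the power-law
#' scattering parameters from a calibrated reflectance spectrum. All
#' parameters are bounded below by zero; if the box-constrained optimum
#' violates `fat + water <= 1` the fit is repeated in a reparameterized
#' (total, share) space that enforces the simplex constraint exactly.
#' Parameter covariance follows the residual-variance form
#' `sigma^2 (J'J)^-1` at the optimum with `sigma^2 = RSS/(n - p)`, and
#' derived physiological parameters (blood content, fat fraction, contents)
#' get first-order delta-method 95% confidence half-widths.
#'
#' @param spec a [drs_spectrum()] covering both the visible blood bands
#'   (450--600 nm) and the NIR fat/water bands (1000--1600 nm).
#' @param inst an [instrument_config()].
#' @param chrom a [load_chromophores()] set.
#' @param options a [fit_options()] list.
#' @return An object of class `drs_fit`; see Details. Key fields:
#'   `composition` (fitted [tissue_composition()]), `blood_content_pct`,
#'   `fat_fraction_pct`, `fat_content_pct`, `water_content_pct`,
#'   `scatter_amp_800`, `covariance`, `ci95` (named 95% half-widths),
#'   `residual_norm`, `fitted_spectrum`, `converged`, `n_iter`.
#' @export
fit_spectrum <- function(spec, inst, chrom, options = fit_options()) {
  stopifnot(inherits(spec, "drs_spectrum"), inherits(inst, "instrument_config"))
  if (any(!is.finite(spec$reflectance))) stop("spectrum contains NaN/Inf values")
  wl <- spec$grid$wavelengths_nm
  if (min(wl) > 600 || max(wl) < 1000) {
    stop("spectrum must cover the 450-600 nm blood bands and the ",
         "NIR fat/water bands to constrain the fit")
  }
  ctx <- fit_context(spec, inst, chrom)
  w <- options$weighting
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$max_iter,
                                     ftol = options$ftol, ptol = options$ptol)

  runs <- lapply(options$starts, function(start) {
    p0 <- pmin(pmax(comp_to_par(start), options$lower), options$upper)
    tryCatch(
      minpack.lm::nls.lm(par = p0, lower = options$lower,
                         upper = options$upper,
                         fn = residual_fn, jac = residual_jac,
                         ctx = ctx, weighting = w, control = ctrl),
      error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("all optimizer starts failed")
  best <- runs[[which.min(vapply(runs, stats::deviance, numeric(1)))]]
  p_hat <- stats::coef(best)
  info <- best$info
  n_iter <- best$niter

  constrained_sum <- FALSE
  if (p_hat[["fat"]] + p_hat[["water"]] > 1 + 1e-9) {
    best <- refit_simplex(p_hat, ctx, w, options, ctrl)
    p_hat <- stats::coef(best)
    info <- best$info
    n_iter <- n_iter + best$niter
    constrained_sum <- TRUE
  }

  converged <- info %in% 1:4
  r <- residual_fn(p_hat, ctx, w)
  J <- residual_jac(p_hat, ctx, w)
  ci <- fit_covariance(p_hat, r, J)

  comp_hat <- par_to_comp(p_hat)
  fitted <- drs_spectrum(spec$grid, model_eval(p_hat, ctx)$f,
                         meta = list(fitted = TRUE))
  structure(list(
    composition = comp_hat,
    parameters = p_hat,
    blood_content_pct = blood_content(comp_hat),
    fat_fraction_pct = as.numeric(fat_fraction(p_hat[["fat"]], p_hat[["water"]])),
    fat_content_pct = 100 * p_hat[["fat"]],
    water_content_pct = 100 * p_hat[["water"]],
    scatter_amp_800 = p_hat[["amp"]],
    scatter_slope = p_hat[["slope"]],
    covariance = ci$covariance,
    ci95 = ci$ci95,
    identifiable = ci$identifiable,
    sigma2 = ci$sigma2,
    residual_norm = sqrt(sum(r^2)),
    deviance = sum(r^2),
    n_obs = length(r),
    fitted_spectrum = fitted,
    converged = converged,
    constrained_sum = constrained_sum,
    n_iter = n_iter,
    weighting = w
  ), class = "drs_fit")
}

# Refit under fat + water <= 1 via (total, share) reparameterization.
refit_simplex <- function(p_hat, ctx, weighting, options, ctrl) {
  tot0 <- min(p_hat[["fat"]] + p_hat[["water"]], 1)
  share0 <- if (tot0 > 0) p_hat[["fat"]] / (p_hat[["fat"]] + p_hat[["water"]]) else 0.5
  q0 <- c(hbo2 = p_hat[["hbo2"]], hb = p_hat[["hb"]], total = tot0,
          share = share0, amp = p_hat[["amp"]], slope = p_hat[["slope"]])
  q_to_p <- function(q) c(hbo2 = q[["hbo2"]], hb = q[["hb"]],
                          fat = q[["total"]] * q[["share"]],
                          water = q[["total"]] * (1 - q[["share"]]),
                          amp = q[["amp"]], slope = q[["slope"]])
  fn <- function(q, ...) residual_fn(q_to_p(q), ctx, weighting)
  jac <- function(q, ...) {
    Jp <- residual_jac(q_to_p(q), ctx, weighting)
    cbind(Jp[, "hbo2"], Jp[, "hb"],
          Jp[, "fat"] * q[["share"]] + Jp[, "water"] * (1 - q[["share"]]),
          q[["total"]] * (Jp[, "fat"] - Jp[, "water"]),
          Jp[, "amp"], Jp[, "slope"])
  }
  lo <- c(options$lower[["hbo2"]], options$lower[["hb"]], 0, 0,
          options$lower[["amp"]], options$lower[["slope"]])
  hi <- c(options$upper[["hbo2"]], options$upper[["hb"]], 1, 1,
          options$upper[["amp"]], options$upper[["slope"]])
  out <- minpack.lm::nls.lm(par = q0, lower = lo, upper = hi,
                            fn = fn, jac = jac, control = ctrl)
  q_hat <- stats::coef(out)
  names(q_hat) <- names(q0)
  out$par <- q_to_p(q_hat)
  out
}

# Residual-variance covariance and delta-method 95% half-widths.
fit_covariance <- function(p_hat, r, J, z95 = 1.959964) {
  n <- length(r)
  k <- length(p_hat)
  dof <- max(n - k, 1)
  sigma2 <- sum(r^2) / dof
  JtJ <- crossprod(J)
  ev <- eigen(JtJ, symmetric = TRUE, only.values = TRUE)$values
  identifiable <- min(ev) > 1e-12 * max(ev)
  covm <- sigma2 * if (identifiable) {
    chol2inv(chol(JtJ))
  } else {
    MASS::ginv(JtJ)
  }
  dimnames(covm) <- list(names(p_hat), names(p_hat))

  grads <- list(
    hbo2_conc = c(1, 0, 0, 0, 0, 0),
    hb_conc = c(0, 1, 0, 0, 0, 0),
    fat_frac_vol = c(0, 0, 1, 0, 0, 0),
    water_frac_vol = c(0, 0, 0, 1, 0, 0),
    scatter_amp_800 = c(0, 0, 0, 0, 1, 0),
    scatter_slope = c(0, 0, 0, 0, 0, 1),
    blood_content_pct = c(100 / 150, 100 / 150, 0, 0, 0, 0),
    fat_content_pct = c(0, 0, 100, 0, 0, 0),
    water_content_pct = c(0, 0, 0, 100, 0, 0)
  )
  tot <- p_hat[["fat"]] + p_hat[["water"]]
  grads$fat_fraction_pct <- if (tot > 0) {
    c(0, 0, 100 * p_hat[["water"]] / tot^2, -100 * p_hat[["fat"]] / tot^2, 0, 0)
  } else {
    c(0, 0, NA_real_, NA_real_, 0, 0)
  }
  ci95 <- vapply(grads, function(g) {
    if (any(is.na(g))) return(Inf)
    v <- drop(t(g) %*% covm %*% g)
    z95 * sqrt(max(v, 0))
  }, numeric(1))
  list(covariance = covm, ci95 = ci95, identifiable = identifiable,
       sigma2 = sigma2)
}

#' Confidence-interval table of a fit
#'
#' Returns the per-parameter and derived-parameter 95% confidence half-widths
#' computed from the residual variance and the model Jacobian at the optimum
#' (delta method for derived quantities). Non-converged fits are refused.
#'
#' @param fit a [fit_spectrum()] result.
#' @return A data frame with columns `parameter`, `estimate`, `ci95`.
#' @export
confidence_intervals <- function(fit) {
  stopifnot(inherits(fit, "drs_fit"))
  if (!fit$converged) stop("confidence intervals require a converged fit")
  est <- c(fit$parameters[["hbo2"]], fit$parameters[["hb"]],
           fit$parameters[["fat"]], fit$parameters[["water"]],
           fit$scatter_amp_800, fit$scatter_slope,
           fit$blood_content_pct, fit$fat_content_pct,
           fit$water_content_pct, fit$fat_fraction_pct)
  data.frame(parameter = names(fit$ci95), estimate = est,
             ci95 = unname(fit$ci95), row.names = NULL)
}

#' @export
print.drs_fit <- function(x, ...) {
  cat(sprintf("<drs_fit> %s (%d iterations, %s residuals)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$weighting))
  cat(sprintf("  blood content %.1f%% (ci95 %.2f), fat fraction %.1f%% (ci95 %.2f)\n",
              x$blood_content_pct, x$ci95[["blood_content_pct"]],
              x$fat_fraction_pct, x$ci95[["fat_fraction_pct"]]))
  cat(sprintf("  fat %.1f%%, water %.1f%%, mu_s'(800) %.2f cm^-1, slope %.2f\n",
              x$fat_content_pct, x$water_content_pct, x$scatter_amp_800,
              x$scatter_slope))
  cat(sprintf("  residual norm %.3g on %d points\n", x$residual_norm, x$n_obs))
  invisible(x)
}

#' Fit every measurement of a generated dataset
#'
#' Convenience wrapper mapping [fit_spectrum()] over a list of probe
#' measurements (as produced by the synthetic-experiment generators) and
#' returning a tidy per-measurement table of fitted physiological parameters
#' alongside the measurement metadata and, when available, the generating
#' truth.
#'
#' @param measurements list of `probe_measurement` objects, or an object with
#'   a `measurements` field (insertion trajectory, sacrifice series, dataset).
#' @param inst,chrom,options as in [fit_spectrum()].
#' @return A data frame with one row per measurement.
#' @export
fit_dataset <- function(measurements, inst, chrom, options = fit_options()) {
  meas <- as_measurement_list(measurements)
  rows <- lapply(meas, function(m) {
    fit <- fit_spectrum(m$spectrum, inst, chrom, options)
    cbind(measurement_meta_row(m),
          data.frame(
            blood_pct = fit$blood_content_pct,
            fat_fraction_pct = fit$fat_fraction_pct,
            fat_pct = fit$fat_content_pct,
            water_pct = fit$water_content_pct,
            scatter_amp_800 = fit$scatter_amp_800,
            scatter_slope = fit$scatter_slope,
            ci95_fat_fraction = fit$ci95[["fat_fraction_pct"]],
            ci95_blood = fit$ci95[["blood_content_pct"]],
            converged = fit$converged,
            residual_norm = fit$residual_norm))
  })
  do.call(rbind, rows)
}
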