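# Shared fixtures, built in code at test time.

test_chrom <- load_chromophores()
test_inst <- instrument_config()
# coarser grid for tests whose conclusions do not depend on spectral density
coarse_inst <- instrument_config(grid_step_nm = 3)

# Independent transliteration of the extrapolated-boundary diffusion dipole,
# written directly from the published formula (scalar arrangement via the
# diffusion constant D), used as the formula oracle for the forward model.
farrell_oracle <- function(mua, musp, rho, n = 1.4) {
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  A <- (1 + rd) / (1 - rd)
  rho <- rep(rho, length.out = length(mua))
  vapply(seq_along(mua), function(i) {
    mut <- mua[i] + musp[i]
    D <- 1 / (3 * mut)
    mueff <- sqrt(mua[i] / D)
    z0 <- 1 / mut
    zb <- 2 * A * D
    r1 <- sqrt(z0^2 + rho[i]^2)
    r2 <- sqrt((z0 + 2 * zb)^2 + rho[i]^2)
    (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
       (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2) / (4 * pi)
  }, numeric(1))
}

# Random but physiologically plausible composition spanning the per-zone
# parameter ranges of the generator.
random_composition <- function(seed) {
  set.seed(seed)
  zone <- sample(c("cancellous", "pcz", "cortical", "breach"), 1)
  cond <- sample(c("low_pressure", "high_pressure", "retracted"), 1)
  sample_zone_composition(zone, cond, zone_model())
}

true_fat_fraction <- function(comp) {
  as.numeric(fat_fraction(comp$fat_frac_vol, comp$water_frac_vol))
}

# |est - truth| <= tol_rel * |truth|, falling back to an absolute check for
# truths at (or numerically near) zero.
expect_close_rel <- function(est, truth, tol_rel, tol_abs = 1e-6) {
  err <- abs(est - truth)
  lim <- ifelse(abs(truth) > 1e-3, tol_rel * abs(truth), tol_abs)
  expect_true(all(err <= lim),
              label = sprintf("max rel err %.3g within %.1g", max(err / pmax(abs(truth), 1e-12)), tol_rel))
}
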