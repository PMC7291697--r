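new_test_result <- function(method, statistic, p_value, n, alpha) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n = n, alpha = alpha, significant = p_value < alpha),
            class = "drs_test")
}

#' @export
print.drs_test <- function(x, ...) {
  cat(sprintf("<drs_test> %s: statistic %.4g, p = %.4g (n = %s), %s at alpha = %g\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Jarque-Bera normality test
#'
#' Classical moment-based Jarque-Bera statistic
#' `JB = n/6 * (S^2 + K^2/4)` with S the sample skewness and K the excess
#' kurtosis, both computed with biased (moment) estimators; the p-value
#' comes from the chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric sample, n >= 8, non-constant.
#' @param alpha significance level (default 0.01).
#' @return A `drs_test` result.
#' @export
jarque_bera <- function(x, alpha = 0.01) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("Jarque-Bera needs at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant sample: sample moments are undefined")
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2 - 3
  jb <- n / 6 * (s^2 + k^2 / 4)
  p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  new_test_result("Jarque-Bera", jb, p, n, alpha)
}

# Rank-sum of x with midranks for ties.
rank_sum_statistic <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_along(x)])
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midranks for ties. For small samples
#' (`length(x) + length(y) <= exact_max`, default 12) the null distribution
#' of the rank-sum is enumerated exactly over all assignments of the pooled
#' (mid)ranks to the first group, which remains valid under ties. Larger
#' samples use the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param x,y numeric samples, each with at least 3 observations.
#' @param alpha significance level (default 0.01).
#' @param exact_max largest pooled size for which the exact enumeration path
#'   is used.
#' @return A `drs_test` result; the statistic is the rank sum of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, alpha = 0.01, exact_max = 12) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 3 || ny < 3) stop("both groups need at least 3 observations")
  W <- rank_sum_statistic(x, y)
  n <- nx + ny
  if (n <= exact_max) {
    r <- rank(c(x, y), ties.method = "average")
    idx <- utils::combn(n, nx)
    sums <- colSums(matrix(r[idx], nrow = nx))
    mu <- nx * (n + 1) / 2
    eps <- 1e-9
    p <- mean(abs(sums - mu) >= abs(W - mu) - eps)
  } else {
    mu <- nx * (n + 1) / 2
    r <- rank(c(x, y), ties.method = "average")
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  new_test_result("Wilcoxon rank-sum", W, p, c(nx, ny), alpha)
}

#' Coefficient of determination of a simple linear regression
#'
#' R-squared of the ordinary least-squares line of `y` on `x`, equal to the
#' squared Pearson correlation.
#'
#' @param x,y numeric vectors of equal length, n >= 3; `x` must vary.
#' @return R-squared in \[0, 1\].
#' @export
linear_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("x has zero variance")
  if (stats::var(y) == 0) return(1)
  stats::cor(x, y)^2
}

#' Range of confidence-interval half-widths across fits
#'
#' Minimum and maximum of the per-measurement 95% confidence half-widths for
#' a named parameter, the summary used to report DRS signal quality.
#'
#' @param fits a data frame from [fit_dataset()] (uses the `ci95_*` column),
#'   or a list of [fit_spectrum()] results.
#' @param parameter `"fat_fraction_pct"` or `"blood_content_pct"` (for fit
#'   lists, any name in `ci95`).
#' @return Named numeric `c(min, max)` in the parameter's units.
#' @export
ci_range_summary <- function(fits, parameter = "fat_fraction_pct") {
  if (is.data.frame(fits)) {
    col <- switch(parameter,
                  fat_fraction_pct = "ci95_fat_fraction",
                  blood_content_pct = "ci95_blood",
                  stop("unknown parameter column for ", parameter))
    if (!col %in% names(fits)) stop("column ", col, " not found")
    if ("converged" %in% names(fits) && !all(fits$converged)) {
      stop("ci_range_summary requires all fits to have converged")
    }
    h <- fits[[col]]
  } else {
    fits <- if (inherits(fits, "drs_fit")) list(fits) else fits
    if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
      stop("ci_range_summary requires all fits to have converged")
    }
    h <- vapply(fits, function(f) f$ci95[[parameter]], numeric(1))
  }
  c(min = min(h), max = max(h))
}
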