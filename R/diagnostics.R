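#' MCMC convergence diagnostics
#'
#' Geweke's z compares the means of the first `frac1` and last `frac2` of
#' a chain, with variances estimated from the spectral density at
#' frequency zero (autoregressive estimator), so autocorrelation is
#' accounted for.  The Heidelberger-Welch procedure tests stationarity
#' with a Cramer-von Mises statistic on the Brownian-bridge transform of
#' the cumulative sums, iteratively discarding initial 10% chunks (up to
#' half the chain) until the test passes.
#'
#' @param x numeric vector: one parameter's chain.
#' @param frac1,frac2 fractions of the chain used for the early and late
#'   windows of Geweke's test.
#' @return `geweke_z`: the z statistic (0 for a constant chain).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  stopifnot(n >= 20, frac1 + frac2 <= 1)
  x1 <- x[seq_len(max(1, floor(frac1 * n)))]
  x2 <- x[seq(floor((1 - frac2) * n) + 1, n)]
  if (var(x) == 0) return(0)
  v1 <- spectrum0(x1) / length(x1)
  v2 <- spectrum0(x2) / length(x2)
  if (v1 + v2 == 0) return(0)
  (mean(x1) - mean(x2)) / sqrt(v1 + v2)
}

#' @rdname geweke_z
#' @param alpha significance level of the stationarity test.
#' @return `heidel_welch`: list with `passed`, `start` (fraction of the
#'   chain discarded before stationarity was accepted; `NA` if failed)
#'   and `pvalue` of the accepted window.  A constant chain passes.
#' @export
heidel_welch <- function(x, alpha = 0.05) {
  n <- length(x)
  stopifnot(n >= 100)
  if (var(x) == 0) return(list(passed = TRUE, start = 0, pvalue = 1))
  p <- 0
  for (frac in seq(0, 0.5, by = 0.1)) {
    seg <- x[seq(floor(frac * n) + 1, n)]
    m <- length(seg)
    sp <- spectrum0_ar(seg[seq(floor(m / 2), m)])
    # a near-unit-root AR fit is itself evidence of nonstationarity
    if (sp$near_unit_root || sp$spec <= 0) next
    ybar <- mean(seg)
    B <- cumsum(seg) - ybar * seq_len(m)
    I <- sum((B^2) / (m * sp$spec)) / m
    p <- 1 - pcramer(I)
    if (p > alpha) return(list(passed = TRUE, start = frac, pvalue = p))
  }
  list(passed = FALSE, start = NA_real_, pvalue = p)
}

#' @rdname geweke_z
#' @param fit a `threshold_fit` (or samples matrix with named columns).
#' @param parameters which columns to diagnose; default the variance
#'   components actually fitted.
#' @return `diagnostics`: data.frame with one row per parameter: Geweke z,
#'   Heidelberger-Welch pass flag, discarded fraction and p-value.
#' @export
diagnostics <- function(fit, parameters = NULL) {
  samples <- if (inherits(fit, "threshold_fit")) fit$samples else fit
  if (is.null(parameters)) {
    keep <- apply(samples, 2, function(v) var(v) > 0 || all(v != 0))
    parameters <- colnames(samples)[keep]
  }
  if (nrow(samples) < 100) stop("need at least 100 retained samples")
  out <- lapply(parameters, function(pn) {
    hw <- heidel_welch(samples[, pn])
    data.frame(parameter = pn, geweke_z = geweke_z(samples[, pn]),
               hw_passed = hw$passed, hw_start = hw$start,
               hw_pvalue = hw$pvalue)
  })
  do.call(rbind, out)
}

# Spectral density of a series at frequency zero via an AR fit:
# var_pred / (1 - sum(ar coefficients))^2.  Falls back to the plain
# variance when the AR fit degenerates.
spectrum0 <- function(x) {
  spectrum0_ar(x)$spec
}

spectrum0_ar <- function(x, unit_root_tol = 0.97) {
  if (length(unique(x)) < 3 || var(x) == 0) {
    return(list(spec = 0, near_unit_root = FALSE))
  }
  fit <- tryCatch(ar(x, aic = TRUE,
                     order.max = min(length(x) - 1, 10 * log10(length(x)))),
                  error = function(e) NULL)
  if (is.null(fit)) return(list(spec = var(x), near_unit_root = FALSE))
  if (length(fit$ar) == 0) {
    return(list(spec = fit$var.pred, near_unit_root = FALSE))
  }
  s <- sum(fit$ar)
  list(spec = fit$var.pred / (1 - s)^2, near_unit_root = s >= unit_root_tol)
}

# Asymptotic CDF of the Cramer-von Mises statistic (series expansion with
# modified Bessel functions of the second kind).
pcramer <- function(q, eps = 1e-5) {
  if (q <= 0) return(0)
  y <- vapply(0:3, function(k) {
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    u <- (4 * k + 1)^2 / (16 * q)
    if (u > -log(eps)) 0 else z * exp(-u) * besselK(u, nu = 0.25)
  }, numeric(1))
  min(1, max(0, sum(y)))
}
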