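#' Back-solve marker effects from genomic breeding values
#'
#' Given GEBVs for the genotyped animals and the genomic relationship
#' matrix built from the same weights and allele frequencies, the marker
#' effects are
#'
#'   `u_hat = k D R' G^-1 gebv`,  `k = 1 / (2 sum p (1 - p))`
#'
#' with `R` the centered gene content, so the marker effects decompose
#' each animal's genomic value exactly (`R u_hat = gebv`).
#'
#' Centering R on the observed allele frequencies makes the all-ones
#' vector an exact null vector of G, so G is singular by construction;
#' since GEBVs centered the same way lie in G's range, the system is
#' solved with a Moore-Penrose pseudo-inverse by default.  A GEBV vector
#' genuinely outside the range of G (inconsistent weights or frequencies)
#' triggers a warning.
#'
#' @param gebv numeric vector of GEBVs, named by (or aligned with) the
#'   rows of `geno`.
#' @param geno QC'd 0/1/2 genotype matrix of the same animals.
#' @param weights per-marker weights D (default all 1 — the unweighted
#'   analysis).
#' @param freq allele frequencies used when G was built; default observed.
#' @param on_singular `"pseudo"` (default: Moore-Penrose solve when G has
#'   no ordinary inverse) or `"error"`.
#' @return list of class `snp_effects`: `effects` (named per marker),
#'   `weights`, `freq`, `iteration`.
#' @export
backsolve_snp_effects <- function(gebv, geno, weights = NULL, freq = NULL,
                                  on_singular = c("pseudo", "error")) {
  on_singular <- match.arg(on_singular)
  stopifnot(length(gebv) == nrow(geno))
  gm <- g_matrix(geno, weights = weights, freq = freq)
  sol <- tryCatch(solve(gm$G, gebv), error = function(e) e)
  if (inherits(sol, "error")) {
    if (on_singular == "error") {
      stop("G is singular; rerun with on_singular = \"pseudo\" or blend G")
    }
    sol <- as.numeric(MASS::ginv(gm$G) %*% gebv)
    # the mean of the GEBVs is G's structural null direction and is
    # legitimately projected out; flag only residuals beyond it
    resid <- max(abs(gm$G %*% sol - (gebv - mean(gebv))))
    if (resid > 1e-6 * max(1, max(abs(gebv)))) {
      warning("GEBVs are not in the range of G (residual ", signif(resid, 3),
              "); marker effects are a least-squares projection")
    }
  }
  R <- sweep(geno, 2, 2 * gm$freq)
  eff <- gm$weights * as.numeric(crossprod(R, sol)) / gm$denom
  structure(list(effects = setNames(eff, colnames(geno)),
                 weights = gm$weights, freq = gm$freq, iteration = 1L),
            class = "snp_effects")
}

#' Nonlinear marker weights from estimated effects
#'
#' Departure-from-normality weighting: each marker effect is standardized
#' by its gene-content standard deviation,
#' `u_std = effect * sqrt(2 p (1 - p))`, and the weight is
#'
#'   `d = base ^ (min(|u_std| / sd(u_std), cap) - 2)`
#'
#' so a marker at 2 SD keeps weight 1, small effects are shrunk toward
#' `base^-2` and large effects are amplified up to `base^(cap - 2)`.
#'
#' @param effects marker effects (an `snp_effects` object or numeric
#'   vector).
#' @param freq allele frequencies (taken from the `snp_effects` object if
#'   available).
#' @param base base of the nonlinear weighting (default 1.125).
#' @param cap cap on the standardized effect, in SD units (default 5).
#' @return numeric vector of positive weights.
#' @export
nonlinear_weights <- function(effects, freq = NULL, base = 1.125, cap = 5) {
  if (inherits(effects, "snp_effects")) {
    freq <- freq %||% effects$freq
    effects <- effects$effects
  }
  stopifnot(!is.null(freq), length(freq) == length(effects))
  u_std <- effects * sqrt(2 * freq * (1 - freq))
  s <- sd(u_std)
  if (!is.finite(s) || s == 0) return(rep(1, length(effects)))
  base^(pmin(abs(u_std) / s, cap) - 2)
}

#' Iterative weighted single-step marker solutions
#'
#' Iteration 1 back-solves with identity weights (the unweighted
#' analysis); each later iteration derives nonlinear weights from the
#' previous marker solutions, rebuilds G with them (allele frequencies
#' held fixed) and re-back-solves.  By default the GEBVs are kept fixed
#' between iterations (re-back-solve only); supply `refit_fn` to
#' re-estimate GEBVs from each weighted G instead.
#'
#' @param gebv GEBVs of the genotyped animals.
#' @param geno QC'd genotype matrix.
#' @param n_iter number of iterations (weights for reporting are
#'   conventionally taken from iteration 3).
#' @param freq allele frequencies fixed across iterations (default
#'   observed).
#' @param refit_fn optional `function(G)` returning updated GEBVs, called
#'   with the weighted genomic relationship matrix of each iteration
#'   after the first.
#' @param ... passed to [nonlinear_weights()].
#' @return the final iteration's `snp_effects` (with `iteration` set),
#'   with the full `history` of per-iteration effects attached.
#' @export
wssgwas_iterate <- function(gebv, geno, n_iter = 3, freq = NULL,
                            refit_fn = NULL, ...) {
  stopifnot(n_iter >= 1)
  if (is.null(freq)) freq <- colMeans(geno) / 2
  history <- vector("list", n_iter)
  weights <- rep(1, ncol(geno))
  g_current <- gebv
  for (it in seq_len(n_iter)) {
    if (it > 1) {
      weights <- nonlinear_weights(history[[it - 1]], freq = freq, ...)
      if (!is.null(refit_fn)) {
        g_current <- refit_fn(g_matrix(geno, weights = weights,
                                       freq = freq)$G)
      }
    }
    se <- backsolve_snp_effects(g_current, geno, weights = weights,
                                freq = freq)
    se$iteration <- it
    history[[it]] <- se
  }
  out <- history[[n_iter]]
  out$history <- lapply(history, `[[`, "effects")
  out
}

#' Sliding-window share of the additive genetic variance
#'
#' For each sliding window of `window` adjacent markers (step 1, never
#' spanning chromosomes) the percentage of the total additive genetic
#' variance it explains is
#'
#'   `100 * var(R_w u_w) / var(R u)`
#'
#' — the variance over animals of the window's contribution to the
#' genomic breeding values, relative to the variance of the full genomic
#' values.  Realized gene content is used, so within-window linkage
#' disequilibrium is captured.  Windows above `threshold` percent are
#' flagged, and overlapping flagged windows are merged into independent
#' regions, each reported with its peak window.
#'
#' @param effects marker effects (`snp_effects` or named numeric vector
#'   aligned with `geno` columns).
#' @param geno QC'd genotype matrix.
#' @param map marker map (`snp_id`, `chrom`, `pos_bp`); sorted internally
#'   by chromosome and position, so marker input order does not matter.
#' @param freq allele frequencies for centering (taken from the
#'   `snp_effects` object if available).
#' @param window window size in markers.
#' @param threshold selection threshold, percent of the additive genetic
#'   variance (strictly greater than).
#' @return list with `windows` (one row per window: chrom, start/end bp
#'   and marker indices, n_snps, pct_variance, selected), `regions`
#'   (merged runs of selected windows with their peak), and `var_genomic`
#'   (the denominator).  Chromosomes with fewer markers than `window` are
#'   skipped with a warning.
#' @export
window_variance <- function(effects, geno, map, freq = NULL,
                            window = 5, threshold = 0.20) {
  if (inherits(effects, "snp_effects")) {
    freq <- freq %||% effects$freq
    effects <- effects$effects
  }
  stopifnot(ncol(geno) == nrow(map), length(effects) == nrow(map))
  if (is.null(freq)) freq <- colMeans(geno) / 2

  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  effects <- effects[ord]
  freq <- freq[ord]

  R <- sweep(geno, 2, 2 * freq)
  gv <- as.numeric(R %*% effects)
  var_g <- var(gv)
  if (var_g == 0) stop("total genomic variance is zero")

  rows <- list()
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    if (length(ix) < window) {
      warning("chromosome ", ch, " has fewer than ", window,
              " markers; skipped")
      next
    }
    starts <- seq_len(length(ix) - window + 1)
    pct <- vapply(starts, function(s) {
      cols <- ix[s:(s + window - 1)]
      wv <- as.numeric(R[, cols, drop = FALSE] %*% effects[cols])
      100 * var(wv) / var_g
    }, numeric(1))
    rows[[ch]] <- data.frame(
      chrom = ch,
      start_idx = ix[starts], end_idx = ix[starts + window - 1],
      start_bp = map$pos_bp[ix[starts]],
      end_bp = map$pos_bp[ix[starts + window - 1]],
      n_snps = window, pct_variance = pct,
      selected = pct > threshold)
  }
  if (length(rows) == 0) stop("no chromosome has at least ", window, " markers")
  windows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  regions <- merge_selected_windows(windows, window)
  list(windows = windows, regions = regions, var_genomic = var_g)
}

# Maximal runs of overlapping selected windows; each run reports its span
# and the peak window's share.
merge_selected_windows <- function(windows, window) {
  sel <- windows[windows$selected, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), peak_pct = numeric(0),
                      peak_start_bp = numeric(0), n_windows = integer(0)))
  }
  out <- list()
  for (ch in unique(sel$chrom)) {
    s <- sel[sel$chrom == ch, , drop = FALSE]
    s <- s[order(s$start_idx), , drop = FALSE]
    run_id <- cumsum(c(1, diff(s$start_idx) >= window))
    for (r in split(s, run_id)) {
      peak <- r[which.max(r$pct_variance), ]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = min(r$start_bp), end_bp = max(r$end_bp),
        peak_pct = peak$pct_variance, peak_start_bp = peak$start_bp,
        n_windows = nrow(r))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
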