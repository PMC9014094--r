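#' Pair two EBV tables and filter on accuracy
#'
#' Keeps animals present in both tables whose EBV accuracy (the square
#' root of the reliability) reaches `min_acc` for **both** traits; the
#' boundary is inclusive.
#'
#' @param ebv1,ebv2 EBV tables with columns `animal`, `ebv`, `rel`.
#' @param min_acc minimum accuracy, on the accuracy (not reliability)
#'   scale.
#' @return data.frame with `animal`, `ebv1`, `rel1`, `ebv2`, `rel2`.
#' @export
filter_by_accuracy <- function(ebv1, ebv2, min_acc = 0.25) {
  need <- c("animal", "ebv", "rel")
  stopifnot(all(need %in% names(ebv1)), all(need %in% names(ebv2)))
  paired <- merge(ebv1[need], ebv2[need], by = "animal",
                  suffixes = c("1", "2"))
  keep <- sqrt(paired$rel1) >= min_acc & sqrt(paired$rel2) >= min_acc
  paired[keep, , drop = FALSE]
}

#' Accuracy-weighted correlation between two sets of EBVs
#'
#' The correlation between breeding-value sets is computed with per-animal
#' weights so that well-proven animals dominate: by default
#' `w_i = sqrt(REL1_i * REL2_i)`, the geometric mean of the two
#' reliabilities.  Weighted means, variances and the covariance all use
#' `sum(w)` denominators, and the correlation is their ratio.  The
#' standard error defaults to the usual Pearson form
#' `sqrt((1 - r^2) / (n - 2))`; an alternative `sqrt((1 - r) / (n - 2))`
#' is available (`se_method = "one_minus_r"`).  The 95% confidence
#' interval is the estimate plus or minus 1.96 SE.
#'
#' With all reliabilities equal the weighted correlation reduces exactly
#' to the unweighted Pearson correlation.
#'
#' @param paired output of [filter_by_accuracy()], or any data.frame with
#'   `ebv1`, `rel1`, `ebv2`, `rel2`.
#' @param weight_fn `"sqrt_product"` (default) or `"unit"` (equal
#'   weights), or a function of `(rel1, rel2)` returning the weights.
#' @param se_method `"pearson"` (default) or `"one_minus_r"`.
#' @return list of class `weighted_correlation`: `r_w`, `se`, `ci95`,
#'   `n_pairs`.
#' @export
weighted_correlation <- function(paired,
                                 weight_fn = c("sqrt_product", "unit"),
                                 se_method = c("pearson", "one_minus_r")) {
  n <- nrow(paired)
  if (n < 3) stop("need at least 3 paired animals")
  se_method <- match.arg(se_method)
  if (is.function(weight_fn)) {
    w <- weight_fn(paired$rel1, paired$rel2)
  } else {
    weight_fn <- match.arg(weight_fn)
    w <- switch(weight_fn,
                sqrt_product = sqrt(paired$rel1 * paired$rel2),
                unit = rep(1, n))
  }
  stopifnot(all(w >= 0), sum(w) > 0)
  sw <- sum(w)
  m1 <- sum(w * paired$ebv1) / sw
  m2 <- sum(w * paired$ebv2) / sw
  s1 <- sum(w * (paired$ebv1 - m1)^2) / sw
  s2 <- sum(w * (paired$ebv2 - m2)^2) / sw
  if (s1 == 0 || s2 == 0) stop("zero weighted variance; correlation undefined")
  s12 <- sum(w * (paired$ebv1 - m1) * (paired$ebv2 - m2)) / sw
  r <- s12 / sqrt(s1 * s2)
  se <- switch(se_method,
               pearson = sqrt((1 - r^2) / (n - 2)),
               one_minus_r = sqrt(max(0, 1 - r) / (n - 2)))
  structure(list(r_w = r, se = se,
                 ci95 = c(r - 1.96 * se, r + 1.96 * se),
                 n_pairs = n),
            class = "weighted_correlation")
}

#' @export
print.weighted_correlation <- function(x, ...) {
  cat(sprintf("r_w = %.4f (SE %.4f, 95%% CI [%.4f, %.4f], n = %d)\n",
              x$r_w, x$se, x$ci95[1], x$ci95[2], x$n_pairs))
  invisible(x)
}

#' All pairwise accuracy-weighted correlations
#'
#' @param ebv_list named list of at least two EBV tables (`animal`,
#'   `ebv`, `rel`).
#' @param min_acc accuracy filter passed to [filter_by_accuracy()].
#' @param ... passed to [weighted_correlation()].
#' @return list with `matrix` (square correlation matrix, unit diagonal),
#'   `n_pairs` (matrix of pair counts) and `pairs` (long-format
#'   data.frame: trait1, trait2, r_w, se, ci_low, ci_high, n).
#' @export
correlation_matrix <- function(ebv_list, min_acc = 0.25, ...) {
  k <- length(ebv_list)
  stopifnot(k >= 2)
  nm <- names(ebv_list) %||% paste0("trait", seq_len(k))
  R <- diag(1, k)
  N <- matrix(NA_integer_, k, k)
  dimnames(R) <- dimnames(N) <- list(nm, nm)
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      paired <- filter_by_accuracy(ebv_list[[i]], ebv_list[[j]], min_acc)
      wc <- weighted_correlation(paired, ...)
      R[i, j] <- R[j, i] <- wc$r_w
      N[i, j] <- N[j, i] <- wc$n_pairs
      rows[[length(rows) + 1]] <- data.frame(
        trait1 = nm[i], trait2 = nm[j], r_w = wc$r_w, se = wc$se,
        ci_low = wc$ci95[1], ci_high = wc$ci95[2], n = wc$n_pairs)
    }
  }
  list(matrix = R, n_pairs = N, pairs = do.call(rbind, rows))
}
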