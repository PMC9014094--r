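#' Genotype quality control
#'
#' Filters a raw 0/1/2 genotype matrix the way a single-step evaluation
#' does: animals with a call rate below `min_call_rate` are removed first;
#' then X-labelled markers outside the pseudo-autosomal region (position
#' not above `par_boundary`) are dropped and the remaining X markers are
#' relabelled autosomal; finally markers are removed for low call rate,
#' minor allele frequency below `min_maf`, or an absolute deviation of the
#' observed heterozygote frequency from its Hardy-Weinberg expectation
#' `2p(1-p)` above `max_hwe_dev`.
#'
#' @param geno integer matrix of 0/1/2 with `NA` for missing calls; rows
#'   named by animal id, columns by SNP id.
#' @param map `data.frame(snp_id, chrom, pos_bp)` aligned with the columns
#'   of `geno`.
#' @param min_call_rate minimum per-animal and per-marker call rate.
#' @param min_maf minimum minor allele frequency (markers strictly below
#'   are removed).
#' @param max_hwe_dev maximum |observed - expected| heterozygote
#'   frequency.
#' @param par_boundary X positions must be strictly above this to be kept.
#' @return list with filtered `geno` (missing calls imputed to the rounded
#'   marker mean), `map` (X relabelled `"X_PAR"`), observed allele
#'   frequencies `freq`, and `audit` (per-rule removal counts).
#' @export
genotype_qc <- function(geno, map,
                        min_call_rate = 0.90,
                        min_maf = 0.01,
                        max_hwe_dev = 0.15,
                        par_boundary = PAR_BOUNDARY_BP) {
  stopifnot(ncol(geno) == nrow(map))
  audit <- list()

  cr_animal <- rowMeans(!is.na(geno))
  drop_an <- cr_animal < min_call_rate
  audit$animal_call_rate <- sum(drop_an)
  geno <- geno[!drop_an, , drop = FALSE]

  on_x <- map$chrom %in% c("X", "x", "30")
  drop_par <- on_x & !(map$pos_bp > par_boundary)
  audit$x_non_par <- sum(drop_par)
  geno <- geno[, !drop_par, drop = FALSE]
  map <- map[!drop_par, , drop = FALSE]
  map$chrom[map$chrom %in% c("X", "x", "30")] <- "X_PAR"

  cr_snp <- colMeans(!is.na(geno))
  drop_cr <- cr_snp < min_call_rate
  audit$snp_call_rate <- sum(drop_cr)
  geno <- geno[, !drop_cr, drop = FALSE]
  map <- map[!drop_cr, , drop = FALSE]

  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- maf < min_maf
  audit$maf <- sum(drop_maf)
  geno <- geno[, !drop_maf, drop = FALSE]
  map <- map[!drop_maf, , drop = FALSE]
  p <- p[!drop_maf]

  het <- colMeans(geno == 1, na.rm = TRUE)
  drop_hwe <- abs(het - 2 * p * (1 - p)) > max_hwe_dev
  audit$hwe <- sum(drop_hwe)
  geno <- geno[, !drop_hwe, drop = FALSE]
  map <- map[!drop_hwe, , drop = FALSE]
  p <- p[!drop_hwe]

  if (anyNA(geno)) {
    for (j in which(colSums(is.na(geno)) > 0)) {
      geno[is.na(geno[, j]), j] <- round(2 * p[j])
    }
  }
  list(geno = geno, map = map, freq = unname(p),
       audit = data.frame(rule = names(audit),
                          removed = as.integer(unlist(audit))))
}

#' Genomic relationship matrix with marker weights
#'
#' `G = R D R' / (2 * sum(p (1 - p)))` with `R` the gene content centered
#' on twice the observed allele frequencies and `D` a diagonal matrix of
#' per-marker weights.  The denominator deliberately excludes the weights,
#' so that `D = I` gives the standard unweighted genomic relationship
#' matrix and scaling all weights scales G proportionally.
#'
#' @param geno QC'd 0/1/2 matrix (no missing values).
#' @param weights per-marker weights (default all 1).
#' @param freq allele frequencies used for centering; default the observed
#'   frequencies of `geno`.  Fix these once at G-build time and reuse them
#'   when back-solving marker effects.
#' @return list with the dense symmetric matrix `G`, the `freq` and
#'   `weights` used, and the scalar `denom = 2 * sum(p (1 - p))`.
#' @export
g_matrix <- function(geno, weights = NULL, freq = NULL) {
  m <- ncol(geno)
  if (is.null(freq)) freq <- colMeans(geno) / 2
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(freq) == m, length(weights) == m, all(weights > 0))
  if (any(freq <= 0 | freq >= 1)) {
    stop("monomorphic marker(s) present; run genotype_qc() first")
  }
  R <- sweep(geno, 2, 2 * freq)
  denom <- 2 * sum(freq * (1 - freq))
  G <- tcrossprod(sweep(R, 2, weights, `*`), R) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(geno), rownames(geno))
  list(G = G, freq = freq, weights = weights, denom = denom)
}

#' Inverse of the blended single-step relationship matrix
#'
#' Augments the sparse pedigree inverse in the genotyped block:
#'
#'   `H^-1 = A^-1 + [0 0; 0 (w_g G + w_a A22)^-1 - A22^-1]`
#'
#' with the default blend `(0.90, 0.10)`.  Blending G with a fraction of
#' A22 guarantees the combined matrix is invertible; outside the genotyped
#' block `H^-1` is exactly `A^-1`.
#'
#' @param a_inv sparse inverse of the full pedigree relationship matrix
#'   (dimnames = animal ids).
#' @param a22 dense pedigree relationship matrix of the genotyped animals
#'   (dimnames = their ids, a subset of `a_inv`'s).
#' @param G dense genomic relationship matrix, aligned with `a22`.
#' @param blend weights `(on G, on A22)`; must be positive and sum to 1.
#' @param min_rcond minimum reciprocal condition number tolerated for the
#'   blended matrix.
#' @return sparse symmetric H-inverse with the same dimnames as `a_inv`.
#' @export
h_inverse <- function(a_inv, a22, G, blend = c(0.90, 0.10),
                      min_rcond = 1e-12) {
  stopifnot(length(blend) == 2, all(blend > 0),
            abs(sum(blend) - 1) < 1e-8)
  if (nrow(a22) == 0) return(a_inv)
  ids <- rownames(a22)
  if (is.null(ids) || !all(ids %in% rownames(a_inv))) {
    stop("a22 dimnames must identify a subset of a_inv's animals")
  }
  stopifnot(all(dim(a22) == dim(G)))
  Gb <- blend[1] * G + blend[2] * a22
  rc <- rcond(Gb)
  if (rc < min_rcond) {
    stop(sprintf(
      "blended genomic matrix is numerically singular (rcond = %.3e)", rc))
  }
  aug <- solve(Gb) - solve(a22)
  aug <- (aug + t(aug)) / 2
  idx <- match(ids, rownames(a_inv))
  n <- nrow(a_inv)
  ng <- length(idx)
  Aug <- Matrix::sparseMatrix(i = idx[rep(seq_len(ng), times = ng)],
                              j = idx[rep(seq_len(ng), each = ng)],
                              x = as.vector(aug), dims = c(n, n),
                              dimnames = dimnames(a_inv))
  Matrix::drop0(a_inv + Aug)
}
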