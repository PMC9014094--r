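#' Trace a pedigree back from a set of anchor animals
#'
#' Returns the sub-pedigree containing the anchors and their ancestors up
#' to `n_generations` parent links away.  Parent links that point outside
#' the retained set (beyond the horizon) are set to unknown so the result
#' is a self-contained pedigree.
#'
#' @param pedigree pedigree table in parents-before-offspring order.
#' @param anchors animal ids to trace from (typically the phenotyped or
#'   genotyped animals).
#' @param n_generations how many generations of ancestors to keep.
#' @return the sub-pedigree, in the original row order.
#' @export
trace_pedigree <- function(pedigree, anchors, n_generations) {
  check_pedigree(pedigree)
  stopifnot(n_generations >= 0)
  if (!all(anchors %in% pedigree$animal)) {
    stop("some anchors are not in the pedigree")
  }
  keep <- pedigree$animal %in% anchors
  frontier <- keep
  for (g in seq_len(n_generations)) {
    parents <- c(pedigree$sire[frontier], pedigree$dam[frontier])
    parents <- parents[!is.na(parents)]
    frontier <- pedigree$animal %in% parents & !keep
    if (!any(frontier)) break
    keep <- keep | frontier
  }
  out <- pedigree[keep, , drop = FALSE]
  out$sire[!(out$sire %in% out$animal)] <- NA
  out$dam[!(out$dam %in% out$animal)] <- NA
  out
}

#' Inbreeding coefficients
#'
#' Computes Wright's inbreeding coefficient for every animal by the
#' Meuwissen-Luo recursion (equivalent to the tabular method's diagonal,
#' `F = diag(A) - 1`).  Founders have `F = 0`.
#'
#' @param pedigree pedigree table in parents-before-offspring order.
#' @return numeric vector of inbreeding coefficients named by animal id.
#' @export
inbreeding <- function(pedigree) {
  check_pedigree(pedigree)
  sire <- match(pedigree$sire, pedigree$animal)
  dam <- match(pedigree$dam, pedigree$animal)
  f <- ml_inbreeding(ifelse(is.na(sire), 0L, sire),
                     ifelse(is.na(dam), 0L, dam))
  setNames(f, pedigree$animal)
}

#' Pedigree relationship matrix (tabular method)
#'
#' Dense numerator relationship matrix A.  Intended for moderate
#' pedigrees (tests, genotyped subsets); the mixed-model machinery uses
#' the sparse inverse from [a_inverse()] instead.
#'
#' @param pedigree pedigree table in parents-before-offspring order.
#' @return dense symmetric matrix with dimnames = animal ids; the diagonal
#'   equals 1 + F.
#' @export
a_matrix <- function(pedigree) {
  check_pedigree(pedigree)
  n <- nrow(pedigree)
  sire <- match(pedigree$sire, pedigree$animal)
  dam <- match(pedigree$dam, pedigree$animal)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]
    d <- dam[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[j, s] else numeric(i - 1L)
      ad_ <- if (!is.na(d)) A[j, d] else numeric(i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(pedigree$animal, pedigree$animal)
  A
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `alpha_i = 1 / d_i` to the inverse, where `d_i` is the
#' Mendelian-sampling variance `0.5 - 0.25 (F_s + F_d)` (adjusted for
#' unknown parents).  Accounting for inbreeding keeps `A %*% a_inverse(A)`
#' an identity even in inbred pedigrees.
#'
#' @param pedigree pedigree table in parents-before-offspring order.
#' @return sparse symmetric `dgCMatrix` with dimnames = animal ids.
#' @export
a_inverse <- function(pedigree) {
  check_pedigree(pedigree)
  n <- nrow(pedigree)
  sire <- match(pedigree$sire, pedigree$animal)
  dam <- match(pedigree$dam, pedigree$animal)
  f <- unname(inbreeding(pedigree))
  fs <- ifelse(is.na(sire), -1, f[sire])  # F = -1 encodes unknown parent:
  fd <- ifelse(is.na(dam), -1, f[dam])    # d then gains the missing 0.25
  d <- 0.5 - 0.25 * (fs + fd)
  alpha <- 1 / d

  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  half <- -0.5 * alpha
  quarter <- 0.25 * alpha
  add(seq_len(n), seq_len(n), alpha)
  ks <- which(!is.na(sire))
  kd <- which(!is.na(dam))
  add(ks, sire[ks], half[ks]); add(sire[ks], ks, half[ks])
  add(kd, dam[kd], half[kd]); add(dam[kd], kd, half[kd])
  add(sire[ks], sire[ks], quarter[ks])
  add(dam[kd], dam[kd], quarter[kd])
  kb <- which(!is.na(sire) & !is.na(dam))
  add(sire[kb], dam[kb], quarter[kb]); add(dam[kb], sire[kb], quarter[kb])

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(pedigree$animal,
                                               pedigree$animal))
  Matrix::drop0(Ainv)
}

#' Pedigree relationship matrix for a subset of animals
#'
#' Computes the block `A[ids, ids]` of the numerator relationship matrix
#' without forming the full dense A, via the factorization
#' `A = T^-1 D T^-T` (T the parent-contribution triangle, D the
#' Mendelian-sampling variances).
#'
#' @param pedigree pedigree table in parents-before-offspring order.
#' @param ids animal ids of the subset (e.g. the genotyped animals).
#' @return dense symmetric matrix with dimnames = `ids`.
#' @export
a_subset <- function(pedigree, ids) {
  check_pedigree(pedigree)
  if (!all(ids %in% pedigree$animal)) stop("ids must be in the pedigree")
  n <- nrow(pedigree)
  sire <- match(pedigree$sire, pedigree$animal)
  dam <- match(pedigree$dam, pedigree$animal)
  f <- unname(inbreeding(pedigree))
  fs <- ifelse(is.na(sire), -1, f[sire])
  fd <- ifelse(is.na(dam), -1, f[dam])
  d <- 0.5 - 0.25 * (fs + fd)

  ks <- which(!is.na(sire))
  kd <- which(!is.na(dam))
  Tmat <- Matrix::sparseMatrix(
    i = c(seq_len(n), ks, kd), j = c(seq_len(n), sire[ks], dam[kd]),
    x = c(rep(1, n), rep(-0.5, length(ks)), rep(-0.5, length(kd))),
    dims = c(n, n))
  rows <- match(ids, pedigree$animal)
  E <- matrix(0, n, length(rows))
  E[cbind(rows, seq_along(rows))] <- 1
  # rows of T^-1 for the subset: solve T' X = E, take t(X)
  X <- as.matrix(Matrix::solve(Matrix::t(Tmat), E))
  A22 <- crossprod(X * d, X)
  A22 <- (A22 + t(A22)) / 2
  dimnames(A22) <- list(ids, ids)
  A22
}
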