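test_that("pedigree tracing equals a brute-force BFS closure", {
  chain <- data.frame(animal = 1:4, sire = c(NA, 1, 2, 3),
                      dam = rep(NA_integer_, 4))
  expect_equal(trace_pedigree(chain, anchors = 1, n_generations = 3)$animal, 1)
  expect_equal(trace_pedigree(chain, anchors = 3, n_generations = 1)$animal,
               c(2, 3))

  ped <- random_pedigree(200, seed = 11)
  anchors <- sample(ped$animal, 15)
  got <- trace_pedigree(ped, anchors, n_generations = 4)
  expect_equal(sort(got$animal), bfs_ancestors(ped, anchors, 4))
  # retained parent links are internally consistent
  expect_silent(docility:::check_pedigree(got))

  expect_error(trace_pedigree(ped, anchors = 999, n_generations = 1),
               "not in the pedigree")
})

test_that("inbreeding matches textbook identities and the tabular diagonal", {
  trio <- data.frame(animal = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2))
  expect_equal(unname(inbreeding(trio)), c(0, 0, 0))

  fullsib <- data.frame(animal = 1:5, sire = c(NA, NA, 1, 1, 3),
                        dam = c(NA, NA, 2, 2, 4))
  expect_equal(unname(inbreeding(fullsib))[5], 0.25)

  halfsib <- data.frame(animal = 1:6, sire = c(NA, NA, NA, 1, 1, 4),
                        dam = c(NA, NA, NA, 2, 3, 5))
  expect_equal(unname(inbreeding(halfsib))[6], 0.125)

  ped <- random_pedigree(120, seed = 4, p_unknown = 0.05)
  expect_equal(unname(inbreeding(ped)), unname(diag(a_matrix(ped)) - 1),
               tolerance = 1e-12)
})

test_that("tabular A and Henderson A-inverse are mutual inverses", {
  trio <- data.frame(animal = c("A", "B", "C"), sire = c(NA, NA, "A"),
                     dam = c(NA, NA, "B"))
  A <- a_matrix(trio)
  expect_equal(A["A", "C"], 0.5)
  expect_equal(A["C", "C"], 1.0)
  expect_equal(A["A", "B"], 0)

  fullsib <- data.frame(animal = 1:4, sire = c(NA, NA, 1, 1),
                        dam = c(NA, NA, 2, 2))
  expect_equal(a_matrix(fullsib)[3, 4], 0.5)

  for (seed in 1:3) {
    ped <- random_pedigree(50, seed = seed, p_unknown = 0.15)
    A <- a_matrix(ped)
    Ainv <- as.matrix(a_inverse(ped))
    expect_lt(max(abs(A %*% Ainv - diag(50))), 1e-8)
    expect_lt(max(abs(Ainv - t(Ainv))), 1e-10)
  }
})

test_that("subset relationship block agrees with the dense tabular matrix", {
  ped <- random_pedigree(80, seed = 6, p_unknown = 0.1)
  ids <- sample(ped$animal, 12)
  expect_equal(a_subset(ped, ids),
               a_matrix(ped)[as.character(ids), as.character(ids)],
               tolerance = 1e-10)
})

test_that("genotype QC applies the thresholds and the PAR rule", {
  set.seed(2)
  n <- 400
  g <- iid_genotypes(n, 20, seed = 2, maf = c(0.3, 0.5))
  # plant: snp1 below, snp2 just above the MAF threshold (after the
  # low-call-rate animal is removed there are 399 animals, 798 alleles)
  g[, 1] <- 0L; g[2:8, 1] <- 1L      # 7/798  = 0.0088 < 0.01
  g[, 2] <- 0L; g[2:10, 2] <- 1L     # 9/798  = 0.0113 >= 0.01
  # snp3: HWE violation (all hets)
  g[, 3] <- 1L
  # snp4: low call rate
  g[seq_len(50), 4] <- NA
  # animal 1: low call rate
  g[1, ] <- NA
  map <- data.frame(snp_id = colnames(g),
                    chrom = c("1", "1", "2", "2", "X", "X",
                              rep("3", 14)),
                    pos_bp = c(10, 20, 30, 40, 133300518, 133300519,
                               seq(1000, by = 1000, length.out = 14)))
  res <- genotype_qc(g, map)
  expect_false("snp1" %in% colnames(res$geno))   # below MAF 0.01
  expect_true("snp2" %in% colnames(res$geno))    # above MAF 0.01
  expect_false("snp3" %in% colnames(res$geno))   # HWE deviation > 0.15
  expect_false("snp4" %in% colnames(res$geno))   # call rate < 0.90
  expect_false("snp5" %in% colnames(res$geno))   # X at boundary: not PAR
  expect_true("snp6" %in% colnames(res$geno))    # X above boundary: kept
  expect_equal(res$map$chrom[res$map$snp_id == "snp6"], "X_PAR")
  expect_false("an1" %in% rownames(res$geno))
  expect_false(anyNA(res$geno))
  expect_equal(sum(res$audit$removed),
               1 + 4)  # one animal, four markers
})

test_that("genomic relationship matrix matches hand and brute-force results", {
  g <- matrix(c(0L, 2L), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  G <- g_matrix(g)$G
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2))

  # weights enter the numerator only: doubling D doubles G
  gm <- iid_genotypes(20, 50, seed = 9)
  G1 <- g_matrix(gm)$G
  G2 <- g_matrix(gm, weights = rep(2, 50))$G
  expect_equal(G2, 2 * G1, tolerance = 1e-12)

  # naive triple-product oracle
  w <- runif(50, 0.5, 2)
  p <- colMeans(gm) / 2
  R <- sweep(gm, 2, 2 * p)
  G_oracle <- (R %*% diag(w) %*% t(R)) / (2 * sum(p * (1 - p)))
  expect_lt(max(abs(g_matrix(gm, weights = w)$G - G_oracle)), 1e-10)

  mono <- cbind(gm, mono = rep(2L, 20))
  expect_error(g_matrix(mono), "monomorphic")
})

test_that("H-inverse augments only the genotyped block and inverts the
           assembled H", {
  ped <- random_pedigree(30, n_founders = 8, seed = 3, p_unknown = 0)
  Ainv <- a_inverse(ped)

  # no genotyped animals: untouched
  empty <- matrix(numeric(0), 0, 0)
  expect_identical(h_inverse(Ainv, empty, empty), Ainv)

  ids <- as.character(sample(ped$animal, 10))
  A22 <- a_subset(ped, ids)

  # G = A22 collapses the augmentation
  Hinv0 <- h_inverse(Ainv, A22, A22)
  expect_lt(max(abs(Hinv0 - Ainv)), 1e-10)

  # dense oracle: assemble H explicitly and compare inverses
  gm <- iid_genotypes(10, 120, seed = 13, maf = c(0.35, 0.5))
  gm <- gm[, apply(gm, 2, var) > 0]
  rownames(gm) <- ids
  G <- g_matrix(gm)$G
  Hinv <- as.matrix(h_inverse(Ainv, A22, G))
  A <- a_matrix(ped)
  idx <- match(ids, rownames(A))
  Gb <- 0.90 * G + 0.10 * A22
  D22 <- Gb - A22
  A12 <- A[-idx, idx, drop = FALSE]
  S <- solve(A22)
  H <- A
  H[-idx, -idx] <- A[-idx, -idx] + A12 %*% S %*% D22 %*% S %*% t(A12)
  H[-idx, idx] <- A12 + A12 %*% S %*% D22
  H[idx, -idx] <- t(H[-idx, idx])
  H[idx, idx] <- Gb
  expect_lt(max(abs(solve(H) - Hinv)), 1e-6)

  # A-inverse preserved outside the genotyped block
  out <- setdiff(rownames(A), ids)
  expect_equal(as.matrix(Hinv)[out, out], as.matrix(Ainv)[out, out],
               tolerance = 1e-12)
})
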