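test_that("back-solving marker effects matches SNP-BLUP on small instances", {
  g <- iid_genotypes(20, 50, seed = 1)
  p <- colMeans(g) / 2
  R <- sweep(g, 2, 2 * p)
  k <- 1 / (2 * sum(p * (1 - p)))
  G <- k * R %*% t(R)
  set.seed(2)
  a_true <- rnorm(50, 0, 0.1)
  y <- as.numeric(R %*% a_true) + rnorm(20, 0, 0.3)
  lambda <- 0.5
  # GBLUP breeding values and the equivalent SNP-BLUP marker solutions
  gebv <- as.numeric(G %*% solve(G + lambda * diag(20), y))
  a_blup <- k * as.numeric(t(R) %*% solve(G + lambda * diag(20), y))
  got <- backsolve_snp_effects(gebv, g)
  expect_lt(max(abs(got$effects - a_blup)), 1e-6)
  # the marker effects reconstruct the GEBVs exactly
  expect_lt(max(abs(as.numeric(R %*% got$effects) - gebv)), 1e-8)
  # zero GEBVs give zero effects
  expect_equal(unname(backsolve_snp_effects(rep(0, 20), g)$effects),
               rep(0, 50))
})

test_that("projection of marker effects is invariant to rescaling the
           weights", {
  g <- iid_genotypes(25, 40, seed = 3)
  set.seed(4)
  gebv <- rnorm(25)
  p <- colMeans(g) / 2
  R <- sweep(g, 2, 2 * p)
  w <- runif(40, 0.5, 2)
  e1 <- backsolve_snp_effects(gebv, g, weights = w)
  e2 <- backsolve_snp_effects(gebv, g, weights = 2 * w)
  expect_equal(as.numeric(R %*% e1$effects),
               as.numeric(R %*% e2$effects), tolerance = 1e-8)
})

test_that("nonlinear weights follow the capped exponential formula", {
  p <- rep(0.5, 6)
  sdg <- sqrt(2 * 0.5 * 0.5)
  # construct standardized effects with known SD ratios
  u_std <- c(0, 1, 2, -2, 3, 10)
  eff <- u_std / sdg
  s <- sd(u_std)
  d <- nonlinear_weights(eff, freq = p)
  expect_equal(d, 1.125^(pmin(abs(u_std) / s, 5) - 2), tolerance = 1e-12)

  # anchor values: a zero effect keeps the floor weight; an effect at
  # exactly 2 SD keeps weight 1; huge effects hit the cap
  expect_equal(unname(nonlinear_weights(c(0, rep(c(-1, 1), 10)),
                                        freq = rep(0.5, 21))[1]),
               1.125^-2, tolerance = 1e-12)
  big <- c(rep(c(-0.1, 0.1), 20), 100)
  dbig <- nonlinear_weights(big, freq = rep(0.5, 41))
  expect_equal(unname(dbig[41]), 1.125^3, tolerance = 1e-12)

  expect_equal(nonlinear_weights(rep(0, 5), freq = rep(0.5, 5)), rep(1, 5))
})

test_that("weight iteration sharpens an oligogenic signal and leaves a
           polygenic profile essentially unchanged", {
  n <- 300; m <- 400
  g <- iid_genotypes(n, m, seed = 5)
  p <- colMeans(g) / 2
  R <- sweep(g, 2, 2 * p)

  run_profile <- function(a_true, noise_sd, seed) {
    set.seed(seed)
    y <- as.numeric(R %*% a_true) + rnorm(n, 0, noise_sd)
    G <- g_matrix(g)$G
    gebv <- as.numeric(G %*% solve(G + 0.5 * diag(n), y))
    it1 <- wssgwas_iterate(gebv, g, n_iter = 1)
    it3 <- wssgwas_iterate(gebv, g, n_iter = 3)
    map <- data.frame(snp_id = colnames(g), chrom = "1", pos_bp = seq_len(m))
    list(w1 = window_variance(it1, g, map)$windows,
         w3 = window_variance(it3, g, map)$windows,
         it1 = it1, it3 = it3)
  }

  # n_iter = 1 must be the unweighted analysis
  set.seed(6)
  gebv <- rnorm(n)
  expect_equal(wssgwas_iterate(gebv, g, n_iter = 1)$effects,
               backsolve_snp_effects(gebv, g)$effects, tolerance = 1e-12)

  # oligogenic: 5 QTL carry all the signal
  a_olig <- numeric(m)
  qtl <- c(40, 120, 200, 280, 360)
  set.seed(7)
  a_olig[qtl] <- rnorm(5, 0, 0.5)
  ol <- run_profile(a_olig, 0.5, seed = 8)
  in_qtl <- function(w) {
    hit <- w$start_idx <= rep(qtl, each = nrow(w)) &
      w$end_idx >= rep(qtl, each = nrow(w))
    rowSums(matrix(hit, nrow = nrow(w))) > 0
  }
  share <- function(w) sum(w$pct_variance[in_qtl(w)]) / sum(w$pct_variance)
  expect_gte(share(ol$w3), share(ol$w1))

  # polygenic: profiles of iteration 1 and 3 stay highly correlated
  set.seed(9)
  a_poly <- rnorm(m, 0, 0.05)
  po <- run_profile(a_poly, 0.5, seed = 10)
  expect_gt(cor(po$w1$pct_variance, po$w3$pct_variance), 0.9)
})

test_that("window variances localize signal, tile the chromosomes and sum
           to the genomic variance for unlinked markers", {
  n <- 1500; m <- 60
  g <- iid_genotypes(n, m, seed = 11)
  map <- data.frame(snp_id = colnames(g), chrom = rep(c("1", "2"), each = 30),
                    pos_bp = rep(seq_len(30) * 1000, 2))
  # all effects inside one window on chromosome 1
  eff <- numeric(m); eff[11:15] <- c(0.3, -0.2, 0.25, 0.1, -0.15)
  wv <- window_variance(eff, g, map)
  top <- wv$windows[which.max(wv$windows$pct_variance), ]
  expect_equal(top$start_idx, 11)
  expect_equal(top$pct_variance, 100)
  expect_equal(sum(wv$windows$chrom == "1"), 26)   # 30 - 5 + 1
  expect_true(all(wv$windows$end_idx - wv$windows$start_idx == 4))
  expect_equal(nrow(wv$regions), 1)
  expect_equal(wv$regions$peak_pct, 100)

  # exactly one window when the chromosome has window-many markers
  one <- window_variance(rnorm(5), g[, 1:5],
                         data.frame(snp_id = colnames(g)[1:5], chrom = "1",
                                    pos_bp = 1:5))
  expect_equal(nrow(one$windows), 1)

  # disjoint windows of unlinked markers recover the genomic variance
  set.seed(12)
  eff2 <- rnorm(m, 0, 0.1)
  wv2 <- window_variance(eff2, g, map)
  disjoint <- wv2$windows[wv2$windows$start_idx %in% seq(1, m, by = 5), ]
  expect_lt(abs(sum(disjoint$pct_variance) - 100), 5)

  # short chromosome skipped with a warning
  map3 <- map; map3$chrom[1:3] <- "9"
  expect_warning(window_variance(eff2, g, map3), "fewer than 5")

  # marker input order is irrelevant after map sorting
  perm <- sample(m)
  wv3 <- window_variance(eff2[perm], g[, perm], map[perm, ])
  expect_equal(wv3$windows, wv2$windows)
})

test_that("windows containing simulated QTL outrank the null background", {
  hits <- 0
  for (seed in 1:4) {
    n <- 500; m <- 600
    g <- iid_genotypes(n, m, seed = 100 + seed)
    p <- colMeans(g) / 2
    R <- sweep(g, 2, 2 * p)
    set.seed(200 + seed)
    qtl <- sample(seq(10, m - 10), 10)
    a <- numeric(m); a[qtl] <- rnorm(10, 0, 0.4)
    y <- as.numeric(R %*% a) + rnorm(n, 0, 1)
    G <- g_matrix(g)$G
    gebv <- as.numeric(G %*% solve(G + diag(n), y))
    eff <- wssgwas_iterate(gebv, g, n_iter = 3)
    map <- data.frame(snp_id = colnames(g), chrom = "1", pos_bp = seq_len(m))
    w <- window_variance(eff, g, map)$windows
    has_qtl <- vapply(seq_len(nrow(w)), function(i)
      any(qtl >= w$start_idx[i] & qtl <= w$end_idx[i]), logical(1))
    thr95 <- quantile(w$pct_variance[!has_qtl], 0.95)
    # the strongest QTL windows clear the null 95th percentile
    hits <- hits + (mean(sort(w$pct_variance[has_qtl],
                              decreasing = TRUE)[1:5] > thr95) == 1)
  }
  expect_gte(hits, 3)
})
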