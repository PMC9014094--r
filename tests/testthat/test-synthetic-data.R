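test_that("pedigree simulation builds valid multi-generation pedigrees", {
  cfg <- sim_config(n_founders = 2, n_generations = 1,
                    progeny_per_dam_mean = 1, seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3)
  expect_identical(sort(c(ped$sire[3], ped$dam[3])), c(1L, 2L))
  expect_silent(check_pedigree <- docility:::check_pedigree(ped))

  # determinism under a fixed seed
  cfg2 <- sim_config(n_founders = 80, n_generations = 3, seed = 42)
  expect_identical(simulate_pedigree(cfg2), simulate_pedigree(cfg2))

  # parents always born earlier
  big <- simulate_pedigree(sim_config(n_founders = 150, n_generations = 4,
                                      seed = 9))
  row <- seq_len(nrow(big))
  expect_true(all(match(big$sire, big$animal) < row, na.rm = TRUE))
  expect_true(all(match(big$dam, big$animal) < row, na.rm = TRUE))
})

test_that("progeny-per-dam mean matches the configured target", {
  cfg <- sim_config(n_founders = 1700, n_generations = 3,
                    progeny_per_dam_mean = 1.6, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_gt(nrow(ped), 4000)
  per_dam <- table(ped$dam[!is.na(ped$dam)])
  expect_lt(abs(mean(per_dam) - 1.6), 0.2)
})

test_that("gene dropping respects Mendelian transmission and target MAF", {
  cfg <- sim_config(n_founders = 600, n_generations = 2, n_snps = 200,
                    n_qtl = 5, maf_range = c(0.05, 0.5), seed = 3)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  g <- gen$geno
  expect_true(all(g %in% 0:2))

  # offspring of two homozygous-reference parents are homozygous reference
  off <- which(!is.na(ped$sire) & !is.na(ped$dam))
  s <- match(ped$sire[off], ped$animal)
  d <- match(ped$dam[off], ped$animal)
  for (j in sample(ncol(g), 20)) {
    both0 <- g[s, j] == 0 & g[d, j] == 0
    expect_true(all(g[off[both0], j] == 0))
    both2 <- g[s, j] == 2 & g[d, j] == 2
    expect_true(all(g[off[both2], j] == 2))
    # an offspring always inherits at least one allele present in a parent
    expect_true(all(abs(g[off, j] - (g[s, j] + g[d, j]) / 2) <= 1))
  }

  # realized frequencies track the sampled founder frequencies
  realized <- colMeans(g) / 2
  expect_true(all(abs(realized - gen$truth$founder_freq) < 0.05))

  # X block sits above the pseudo-autosomal boundary
  xm <- gen$map[gen$map$chrom == "X", ]
  expect_gt(nrow(xm), 0)
  expect_true(all(xm$pos_bp > PAR_BOUNDARY_BP))

  # QTL effects present and scaled
  expect_equal(sum(gen$truth$snp_effects != 0), 5)

  # determinism
  expect_identical(gen$geno, simulate_genotypes(ped, cfg)$geno)
})

test_that("ordinal scores follow the probit-implied category probabilities", {
  cfg <- sim_config(n_founders = 30000, n_generations = 1,
                    var_direct = 0, var_maternal_gen = 0,
                    var_maternal_env = 0, var_cg = 0, var_residual = 1,
                    cor_direct_maternal = 0,
                    thresholds = c(0, 1, 2),
                    beta_season = c(0, 0, 0), beta_calfdev = 0,
                    seed = 8)
  sim <- simulate_phenotypes(simulate_pedigree(cfg), config = cfg)
  emp <- as.numeric(table(factor(sim$pheno$score, levels = 1:4))) /
    nrow(sim$pheno)
  expected <- diff(c(0, pnorm(c(0, 1, 2)), 1))
  expect_lt(max(abs(cumsum(emp) - cumsum(expected))), 0.01)
})

test_that("heavily skewed category probabilities are realized empirically", {
  cfg <- sim_config(n_founders = 40000, n_generations = 1,
                    category_probs = c(0.72, 0.22, 0.05, 0.01), seed = 4)
  sim <- simulate_phenotypes(simulate_pedigree(cfg), config = cfg)
  emp <- as.numeric(table(factor(sim$pheno$score, levels = 1:4))) /
    nrow(sim$pheno)
  expect_true(all(abs(emp - c(0.72, 0.22, 0.05, 0.01)) < 0.01))
})

test_that("simulated breeding values have the configured variance and produce
           the expected parent-offspring regression", {
  cfg <- sim_config(n_founders = 4000, n_generations = 3,
                    var_direct = 0.4, var_maternal_gen = 0,
                    var_maternal_env = 0, var_cg = 0, var_residual = 0.6,
                    cor_direct_maternal = 0, beta_season = c(0, 0, 0),
                    beta_calfdev = 0, seed = 12)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, config = cfg)
  expect_lt(abs(var(sim$truth$u) / 0.4 - 1), 0.05)

  # offspring liability on sire liability: slope ~ 0.5 var_u / var_total
  lia <- sim$truth$liability
  off <- names(lia)[names(lia) %in%
                      as.character(ped$animal[!is.na(ped$sire)])]
  sire <- as.character(ped$sire[match(as.integer(off), ped$animal)])
  keep <- sire %in% names(lia)
  slope <- coef(lm(lia[off[keep]] ~ lia[sire[keep]]))[2]
  expect_lt(abs(slope - 0.2), 0.05)
})

test_that("paired EBV fixtures carry the requested correlation and noise", {
  exact <- simulate_ebv_pairs(500, 1, reliability_range = c(1, 1), seed = 2)
  expect_equal(cor(exact$ebv1$ebv, exact$ebv2$ebv), 1, tolerance = 1e-12)
  expect_true(all(exact$ebv1$rel == 1))

  null <- simulate_ebv_pairs(10000, 0, reliability_range = c(0.3, 0.9),
                             seed = 3)
  paired <- filter_by_accuracy(null$ebv1, null$ebv2, min_acc = 0)
  expect_lt(abs(weighted_correlation(paired)$r_w), 0.03)
})
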