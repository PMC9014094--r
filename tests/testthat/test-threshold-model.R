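# Small shared fixture: a compact simulated dataset with maternal structure.
small_sim <- function(seed = 2, n_founders = 250, model_vars = TRUE) {
  cfg <- sim_config(n_founders = n_founders, n_generations = 3,
                    var_direct = 0.4,
                    var_maternal_gen = if (model_vars) 0.04 else 0,
                    var_maternal_env = if (model_vars) 0.02 else 0,
                    cor_direct_maternal = if (model_vars) -0.4 else 0,
                    var_cg = 0.1, var_residual = 0.5, seed = seed)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, config = cfg)
  list(cfg = cfg, ped = ped, sim = sim)
}

test_that("sampled liabilities honour the category truncation bounds", {
  fx <- small_sim(seed = 3, n_founders = 120)
  for (seed in 1:3) {
    fit <- fit_threshold_model(fx$sim$pheno, pedigree = fx$ped,
                               spec = model_spec("D"),
                               chain = chain_config(n_iter = 300,
                                                    burn_in = 100,
                                                    thin = 2, seed = seed))
    t <- fit$thresholds
    C <- fit$meta$n_categories
    lo <- c(-Inf, t)[fx$sim$pheno$score]
    hi <- c(t, Inf)[fx$sim$pheno$score]
    expect_true(all(fit$liab_final >= lo & fit$liab_final <= hi))
  }
})

test_that("gaussian-mode posterior means solve the mixed-model equations", {
  # 10 phenotyped animals, fixed variances: the Gibbs posterior mean of
  # each location effect must match the closed-form GLS/BLUP solution.
  ped <- data.frame(animal = 1:12,
                    sire = c(NA, NA, NA, NA, 1, 1, 3, 3, 5, 5, 7, 7),
                    dam = c(NA, NA, NA, NA, 2, 2, 4, 4, 6, 6, 8, 8))
  set.seed(99)
  ph <- data.frame(animal = 3:12,
                   y = rnorm(10),
                   cg = rep(1:2, each = 5),
                   season = rep(1:2, 5),
                   calfdev = runif(10, -20, 20))
  var_u <- 0.4; var_e <- 0.6; var_cg <- 0.2
  fit <- fit_threshold_model(ph, pedigree = ped, spec = model_spec("D"),
                             chain = chain_config(n_iter = 60000,
                                                  burn_in = 5000,
                                                  thin = 2, seed = 1),
                             response = "y", gaussian = TRUE,
                             fix_variances = list(var_u = var_u,
                                                  var_e = var_e,
                                                  var_cg = var_cg))
  # dense MME oracle
  X <- stats::model.matrix(~ 1 + factor(season) + calfdev, ph)
  Zc <- stats::model.matrix(~ 0 + factor(cg), ph)
  Zu <- matrix(0, 10, 12); Zu[cbind(1:10, ph$animal)] <- 1
  Ainv <- as.matrix(a_inverse(ped))
  W <- cbind(X, Zc, Zu)
  lhs <- crossprod(W) / var_e
  ii <- ncol(X) + seq_len(2)
  lhs[ii, ii] <- lhs[ii, ii] + diag(2) / var_cg
  ju <- ncol(X) + 2 + seq_len(12)
  lhs[ju, ju] <- lhs[ju, ju] + Ainv / var_u
  sol <- solve(lhs, crossprod(W, ph$y) / var_e)
  got <- c(fit$effects$b, fit$effects$w,
           fit$ebv$ebv[match(1:12, fit$ebv$animal)])
  expect_equal(unname(got), as.numeric(sol), tolerance = 0.03)
})

test_that("maternal models keep the covariance inside the Cauchy-Schwarz
           bound and produce maternal EBVs", {
  fx <- small_sim(seed = 5, n_founders = 250)
  fit <- fit_threshold_model(fx$sim$pheno, pedigree = fx$ped,
                             spec = model_spec("DMG"),
                             chain = chain_config(n_iter = 2500,
                                                  burn_in = 500,
                                                  thin = 2, seed = 2))
  s <- fit$samples
  expect_true(all(s[, "var_u"] > 0 & s[, "var_m"] > 0 & s[, "var_e"] > 0))
  expect_true(all(abs(s[, "cov_um"]) <=
                    sqrt(s[, "var_u"] * s[, "var_m"]) + 1e-12))
  expect_true(all(c("ebv_m", "pev_m", "rel_m") %in% names(fit$ebv)))
  expect_true(all(fit$ebv$rel >= 0 & fit$ebv$rel <= 1))

  # DMP: maternal-environment variance sampled and positive
  fit2 <- fit_threshold_model(fx$sim$pheno, pedigree = fx$ped,
                              spec = model_spec("DMP"),
                              chain = chain_config(n_iter = 1500,
                                                   burn_in = 300,
                                                   thin = 2, seed = 2))
  expect_true(all(fit2$samples[, "var_pe"] > 0))
})

test_that("posterior summaries are invariant to relabelling animal ids", {
  fx <- small_sim(seed = 7, n_founders = 100, model_vars = FALSE)
  ped <- fx$ped
  ph <- fx$sim$pheno
  relabel <- function(x) paste0("ID", x)
  ped2 <- transform(ped, animal = relabel(animal),
                    sire = ifelse(is.na(sire), NA, relabel(sire)),
                    dam = ifelse(is.na(dam), NA, relabel(dam)))
  ph2 <- transform(ph, animal = relabel(animal))
  ch <- chain_config(n_iter = 800, burn_in = 200, thin = 2, seed = 4)
  f1 <- fit_threshold_model(ph, pedigree = ped, spec = model_spec("D"),
                            chain = ch)
  f2 <- fit_threshold_model(ph2, pedigree = ped2, spec = model_spec("D"),
                            chain = ch)
  expect_equal(f1$samples, f2$samples, tolerance = 1e-12)
  expect_equal(f1$ebv$ebv, f2$ebv$ebv, tolerance = 1e-12)
})

test_that("heritability ratios match a per-sample loop oracle", {
  set.seed(6)
  n <- 200
  s <- cbind(var_cg = runif(n, 0.05, 0.2), var_u = runif(n, 0.2, 0.6),
             cov_um = runif(n, -0.05, 0.05), var_m = runif(n, 0.01, 0.1),
             var_pe = runif(n, 0.01, 0.1), var_e = runif(n, 0.3, 0.7))
  h <- heritabilities(s, spec = model_spec("DMGP"))
  oracle <- t(apply(s, 1, function(r) {
    vt <- r["var_u"] + r["var_cg"] + r["var_e"] + r["cov_um"] +
      r["var_m"] + r["var_pe"]
    c(r["var_u"] / vt, r["var_m"] / vt,
      (r["var_u"] + 1.5 * r["cov_um"] + 0.5 * r["var_m"]) / vt)
  }))
  expect_equal(unname(h$samples), unname(oracle), tolerance = 1e-14)

  # no maternal terms: total equals direct heritability
  hD <- heritabilities(s, spec = model_spec("D"))
  zero <- s; zero[, c("cov_um", "var_m")] <- 0
  hD0 <- heritabilities(zero, spec = model_spec("D"))
  expect_equal(hD0$samples[, "ht2"], hD0$samples[, "hd2"])
})

test_that("docile probability is the probit tail below the first threshold", {
  expect_equal(docile_probability(0, t1 = 0, sigma_e = 1), 0.5)
  expect_equal(docile_probability(0.5, t1 = 0, sigma_e = 1),
               pnorm(-0.5), tolerance = 1e-12)
  expect_equal(docile_probability(-50), 1)
  u <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(docile_probability(u)) < 0))
  tab <- docile_probability(data.frame(animal = 1:3, ebv = c(-1, 0, 1)))
  expect_true(all(diff(tab$prob_docile) < 0))
})
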