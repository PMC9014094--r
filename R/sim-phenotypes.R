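#' Simulate ordinal phenotypes from a liability threshold model
#'
#' Builds, for every animal with a known dam, a latent liability
#'
#'   l = intercept + season + b * CALFDEV + cg + u(animal) + m(dam) +
#'       pe(dam) + e
#'
#' and converts it to an ordinal score by the configured thresholds.
#' Direct and maternal breeding values (u, m) are drawn jointly along the
#' pedigree with covariance `cor_direct_maternal * sqrt(var_u * var_m)`,
#' using Mendelian-sampling variances that account for parental inbreeding.
#' Contemporary groups partition each generation into cohorts of roughly
#' `cg_size` records and carry an independent normal effect.
#'
#' Animals whose dam is unknown but for whom maternal components are
#' requested get independent maternal draws and are flagged in the output
#' (`dam_known = FALSE`).
#'
#' @param pedigree pedigree table in parents-before-offspring order.
#' @param genotypes optional result of [simulate_genotypes()]; when
#'   supplied, the marker-determined genetic values replace the
#'   pedigree-sampled direct breeding values so that GWAS signal recovery
#'   can be tested against a marker-level truth.
#' @param config a [sim_config()].
#' @return list with
#'   * `pheno`: one row per phenotyped animal — `animal`, ordinal `score`,
#'     `cg` (integer contemporary-group id), `season`, `calfdev`,
#'     `age_days`, `sex`, `birth_year`, `dam_known`, plus the raw
#'     management fields a record-editing step expects (`herd_birth`,
#'     `herd_wean`, `herd_year`, month-year date strings, `aod_class`,
#'     `et_flag`, `creep`, `ultrasound`);
#'   * `truth`: per-animal `u` and `m` (named by animal id), per-dam `pe`,
#'     per-group `cg_effects`, the realized `liability`, the `thresholds`
#'     used and the implied `category_probs`.
#' @export
simulate_phenotypes <- function(pedigree, genotypes = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  check_pedigree(pedigree)
  set.seed(derive_seed(config$seed, "phenotypes"))

  n <- nrow(pedigree)
  thr <- sim_thresholds(config)

  bv <- sim_breeding_values(pedigree, config)
  u <- bv$u
  m <- bv$m
  if (!is.null(genotypes)) {
    u <- as.numeric(genotypes$truth$qtl_values[as.character(pedigree$animal)])
  }

  pe_dam <- rnorm(n, 0, sqrt(config$var_maternal_env))  # indexed by dam row

  has_record <- !is.na(pedigree$dam) | config$n_generations == 0
  rec <- which(has_record)
  nr <- length(rec)
  if (nr == 0) stop("no animal has a known dam; nothing to phenotype")

  dam_row <- match(pedigree$dam, pedigree$animal)[rec]
  dam_known <- !is.na(dam_row)

  m_term <- numeric(nr)
  pe_term <- numeric(nr)
  m_term[dam_known] <- m[dam_row[dam_known]]
  pe_term[dam_known] <- pe_dam[dam_row[dam_known]]
  if (any(!dam_known)) {
    m_term[!dam_known] <- rnorm(sum(!dam_known), 0,
                                sqrt(config$var_maternal_gen))
    pe_term[!dam_known] <- rnorm(sum(!dam_known), 0,
                                 sqrt(config$var_maternal_env))
  }

  gen <- pedigree$generation[rec] %||% pedigree$birth_year[rec]
  cg <- sim_contemporary_groups(gen, config$cg_size)
  cg_eff <- rnorm(max(cg), 0, sqrt(config$var_cg))

  season <- sample.int(length(config$beta_season), nr, replace = TRUE)
  age_days <- pmin(440L, pmax(320L, round(rnorm(nr, 365, 25))))
  calfdev <- age_days - 365

  fixed <- config$mean_liability + config$beta_season[season] +
    config$beta_calfdev * calfdev
  e <- rnorm(nr, 0, sqrt(config$var_residual))
  liab <- fixed + cg_eff[cg] + u[rec] + m_term + pe_term + e
  score <- findInterval(liab, thr) + 1L

  herd <- paste0("H", ((cg - 1L) %% 7L) + 1L)
  my <- function(y) paste0(sprintf("%02d", ((cg + y) %% 12L) + 1L), "-",
                           pedigree$birth_year[rec])
  pheno <- data.frame(
    animal = pedigree$animal[rec],
    score = score,
    cg = cg,
    season = season,
    calfdev = calfdev,
    age_days = age_days,
    sex = pedigree$sex[rec] %||% "U",
    birth_year = pedigree$birth_year[rec],
    dam_known = dam_known,
    herd_birth = herd, herd_wean = herd, herd_year = herd,
    date_birth = my(0L), date_wean = my(3L), date_year = my(9L),
    aod_class = sample.int(10L, nr, replace = TRUE),
    et_flag = rbinom(nr, 1, 0.02),
    creep = rbinom(nr, 1, 0.3),
    ultrasound = rbinom(nr, 1, 0.5)
  )
  probs <- diff(c(0, pnorm(thr, mean = config$mean_liability,
                           sd = sqrt(sim_total_variance(config))), 1))
  list(pheno = pheno,
       truth = list(u = setNames(u, pedigree$animal),
                    m = setNames(m, pedigree$animal),
                    pe = setNames(pe_dam, pedigree$animal),
                    cg_effects = cg_eff,
                    liability = setNames(liab, pedigree$animal[rec]),
                    thresholds = thr,
                    category_probs = probs))
}

# Joint (direct, maternal) breeding values along the pedigree.  Mendelian
# sampling variance is (0.5 - 0.25 (F_s + F_d)) Sigma for two known
# parents, (0.75 - 0.25 F_p) Sigma for one, Sigma for none.
sim_breeding_values <- function(pedigree, config) {
  n <- nrow(pedigree)
  s2u <- config$var_direct
  s2m <- config$var_maternal_gen
  cum <- config$cor_direct_maternal * sqrt(s2u * s2m)
  Sigma <- matrix(c(s2u, cum, cum, s2m), 2, 2)
  if (s2u == 0 && s2m == 0) {
    return(list(u = numeric(n), m = numeric(n)))
  }
  Fcoef <- inbreeding(pedigree)
  sire_row <- match(pedigree$sire, pedigree$animal)
  dam_row <- match(pedigree$dam, pedigree$animal)
  u <- numeric(n)
  m <- numeric(n)
  # Cholesky of Sigma (allowing singular components)
  L <- tryCatch(t(chol(Sigma)), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  })
  z <- matrix(rnorm(2 * n), 2, n)
  for (i in seq_len(n)) {
    s <- sire_row[i]
    d <- dam_row[i]
    pa <- c(if (!is.na(s)) c(u[s], m[s]) / 2 else c(0, 0)) +
      c(if (!is.na(d)) c(u[d], m[d]) / 2 else c(0, 0))
    w <- 1 - 0.25 * sum(!is.na(c(s, d))) -
      0.25 * sum(Fcoef[c(s, d)], na.rm = TRUE)
    ms <- sqrt(w) * (L %*% z[, i])
    u[i] <- pa[1] + ms[1]
    m[i] <- pa[2] + ms[2]
  }
  list(u = u, m = m)
}

# Contemporary groups: within each generation, consecutive chunks of about
# `size` records; ids are global across generations.
sim_contemporary_groups <- function(gen, size) {
  cg <- integer(length(gen))
  offset <- 0L
  for (g in sort(unique(gen))) {
    ix <- which(gen == g)
    k <- max(1L, round(length(ix) / size))
    cg[ix] <- offset + (sample(rep_len(seq_len(k), length(ix))))
    offset <- offset + k
  }
  cg
}
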