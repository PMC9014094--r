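# Shared fixture builders, all deterministic given a seed.

# A random but structurally valid pedigree: the first n_founders animals
# are founders; every later animal draws parents among strictly earlier
# animals (possibly unknown with prob p_unknown).
random_pedigree <- function(n, n_founders = max(4, n %/% 5),
                            p_unknown = 0.1, seed = 1) {
  set.seed(seed)
  sire <- dam <- rep(NA_integer_, n)
  for (i in seq(n_founders + 1, n)) {
    cand <- seq_len(i - 1)
    if (runif(1) > p_unknown) sire[i] <- sample(cand, 1)
    if (runif(1) > p_unknown) dam[i] <- sample(cand, 1)
    if (!is.na(sire[i]) && !is.na(dam[i]) && sire[i] == dam[i]) {
      dam[i] <- NA_integer_
    }
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam,
             birth_year = 2000 + (seq_len(n) - 1) %/% n_founders)
}

# Brute-force ancestor closure by breadth-first search over parent links.
bfs_ancestors <- function(pedigree, anchors, n_generations) {
  keep <- unique(anchors)
  frontier <- keep
  for (g in seq_len(n_generations)) {
    rows <- match(frontier, pedigree$animal)
    parents <- c(pedigree$sire[rows], pedigree$dam[rows])
    parents <- unique(parents[!is.na(parents)])
    frontier <- setdiff(parents, keep)
    if (length(frontier) == 0) break
    keep <- c(keep, frontier)
  }
  sort(keep)
}

# A small phenotype table carrying every column the QC pipeline expects.
toy_pheno <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    animal = seq_len(n),
    score = sample(1:4, n, replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)),
    age_days = sample(320:440, n, replace = TRUE),
    aod_class = sample(1:3, n, replace = TRUE),
    et_flag = rbinom(n, 1, 0.1),
    season = sample(1:2, n, replace = TRUE),
    calfdev = sample(-40:40, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    herd_birth = sample(c("h1", "h2", "h3"), n, replace = TRUE),
    herd_wean = "hw", herd_year = "hy",
    date_birth = "01-2010", date_wean = "04-2010", date_year = "01-2011",
    creep = rbinom(n, 1, 0.5), ultrasound = rbinom(n, 1, 0.5),
    birth_year = 2010
  )
}

# Independent (linkage-equilibrium) genotypes, not pedigree-derived.
iid_genotypes <- function(n, m, seed = 1, maf = c(0.2, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(g) <- paste0("an", seq_len(n))
  colnames(g) <- paste0("snp", seq_len(m))
  g
}
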