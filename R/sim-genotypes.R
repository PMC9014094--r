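#' Simulate biallelic genotypes by gene dropping through a pedigree
#'
#' Founder haplotypes are drawn per marker from allele frequencies sampled
#' uniformly in `maf_range`; every descendant inherits one allele from each
#' parent.  Explicit allele transmission (rather than multivariate-normal
#' genotypes) makes the realized genomic relationships agree in expectation
#' with the pedigree relationship matrix, which downstream single-step
#' machinery relies on.
#'
#' Markers are laid out on `n_chrom` autosomes plus a small X-labelled
#' block whose base-pair positions all exceed the pseudo-autosomal boundary
#' (133,300,518 bp), so that the X markers the panel carries are the
#' pseudo-autosomal ones and segregate autosomally — which is exactly how
#' they are simulated.
#'
#' By default markers segregate independently (linkage equilibrium).  With
#' `ld_blocks = TRUE` parental alleles are copied in blocks of adjacent
#' markers, inducing within-block linkage disequilibrium; no claim is made
#' that this matches any real LD decay.
#'
#' @param pedigree a pedigree table in parents-before-offspring order.
#' @param config a [sim_config()].
#' @return a list with elements
#'   * `geno`: integer matrix of 0/1/2 gene content, rows named by animal id,
#'     columns by SNP id;
#'   * `map`: `data.frame(snp_id, chrom, pos_bp)` with 1-based positions,
#'     sorted by chromosome then position;
#'   * `truth`: list with the sampled founder allele frequencies
#'     (`founder_freq`), the true marker effects (`snp_effects`, zero for
#'     non-QTL markers) and the per-animal genetic values they generate
#'     (`qtl_values`, centered on observed frequencies).
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  check_pedigree(pedigree)
  set.seed(derive_seed(config$seed, "genotypes"))

  n <- nrow(pedigree)
  m <- config$n_snps
  p <- runif(m, config$maf_range[1], config$maf_range[2])

  map <- sim_snp_map(config)

  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  sire_row <- match(pedigree$sire, pedigree$animal)
  dam_row <- match(pedigree$dam, pedigree$animal)
  block <- if (config$ld_blocks) {
    rep(seq_len(ceiling(m / config$ld_block_size)),
        each = config$ld_block_size)[seq_len(m)]
  } else {
    seq_len(m)
  }
  n_block <- max(block)
  for (i in seq_len(n)) {
    h1[i, ] <- sim_gamete(h1, h2, sire_row[i], p, block, n_block)
    h2[i, ] <- sim_gamete(h1, h2, dam_row[i], p, block, n_block)
  }
  geno <- h1 + h2
  rownames(geno) <- pedigree$animal
  colnames(geno) <- map$snp_id

  effects <- numeric(m)
  if (config$n_qtl > 0) {
    qtl <- sample.int(m, config$n_qtl)
    raw <- rnorm(config$n_qtl)
    scale <- sqrt(config$var_direct / sum(2 * p[qtl] * (1 - p[qtl]) * raw^2))
    effects[qtl] <- raw * scale
  }
  p_obs <- colMeans(geno) / 2
  qtl_values <- as.numeric(sweep(geno, 2, 2 * p_obs) %*% effects)

  list(geno = geno, map = map,
       truth = list(founder_freq = p, snp_effects = effects,
                    qtl_values = setNames(qtl_values, pedigree$animal)))
}

# One gamete: an allele per marker from the parent (or a founder draw from
# the population frequency when the parent is unknown).  With LD blocks the
# grandparental origin is constant within a block.
sim_gamete <- function(h1, h2, parent_row, p, block, n_block) {
  m <- length(p)
  if (is.na(parent_row)) {
    return(as.integer(runif(m) < p))
  }
  from_first <- (runif(n_block) < 0.5)[block]
  ifelse(from_first, h1[parent_row, ], h2[parent_row, ])
}

#' Pseudo-autosomal boundary on the X chromosome
#'
#' X-labelled markers with a base-pair position strictly above this
#' boundary are pseudo-autosomal: they recombine like autosomal markers
#' and are the only X markers retained by [genotype_qc()].
#' @export
PAR_BOUNDARY_BP <- 133300518L

sim_snp_map <- function(config) {
  m <- config$n_snps
  # a small X-PAR block; at least a window's worth so it is analyzable
  n_x <- max(5L, min(m - config$n_chrom, round(0.005 * m)))
  if (m <= 10) n_x <- 0L
  n_auto <- m - n_x
  chrom <- sort(rep_len(seq_len(config$n_chrom), n_auto))
  pos <- unlist(lapply(split(seq_len(n_auto), chrom), function(ix) {
    sort(sample.int(1e8, length(ix)))
  }), use.names = FALSE)
  map <- data.frame(snp_id = paste0("snp", seq_len(m)),
                    chrom = c(as.character(chrom), rep("X", n_x)),
                    pos_bp = c(pos,
                               if (n_x > 0)
                                 sort(PAR_BOUNDARY_BP +
                                        sample.int(2e7, n_x))
                               else integer(0)))
  map
}
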