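#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the simulator in one validated object: pedigree
#' structure, marker panel, liability-scale variance components and the
#' thresholds that discretize the liability into ordinal scores.
#'
#' Defaults emulate the data structure a yearling-temperament evaluation
#' faces: sparse maternal links (about 1.6 progeny per dam), a direct
#' heritability around 0.40 with a small maternal genetic component that is
#' negatively correlated with the direct effect, and a heavily skewed
#' four-category score distribution (roughly 72/22/5/1 percent).
#'
#' @param n_founders number of unrelated founder animals.
#' @param n_generations number of discrete offspring generations bred from
#'   the founders.
#' @param progeny_per_dam_mean target mean number of progeny per dam
#'   (zero-truncated Poisson); values at or below 1 give exactly one
#'   progeny per dam.
#' @param n_snps,n_qtl marker panel size and number of markers carrying a
#'   true effect.
#' @param maf_range two values in (0, 0.5]; founder allele frequencies are
#'   drawn uniformly in this range.
#' @param n_chrom number of autosomes the panel is spread over (an extra
#'   pseudo-autosomal X block is always appended, see
#'   [simulate_genotypes()]).
#' @param var_direct,var_maternal_gen,var_maternal_env,var_cg,var_residual
#'   liability-scale variance components: direct additive, maternal
#'   genetic, maternal environmental, contemporary group and residual.
#' @param cor_direct_maternal correlation between direct and maternal
#'   genetic effects, in \[-1, 1\].
#' @param thresholds strictly increasing cut points on the liability scale.
#'   When `NULL` they are derived from `category_probs` at the marginal
#'   liability variance implied by the variance components.
#' @param category_probs probabilities of the ordinal categories used to
#'   derive `thresholds`; must sum to 1.
#' @param mean_liability intercept of the liability.
#' @param beta_season fixed effects of a 3-level categorical stand-in
#'   (season); first level is the reference.
#' @param beta_calfdev regression of the liability on age deviation from
#'   365 days.
#' @param cg_size target number of records per contemporary group.
#' @param ld_blocks when `TRUE`, founder haplotypes are copied in blocks of
#'   `ld_block_size` adjacent markers so that markers within a block are in
#'   linkage disequilibrium; by default markers segregate independently.
#' @param ld_block_size block length used when `ld_blocks = TRUE`.
#' @param year_start birth year assigned to the founders.
#' @param seed integer seed making every generator deterministic.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_founders = 50, n_generations = 2, seed = 42)
#' cfg$var_direct
#' @export
sim_config <- function(n_founders = 200,
                       n_generations = 4,
                       progeny_per_dam_mean = 1.6,
                       n_snps = 1000,
                       n_qtl = 10,
                       maf_range = c(0.05, 0.5),
                       n_chrom = 5,
                       var_direct = 0.40,
                       var_maternal_gen = 0.04,
                       var_maternal_env = 0.02,
                       var_cg = 0.10,
                       var_residual = 0.50,
                       cor_direct_maternal = -0.40,
                       thresholds = NULL,
                       category_probs = c(0.72, 0.22, 0.05, 0.01),
                       mean_liability = 0,
                       beta_season = c(0, 0.05, -0.05),
                       beta_calfdev = 0.002,
                       cg_size = 20,
                       ld_blocks = FALSE,
                       ld_block_size = 5,
                       year_start = 2000L,
                       seed = 1L) {
  stopifnot(n_founders >= 2, n_generations >= 0,
            progeny_per_dam_mean > 0,
            n_snps >= 1, n_qtl >= 0, n_qtl <= n_snps,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            n_chrom >= 1, cg_size >= 1)
  vars <- c(var_direct = var_direct, var_maternal_gen = var_maternal_gen,
            var_maternal_env = var_maternal_env, var_cg = var_cg,
            var_residual = var_residual)
  if (any(vars < 0)) {
    stop("variance components must be non-negative: ",
         paste(names(vars)[vars < 0], collapse = ", "))
  }
  if (var_residual <= 0) stop("var_residual must be positive")
  if (abs(cor_direct_maternal) > 1) {
    stop("cor_direct_maternal must lie in [-1, 1]")
  }
  if (!is.null(thresholds)) {
    if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  } else {
    if (abs(sum(category_probs) - 1) > 1e-8 || any(category_probs <= 0)) {
      stop("category_probs must be positive and sum to 1")
    }
  }
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              progeny_per_dam_mean = progeny_per_dam_mean,
              n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
              maf_range = maf_range, n_chrom = as.integer(n_chrom),
              var_direct = var_direct, var_maternal_gen = var_maternal_gen,
              var_maternal_env = var_maternal_env, var_cg = var_cg,
              var_residual = var_residual,
              cor_direct_maternal = cor_direct_maternal,
              thresholds = thresholds, category_probs = category_probs,
              mean_liability = mean_liability,
              beta_season = beta_season, beta_calfdev = beta_calfdev,
              cg_size = as.integer(cg_size),
              ld_blocks = isTRUE(ld_blocks),
              ld_block_size = as.integer(ld_block_size),
              year_start = as.integer(year_start),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Marginal liability variance implied by the components: the maternal
# genetic value entering a record is the dam's, whose covariance with the
# animal's own direct value contributes sigma_um once (the same convention
# the model-specific total variance uses).
sim_total_variance <- function(cfg) {
  cov_um <- cfg$cor_direct_maternal *
    sqrt(cfg$var_direct * cfg$var_maternal_gen)
  cfg$var_direct + cfg$var_maternal_gen + cov_um +
    cfg$var_maternal_env + cfg$var_cg + cfg$var_residual
}

# Thresholds realizing the configured category probabilities under a
# normal liability with the configured mean and total variance.
sim_thresholds <- function(cfg) {
  if (!is.null(cfg$thresholds)) return(cfg$thresholds)
  p <- cumsum(cfg$category_probs)
  qnorm(p[-length(p)], mean = cfg$mean_liability,
        sd = sqrt(sim_total_variance(cfg)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  pedigree : %d founders, %d generations, %.2f progeny/dam\n",
              x$n_founders, x$n_generations, x$progeny_per_dam_mean))
  cat(sprintf("  markers  : %d SNPs (%d QTL) on %d autosomes + X-PAR block\n",
              x$n_snps, x$n_qtl, x$n_chrom))
  cat(sprintf(
    "  liability: var u=%.3f m=%.3f pe=%.3f cg=%.3f e=%.3f, cor(u,m)=%.2f\n",
    x$var_direct, x$var_maternal_gen, x$var_maternal_env, x$var_cg,
    x$var_residual, x$cor_direct_maternal))
  cat(sprintf("  seed     : %d\n", x$seed))
  invisible(x)
}
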