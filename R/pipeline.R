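#' Run the evaluation pipeline end to end on synthetic data
#'
#' Orchestrates the full analysis: simulate a pedigree, genotypes and
#' ordinal phenotypes; apply the record-editing rules and build
#' contemporary groups; assemble the pedigree (and, when genotypes are
#' used, the blended single-step) relationship structure; fit the
#' threshold animal model; forward-validate by masking the final birth
#' year; and run the weighted single-step GWAS on the genotyped animals.
#' Every stage writes its artifacts as TSV into `dir`, together with a
#' `run_info.json` holding the resolved configuration, seeds and stage
#' timings.  Re-running with the same configuration and seed reproduces
#' all outputs.
#'
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param dir output directory (created if needed).
#' @param model animal model passed to [model_spec()].
#' @param chain a [chain_config()] for the variance-component fit.
#' @param genomic include the genomic stages (genotype QC, H-inverse,
#'   WssGWAS).
#' @param n_genotyped number of phenotyped animals treated as genotyped
#'   (default: all, capped at 800 to keep the dense genomic algebra
#'   small).
#' @param mask_year birth year masked for LR validation (default: the
#'   last generation; `NA` skips validation).
#' @param window,threshold WssGWAS window size (markers) and selection
#'   threshold (percent of additive genetic variance).
#' @param gwas_iters weighting iterations for the WssGWAS.
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = sim_config(),
                         dir = tempfile("docility_run_"),
                         model = "D",
                         chain = chain_config(seed = config$seed),
                         genomic = TRUE,
                         n_genotyped = NULL,
                         mask_year = NULL,
                         window = 5, threshold = 0.20, gwas_iters = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, name) {
    timings[[name]] <<- round(as.numeric(Sys.time() - start, units = "secs"), 2)
  }

  ## --- simulate ----------------------------------------------------------
  s <- tic()
  ped <- simulate_pedigree(config)
  gen <- if (genomic) simulate_genotypes(ped, config)
  sim <- simulate_phenotypes(ped, genotypes = NULL, config = config)
  write_tsv(ped, file.path(dir, "pedigree.tsv"))
  write_tsv(sim$pheno, file.path(dir, "phenotypes_raw.tsv"))
  if (genomic) {
    write_tsv(gen$map, file.path(dir, "snp_map.tsv"))
    write_tsv(data.frame(animal = rownames(gen$geno), gen$geno,
                         check.names = FALSE),
              file.path(dir, "genotypes.tsv"))
  }
  toc(s, "simulate")

  ## --- phenotype QC -------------------------------------------------------
  s <- tic()
  coll <- collapse_scores(sim$pheno)
  filt <- apply_filters(coll$pheno)
  cgd <- build_cg(filt$pheno)
  pheno <- cgd$pheno
  write_tsv(pheno, file.path(dir, "phenotypes_qc.tsv"))
  write_tsv(filt$audit, file.path(dir, "qc_audit.tsv"))
  toc(s, "qc")

  ## --- relationship structures -------------------------------------------
  s <- tic()
  ainv <- a_inverse(ped)
  kinv <- ainv
  geno_qc <- NULL
  gmat <- NULL
  geno_ids <- character(0)
  if (genomic) {
    cand <- as.character(pheno$animal)
    cap <- n_genotyped %||% min(length(cand), 800L)
    set.seed(derive_seed(config$seed, "fit"))
    geno_ids <- sort(sample(cand, min(cap, length(cand))))
    geno_qc <- genotype_qc(gen$geno[geno_ids, , drop = FALSE], gen$map)
    gmat <- g_matrix(geno_qc$geno)
    a22 <- a_subset(ped, rownames(geno_qc$geno))
    kinv <- h_inverse(ainv, a22, gmat$G)
    write_tsv(geno_qc$audit, file.path(dir, "genotype_qc_audit.tsv"))
  }
  toc(s, "relationship")

  ## --- threshold-model fit ------------------------------------------------
  s <- tic()
  spec <- model_spec(model, relationship = if (genomic) "H" else "A")
  fit <- fit_threshold_model(pheno, pedigree = ped, kinv = kinv, spec = spec,
                             chain = chain, cg_col = "cg_key")
  write_tsv(as.data.frame(fit$samples), file.path(dir, "chain.tsv"))
  write_tsv(fit$ebv, file.path(dir, "ebv.tsv"))
  h2 <- heritabilities(fit)
  write_tsv(h2$summary, file.path(dir, "heritabilities.tsv"))
  toc(s, "fit")

  ## --- LR validation ------------------------------------------------------
  s <- tic()
  lr <- NULL
  mask_year <- mask_year %||% max(pheno$birth_year)
  if (!is.na(mask_year) && any(pheno$birth_year == mask_year) &&
      !all(pheno$birth_year == mask_year)) {
    sp <- split_partial(pheno, mask_year)
    post <- colMeans(fit$samples)
    fixv <- list(var_cg = post[["var_cg"]], var_u = post[["var_u"]],
                 var_e = post[["var_e"]])
    if (spec$maternal_genetic) {
      fixv$cov_um <- post[["cov_um"]]
      fixv$var_m <- post[["var_m"]]
    }
    if (spec$maternal_env) fixv$var_pe <- post[["var_pe"]]
    fit_p <- fit_threshold_model(sp$partial, pedigree = ped, kinv = kinv,
                                 spec = spec, chain = chain,
                                 cg_col = "cg_key", fix_variances = fixv)
    fbar <- mean(inbreeding(ped)[as.character(sp$validation_ids)])
    lr <- lr_metrics(fit_p$ebv, fit$ebv, as.character(sp$validation_ids),
                     var_u = post[["var_u"]], mean_f = fbar)
    write_tsv(lr, file.path(dir, "lr_validation.tsv"))
  }
  toc(s, "validate")

  ## --- WssGWAS ------------------------------------------------------------
  s <- tic()
  gwas <- NULL
  if (genomic) {
    gebv <- fit$ebv$ebv[match(rownames(geno_qc$geno), fit$ebv$animal)]
    eff <- wssgwas_iterate(gebv, geno_qc$geno, n_iter = gwas_iters,
                           freq = gmat$freq)
    gwas <- window_variance(eff, geno_qc$geno, geno_qc$map,
                            window = window, threshold = threshold)
    write_tsv(gwas$windows, file.path(dir, "gwas_windows.tsv"))
    write_tsv(gwas$regions, file.path(dir, "gwas_regions.tsv"))
    if (nrow(gwas$regions)) {
      bed <- data.frame(chrom = gwas$regions$chrom,
                        start = gwas$regions$start_bp - 1L,
                        end = gwas$regions$end_bp)
      write.table(bed, file.path(dir, "gwas_regions.bed"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  toc(s, "gwas")

  info <- list(config = unclass(config),
               model = model, chain = unclass(chain),
               n_genotyped = length(geno_ids),
               mask_year = mask_year,
               timings_sec = timings,
               total_sec = round(as.numeric(Sys.time() - t0,
                                            units = "secs"), 2))
  jsonlite::write_json(info, file.path(dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dir = dir, pedigree = ped, pheno = pheno, fit = fit,
                 heritabilities = h2, lr = lr, gwas = gwas,
                 genotype_qc = geno_qc))
}
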