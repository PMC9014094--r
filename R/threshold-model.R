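#' Model, prior and chain specifications for the threshold animal model
#'
#' Four nested animal models are supported, differing in which random
#' effects accompany the contemporary group (always fitted) and the direct
#' additive genetic effect (always fitted):
#' * `"D"`   — direct genetic effect only;
#' * `"DMG"` — adds the maternal genetic effect with a direct-maternal
#'   covariance;
#' * `"DMP"` — adds a maternal environmental (dam permanent environment)
#'   effect;
#' * `"DMGP"`— both maternal effects (often poorly identified in data with
#'   few progeny per dam; inspect [diagnostics()] before trusting it).
#'
#' @param model one of `"D"`, `"DMG"`, `"DMP"`, `"DMGP"`.
#' @param relationship `"A"` (pedigree) or `"H"` (blended single-step);
#'   informational tag — the structure actually used is whichever
#'   precision matrix is passed to [fit_threshold_model()].
#' @return a `model_spec` list.
#' @export
model_spec <- function(model = c("D", "DMG", "DMP", "DMGP"),
                       relationship = c("A", "H")) {
  model <- match.arg(model)
  structure(list(model = model,
                 maternal_genetic = model %in% c("DMG", "DMGP"),
                 maternal_env = model %in% c("DMP", "DMGP"),
                 relationship = match.arg(relationship)),
            class = "model_spec")
}

#' @rdname model_spec
#' @param nu_cg,s2_cg,nu_u,s2_u,nu_pe,s2_pe,nu_e,s2_e degrees of freedom
#'   and scale of the scaled inverse-chi-squared priors on the
#'   contemporary-group, direct-genetic (non-maternal models), maternal
#'   environmental and residual variances.  The defaults (`nu = -2`,
#'   `scale = 0`) are the flat limiting case.
#' @param nu_sig,V_sig degrees of freedom and scale matrix of the
#'   inverse-Wishart prior on the 2x2 direct/maternal covariance matrix;
#'   the default (`nu_sig = 0`, zero matrix) is the Jeffreys-type flat
#'   limit.
#' @export
prior_spec <- function(nu_cg = -2, s2_cg = 0, nu_u = -2, s2_u = 0,
                       nu_pe = -2, s2_pe = 0, nu_e = -2, s2_e = 0,
                       nu_sig = 0, V_sig = matrix(0, 2, 2)) {
  structure(list(nu_cg = nu_cg, s2_cg = s2_cg, nu_u = nu_u, s2_u = s2_u,
                 nu_pe = nu_pe, s2_pe = s2_pe, nu_e = nu_e, s2_e = s2_e,
                 nu_sig = nu_sig, V_sig = V_sig),
            class = "prior_spec")
}

#' @rdname model_spec
#' @param n_iter,burn_in,thin chain length, burn-in and thinning interval.
#'   The defaults mirror a production run used for breeding-value
#'   prediction with fixed variance components; variance-component
#'   estimation warrants much longer chains.
#' @param seed integer seed for the sampler.
#' @export
chain_config <- function(n_iter = 10000, burn_in = 1000, thin = 5,
                         seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

#' Fit a Bayesian threshold animal model by Gibbs sampling
#'
#' Single-site Gibbs sampler on the liability scale.  Each ordinal score
#' is linked to a latent normal liability; liabilities are sampled from
#' truncated normals within their category bounds, location effects from
#' their normal full conditionals, variances from scaled
#' inverse-chi-squared conditionals, the direct/maternal covariance matrix
#' from an inverse-Wishart, and free thresholds from uniform conditionals.
#'
#' Identification: the first threshold is fixed at 0 and, with three or
#' more categories, the second at 1, leaving the residual variance free to
#' be estimated; with only two categories the residual variance is fixed
#' at 1 instead.  Heritabilities, being variance ratios, do not depend on
#' this scaling choice.
#'
#' The solve order for the genetic effects is the pedigree order of
#' `kinv`'s rows, fixed for reproducibility.
#'
#' @param pheno data.frame with columns `animal`, the response, a
#'   contemporary-group column, and the fixed-effect columns.
#' @param pedigree pedigree table; used to build the A-inverse when `kinv`
#'   is not given, and to look up each record's dam for maternal effects.
#' @param kinv optional sparse precision structure of the genetic effects
#'   (A-inverse or H-inverse) with animal ids as dimnames; overrides
#'   `pedigree`-derived A-inverse.
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param chain a [chain_config()].
#' @param fixed_effects categorical fixed-effect columns.
#' @param covariates numeric covariate columns.
#' @param cg_col contemporary-group column (integer ids or keys).
#' @param response response column; ordinal scores `1..C` or, with
#'   `gaussian = TRUE`, a continuous trait.
#' @param gaussian fit the linear (identity-link) version of the same
#'   model, treating the response as the observed liability.
#' @param fix_variances named list fixing any of `var_cg`, `var_u`,
#'   `cov_um`, `var_m`, `var_pe`, `var_e` (the genetic block `var_u`,
#'   `cov_um`, `var_m` is fixed jointly).
#' @return object of class `threshold_fit`: list with `samples` (matrix of
#'   retained draws of the variance components and free thresholds),
#'   `ebv` (animal, posterior-mean EBV, PEV, reliability; maternal columns
#'   when fitted), `effects` (posterior means of fixed and
#'   contemporary-group effects), `thresholds`, `liab_final`, `spec`,
#'   `priors`, `chain` and `meta`.
#' @export
fit_threshold_model <- function(pheno, pedigree = NULL, kinv = NULL,
                                spec = model_spec("D"),
                                priors = prior_spec(),
                                chain = chain_config(),
                                fixed_effects = "season",
                                covariates = "calfdev",
                                cg_col = "cg", response = "score",
                                gaussian = FALSE,
                                fix_variances = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(priors, "prior_spec"),
            inherits(chain, "chain_config"))
  if (is.null(kinv)) {
    if (is.null(pedigree)) stop("supply either a pedigree or kinv")
    kinv <- a_inverse(pedigree)
  }
  kinv <- methods::as(kinv, "CsparseMatrix")
  animals <- rownames(kinv)
  if (is.null(animals)) stop("kinv must carry animal ids as dimnames")
  if (!all(as.character(pheno$animal) %in% animals)) {
    stop("phenotyped animals missing from the relationship structure")
  }

  n <- nrow(pheno)
  uidx <- match(as.character(pheno$animal), animals)

  need_dam <- spec$maternal_genetic || spec$maternal_env
  midx <- integer(n)
  pidx <- integer(n)
  npe <- 0L
  if (need_dam) {
    if (is.null(pedigree)) stop("maternal effects need the pedigree (dam links)")
    dam <- pedigree$dam[match(pheno$animal, pedigree$animal)]
    dm <- match(as.character(dam), animals)
    dm[is.na(dm)] <- 0L
    if (spec$maternal_genetic) midx <- dm
    if (spec$maternal_env) {
      known <- dm > 0L
      lev <- unique(dm[known])
      pidx[known] <- match(dm[known], lev)
      npe <- length(lev)
    }
  }

  cg <- as.integer(factor(pheno[[cg_col]]))
  ncg <- max(cg)

  fixed_effects <- intersect(fixed_effects, names(pheno))
  covariates <- intersect(covariates, names(pheno))
  rhs <- paste(c("1", if (length(fixed_effects))
    paste0("factor(", fixed_effects, ")"), covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = pheno)

  yv <- pheno[[response]]
  if (gaussian) {
    C <- 2L
    y <- integer(n)
    y_cont <- as.numeric(yv)
  } else {
    y <- as.integer(yv)
    C <- max(y)
    if (C < 2) stop("need at least two score categories")
    if (!all(sort(unique(y)) == seq_len(C))) {
      stop("scores must occupy the contiguous range 1..C")
    }
    y_cont <- numeric(n)
  }

  fx <- rep(NA_real_, 6)
  names(fx) <- c("var_cg", "var_u", "cov_um", "var_m", "var_pe", "var_e")
  if (!is.null(fix_variances)) {
    bad <- setdiff(names(fix_variances), names(fx))
    if (length(bad)) stop("unknown components in fix_variances: ",
                          paste(bad, collapse = ", "))
    fx[names(fix_variances)] <- unlist(fix_variances)
    if (spec$maternal_genetic && !is.na(fx["var_u"]) &&
        (is.na(fx["var_m"]) || is.na(fx["cov_um"]))) {
      stop("with maternal genetic effects, fix var_u, cov_um and var_m jointly")
    }
  }
  if (!gaussian && C == 2 && is.na(fx["var_e"])) fx["var_e"] <- 1

  init <- c(var_cg = 0.1, var_u = 0.3, cov_um = 0, var_m = 0.1,
            var_pe = 0.1, var_e = if (gaussian) var(y_cont) / 2 else 1)

  set.seed(chain$seed)
  res <- threshold_gibbs_cpp(
    y = y, y_cont = y_cont, gaussian = gaussian, X = X,
    cg = cg, ncg = ncg, uidx = uidx, midx = midx, pidx = pidx, npe = npe,
    use_m = spec$maternal_genetic, use_pe = spec$maternal_env,
    Ki = kinv@i, Kp = kinv@p, Kx = kinv@x, q = nrow(kinv),
    C = C, n_iter = chain$n_iter, burn_in = chain$burn_in,
    thin = chain$thin, priors = unclass(priors),
    fixed_vals = unname(fx), init_vals = unname(init))

  n_free_t <- max(0L, C - 3L)
  cn <- c("var_cg", "var_u", "cov_um", "var_m", "var_pe", "var_e",
          if (n_free_t > 0) paste0("t", seq(3, C - 1)))
  samples <- res$samples
  colnames(samples) <- cn

  var_u_hat <- mean(samples[, "var_u"])
  rel <- function(pev, s2) pmin(1, pmax(0, 1 - pev / s2))
  ebv <- data.frame(animal = animals,
                    ebv = res$u_mean, pev = res$u_var,
                    rel = rel(res$u_var, var_u_hat))
  if (spec$maternal_genetic) {
    var_m_hat <- mean(samples[, "var_m"])
    ebv$ebv_m <- res$m_mean
    ebv$pev_m <- res$m_var
    ebv$rel_m <- rel(res$m_var, var_m_hat)
  }

  structure(list(
    samples = samples,
    ebv = ebv,
    effects = list(b = setNames(as.numeric(res$b_mean), colnames(X)),
                   w = as.numeric(res$w_mean),
                   pe = if (spec$maternal_env) as.numeric(res$pe_mean)),
    thresholds = as.numeric(res$thresholds),
    liab_final = as.numeric(res$liab_final),
    spec = spec, priors = priors, chain = chain,
    meta = list(n_records = n, n_animals = nrow(kinv), n_cg = ncg,
                n_categories = C, gaussian = gaussian,
                fixed_variances = fx[!is.na(fx)],
                parameterization = if (gaussian) "identity link"
                else if (C == 2) "t1 = 0, var_e = 1"
                else "t1 = 0, t2 = 1, var_e estimated",
                reliability = "PEV-based: 1 - PEV / posterior mean var_u",
                solve_order = "pedigree order of kinv rows")),
    class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> model %s on %d records, %d animals, %d CGs\n",
              x$spec$model, x$meta$n_records, x$meta$n_animals, x$meta$n_cg))
  cat(sprintf("  %d retained samples; %s\n", nrow(x$samples),
              x$meta$parameterization))
  keep <- c("var_cg", "var_u",
            if (x$spec$maternal_genetic) c("cov_um", "var_m"),
            if (x$spec$maternal_env) "var_pe", "var_e")
  print(round(colMeans(x$samples[, keep, drop = FALSE]), 4))
  invisible(x)
}

#' Liability-scale heritabilities from a posterior chain
#'
#' Direct, maternal and total heritabilities computed sample by sample and
#' then summarized.  The total phenotypic variance is the model-specific
#' sum of the fitted components (direct, contemporary group, residual,
#' plus the maternal variance and direct-maternal covariance and/or the
#' maternal environmental variance when fitted) and the total heritability
#' weights the maternal terms by the fraction transmitted:
#'
#'   `ht2 = (var_u + 1.5 cov_um + 0.5 var_m) / var_total`
#'
#' @param fit a `threshold_fit`, or a samples matrix with the standard
#'   column names.
#' @param spec the [model_spec()] (taken from the fit when omitted).
#' @return list with `summary` (data.frame: parameter, mean, sd, q2.5,
#'   q97.5) and `samples` (per-draw matrix with columns `hd2`, `hm2`,
#'   `ht2`).
#' @export
heritabilities <- function(fit, spec = NULL) {
  if (inherits(fit, "threshold_fit")) {
    samples <- fit$samples
    spec <- spec %||% fit$spec
  } else {
    samples <- fit
    if (is.null(spec)) stop("supply a model_spec with a raw samples matrix")
  }
  vu <- samples[, "var_u"]
  vm <- samples[, "var_m"]
  cum <- samples[, "cov_um"]
  vt <- vu + samples[, "var_cg"] + samples[, "var_e"]
  if (spec$maternal_genetic) vt <- vt + cum + vm
  if (spec$maternal_env) vt <- vt + samples[, "var_pe"]
  h <- cbind(hd2 = vu / vt,
             hm2 = if (spec$maternal_genetic) vm / vt else rep(0, length(vt)),
             ht2 = (vu + 1.5 * cum + 0.5 * vm) / vt)
  summ <- data.frame(parameter = colnames(h),
                     mean = colMeans(h),
                     sd = apply(h, 2, sd),
                     q2.5 = apply(h, 2, quantile, 0.025),
                     q97.5 = apply(h, 2, quantile, 0.975),
                     row.names = NULL)
  list(summary = summ, samples = h)
}

#' Total heritability from point estimates
#'
#' Closed-form combination of the direct heritability, maternal
#' heritability and direct-maternal correlation on the variance-ratio
#' scale, using `cov_um / var_total = r * sqrt(hd2 * hm2)`:
#'
#'   `ht2 = hd2 + 1.5 r sqrt(hd2 hm2) + 0.5 hm2`
#'
#' @param hd2 direct heritability.
#' @param hm2 maternal heritability.
#' @param r_dm direct-maternal genetic correlation.
#' @return total heritability.
#' @examples
#' total_heritability(0.44, 0.04, -0.40)  # 0.3804
#' @export
total_heritability <- function(hd2, hm2 = 0, r_dm = 0) {
  stopifnot(hd2 >= 0, hm2 >= 0, abs(r_dm) <= 1)
  hd2 + 1.5 * r_dm * sqrt(hd2 * hm2) + 0.5 * hm2
}

#' Probability of the most docile score from an EBV
#'
#' Converts a direct EBV on the liability scale into the probability of
#' the animal scoring in the first (docile) category,
#' `P = pnorm((t1 - ebv) / sigma_e)`, with the population fixed-effect
#' baseline absorbed at zero.  Strictly decreasing in the EBV: higher
#' liability means a more temperamental animal.
#'
#' @param ebv numeric vector of direct EBVs, or an EBV table with an
#'   `ebv` column (a `prob_docile` column is appended).
#' @param t1 first threshold (default 0, the identification constraint).
#' @param sigma_e residual standard deviation on the liability scale.
#' @return numeric vector, or the table with `prob_docile` appended.
#' @export
docile_probability <- function(ebv, t1 = 0, sigma_e = 1) {
  stopifnot(sigma_e > 0)
  if (is.data.frame(ebv)) {
    ebv$prob_docile <- pnorm((t1 - ebv$ebv) / sigma_e)
    return(ebv)
  }
  pnorm((t1 - ebv) / sigma_e)
}
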