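#' Simulate paired EBV tables with known true correlation
#'
#' Fixture generator for the accuracy-weighted correlation machinery: true
#' breeding values for two traits are drawn from a standard bivariate
#' normal with correlation `true_correlation`; each reported EBV is the
#' true value plus prediction error with variance `1 - REL`, where the
#' reliability `REL` is drawn uniformly in `reliability_range`.  With
#' `REL = 1` the EBV equals the true value exactly.
#'
#' The prediction errors of the two traits are themselves correlated at
#' `true_correlation`, emulating EBVs from a joint evaluation of the same
#' animals, where the error (PEV) covariance structure follows the
#' genetic covariance.  With equal reliabilities this makes the
#' correlation between the EBV sets equal to the correlation between the
#' true values, so EBV correlations are an (approximately) unattenuated
#' proxy for the genetic correlation; with independent errors they would
#' be shrunk by the mean accuracy product.
#'
#' @param n number of animals.
#' @param true_correlation correlation of the underlying true values,
#'   in \[-1, 1\].
#' @param reliability_range two values in \[0, 1\] bounding the per-animal
#'   reliabilities.
#' @param seed integer seed.
#' @return list with two `data.frame`s (`ebv1`, `ebv2`), each with columns
#'   `animal`, `ebv`, `rel`, and a `truth` list carrying the latent values.
#' @export
simulate_ebv_pairs <- function(n, true_correlation,
                               reliability_range = c(0.3, 0.9),
                               seed = 1L) {
  stopifnot(abs(true_correlation) <= 1,
            length(reliability_range) == 2,
            reliability_range[1] >= 0, reliability_range[2] <= 1,
            reliability_range[1] <= reliability_range[2])
  set.seed(derive_seed(seed, "ebv"))
  rho <- true_correlation
  t1 <- rnorm(n)
  t2 <- rho * t1 + sqrt(1 - rho^2) * rnorm(n)
  rel1 <- runif(n, reliability_range[1], reliability_range[2])
  rel2 <- runif(n, reliability_range[1], reliability_range[2])
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  ebv1 <- t1 + sqrt(1 - rel1) * z1
  ebv2 <- t2 + sqrt(1 - rel2) * z2
  id <- seq_len(n)
  list(ebv1 = data.frame(animal = id, ebv = ebv1, rel = rel1),
       ebv2 = data.frame(animal = id, ebv = ebv2, rel = rel2),
       truth = list(t1 = t1, t2 = t2))
}
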