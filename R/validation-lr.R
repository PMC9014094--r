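#' Mask the final birth year for forward validation
#'
#' Defines the validation set as the animals born in `mask_year` that
#' carry a phenotype, and returns the partial dataset with their records
#' removed.  The animals themselves remain in the pedigree, so their
#' partial-data EBVs are parent averages propagated through relatives.
#'
#' @param pheno phenotype table with `animal` and a birth-year column.
#' @param mask_year the birth year whose phenotypes are masked.
#' @param year_col birth-year column name.
#' @return list with `partial` (records of all other animals) and
#'   `validation_ids`.
#' @export
split_partial <- function(pheno, mask_year, year_col = "birth_year") {
  if (!year_col %in% names(pheno)) stop("missing column: ", year_col)
  in_year <- pheno[[year_col]] == mask_year
  if (!any(in_year)) {
    stop("no phenotyped animals born in ", mask_year,
         "; empty validation set")
  }
  list(partial = pheno[!in_year, , drop = FALSE],
       validation_ids = unique(pheno$animal[in_year]))
}

#' LR-method validation metrics
#'
#' Compares breeding values estimated from the partial dataset (recent
#' phenotypes masked) with those from the whole dataset, over the
#' validation animals:
#' * bias `delta = mean(ebv_partial) - mean(ebv_whole)` (EBV units; the
#'   sign convention partial-minus-whole is fixed here);
#' * dispersion `b = cov(ebv_whole, ebv_partial) / var(ebv_partial)`, the
#'   regression of whole on partial, with expectation 1;
#' * accuracy `acc = sqrt(cov(partial, whole) / ((1 - mean_F) var_u))`,
#'   clamped to \[0, 1\].
#'
#' @param ebv_partial,ebv_whole EBV tables (`animal`, `ebv`) covering the
#'   validation animals.
#' @param validation_ids animals to evaluate.
#' @param var_u additive genetic variance used in the accuracy
#'   denominator.
#' @param mean_f mean inbreeding coefficient of the validation animals
#'   (from [inbreeding()]).
#' @return data.frame of class `lr_metrics`: `bias`, `dispersion`,
#'   `accuracy`, `n_validation`.
#' @export
lr_metrics <- function(ebv_partial, ebv_whole, validation_ids,
                       var_u, mean_f = 0) {
  ip <- match(validation_ids, ebv_partial$animal)
  iw <- match(validation_ids, ebv_whole$animal)
  if (anyNA(ip) || anyNA(iw)) {
    stop("EBV tables do not cover all validation animals")
  }
  up <- ebv_partial$ebv[ip]
  uw <- ebv_whole$ebv[iw]
  if (var(up) == 0) stop("partial EBVs have zero variance; dispersion undefined")
  acc2 <- cov(up, uw) / ((1 - mean_f) * var_u)
  out <- data.frame(bias = mean(up) - mean(uw),
                    dispersion = cov(uw, up) / var(up),
                    accuracy = sqrt(min(1, max(0, acc2))),
                    n_validation = length(validation_ids))
  class(out) <- c("lr_metrics", "data.frame")
  out
}
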