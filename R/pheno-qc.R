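#' Collapse rare top temperament categories
#'
#' Ordinal temperament is scored 1-6, but the three most temperamental
#' categories are too rare to estimate separate thresholds for; they are
#' combined into a single top category, giving scores 1-4.
#'
#' @param pheno data.frame with a `score` column of integer scores.
#' @param top_from scores at or above this value are merged into one
#'   category (default 4, i.e. 4/5/6 become 4).
#' @return list with `pheno` (valid records, scores collapsed) and
#'   `rejected` (records whose score fell outside 1-6, with a `reason`
#'   column).
#' @examples
#' collapse_scores(data.frame(score = c(1, 4, 5, 6)))$pheno$score
#' @export
collapse_scores <- function(pheno, top_from = 4L) {
  stopifnot("score" %in% names(pheno))
  bad <- is.na(pheno$score) | pheno$score < 1 | pheno$score > 6 |
    pheno$score != as.integer(pheno$score)
  rejected <- pheno[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "score outside 1-6"
  out <- pheno[!bad, , drop = FALSE]
  out$score <- pmin(as.integer(out$score), as.integer(top_from))
  list(pheno = out, rejected = rejected)
}

#' Tabulate an ordinal score distribution
#'
#' @param scores integer vector of (collapsed) scores.
#' @return data.frame with `score`, `n` and `pct` (percentage of records,
#'   rounded to one decimal).
#' @export
score_distribution <- function(scores) {
  tab <- table(scores)
  data.frame(score = as.integer(names(tab)),
             n = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(scores), 1))
}

#' Record-editing filters for ordinal temperament data
#'
#' Applies, in a fixed order, the editing rules a temperament evaluation
#' uses: (1) drop records missing any systematic effect or covariate;
#' (2) drop levels of categorical systematic effects represented by fewer
#' than `min_level_size` animals; (3) drop herds whose records all carry a
#' single score (no within-herd variability, a hallmark of evaluator
#' bias); (4) drop records outside the eligible age window (inclusive on
#' both ends).  Because removals can re-expose violations of earlier
#' rules, the sequence is repeated until no record is removed, which makes
#' the operation idempotent.
#'
#' @param pheno collapsed phenotype table.
#' @param min_level_size minimum animals per categorical-effect level.
#' @param age_window inclusive `[min, max]` age in days.
#' @param effect_cols categorical systematic-effect columns subject to the
#'   level-size rule.
#' @param covariate_cols numeric covariate columns checked for missingness.
#' @param herd_cols herd-id columns subject to the single-score rule.
#' @param age_col age column name.
#' @return list with `pheno` (surviving records) and `audit`, a data.frame
#'   of per-rule removal counts in application order (summed over passes).
#' @export
apply_filters <- function(pheno,
                          min_level_size = 3,
                          age_window = c(320, 440),
                          effect_cols = c("aod_class", "et_flag", "season"),
                          covariate_cols = "calfdev",
                          herd_cols = c("herd_birth", "herd_wean", "herd_year"),
                          age_col = "age_days") {
  effect_cols <- intersect(effect_cols, names(pheno))
  covariate_cols <- intersect(covariate_cols, names(pheno))
  herd_cols <- intersect(herd_cols, names(pheno))
  rules <- c("missing_effects", "level_size", "single_score_herd",
             "age_window")
  removed <- setNames(rep(0L, length(rules)), rules)

  repeat {
    n_before <- nrow(pheno)

    keep <- !Reduce(`|`, lapply(c(effect_cols, covariate_cols),
                                function(cl) is.na(pheno[[cl]])),
                    init = rep(FALSE, nrow(pheno)))
    removed["missing_effects"] <- removed["missing_effects"] + sum(!keep)
    pheno <- pheno[keep, , drop = FALSE]

    for (cl in effect_cols) {
      cnt <- table(pheno[[cl]])
      ok_levels <- names(cnt)[cnt >= min_level_size]
      keep <- as.character(pheno[[cl]]) %in% ok_levels
      removed["level_size"] <- removed["level_size"] + sum(!keep)
      pheno <- pheno[keep, , drop = FALSE]
    }

    for (cl in herd_cols) {
      n_scores <- tapply(pheno$score, pheno[[cl]],
                         function(s) length(unique(s)))
      bad_herds <- names(n_scores)[n_scores == 1]
      keep <- !(as.character(pheno[[cl]]) %in% bad_herds)
      removed["single_score_herd"] <- removed["single_score_herd"] +
        sum(!keep)
      pheno <- pheno[keep, , drop = FALSE]
    }

    if (age_col %in% names(pheno)) {
      keep <- pheno[[age_col]] >= age_window[1] &
        pheno[[age_col]] <= age_window[2]
      removed["age_window"] <- removed["age_window"] + sum(!keep)
      pheno <- pheno[keep, , drop = FALSE]
    }

    if (nrow(pheno) == n_before) break
    if (nrow(pheno) == 0) break
  }
  if (nrow(pheno) == 0) stop("no records survive the editing rules")
  list(pheno = pheno,
       audit = data.frame(rule = rules, removed = as.integer(removed)))
}

#' Assign contemporary-group keys
#'
#' The contemporary group is the ordered concatenation of birth month-year
#' and herd, weaning month-year and herd, creep-feeding flag, ultrasound
#' flag, yearling month-year and herd, sex, and the age-deviation group
#' (signed deviation from 365 days binned in `age_bin`-day bins).  Records
#' missing any component are dropped, consistent with the
#' missing-systematic-effect rule.
#'
#' @param pheno phenotype table carrying the component columns
#'   `date_birth`, `herd_birth`, `date_wean`, `herd_wean`, `creep`,
#'   `ultrasound`, `date_year`, `herd_year`, `sex`, `calfdev`.
#' @param age_bin width in days of the age-deviation bins.
#' @return list with `pheno` (a `cg_key` column appended) and `dropped`
#'   (records missing a component).
#' @export
build_cg <- function(pheno, age_bin = 30) {
  comp <- c("date_birth", "herd_birth", "date_wean", "herd_wean",
            "creep", "ultrasound", "date_year", "herd_year", "sex")
  miss <- setdiff(c(comp, "calfdev"), names(pheno))
  if (length(miss)) {
    stop("missing contemporary-group component columns: ",
         paste(miss, collapse = ", "))
  }
  incomplete <- Reduce(`|`, lapply(c(comp, "calfdev"),
                                   function(cl) is.na(pheno[[cl]])),
                       init = rep(FALSE, nrow(pheno)))
  dropped <- pheno[incomplete, , drop = FALSE]
  pheno <- pheno[!incomplete, , drop = FALSE]
  age_group <- floor(pheno$calfdev / age_bin)
  pheno$cg_key <- do.call(paste, c(lapply(comp, function(cl) pheno[[cl]]),
                                   list(age_group, sep = "|")))
  list(pheno = pheno, dropped = dropped)
}
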