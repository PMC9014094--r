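#' Simulate a multi-generation pedigree with sparse maternal links
#'
#' Breeds `n_generations` discrete generations from a founder population.
#' Every female of the previous generation becomes a dam and receives a
#' zero-truncated Poisson number of progeny whose mean matches
#' `progeny_per_dam_mean`, reproducing the sparse maternal family structure
#' (few progeny per dam) that makes maternal effects hard to estimate.
#' Sires are sampled with replacement from the males of the previous
#' generation, mimicking the heavy use of a few service sires.
#'
#' Founder sexes alternate male/female so that even a two-founder
#' configuration yields a breeding pair; offspring sexes are random.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `animal`, `sire`, `dam` (integer
#'   ids, `NA` for unknown), `sex` (`"M"`/`"F"`), `birth_year` and
#'   `generation` (0 for founders).  Rows are in pedigree order: parents
#'   always precede offspring.
#' @examples
#' ped <- simulate_pedigree(sim_config(n_founders = 20, n_generations = 2))
#' table(ped$generation)
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "pedigree"))
  nf <- config$n_founders

  animal <- seq_len(nf)
  sire <- rep(NA_integer_, nf)
  dam <- rep(NA_integer_, nf)
  sex <- rep(c("M", "F"), length.out = nf)
  year <- rep(config$year_start, nf)
  gen <- rep(0L, nf)

  lambda <- ztp_lambda(config$progeny_per_dam_mean)
  prev <- animal
  prev_sex <- sex
  for (g in seq_len(config$n_generations)) {
    dams <- prev[prev_sex == "F"]
    sires <- prev[prev_sex == "M"]
    if (length(dams) == 0 || length(sires) == 0) break
    counts <- rztpois(length(dams), lambda)
    n_off <- sum(counts)
    off_dam <- rep(dams, counts)
    off_sire <- sample(sires, n_off, replace = TRUE)
    off_id <- length(animal) + seq_len(n_off)
    animal <- c(animal, off_id)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    off_sex <- sample(c("M", "F"), n_off, replace = TRUE)
    sex <- c(sex, off_sex)
    year <- c(year, rep(config$year_start + g, n_off))
    gen <- c(gen, rep(g, n_off))
    prev <- off_id
    prev_sex <- off_sex
  }
  data.frame(animal = animal, sire = sire, dam = dam, sex = sex,
             birth_year = year, generation = gen)
}

# Rate of a zero-truncated Poisson with the requested mean; a mean at or
# below 1 degenerates to "exactly one progeny".
ztp_lambda <- function(mean_target) {
  if (mean_target <= 1 + 1e-9) return(0)
  uniroot(function(l) l / (1 - exp(-l)) - mean_target,
          interval = c(1e-9, 1e3), tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- rpois(length(todo), lambda)
    ok <- draw > 0
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# Basic structural validation shared by consumers of pedigree tables.
check_pedigree <- function(pedigree) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(pedigree))) {
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(pedigree$animal)) stop("duplicated animal ids in pedigree")
  idx <- match(pedigree$sire, pedigree$animal)
  if (any(!is.na(pedigree$sire) & is.na(idx))) {
    stop("sire ids not present in pedigree")
  }
  jdx <- match(pedigree$dam, pedigree$animal)
  if (any(!is.na(pedigree$dam) & is.na(jdx))) {
    stop("dam ids not present in pedigree")
  }
  row <- seq_len(nrow(pedigree))
  if (any(idx >= row, na.rm = TRUE) || any(jdx >= row, na.rm = TRUE)) {
    stop("pedigree rows must be ordered parents-before-offspring")
  }
  invisible(TRUE)
}
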