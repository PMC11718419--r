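#' Demographic parameters of the individual-based model
#'
#' Defaults follow published Eurasian lynx demography: annual natural
#' mortality 0.13, baseline kitten (first-year) mortality 0.5, litter size
#' 2.1 +/- 0.9, carrying capacity 240 adults, reproduction restricted to
#' individuals older than 2 years.  Inbreeding load enters as an expected
#' annual survival factor `exp(-B * F)` evaluated for each individual,
#' with `B` the number of haploid lethal equivalents and `F` the pedigree
#' identity-by-descent coefficient.
#'
#' @param natural_mortality annual mortality applied to every individual.
#' @param juvenile_mortality baseline first-year mortality applied to
#'   newborns right after mating, before the inbreeding-load term.
#' @param litter_mean,litter_sd litter-size distribution (rounded truncated
#'   normal, minimum 0).
#' @param lethal_equivalents haploid lethal equivalents `B`.
#' @param carrying_capacity ceiling `K`.
#' @param k_on whether `K` constrains the total census (default) or only
#'   the breeding-age count.  Under the census interpretation the standing
#'   population matches published abundance estimates for the motivating
#'   system; the adults-only interpretation allows a census well above
#'   `K`.
#' @param min_breeding_age reproduction requires `age > min_breeding_age`.
#' @param max_age individuals beyond this age are removed.
#' @param k_strategy how the ceiling is enforced: `"cap"` suppresses
#'   reproduction at `K` and removes random excess adults (forced
#'   dispersal once all territories are occupied), `"suppress"` only
#'   suppresses reproduction.
#' @return list of class `demographic_params`.
#' @export
demographic_params <- function(natural_mortality = 0.13,
                               juvenile_mortality = 0.5,
                               litter_mean = 2.1, litter_sd = 0.9,
                               lethal_equivalents = 1.1,
                               carrying_capacity = 240,
                               min_breeding_age = 2, max_age = 16,
                               k_strategy = c("cap", "suppress"),
                               k_on = c("census", "adults")) {
  stopifnot(natural_mortality >= 0, natural_mortality <= 1,
            juvenile_mortality >= 0, juvenile_mortality <= 1,
            litter_mean >= 0, litter_sd >= 0, lethal_equivalents >= 0,
            carrying_capacity > 0, max_age > min_breeding_age)
  structure(list(natural_mortality = natural_mortality,
                 juvenile_mortality = juvenile_mortality,
                 litter_mean = litter_mean, litter_sd = litter_sd,
                 lethal_equivalents = lethal_equivalents,
                 carrying_capacity = carrying_capacity,
                 min_breeding_age = min_breeding_age, max_age = max_age,
                 k_strategy = match.arg(k_strategy),
                 k_on = match.arg(k_on)),
            class = "demographic_params")
}

#' Initialise a simulated population
#'
#' Genotypes are drawn allele-wise from an allele-frequency table, sexes
#' are Bernoulli(0.5), ages follow a truncated negative binomial
#' distribution, and baseline identity-by-descent coefficients are sampled
#' from an empirical distribution (e.g. the output of founder
#' calibration).  The kinship between distinct starting residents defaults
#' to the mean of the sampled baseline F, so that matings among residents
#' reproduce the population's standing inbreeding level rather than
#' resetting it to zero.
#'
#' @param freqs [allele_freqs()] table to draw genotypes from.
#' @param n number of individuals.
#' @param baseline_f numeric vector: empirical distribution of baseline F
#'   values sampled with replacement (a single value gives a point mass;
#'   default 0).
#' @param params [demographic_params()] (for age truncation).
#' @param age_mean,age_size negative-binomial age-distribution parameters
#'   (mean and dispersion).
#' @param baseline_kinship kinship assumed between distinct starting
#'   residents; default `mean(baseline_f draws)`.
#' @param sex_ratio probability that an individual is male.
#' @return object of class `lynx_population`.
#' @export
initialize_population <- function(freqs, n, baseline_f = 0,
                                  params = demographic_params(),
                                  age_mean = 4, age_size = 2,
                                  baseline_kinship = NULL,
                                  sex_ratio = 0.5) {
  stopifnot(inherits(freqs, "allele_freqs"), n > 0)
  if (!is.numeric(baseline_f) || !length(baseline_f) ||
      any(baseline_f < 0 | baseline_f > 1)) {
    stop("baseline_f must be numeric values in [0,1]")
  }
  L <- length(freqs$freqs)
  alleles <- lapply(freqs$freqs, names)
  g1 <- matrix(0L, n, L); g2 <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    p <- freqs$freqs[[j]]
    g1[, j] <- sample.int(length(p), n, replace = TRUE, prob = p)
    g2[, j] <- sample.int(length(p), n, replace = TRUE, prob = p)
  }
  age <- stats::rnbinom(n, size = age_size, mu = age_mean)
  while (any(age > params$max_age)) {
    bad <- age > params$max_age
    age[bad] <- stats::rnbinom(sum(bad), size = age_size, mu = age_mean)
  }
  f <- if (length(baseline_f) == 1) rep(baseline_f, n) else
    sample(baseline_f, n, replace = TRUE)
  k0 <- if (is.null(baseline_kinship)) mean(f) else baseline_kinship
  K <- matrix(k0, n, n)
  diag(K) <- (1 + f) / 2
  structure(list(
    year = 0L, next_id = n + 1L,
    panel = names(freqs$freqs), alleles = alleles,
    id = seq_len(n), age = as.integer(age),
    sex = ifelse(stats::runif(n) < sex_ratio, 1L, 2L),  # 1 = M, 2 = F
    f = f, trans = rep(FALSE, n),
    g1 = g1, g2 = g2, K = K,
    ped = list(id = seq_len(n), sire = rep(NA_integer_, n),
               dam = rep(NA_integer_, n))
  ), class = "lynx_population")
}

#' Build a small founder population with declared relationships
#'
#' Used for reintroduction-from-founders calibration: a handful of
#' founders drawn from the source gene pool, with known kinships between
#' specific founder pairs (e.g. a mother-son pair and a full-sib pair).
#'
#' @param freqs source [allele_freqs()].
#' @param n_males,n_females founder counts.
#' @param founder_kinship optional matrix of kinships between founders
#'   (defaults to unrelated), or a data.frame `i, j, k` of 1-based founder
#'   indices.
#' @param ages founder ages (recycled; default adult ages 3:5).
#' @param params [demographic_params()].
#' @return `lynx_population`.
#' @export
founder_population <- function(freqs, n_males = 3, n_females = 3,
                               founder_kinship = NULL, ages = 3:5,
                               params = demographic_params()) {
  n <- n_males + n_females
  pop <- initialize_population(freqs, n, baseline_f = 0, params = params)
  pop$sex <- rep(c(1L, 2L), c(n_males, n_females))
  pop$age <- as.integer(rep_len(ages, n))
  K <- matrix(0, n, n); diag(K) <- 0.5
  if (!is.null(founder_kinship)) {
    if (is.matrix(founder_kinship)) {
      stopifnot(identical(dim(founder_kinship), dim(K)))
      K <- founder_kinship
    } else {
      K[cbind(founder_kinship$i, founder_kinship$j)] <- founder_kinship$k
      K[cbind(founder_kinship$j, founder_kinship$i)] <- founder_kinship$k
    }
  }
  pop$K <- K
  pop
}

#' @export
print.lynx_population <- function(x, ...) {
  cat("lynx_population: year", x$year, "-", length(x$id), "individuals (",
      sum(x$sex == 1L), "M /", sum(x$sex == 2L), "F ),",
      sum(x$age > 2), "adults\n")
  cat(sprintf("mean IBD F = %.4f; %d translocated-lineage individuals\n",
              mean(x$f), sum(x$trans)))
  invisible(x)
}

#' One mating season
#'
#' Every breeding-age female (age > `min_breeding_age`) mates at most once
#' with a uniformly chosen breeding-age male (males may mate repeatedly);
#' litter sizes are drawn from a rounded truncated normal
#' (`litter_mean`, `litter_sd`); offspring inherit one uniformly chosen
#' allele per locus from each parent, start at age 0 and carry
#' `F = kinship(sire, dam)`.  Reproduction is suppressed when the
#' breeding-age count has reached carrying capacity.  Returns an empty
#' cohort when either sex lacks breeding-age animals.
#'
#' @param pop `lynx_population`.
#' @param params [demographic_params()].
#' @return newborn cohort (internal list structure; pass to
#'   [survival_step()]), possibly of size 0.
#' @export
mating_step <- function(pop, params = demographic_params()) {
  stopifnot(inherits(pop, "lynx_population"))
  n <- length(pop$id)
  breeding <- pop$age > params$min_breeding_age
  males <- which(breeding & pop$sex == 1L)
  females <- which(breeding & pop$sex == 2L)
  if (!length(males) || !length(females)) {
    return(empty_cohort(pop))
  }
  at_capacity <- if (params$k_on == "census") {
    n >= params$carrying_capacity
  } else sum(breeding) >= params$carrying_capacity
  if (at_capacity) return(empty_cohort(pop))
  mate <- males[sample.int(length(males), length(females), replace = TRUE)]
  litter <- pmax(0L, as.integer(round(
    stats::rnorm(length(females), params$litter_mean, params$litter_sd))))
  if (sum(litter) == 0L) return(empty_cohort(pop))
  dam <- rep(females, litter)
  sire <- rep(mate, litter)
  nk <- length(dam); L <- length(pop$panel)

  pick <- function(gm1, gm2, idx) {
    m <- matrix(stats::runif(nk * L) < 0.5, nk, L)
    a <- gm1[idx, , drop = FALSE]
    b <- gm2[idx, , drop = FALSE]
    a[!m] <- b[!m]
    a
  }
  g1 <- pick(pop$g1, pop$g2, sire)
  g2 <- pick(pop$g1, pop$g2, dam)

  Krows <- (pop$K[sire, , drop = FALSE] + pop$K[dam, , drop = FALSE]) / 2
  Kblock <- (Krows[, sire, drop = FALSE] + Krows[, dam, drop = FALSE]) / 2
  f <- pop$K[cbind(sire, dam)]
  diag(Kblock) <- (1 + f) / 2
  Kblock <- (Kblock + t(Kblock)) / 2

  list(n = nk,
       id = pop$next_id + seq_len(nk) - 1L,
       sex = ifelse(stats::runif(nk) < 0.5, 1L, 2L),
       f = f,
       trans = pop$trans[sire] | pop$trans[dam],
       sire_id = pop$id[sire], dam_id = pop$id[dam],
       g1 = g1, g2 = g2, Krows = Krows, Kblock = Kblock)
}

empty_cohort <- function(pop) {
  list(n = 0L, id = integer(0), sex = integer(0), f = numeric(0),
       trans = logical(0), sire_id = integer(0), dam_id = integer(0),
       g1 = matrix(0L, 0, length(pop$panel)),
       g2 = matrix(0L, 0, length(pop$panel)),
       Krows = matrix(0, 0, length(pop$id)), Kblock = matrix(0, 0, 0))
}

#' One survival year
#'
#' Newborns first face the baseline juvenile mortality
#' (survival `1 - juvenile_mortality`); every individual, newborns
#' included, then survives the year with probability
#' `(1 - natural_mortality) * exp(-B * F)` -- the inbreeding-load factor
#' is an expected survival probability evaluated per individual from its
#' identity-by-descent coefficient and realised as an independent
#' Bernoulli event each year.  Individuals beyond `max_age` are removed
#' and survivors age by one year.  Under the `"cap"` strategy random
#' excess breeding-age animals above `K` are also removed.
#'
#' @param pop `lynx_population`.
#' @param cohort newborn cohort from [mating_step()].
#' @param params [demographic_params()].
#' @return updated `lynx_population` (year advanced by 1).
#' @export
survival_step <- function(pop, cohort = empty_cohort(pop),
                          params = demographic_params()) {
  stopifnot(inherits(pop, "lynx_population"))
  n <- length(pop$id)
  ## baseline juvenile mortality of newborns
  nb_alive <- stats::runif(cohort$n) < (1 - params$juvenile_mortality)
  ## annual natural mortality plus inbreeding-load survival for everyone
  B <- params$lethal_equivalents
  old_alive <- stats::runif(n) <
    (1 - params$natural_mortality) * exp(-B * pop$f)
  nb_alive[nb_alive] <- stats::runif(sum(nb_alive)) <
    (1 - params$natural_mortality) * exp(-B * cohort$f[nb_alive])
  old_alive <- old_alive & (pop$age + 1L) <= params$max_age

  keep_old <- which(old_alive); keep_nb <- which(nb_alive)
  new_n <- length(keep_old) + length(keep_nb)
  K <- matrix(0, new_n, new_n)
  io <- seq_along(keep_old); ib <- length(keep_old) + seq_along(keep_nb)
  K[io, io] <- pop$K[keep_old, keep_old]
  if (length(keep_nb)) {
    K[ib, io] <- cohort$Krows[keep_nb, keep_old, drop = FALSE]
    K[io, ib] <- t(K[ib, io, drop = FALSE])
    K[ib, ib] <- cohort$Kblock[keep_nb, keep_nb, drop = FALSE]
    pop$ped$id <- c(pop$ped$id, cohort$id[keep_nb])
    pop$ped$sire <- c(pop$ped$sire, cohort$sire_id[keep_nb])
    pop$ped$dam <- c(pop$ped$dam, cohort$dam_id[keep_nb])
  }
  pop$id <- c(pop$id[keep_old], cohort$id[keep_nb])
  pop$age <- c(pop$age[keep_old] + 1L, rep(1L, length(keep_nb)))
  pop$sex <- c(pop$sex[keep_old], cohort$sex[keep_nb])
  pop$f <- c(pop$f[keep_old], cohort$f[keep_nb])
  pop$trans <- c(pop$trans[keep_old], cohort$trans[keep_nb])
  pop$g1 <- rbind(pop$g1[keep_old, , drop = FALSE],
                  cohort$g1[keep_nb, , drop = FALSE])
  pop$g2 <- rbind(pop$g2[keep_old, , drop = FALSE],
                  cohort$g2[keep_nb, , drop = FALSE])
  pop$K <- K
  pop$next_id <- pop$next_id + cohort$n
  pop$year <- pop$year + 1L

  if (params$k_strategy == "cap") {
    pool <- if (params$k_on == "census") seq_along(pop$id) else
      which(pop$age > params$min_breeding_age)
    excess <- length(pool) - params$carrying_capacity
    if (excess > 0) {
      drop <- pool[sample.int(length(pool), excess)]
      pop <- drop_individuals(pop, drop)
    }
  }
  pop
}

drop_individuals <- function(pop, idx) {
  keep <- setdiff(seq_along(pop$id), idx)
  for (fld in c("id", "age", "sex", "f", "trans")) {
    pop[[fld]] <- pop[[fld]][keep]
  }
  pop$g1 <- pop$g1[keep, , drop = FALSE]
  pop$g2 <- pop$g2[keep, , drop = FALSE]
  pop$K <- pop$K[keep, keep, drop = FALSE]
  pop
}

#' Translocate individuals into a population
#'
#' Adds `n_males + n_females` adults (ages drawn uniformly from
#' `age_range`) with genotypes sampled allele-wise from the source
#' frequency table.  Translocated animals enter as pedigree founders:
#' `F = 0`, unrelated to all residents, `translocated_lineage = TRUE`
#' (inherited by their descendants).  Alleles absent from the resident
#' gene pool are added to the locus allele registries.
#'
#' @param pop `lynx_population`.
#' @param n_males,n_females numbers of translocated males and females.
#' @param source source [allele_freqs()]; locus set must match the panel.
#' @param age_range inclusive age range of translocated animals.
#' @return updated `lynx_population`.
#' @export
translocate <- function(pop, n_males, n_females, source,
                        age_range = c(2, 4)) {
  stopifnot(inherits(pop, "lynx_population"), inherits(source, "allele_freqs"),
            n_males >= 0, n_females >= 0)
  m <- n_males + n_females
  if (m == 0) return(pop)
  if (!setequal(names(source$freqs), pop$panel)) {
    stop("source locus set does not match the population panel")
  }
  L <- length(pop$panel)
  g1 <- matrix(0L, m, L); g2 <- matrix(0L, m, L)
  for (j in seq_len(L)) {
    loc <- pop$panel[j]
    p <- source$freqs[[loc]]
    new_alleles <- setdiff(names(p), pop$alleles[[loc]])
    if (length(new_alleles)) {
      pop$alleles[[loc]] <- c(pop$alleles[[loc]], new_alleles)
    }
    codes <- match(names(p), pop$alleles[[loc]])
    g1[, j] <- codes[sample.int(length(p), m, replace = TRUE, prob = p)]
    g2[, j] <- codes[sample.int(length(p), m, replace = TRUE, prob = p)]
  }
  n <- length(pop$id)
  K <- matrix(0, n + m, n + m)
  K[seq_len(n), seq_len(n)] <- pop$K
  diag(K)[n + seq_len(m)] <- 0.5
  ids <- pop$next_id + seq_len(m) - 1L
  pop$K <- K
  pop$id <- c(pop$id, ids)
  pop$age <- c(pop$age, sample(seq(age_range[1], age_range[2]), m,
                               replace = TRUE))
  pop$sex <- c(pop$sex, rep(c(1L, 2L), c(n_males, n_females)))
  pop$f <- c(pop$f, rep(0, m))
  pop$trans <- c(pop$trans, rep(TRUE, m))
  pop$g1 <- rbind(pop$g1, g1)
  pop$g2 <- rbind(pop$g2, g2)
  pop$ped$id <- c(pop$ped$id, ids)
  pop$ped$sire <- c(pop$ped$sire, rep(NA_integer_, m))
  pop$ped$dam <- c(pop$ped$dam, rep(NA_integer_, m))
  pop$next_id <- pop$next_id + m
  pop
}

#' Extract the accumulated pedigree of a simulated population
#'
#' @param pop `lynx_population`.
#' @return [pedigree()] of every recorded individual (initial residents and
#'   translocated animals are founders).
#' @export
sim_pedigree <- function(pop) {
  stopifnot(inherits(pop, "lynx_population"))
  pedigree(pop$ped$id, pop$ped$sire, pop$ped$dam)
}

## per-population genotype call matrices with allele labels (for ld_ne etc.)
sim_genotype_matrices <- function(pop, idx = seq_along(pop$id)) {
  L <- length(pop$panel)
  a1 <- matrix(NA_character_, length(idx), L,
               dimnames = list(NULL, pop$panel))
  a2 <- a1
  for (j in seq_len(L)) {
    a1[, j] <- pop$alleles[[j]][pop$g1[idx, j]]
    a2[, j] <- pop$alleles[[j]][pop$g2[idx, j]]
  }
  list(a1 = a1, a2 = a2)
}

#' Export a simulated population as a genotype dataset
#'
#' @param pop `lynx_population`.
#' @param population population label for the records.
#' @param idx optional row indices (default all living individuals).
#' @param year sampling year to record (default the population year).
#' @return [genotype_dataset()].
#' @export
as_genotype_dataset <- function(pop, population = "simulated",
                                idx = seq_along(pop$id), year = pop$year) {
  g <- sim_genotype_matrices(pop, idx)
  info <- data.frame(
    individual_id = paste0("sim", pop$id[idx]),
    population = population, year = as.integer(year),
    sex = c("M", "F")[pop$sex[idx]],
    translocated = pop$trans[idx], stringsAsFactors = FALSE)
  genotype_dataset(info, g$a1, g$a2)
}

## population-level summary statistics for one year
pop_metrics <- function(pop, source_he = NA_real_, compute_ne = FALSE,
                        ne_sample = 50, maf = 0.02) {
  n <- length(pop$id)
  if (n == 0) {
    return(data.frame(census = 0L, adults = 0L, ho = NA_real_, he = NA_real_,
                      fe = NA_real_, ibd = NA_real_, ne = NA_real_))
  }
  ho <- mean(colMeans(pop$g1 != pop$g2))
  hexp <- mean(vapply(seq_along(pop$panel), function(j) {
    p <- tabulate(c(pop$g1[, j], pop$g2[, j])) / (2 * n)
    1 - sum(p^2)
  }, numeric(1)))
  ne <- NA_real_
  if (compute_ne) {
    adults <- which(pop$age > 2)
    pool <- if (length(adults) >= 10) adults else seq_len(n)
    idx <- if (length(pool) > ne_sample) {
      pool[sample.int(length(pool), ne_sample)]
    } else pool
    ne <- tryCatch(ld_ne(list(g1 = NULL,
                              a1 = pop$g1[idx, , drop = FALSE],
                              a2 = pop$g2[idx, , drop = FALSE]),
                         maf = maf)$ne,
                   error = function(e) NA_real_)
  }
  data.frame(census = n, adults = sum(pop$age > 2),
             ho = ho, he = hexp,
             fe = if (is.na(source_he)) NA_real_ else
               effective_inbreeding(hexp, source_he),
             ibd = mean(pop$f), ne = ne)
}

is_extinct <- function(pop) {
  length(pop$id) == 0 || !any(pop$sex == 1L) || !any(pop$sex == 2L)
}
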