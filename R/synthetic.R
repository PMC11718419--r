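#' Generate a synthetic source allele-frequency table
#'
#' Per-locus allele frequencies are drawn from a symmetric Dirichlet and
#' then tempered (`p^t`, renormalised, with `t` found by bisection) until
#' the mean expected heterozygosity matches a target, emulating a diverse
#' Carpathian-like source population (defaults: 19 microsatellite loci,
#' 2-6 alleles per locus, mean He 0.583).
#'
#' @param n_loci number of loci.
#' @param alleles_range inclusive range of alleles per locus (sampled
#'   uniformly).
#' @param he_target target mean expected heterozygosity.
#' @param he_tol acceptable deviation of the realised mean He.
#' @param concentration Dirichlet concentration (1 gives realistically
#'   skewed frequencies).
#' @param population label for the table.
#' @param seed optional RNG seed.
#' @return [allele_freqs()].
#' @export
generate_source_frequencies <- function(n_loci = 19,
                                        alleles_range = c(2, 6),
                                        he_target = 0.583, he_tol = 0.02,
                                        concentration = 1,
                                        population = "source",
                                        seed = NULL) {
  stopifnot(he_target > 0, he_target < 1, n_loci > 0)
  if (!is.null(seed)) set.seed(seed)
  ks <- seq(alleles_range[1], alleles_range[2])
  k <- ks[sample.int(length(ks), n_loci, replace = TRUE)]
  raw <- lapply(k, function(ki) {
    g <- stats::rgamma(ki, shape = concentration)
    g / sum(g)
  })
  mean_he <- function(t) {
    mean(vapply(raw, function(p) {
      q <- p^t; q <- q / sum(q); 1 - sum(q^2)
    }, numeric(1)))
  }
  if (mean_he(0) < he_target - he_tol) {
    stop("He target ", he_target, " unattainable: equifrequent maximum is ",
         round(mean_he(0), 3), " for the drawn allele counts")
  }
  lo <- 0; hi <- 1
  while (mean_he(hi) > he_target && hi < 64) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mean_he(mid) > he_target) lo <- mid else hi <- mid
  }
  t_star <- (lo + hi) / 2
  freqs <- lapply(raw, function(p) {
    q <- p^t_star; q <- q / sum(q)
    stats::setNames(q, as.character(seq_along(q)))
  })
  names(freqs) <- sprintf("loc%02d", seq_len(n_loci))
  out <- allele_freqs(population, freqs, n_source = NA_integer_)
  if (abs(expected_het_freqs(out) - he_target) > he_tol) {
    stop("could not reach He target within tolerance")
  }
  out
}

#' Default founder relationships of a six-animal reintroduction
#'
#' One mother-son pair and one full-sib pair among the six founders
#' (kinship 0.25 each), all other pairs unrelated.
#'
#' @return data.frame `i, j, k` of founder indices and kinships, suitable
#'   for [founder_population()].
#' @export
default_founder_kinship <- function() {
  data.frame(i = c(1L, 2L), j = c(4L, 3L), k = c(0.25, 0.25))
}

#' Simulate a bottlenecked, drifted descendant population
#'
#' Runs the individual-based model from a handful of founders sampled from
#' a source gene pool (by default six animals containing a mother-son pair
#' and a full-sib pair) and collects dated genotype samples along the way,
#' emulating the longitudinal monitoring record of a reintroduced
#' population: heterozygosity decays and effective inbreeding against the
#' source grows with time.
#'
#' @param source source [allele_freqs()].
#' @param n_founders number of founders (half male, half female).
#' @param founder_kinship declared founder kinships (see
#'   [founder_population()]); default [default_founder_kinship()] when six
#'   founders are used, otherwise none.
#' @param years years of drift to simulate.
#' @param sample_years years (1-based) at which monitoring samples are
#'   taken.
#' @param sample_sizes individuals newly sampled per sampling year
#'   (recycled).
#' @param start_year calendar year of the founding event (sampling dates
#'   are `start_year + sample_years`).
#' @param population label for sampled records.
#' @param params [demographic_params()].
#' @param seed optional RNG seed.
#' @return list with `dataset` ([genotype_dataset()] of the samples;
#'   individuals are sampled at most once), `pedigree` (full simulation
#'   pedigree), `population` (final `lynx_population`) and `extinct`
#'   (logical; when `TRUE` the dataset is partial).
#' @export
generate_drifted_population <- function(source, n_founders = 6,
                                        founder_kinship = NULL,
                                        years = 45,
                                        sample_years = 6:years,
                                        sample_sizes = 3,
                                        start_year = 1973,
                                        population = "Dinaric",
                                        params = demographic_params(),
                                        seed = NULL) {
  stopifnot(inherits(source, "allele_freqs"), n_founders >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(founder_kinship) && n_founders == 6) {
    founder_kinship <- default_founder_kinship()
  }
  pop <- founder_population(source, n_males = ceiling(n_founders / 2),
                            n_females = floor(n_founders / 2),
                            founder_kinship = founder_kinship,
                            params = params)
  sizes <- rep_len(sample_sizes, length(sample_years))
  sampled <- integer(0)
  chunks <- list()
  extinct <- FALSE
  for (t in seq_len(years)) {
    pop <- survival_step(pop, mating_step(pop, params), params)
    if (is_extinct(pop)) { extinct <- TRUE; break }
    if (t %in% sample_years) {
      size <- sizes[match(t, sample_years)]
      avail <- which(!(pop$id %in% sampled))
      if (length(avail)) {
        take <- avail[sample.int(length(avail), min(size, length(avail)))]
        sampled <- c(sampled, pop$id[take])
        chunks[[length(chunks) + 1L]] <-
          as_genotype_dataset(pop, population = population, idx = take,
                              year = start_year + t)
      }
    }
  }
  dataset <- if (length(chunks)) do.call(rbind_datasets, chunks) else NULL
  list(dataset = dataset, pedigree = sim_pedigree(pop), population = pop,
       extinct = extinct)
}

## concatenate genotype datasets sharing a panel
rbind_datasets <- function(...) {
  xs <- list(...)
  panel <- xs[[1]]$panel
  stopifnot(all(vapply(xs, function(x) identical(x$panel, panel), TRUE)))
  genotype_dataset(do.call(rbind, lapply(xs, `[[`, "info")),
                   do.call(rbind, lapply(xs, `[[`, "a1")),
                   do.call(rbind, lapply(xs, `[[`, "a2")))
}

#' Pedigrees with analytically known inbreeding coefficients
#'
#' Builds small test pedigrees whose focal individuals have textbook F
#' values, or a random acyclic pedigree.  The expected F values are
#' attached as the `expected_f` attribute (named by individual).
#'
#' @param pattern `"full-sib"`, `"parent-offspring"`, `"cousins"` or
#'   `"random"`.
#' @param n size of the random pedigree (founders plus descendants).
#' @param n_founders founders of the random pedigree.
#' @param seed optional RNG seed.
#' @return [pedigree()] with attribute `expected_f` (absent for
#'   `"random"`).
#' @export
generate_test_pedigree <- function(pattern = c("full-sib",
                                               "parent-offspring",
                                               "cousins", "random"),
                                   n = 30, n_founders = 8, seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is.null(seed)) set.seed(seed)
  if (pattern == "full-sib") {
    p <- pedigree(id = c("a", "b", "s1", "s2", "x"),
                  sire = c(NA, NA, "a", "a", "s1"),
                  dam = c(NA, NA, "b", "b", "s2"))
    attr(p, "expected_f") <- c(x = 0.25)
  } else if (pattern == "parent-offspring") {
    p <- pedigree(id = c("a", "b", "o", "x"),
                  sire = c(NA, NA, "a", "a"),
                  dam = c(NA, NA, "b", "o"))
    attr(p, "expected_f") <- c(x = 0.25)
  } else if (pattern == "cousins") {
    p <- pedigree(
      id = c("g1", "g2", "u1", "u2", "p1", "p2", "c1", "c2", "x"),
      sire = c(NA, NA, NA, NA, "g1", "g1", "u1", "u2", "c1"),
      dam = c(NA, NA, NA, NA, "g2", "g2", "p1", "p2", "c2"))
    attr(p, "expected_f") <- c(x = 0.0625)
  } else {
    stopifnot(n > n_founders, n_founders >= 2)
    id <- paste0("r", seq_len(n))
    sire <- rep(NA_character_, n); dam <- rep(NA_character_, n)
    for (i in (n_founders + 1):n) {
      par <- sample(i - 1L, 2L)
      sire[i] <- id[par[1]]; dam[i] <- id[par[2]]
    }
    p <- pedigree(id, sire, dam)
  }
  p
}

#' Generate a synthetic three-population study dataset
#'
#' A self-contained stand-in for a real longitudinal monitoring dataset:
#' a diverse source population ("Slovakia", mean He ~0.58), a second,
#' differentiated source ("Romania", He ~0.55), and a reintroduced,
#' bottlenecked population ("Dinaric") descended from six partially
#' related founders with ~45 years of drift, sampled longitudinally.
#' Optionally the 12-animal reinforcement is simulated and the
#' post-reinforcement years are sampled as well, with translocated
#' lineages flagged.
#'
#' @param seed RNG seed.
#' @param n_source,n_source2 sample sizes for the two source populations.
#' @param reinforcement simulate the 12-animal 5-year reinforcement and
#'   sample three post-reinforcement seasons?
#' @param params [demographic_params()].
#' @return list with `dataset` (combined [genotype_dataset()]),
#'   `slovakia`, `romania` ([allele_freqs()] the sources were drawn
#'   from), `dinaric_freqs` (frequencies realised in the drifted
#'   population at the end), `baseline_f` (IBD coefficients of the living
#'   drifted population) and `population` (final `lynx_population`).
#' @export
generate_study_dataset <- function(seed = 1, n_source = 48, n_source2 = 22,
                                   reinforcement = TRUE,
                                   params = demographic_params()) {
  set.seed(seed)
  slovakia <- generate_source_frequencies(population = "Slovakia",
                                          he_target = 0.583)
  romania <- generate_source_frequencies(population = "Romania",
                                         he_target = 0.545)
  ## source samples: adults drawn straight from the source gene pools
  sample_source <- function(freqs, n, label, years) {
    p <- initialize_population(freqs, n)
    d <- as_genotype_dataset(p, population = label)
    d$info$year <- sample(years, n, replace = TRUE)
    d$info$individual_id <- paste0(label, seq_len(n))
    genotype_dataset(d$info, d$a1, d$a2)
  }
  sk <- sample_source(slovakia, n_source, "Slovakia", 2002:2019)
  ro <- sample_source(romania, n_source2, "Romania", 2002:2019)

  ## condition on persistence, as the observed history does: the real
  ## reintroduced population survived its founding bottleneck
  drift <- NULL
  for (attempt in 1:100) {
    cand <- generate_drifted_population(slovakia, years = 45,
                                        sample_years = 6:45,
                                        sample_sizes = c(3, 4),
                                        params = params)
    if (!cand$extinct && length(cand$population$id) >= 10 &&
          !is.null(cand$dataset) && nrow(cand$dataset$info) >= 80) {
      drift <- cand; break
    }
  }
  if (is.null(drift)) stop("no surviving drifted population in 100 attempts")
  din <- drift$dataset
  pop <- drift$population
  chunks <- list(din)
  if (reinforcement && !drift$extinct) {
    sched <- reinforcement_schedule()
    sampled <- as.integer(sub("^sim", "", din$info$individual_id))
    for (t in 1:3) {
      ev <- sched[sched$year == t, , drop = FALSE]
      for (e in seq_len(nrow(ev))) {
        src <- if (ev$source[e] == "Slovakia") slovakia else romania
        pop <- translocate(pop, ev$n_males[e], ev$n_females[e], src)
      }
      pop <- survival_step(pop, mating_step(pop, params), params)
      avail <- which(!(pop$id %in% sampled))
      take <- avail[sample.int(length(avail), min(15, length(avail)))]
      sampled <- c(sampled, pop$id[take])
      chunks[[length(chunks) + 1L]] <-
        as_genotype_dataset(pop, population = "Dinaric", idx = take,
                            year = 2018 + t)
    }
  }
  dataset <- do.call(rbind_datasets, c(chunks, list(sk, ro)))
  list(dataset = dataset, slovakia = slovakia, romania = romania,
       dinaric_freqs = compute_allele_frequencies(
         as_genotype_dataset(drift$population)),
       baseline_f = drift$population$f,
       population = pop)
}
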