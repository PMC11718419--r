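#' Observed heterozygosity
#'
#' Per-locus proportion of scored individuals that are heterozygous, with
#' the mean over loci and its standard error (sd across loci / sqrt(L)).
#'
#' @param dataset genotype_dataset.
#' @param population optional population label.
#' @param loci optional locus subset.
#' @return list with `per_locus`, `mean`, `se`, `n` (individuals used).
#' @export
observed_heterozygosity <- function(dataset, population = NULL, loci = NULL) {
  d <- select_pop(dataset, population, loci)
  per_locus <- vapply(d$panel, function(loc) {
    scored <- !is.na(d$a1[, loc])
    if (!any(scored)) return(NA_real_)
    mean(d$a1[scored, loc] != d$a2[scored, loc])
  }, numeric(1))
  summarise_loci(per_locus, nrow(d$info))
}

#' Nei's unbiased expected heterozygosity
#'
#' Per-locus `(2n/(2n-1)) * (1 - sum(p_i^2))` where `n` is the number of
#' individuals scored at the locus and `p_i` the sample allele frequencies.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus`, `mean`, `se`, `n`.
#' @export
expected_heterozygosity_nei <- function(dataset, population = NULL,
                                        loci = NULL) {
  d <- select_pop(dataset, population, loci)
  per_locus <- vapply(d$panel, function(loc) {
    calls <- c(d$a1[, loc], d$a2[, loc])
    calls <- calls[!is.na(calls)]
    if (!length(calls)) {
      warning("locus '", loc, "' has no scored genotypes; skipped")
      return(NA_real_)
    }
    n <- length(calls) / 2
    p <- as.numeric(table(calls)) / length(calls)
    (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  }, numeric(1))
  if (all(is.na(per_locus))) stop("all loci unscored")
  summarise_loci(per_locus, nrow(d$info))
}

#' Allelic diversity
#'
#' Number of distinct observed alleles per locus, with mean and SE over
#' loci.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus`, `mean`, `se`, `n`.
#' @export
allelic_diversity <- function(dataset, population = NULL, loci = NULL) {
  d <- select_pop(dataset, population, loci)
  per_locus <- vapply(d$panel, function(loc) {
    calls <- c(d$a1[, loc], d$a2[, loc])
    calls <- calls[!is.na(calls)]
    if (!length(calls)) return(NA_real_)
    length(unique(calls))
  }, numeric(1))
  summarise_loci(per_locus, nrow(d$info))
}

#' Diversity summary for one population
#'
#' Bundles observed heterozygosity (Ho), Nei's unbiased expected
#' heterozygosity (He) and allelic diversity (A), each as mean +/- SE over
#' loci.
#'
#' @inheritParams observed_heterozygosity
#' @return object of class `diversity_summary`.
#' @export
diversity_summary <- function(dataset, population = NULL, loci = NULL) {
  structure(list(
    population = if (is.null(population)) "all" else population,
    n = nrow(select_pop(dataset, population, loci)$info),
    ho = observed_heterozygosity(dataset, population, loci),
    he = expected_heterozygosity_nei(dataset, population, loci),
    a = allelic_diversity(dataset, population, loci)
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("population %s (n = %d individuals)\n", x$population, x$n))
  cat(sprintf("  He = %.3f +/- %.3f\n", x$he$mean, x$he$se))
  cat(sprintf("  Ho = %.3f +/- %.3f\n", x$ho$mean, x$ho$se))
  cat(sprintf("  A  = %.2f +/- %.3f\n", x$a$mean, x$a$se))
  invisible(x)
}

#' Effective inbreeding relative to a source population
#'
#' Drift inbreeding of a derived population measured against its source
#' gene pool: `Fe = 1 - h_target / h_source`.  Negative values indicate the
#' target is currently more heterozygous than the source (e.g. a Wahlund
#' excess right after admixture).
#'
#' @param h_target heterozygosity of the focal (derived) population.
#' @param h_source heterozygosity of the source population (> 0).
#' @return Fe, a scalar `<= 1`.
#' @examples
#' effective_inbreeding(0.457, 0.583)
#' @export
effective_inbreeding <- function(h_target, h_source) {
  stopifnot(is.numeric(h_target), is.numeric(h_source))
  if (any(h_source <= 0)) stop("Fe undefined for h_source = 0")
  if (any(h_target < 0 | h_target > 1) || any(h_source > 1)) {
    stop("heterozygosities must lie in [0,1]")
  }
  1 - h_target / h_source
}

#' Multilocus Fis
#'
#' Within-population inbreeding coefficient `1 - Ho/He` from multilocus
#' mean observed and Nei-unbiased expected heterozygosity.
#'
#' @inheritParams observed_heterozygosity
#' @return scalar Fis.
#' @export
fis <- function(dataset, population = NULL, loci = NULL) {
  he <- expected_heterozygosity_nei(dataset, population, loci)$mean
  if (he <= 0) stop("Fis undefined: He = 0")
  ho <- observed_heterozygosity(dataset, population, loci)$mean
  1 - ho / he
}

select_pop <- function(dataset, population, loci) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  d <- subset_genotypes(dataset, population = population, loci = loci)
  if (nrow(d$info) == 0) stop("empty population selection")
  d
}

summarise_loci <- function(per_locus, n) {
  ok <- per_locus[!is.na(per_locus)]
  list(per_locus = per_locus, mean = mean(ok),
       se = stats::sd(ok) / sqrt(length(ok)), n = n)
}
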