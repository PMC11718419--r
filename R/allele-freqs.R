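#' Allele-frequency table
#'
#' Per-locus allele frequency maps for a named population, used to seed
#' simulated genotypes and as the reference gene pool for effective
#' inbreeding.
#'
#' @param population population label.
#' @param freqs named list; one element per locus, each a named numeric
#'   vector of allele frequencies summing to 1.
#' @param n_source number of individuals the frequencies were estimated
#'   from (`NA` if unknown).
#' @return object of class `allele_freqs`.
#' @export
allele_freqs <- function(population, freqs, n_source = NA_integer_) {
  stopifnot(is.list(freqs), length(freqs) > 0)
  if (is.null(names(freqs)) || any(!nzchar(names(freqs)))) {
    stop("freqs must be a named list of loci")
  }
  for (loc in names(freqs)) {
    f <- freqs[[loc]]
    if (is.null(names(f)) || any(!nzchar(names(f)))) {
      stop("alleles at locus '", loc, "' must be named")
    }
    if (any(f < 0 | f > 1)) stop("frequencies outside [0,1] at locus '", loc, "'")
    if (abs(sum(f) - 1) > 1e-9) {
      stop("frequencies at locus '", loc, "' sum to ", sum(f), ", not 1")
    }
  }
  structure(list(population = as.character(population), freqs = freqs,
                 n_source = as.integer(n_source)),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  na <- vapply(x$freqs, length, 1L)
  cat("allele_freqs for population '", x$population, "': ",
      length(x$freqs), " loci, ", round(mean(na), 2),
      " alleles/locus (n_source = ", x$n_source, ")\n", sep = "")
  cat("mean expected heterozygosity:",
      round(mean(vapply(x$freqs, function(f) 1 - sum(f^2), 1)), 4), "\n")
  invisible(x)
}

#' Estimate allele frequencies from genotypes
#'
#' Frequency of allele a at locus l is its call count over twice the number
#' of individuals scored at l.
#'
#' @param dataset genotype_dataset.
#' @param population population label to use (default: all records).
#' @return [allele_freqs()].
#' @export
compute_allele_frequencies <- function(dataset, population = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!is.null(population)) {
    dataset <- subset_genotypes(dataset, population = population)
  } else {
    population <- paste(unique(dataset$info$population), collapse = "+")
  }
  if (nrow(dataset$info) == 0) stop("no records for population ", population)
  freqs <- lapply(dataset$panel, function(loc) {
    calls <- c(dataset$a1[, loc], dataset$a2[, loc])
    calls <- calls[!is.na(calls)]
    if (!length(calls)) {
      stop("locus '", loc, "' has no scored genotypes in population ",
           population)
    }
    tab <- table(calls)
    stats::setNames(as.numeric(tab) / length(calls), names(tab))
  })
  names(freqs) <- dataset$panel
  allele_freqs(population, freqs, n_source = nrow(dataset$info))
}

#' Read / write allele-frequency tables
#'
#' CSV with columns `population, locus, allele, frequency` (plus optional
#' `n_source`).  Frequencies at each locus must sum to 1 within 1e-6; they
#' are renormalised to machine precision on read.
#'
#' @param path file path.
#' @return [allele_freqs()].
#' @export
read_allele_frequencies <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "locus", "allele", "frequency")
  if (!all(need %in% names(d))) {
    stop("allele-frequency file needs columns: ", paste(need, collapse = ", "))
  }
  pop <- unique(d$population)
  if (length(pop) != 1) stop("expected a single population, found: ",
                             paste(pop, collapse = ", "))
  freqs <- lapply(split(d, factor(d$locus, levels = unique(d$locus))),
                  function(g) {
    f <- stats::setNames(as.numeric(g$frequency), as.character(g$allele))
    if (abs(sum(f) - 1) > 1e-6) {
      stop("frequencies at locus '", g$locus[1], "' sum to ", sum(f))
    }
    f / sum(f)
  })
  n_source <- if ("n_source" %in% names(d)) d$n_source[1] else NA_integer_
  allele_freqs(pop, freqs, n_source)
}

#' @rdname read_allele_frequencies
#' @param x allele_freqs object.
#' @export
write_allele_frequencies <- function(x, path) {
  stopifnot(inherits(x, "allele_freqs"))
  rows <- do.call(rbind, lapply(names(x$freqs), function(loc) {
    data.frame(population = x$population, locus = loc,
               allele = names(x$freqs[[loc]]),
               frequency = unname(x$freqs[[loc]]),
               n_source = x$n_source, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## plain expected heterozygosity of a frequency table (population parameter)
expected_het_freqs <- function(freqs) {
  mean(vapply(freqs$freqs, function(f) 1 - sum(f^2), numeric(1)))
}
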