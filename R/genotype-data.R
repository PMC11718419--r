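#' Multilocus genotype dataset
#'
#' Container for individual-by-locus diploid microsatellite calls with
#' sample metadata.  Alleles are opaque labels; a genotype at a locus is an
#' unordered pair of labels or missing (both calls absent -- half-calls are
#' rejected).
#'
#' @param info data.frame with columns `individual_id`, `population`,
#'   `year` (integer sampling year), `sex` (`"M"`, `"F"` or `"U"`) and
#'   `translocated` (logical: translocated individual or descendant of one).
#' @param a1,a2 character matrices (individuals x loci) holding the two
#'   allele calls per locus; `NA` marks a missing call.  Column names are
#'   the marker panel.
#' @return An object of class `genotype_dataset` with elements `panel`
#'   (ordered locus names), `info`, `a1` and `a2`.
#' @examples
#' info <- data.frame(individual_id = c("i1", "i2"), population = "P",
#'                    year = 2000L, sex = "U", translocated = FALSE)
#' a1 <- matrix(c("A", "A"), 2, 1, dimnames = list(NULL, "loc1"))
#' a2 <- matrix(c("A", "B"), 2, 1, dimnames = list(NULL, "loc1"))
#' gd <- genotype_dataset(info, a1, a2)
#' @export
genotype_dataset <- function(info, a1, a2) {
  stopifnot(is.data.frame(info), is.matrix(a1), is.matrix(a2))
  required <- c("individual_id", "population", "year", "sex", "translocated")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols)) {
    stop("info is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(info$individual_id)) {
    dup <- unique(info$individual_id[duplicated(info$individual_id)])
    stop("duplicate individual_id: ", paste(dup, collapse = ", "))
  }
  if (!identical(dim(a1), dim(a2))) stop("a1 and a2 dimensions differ")
  if (nrow(a1) != nrow(info)) stop("genotype matrices do not match info rows")
  if (is.null(colnames(a1))) stop("genotype matrices need locus column names")
  if (anyDuplicated(colnames(a1))) stop("duplicate locus names in panel")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop("half-called genotype for individual '",
         info$individual_id[idx[1]], "' at locus '", colnames(a1)[idx[2]], "'")
  }
  mode(a1) <- "character"
  mode(a2) <- "character"
  colnames(a2) <- colnames(a1)
  info$individual_id <- as.character(info$individual_id)
  info$population <- as.character(info$population)
  info$year <- as.integer(info$year)
  info$sex <- as.character(info$sex)
  info$translocated <- as.logical(info$translocated)
  rownames(info) <- NULL
  structure(list(panel = colnames(a1), info = info, a1 = a1, a2 = a2),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$info), "individuals,",
      length(x$panel), "loci\n")
  tab <- table(x$info$population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  yrs <- range(x$info$year, na.rm = TRUE)
  cat("sampling years:", yrs[1], "-", yrs[2], "\n")
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  pops <- sort(unique(object$info$population))
  do.call(rbind, lapply(pops, function(p) {
    d <- diversity_summary(object, p)
    data.frame(population = p, n = d$n, He = d$he$mean, Ho = d$ho$mean,
               A = d$a$mean)
  }))
}

#' Subset a genotype dataset
#'
#' @param x genotype_dataset.
#' @param population optional population label(s) to keep.
#' @param from_year,to_year optional inclusive sampling-year bounds.
#' @param include_translocated if `FALSE`, translocated individuals and
#'   their descendants are dropped.
#' @param loci optional subset of panel loci.
#' @return genotype_dataset.
#' @export
subset_genotypes <- function(x, population = NULL, from_year = NULL,
                             to_year = NULL, include_translocated = TRUE,
                             loci = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  keep <- rep(TRUE, nrow(x$info))
  if (!is.null(population)) keep <- keep & x$info$population %in% population
  if (!is.null(from_year)) keep <- keep & x$info$year >= from_year
  if (!is.null(to_year)) keep <- keep & x$info$year <= to_year
  if (!include_translocated) keep <- keep & !x$info$translocated
  cols <- if (is.null(loci)) x$panel else {
    bad <- setdiff(loci, x$panel)
    if (length(bad)) stop("unknown loci: ", paste(bad, collapse = ", "))
    loci
  }
  genotype_dataset(x$info[keep, , drop = FALSE],
                   x$a1[keep, cols, drop = FALSE],
                   x$a2[keep, cols, drop = FALSE])
}
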