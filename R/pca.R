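#' PCA of multilocus genotypes
#'
#' Individuals are encoded as allele-dosage vectors: one column per allele
#' per locus holding the fraction of that individual's two calls carrying
#' the allele (0, 0.5 or 1).  Missing genotypes are imputed to the column
#' mean, columns are mean-centred (not scaled), and the principal axes of
#' the covariance matrix are returned.
#'
#' @param dataset genotype_dataset.
#' @return object of class `pca_genotypes`: `scores` (individuals x axes),
#'   `eigenvalues`, `percent` (percent variance per axis), `populations`.
#' @export
pca_genotypes <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  X <- dosage_matrix(dataset)
  all_missing <- rowSums(!is.na(X)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " individual(s) with no scored loci excluded")
    X <- X[!all_missing, , drop = FALSE]
  }
  if (nrow(X) < 2) stop("need at least 2 scored individuals")
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(
    scores = pc$x,
    rotation = pc$rotation,
    center = pc$center,
    eigenvalues = ev,
    percent = 100 * ev / sum(ev),
    populations = dataset$info$population[!all_missing],
    ids = dataset$info$individual_id[!all_missing]
  ), class = "pca_genotypes")
}

#' @export
print.pca_genotypes <- function(x, ...) {
  cat("genotype PCA:", nrow(x$scores), "individuals,",
      length(x$eigenvalues), "axes\n")
  k <- min(5, length(x$percent))
  cat("percent variance, axes 1..", k, ": ",
      paste(sprintf("%.2f", x$percent[1:k]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.pca_genotypes <- function(x, axes = c(1, 2), ...) {
  pops <- factor(x$populations)
  graphics::plot(x$scores[, axes[1]], x$scores[, axes[2]],
                 col = as.integer(pops), pch = 16,
                 xlab = sprintf("Axis %d (%.2f%%)", axes[1], x$percent[axes[1]]),
                 ylab = sprintf("Axis %d (%.2f%%)", axes[2], x$percent[axes[2]]),
                 ...)
  graphics::legend("topright", legend = levels(pops),
                   col = seq_along(levels(pops)), pch = 16, bty = "n")
  invisible(x)
}

## individuals x (allele per locus) dosage in {0, 0.5, 1}; NA where unscored
dosage_matrix <- function(dataset) {
  cols <- list()
  for (loc in dataset$panel) {
    alleles <- sort(unique(stats::na.omit(c(dataset$a1[, loc],
                                            dataset$a2[, loc]))))
    for (al in alleles) {
      v <- (dataset$a1[, loc] == al) + (dataset$a2[, loc] == al)
      cols[[paste(loc, al, sep = ".")]] <- v / 2
    }
  }
  do.call(cbind, cols)
}
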