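#' Travelling-window effective inbreeding series
#'
#' Traces the erosion (or rescue) of genetic diversity through time:
#' records are ordered by sampling year (ties broken by individual id), a
#' fixed-width window slides one individual at a time, and within each
#' window the mean multilocus heterozygosity is compared against the source
#' population's heterozygosity as `Fe = 1 - H_window / h_source`.
#'
#' @param dataset genotype_dataset (one population's longitudinal samples).
#' @param source_he heterozygosity of the source population used as the Fe
#'   denominator (held fixed across windows).
#' @param window_width window size in individuals (default 60).
#' @param basis `"observed"` or `"expected"` heterozygosity within windows
#'   (expected = Nei's unbiased).
#' @param include_translocated keep translocated individuals and their
#'   descendants in the windows?
#' @return object of class `fe_series`: a data.frame with one row per
#'   window (`from_year`, `to_year`, `mid_year`, `h`, `fe`,
#'   `prop_translocated`).
#' @export
travelling_window_fe <- function(dataset, source_he, window_width = 60,
                                 basis = c("observed", "expected"),
                                 include_translocated = FALSE) {
  basis <- match.arg(basis)
  stopifnot(inherits(dataset, "genotype_dataset"), source_he > 0)
  d <- subset_genotypes(dataset, include_translocated = include_translocated)
  ord <- order(d$info$year, d$info$individual_id)
  n <- length(ord)
  if (n < window_width) {
    stop("only ", n, " eligible records for window width ", window_width)
  }
  hfun <- if (basis == "observed") observed_heterozygosity else
    expected_heterozygosity_nei
  starts <- seq_len(n - window_width + 1L)
  rows <- lapply(starts, function(s) {
    idx <- ord[s:(s + window_width - 1L)]
    w <- genotype_dataset(d$info[idx, , drop = FALSE],
                          d$a1[idx, , drop = FALSE],
                          d$a2[idx, , drop = FALSE])
    h <- hfun(w)$mean
    data.frame(from_year = min(w$info$year), to_year = max(w$info$year),
               mid_year = stats::median(w$info$year), h = h,
               fe = effective_inbreeding(h, source_he),
               prop_translocated = mean(w$info$translocated))
  })
  out <- do.call(rbind, rows)
  attr(out, "window_width") <- window_width
  attr(out, "basis") <- basis
  attr(out, "source_he") <- source_he
  class(out) <- c("fe_series", "data.frame")
  out
}

#' @export
print.fe_series <- function(x, ...) {
  cat("fe_series:", nrow(x), "windows of", attr(x, "window_width"),
      "samples,", attr(x, "basis"), "heterozygosity, source He =",
      attr(x, "source_he"), "\n")
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more windows\n")
  invisible(x)
}

#' @export
plot.fe_series <- function(x, ...) {
  graphics::plot(x$to_year, x$fe, type = "b", pch = 16,
                 xlab = "window end year", ylab = "effective inbreeding (Fe)",
                 ...)
  graphics::abline(h = c(0.15, 0.25), lty = 2,
                   col = c("grey50", "red"))
  invisible(x)
}
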