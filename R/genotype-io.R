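#' Read a genotype table
#'
#' Reads multilocus diploid genotypes from either a long-format CSV (one row
#' per individual and locus) or a GenePop file.  The long dialect has
#' columns `individual_id, population, date, sex, translocated, locus,
#' allele1, allele2`; dates may be ISO dates or plain years, and missing
#' calls are encoded as an empty field or `"0"` (GenePop convention).
#' Column names can be remapped via `columns` for supplementary tables with
#' a different layout.
#'
#' @param path file path.
#' @param format `"long"` (CSV) or `"genepop"`.
#' @param columns named character vector mapping the canonical long-format
#'   column names to the names used in the file, e.g.
#'   `c(individual_id = "sample")`.
#' @return [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("long", "genepop"),
                           columns = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "long") read_genotypes_long(path, columns)
  else read_genotypes_genepop(path)
}

canonical_cols <- c("individual_id", "population", "date", "sex",
                    "translocated", "locus", "allele1", "allele2")

read_genotypes_long <- function(path, columns = character()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  map <- stats::setNames(canonical_cols, canonical_cols)
  map[names(columns)] <- columns
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  d <- stats::setNames(raw[, unname(map)], names(map))
  bad <- which(d$individual_id == "" | d$locus == "")
  if (length(bad)) stop("malformed row ", bad[1], ": empty id or locus")
  d$allele1[d$allele1 %in% c("", "0", "NA")] <- NA
  d$allele2[d$allele2 %in% c("", "0", "NA")] <- NA

  panel <- unique(d$locus)
  ids <- unique(d$individual_id)
  if (anyDuplicated(paste(d$individual_id, d$locus, sep = "\r"))) {
    stop("duplicate individual/locus rows in ", path)
  }
  n <- length(ids)
  a1 <- matrix(NA_character_, n, length(panel), dimnames = list(NULL, panel))
  a2 <- a1
  ri <- match(d$individual_id, ids)
  ci <- match(d$locus, panel)
  a1[cbind(ri, ci)] <- d$allele1
  a2[cbind(ri, ci)] <- d$allele2

  first <- match(ids, d$individual_id)
  info <- data.frame(
    individual_id = ids,
    population = d$population[first],
    year = parse_year(d$date[first]),
    sex = ifelse(d$sex[first] %in% c("M", "F"), d$sex[first], "U"),
    translocated = d$translocated[first] %in% c("TRUE", "true", "T", "1", "yes"),
    stringsAsFactors = FALSE
  )
  genotype_dataset(info, a1, a2)
}

parse_year <- function(x) {
  y <- suppressWarnings(as.integer(substr(x, 1, 4)))
  if (anyNA(y)) stop("unparseable date: ", x[which(is.na(y))[1]])
  y
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()].  The long dialect round-trips every field;
#' GenePop carries only id, population and genotypes (4-digit coding, two
#' digits per allele), so allele labels must be integers in 1--99.
#'
#' @param x genotype_dataset.
#' @param path output file.
#' @param format `"long"` or `"genepop"`.
#' @export
write_genotypes <- function(x, path, format = c("long", "genepop")) {
  stopifnot(inherits(x, "genotype_dataset"))
  format <- match.arg(format)
  if (format == "long") {
    n <- nrow(x$info); L <- length(x$panel)
    d <- data.frame(
      individual_id = rep(x$info$individual_id, each = L),
      population = rep(x$info$population, each = L),
      date = rep(x$info$year, each = L),
      sex = rep(x$info$sex, each = L),
      translocated = rep(x$info$translocated, each = L),
      locus = rep(x$panel, times = n),
      allele1 = as.vector(t(x$a1)),
      allele2 = as.vector(t(x$a2)),
      stringsAsFactors = FALSE
    )
    d$allele1[is.na(d$allele1)] <- "0"
    d$allele2[is.na(d$allele2)] <- "0"
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    code <- function(a) {
      v <- suppressWarnings(as.integer(a))
      if (any(is.na(v) & !is.na(a)) || any(v < 1 | v > 99, na.rm = TRUE)) {
        stop("GenePop export needs integer allele labels in 1..99")
      }
      v[is.na(v)] <- 0
      sprintf("%02d", v)
    }
    lines <- c("genotypes exported by lynxrescue", x$panel)
    for (p in unique(x$info$population)) {
      lines <- c(lines, "Pop")
      rows <- which(x$info$population == p)
      g <- matrix(paste0(code(x$a1[rows, , drop = FALSE]),
                         code(x$a2[rows, , drop = FALSE])),
                  nrow = length(rows))
      lines <- c(lines, paste(x$info$individual_id[rows], ",",
                              apply(g, 1, paste, collapse = " ")))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

read_genotypes_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("malformed GenePop file: ", path)
  lines <- lines[nzchar(trimws(lines))]
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no Pop line in GenePop file: ", path)
  header <- lines[2:(pop_idx[1] - 1)]
  panel <- trimws(unlist(strsplit(header, ",")))
  panel <- panel[nzchar(panel)]

  info <- list(); a1 <- list(); a2 <- list()
  bounds <- c(pop_idx, length(lines) + 1L)
  for (k in seq_along(pop_idx)) {
    body <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    for (ln in body) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2) stop("malformed GenePop row: ", ln)
      id <- trimws(parts[1])
      gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(gts) != length(panel)) {
        stop("row for '", id, "' has ", length(gts), " genotypes, expected ",
             length(panel))
      }
      if (any(nchar(gts) != 4)) stop("non 4-digit genotype in row '", id, "'")
      g1 <- substr(gts, 1, 2); g2 <- substr(gts, 3, 4)
      g1[g1 == "00"] <- NA; g2[g2 == "00"] <- NA
      info[[length(info) + 1L]] <- data.frame(
        individual_id = id, population = paste0("pop", k), year = NA_integer_,
        sex = "U", translocated = FALSE, stringsAsFactors = FALSE)
      a1[[length(a1) + 1L]] <- as.integer(g1)
      a2[[length(a2) + 1L]] <- as.integer(g2)
    }
  }
  a1 <- matrix(as.character(do.call(rbind, a1)), ncol = length(panel),
               dimnames = list(NULL, panel))
  a2 <- matrix(as.character(do.call(rbind, a2)), ncol = length(panel),
               dimnames = list(NULL, panel))
  genotype_dataset(do.call(rbind, info), a1, a2)
}
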