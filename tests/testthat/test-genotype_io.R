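test_that("long-table CSV parses, validates and round-trips exactly", {
  d <- toy_dataset()
  expect_s3_class(d, "genotype_dataset")
  expect_equal(length(d$panel), 2L)
  expect_equal(nrow(d$info), 3L)
  expect_true(is.na(d$a1[3, "locB"]) && is.na(d$a2[3, "locB"]))

  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(d, path)
  d2 <- read_genotypes(path)
  expect_equal(d2$info, d$info)
  expect_equal(d2$a1, d$a1)
  expect_equal(d2$a2, d$a2)
  expect_equal(d2$panel, d$panel)
})

test_that("half-called genotypes and duplicate ids are rejected", {
  info <- data.frame(individual_id = "x", population = "A", year = 2000L,
                     sex = "U", translocated = FALSE)
  a1 <- matrix("1", 1, 1, dimnames = list(NULL, "L1"))
  a2 <- matrix(NA_character_, 1, 1, dimnames = list(NULL, "L1"))
  expect_error(genotype_dataset(info, a1, a2), "half-called")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,population,date,sex,translocated,locus,allele1,allele2",
               "i1,A,2001,M,FALSE,L1,1,0"), path)
  expect_error(read_genotypes(path), "half-called")

  info2 <- data.frame(individual_id = c("x", "x"), population = "A",
                      year = 2000L, sex = "U", translocated = FALSE)
  a1 <- matrix("1", 2, 1, dimnames = list(NULL, "L1")); a2 <- a1
  expect_error(genotype_dataset(info2, a1, a2), "duplicate")
})

test_that("custom column mapping is honoured", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,population,date,sex,translocated,locus,allele1,allele2",
               "i1,A,2001,M,FALSE,L1,1,2"), path)
  expect_error(read_genotypes(path), "individual_id")
  d <- read_genotypes(path, columns = c(individual_id = "sample"))
  expect_equal(d$info$individual_id, "i1")
})

test_that("GenePop export/import preserves ids, populations and genotypes", {
  d <- toy_dataset()
  path <- withr::local_tempfile(fileext = ".gen")
  write_genotypes(d, path, format = "genepop")
  d2 <- read_genotypes(path, format = "genepop")
  expect_equal(d2$panel, d$panel)
  expect_equal(d2$info$individual_id, d$info$individual_id)
  # population labels become positional but the grouping is preserved
  expect_equal(as.integer(factor(d2$info$population,
                                 levels = unique(d2$info$population))),
               as.integer(factor(d$info$population,
                                 levels = unique(d$info$population))))
  expect_equal(d2$a1, d$a1)
  expect_equal(d2$a2, d$a2)
})

test_that("allele frequencies: direct counts, monomorphic loci, errors", {
  info <- data.frame(individual_id = c("i1", "i2"), population = "A",
                     year = 2000L, sex = "U", translocated = FALSE)
  a1 <- matrix(c("A", "A", "M", "M"), 2, 2,
               dimnames = list(NULL, c("L1", "L2")))
  a2 <- matrix(c("A", "B", "M", "M"), 2, 2,
               dimnames = list(NULL, c("L1", "L2")))
  d <- genotype_dataset(info, a1, a2)
  f <- compute_allele_frequencies(d, "A")
  expect_equal(f$freqs$L1, c(A = 0.75, B = 0.25))
  expect_equal(f$freqs$L2, c(M = 1.0))
  expect_equal(f$n_source, 2L)

  a1[, "L2"] <- NA; a2[, "L2"] <- NA
  d0 <- genotype_dataset(info, a1, a2)
  expect_error(compute_allele_frequencies(d0, "A"), "L2")
})

test_that("frequency estimation is permutation-invariant and consistent", {
  set.seed(7)
  freqs <- generate_source_frequencies(n_loci = 6, seed = 7)
  pop <- initialize_population(freqs, 500)
  d <- as_genotype_dataset(pop, "P")
  est <- compute_allele_frequencies(d, "P")
  for (loc in names(freqs$freqs)) {
    p_true <- freqs$freqs[[loc]]
    p_est <- est$freqs[[loc]][names(p_true)]
    p_est[is.na(p_est)] <- 0
    expect_true(all(abs(p_est - p_true) < 0.05))
  }
  perm <- sample(nrow(d$info))
  dp <- genotype_dataset(d$info[perm, ], d$a1[perm, ], d$a2[perm, ])
  ep <- compute_allele_frequencies(dp, "P")
  expect_equal(ep$freqs, est$freqs)
})

test_that("allele-frequency tables round-trip and validate sums", {
  d <- toy_dataset()
  f <- compute_allele_frequencies(d, "A")
  path <- withr::local_tempfile(fileext = ".csv")
  write_allele_frequencies(f, path)
  f2 <- read_allele_frequencies(path)
  expect_equal(f2$population, f$population)
  expect_equal(f2$freqs, f$freqs, tolerance = 1e-12)

  writeLines(c("population,locus,allele,frequency",
               "A,L1,x,0.5", "A,L1,y,0.3"), path)
  expect_error(read_allele_frequencies(path), "sum")
})
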