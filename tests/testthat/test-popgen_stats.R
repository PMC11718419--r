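make_single_locus <- function(a1, a2, pop = "P") {
  n <- length(a1)
  info <- data.frame(individual_id = paste0("i", seq_len(n)),
                     population = pop, year = 2000L, sex = "U",
                     translocated = FALSE)
  genotype_dataset(info,
                   matrix(a1, n, 1, dimnames = list(NULL, "L1")),
                   matrix(a2, n, 1, dimnames = list(NULL, "L1")))
}

test_that("observed heterozygosity counts heterozygotes directly", {
  d <- make_single_locus(rep("A", 10),
                         c(rep("B", 3), rep("A", 7)))
  expect_equal(observed_heterozygosity(d, "P")$per_locus[["L1"]], 0.3)
  d_all <- make_single_locus(rep("A", 5), rep("B", 5))
  expect_equal(observed_heterozygosity(d_all)$mean, 1.0)
  expect_error(observed_heterozygosity(d, "nope"), "empty")
})

test_that("Nei's unbiased expected heterozygosity matches the formula", {
  # p = 0.5/0.5 from 10 individuals: (2n/(2n-1)) * 0.5 = 20/19 * 0.5
  d <- make_single_locus(rep("A", 10), rep("B", 10))
  expect_equal(expected_heterozygosity_nei(d)$mean, 0.5 * 20 / 19,
               tolerance = 1e-12)
  mono <- make_single_locus(rep("A", 6), rep("A", 6))
  expect_equal(expected_heterozygosity_nei(mono)$mean, 0)
  # unbiased value exceeds the plain 1 - sum(p^2)
  expect_gt(expected_heterozygosity_nei(d)$mean, 0.5)
})

test_that("allelic diversity counts alleles and never grows on subsampling", {
  d <- make_single_locus(c("A", "A", "B", "C"), c("A", "B", "B", "C"))
  expect_equal(allelic_diversity(d)$mean, 3)
  set.seed(1)
  full <- generate_study_dataset(seed = 2, reinforcement = FALSE)$dataset
  a_full <- allelic_diversity(full, "Dinaric")$per_locus
  sub <- subset_genotypes(full, population = "Dinaric")
  idx <- sample(nrow(sub$info), 30)
  sub30 <- genotype_dataset(sub$info[idx, ], sub$a1[idx, ], sub$a2[idx, ])
  a_sub <- allelic_diversity(sub30)$per_locus
  expect_true(all(a_sub <= a_full + 1e-12))
})

test_that("effective inbreeding identities and monotonicity hold", {
  expect_equal(effective_inbreeding(0.4, 0.4), 0)
  expect_equal(effective_inbreeding(0, 0.4), 1)
  expect_equal(effective_inbreeding(0.457, 0.583), 1 - 0.457 / 0.583,
               tolerance = 1e-12)
  expect_equal(round(effective_inbreeding(0.457, 0.583), 4), 0.2161)
  expect_error(effective_inbreeding(0.3, 0), "undefined")
  h <- seq(0.1, 0.5, by = 0.1)
  expect_true(all(diff(effective_inbreeding(h, 0.55)) < 0))
  expect_true(all(diff(effective_inbreeding(0.3, h + 0.1)) > 0))
})

test_that("Fis is near zero under Hardy-Weinberg sampling", {
  set.seed(42)
  freqs <- generate_source_frequencies(seed = 42)
  pop <- initialize_population(freqs, 500)
  d <- as_genotype_dataset(pop, "P")
  expect_lt(abs(fis(d, "P")), 0.05)
  d1 <- make_single_locus(rep("A", 8), rep("B", 8))
  expect_equal(fis(d1), 1 - 1 / (0.5 * 16 / 15), tolerance = 1e-12)
})

test_that("travelling window matches the scalar Fe oracle per window", {
  set.seed(5)
  freqs <- generate_source_frequencies(seed = 5)
  pop <- initialize_population(freqs, 120)
  d <- as_genotype_dataset(pop, "P")
  d$info$year <- sample(1990:2010, 120, replace = TRUE)
  d <- genotype_dataset(d$info, d$a1, d$a2)
  she <- expected_heterozygosity_nei(d)$mean
  fw <- travelling_window_fe(d, source_he = she, window_width = 60)
  # sample drawn from the source itself: Fe fluctuates around zero
  expect_true(all(abs(fw$fe) < 0.1))
  # oracle: recompute one window by hand from the date-ordered records
  ord <- order(d$info$year, d$info$individual_id)
  idx <- ord[11:70]
  w <- genotype_dataset(d$info[idx, ], d$a1[idx, ], d$a2[idx, ])
  expect_equal(fw$fe[11],
               effective_inbreeding(observed_heterozygosity(w)$mean, she),
               tolerance = 1e-12)
  expect_equal(nrow(fw), 120 - 60 + 1)
  expect_error(travelling_window_fe(d, she, window_width = 200), "200")
})

test_that("translocated individuals are excluded from windows on request", {
  set.seed(6)
  freqs <- generate_source_frequencies(seed = 6, n_loci = 8)
  pop <- initialize_population(freqs, 80)
  d <- as_genotype_dataset(pop, "P")
  d$info$year <- rep(2000:2019, each = 4)
  d$info$translocated[77:80] <- TRUE
  d <- genotype_dataset(d$info, d$a1, d$a2)
  fw <- travelling_window_fe(d, 0.5, window_width = 60,
                             include_translocated = FALSE)
  expect_equal(nrow(fw), 76 - 60 + 1)
  expect_true(all(fw$prop_translocated == 0))
  fw2 <- travelling_window_fe(d, 0.5, window_width = 60,
                              include_translocated = TRUE)
  expect_gt(max(fw2$prop_translocated), 0)
})

test_that("genotype PCA separates fixed populations and normalises variance", {
  info <- data.frame(individual_id = paste0("i", 1:10),
                     population = rep(c("X", "Y"), each = 5),
                     year = 2000L, sex = "U", translocated = FALSE)
  a1 <- cbind(L1 = rep(c("A", "B"), each = 5), L2 = rep(c("C", "D"), each = 5))
  d <- genotype_dataset(info, a1, a1)
  p <- pca_genotypes(d)
  expect_equal(sum(p$percent), 100, tolerance = 1e-9)
  expect_equal(p$percent[1], 100, tolerance = 1e-9)
  expect_true(min(p$scores[1:5, 1]) > max(p$scores[6:10, 1]) ||
                max(p$scores[1:5, 1]) < min(p$scores[6:10, 1]))
  expect_true(all(p$eigenvalues >= -1e-12))
})

test_that("PCA reconstruction reproduces the centred dosage matrix", {
  set.seed(8)
  freqs <- generate_source_frequencies(seed = 8, n_loci = 5)
  pop <- initialize_population(freqs, 30)
  d <- as_genotype_dataset(pop, "P")
  p <- pca_genotypes(d)
  X <- p$scores %*% t(p$rotation)
  X <- sweep(X, 2, p$center, "+")
  D <- lynxrescue:::dosage_matrix(d)
  expect_equal(unname(X), unname(D), tolerance = 1e-9)
})

test_that("LD-Ne flags undetectable drift and validates inputs", {
  set.seed(9)
  S <- 40; L <- 19
  a1 <- matrix(sample.int(4, S * L, TRUE), S, L)
  a2 <- matrix(sample.int(4, S * L, TRUE), S, L)
  est <- ld_ne(list(a1 = a1, a2 = a2))
  expect_s3_class(est, "ne_estimate")
  expect_true(is.infinite(est$ci[2]))
  expect_true(est$ne > 0)
  expect_error(ld_ne(list(a1 = a1[1:5, ], a2 = a2[1:5, ])), "at least")
  mono1 <- matrix(1L, S, 2); expect_error(ld_ne(list(a1 = mono1, a2 = mono1)),
                                          "polymorphic")
})

test_that("rare alleles below the MAF threshold are excluded", {
  set.seed(10)
  S <- 60
  a1 <- matrix(sample.int(2, S * 4, TRUE), S, 4)
  a2 <- matrix(sample.int(2, S * 4, TRUE), S, 4)
  # plant a single rare allele (frequency 1/120 < 0.02) at locus 1
  a1[1, 1] <- 3L
  est <- ld_ne(list(a1 = a1, a2 = a2), maf = 0.02)
  est_clean <- ld_ne(list(a1 = ifelse(a1 == 3L, 1L, a1), a2 = a2), maf = 0.02)
  expect_equal(est$n_pairs, est_clean$n_pairs)
})
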