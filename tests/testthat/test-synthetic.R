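test_that("source frequency tables hit their heterozygosity targets", {
  f <- generate_source_frequencies(seed = 31)
  he <- mean(vapply(f$freqs, function(p) 1 - sum(p^2), numeric(1)))
  expect_true(he >= 0.563 && he <= 0.603)
  expect_length(f$freqs, 19)
  expect_true(all(vapply(f$freqs, function(p) abs(sum(p) - 1) < 1e-9, TRUE)))

  f2 <- generate_source_frequencies(n_loci = 10, alleles_range = c(2, 2),
                                    he_target = 0.5, seed = 32)
  he2 <- mean(vapply(f2$freqs, function(p) 1 - sum(p^2), numeric(1)))
  expect_equal(he2, 0.5, tolerance = 0.02)
  expect_error(generate_source_frequencies(alleles_range = c(2, 2),
                                           he_target = 0.6, seed = 33),
               "unattainable")
  expect_identical(generate_source_frequencies(seed = 31), f)
})

test_that("an undrifted founder cohort shows no effective inbreeding", {
  src <- generate_source_frequencies(seed = 34)
  she <- mean(vapply(src$freqs, function(p) 1 - sum(p^2), numeric(1)))
  set.seed(34)
  pop <- initialize_population(src, 200)
  he <- lynxrescue:::pop_metrics(pop)$he
  expect_lt(abs(effective_inbreeding(he, she)), 0.05)
})

test_that("45 years of drift from six founders erodes diversity strongly", {
  src <- generate_source_frequencies(seed = 35)
  she <- mean(vapply(src$freqs, function(p) 1 - sum(p^2), numeric(1)))
  set.seed(35)
  fe_end <- c()
  for (i in 1:80) {
    d <- generate_drifted_population(src, years = 45,
                                     sample_years = integer(0))
    if (!d$extinct) {
      fe_end <- c(fe_end,
                  effective_inbreeding(
                    lynxrescue:::pop_metrics(d$population)$he, she))
    }
    if (length(fe_end) >= 3) break
  }
  # surviving lineages show inbreeding of the order seen in reintroduced
  # bottlenecked populations (the calibrated load keeps survivors small,
  # so the upper tail runs beyond the empirical 0.2-0.35 series)
  expect_gte(length(fe_end), 1)
  expect_true(all(fe_end > 0.1 & fe_end < 0.7))
})

test_that("the drifted longitudinal dataset feeds downstream analyses", {
  set.seed(36)
  src <- generate_source_frequencies(seed = 36)
  d <- NULL
  for (i in 1:50) {
    cand <- generate_drifted_population(src, years = 45, seed = 36 + i)
    if (!cand$extinct && !is.null(cand$dataset) &&
          nrow(cand$dataset$info) >= 60) { d <- cand; break }
  }
  expect_false(is.null(d))
  fw <- travelling_window_fe(d$dataset, source_he = 0.583, window_width = 60)
  expect_s3_class(fw, "fe_series")
  expect_true(all(fw$fe <= 1))
  # the pedigree of the simulated population passes structural validation
  expect_s3_class(d$pedigree, "pedigree")
  expect_gt(length(d$pedigree$id), 6)
})

test_that("test pedigrees carry their classical expectations", {
  fs <- generate_test_pedigree("full-sib")
  expect_equal(attr(fs, "expected_f"), c(x = 0.25))
  cz <- generate_test_pedigree("cousins")
  expect_equal(attr(cz, "expected_f"), c(x = 0.0625))
  expect_equal(unname(inbreeding_coefficient(cz, "x")),
               unname(attr(cz, "expected_f")))
  r <- generate_test_pedigree("random", n = 30, seed = 37)
  expect_length(r$id, 30)
  expect_error(generate_test_pedigree("zigzag"))
})

test_that("the synthetic study dataset emulates the monitoring design", {
  study <- generate_study_dataset(seed = 38)
  d <- study$dataset
  expect_setequal(unique(d$info$population),
                  c("Dinaric", "Slovakia", "Romania"))
  expect_equal(sum(d$info$population == "Slovakia"), 48)
  expect_equal(sum(d$info$population == "Romania"), 22)
  expect_gt(sum(d$info$population == "Dinaric"), 100)
  # longitudinal Dinaric sampling with post-reinforcement seasons flagged
  din <- subset_genotypes(d, "Dinaric")
  expect_gt(max(din$info$year), 2018)
  expect_true(any(din$info$translocated))
  expect_true(all(!d$info$translocated[d$info$population != "Dinaric"]))
  # the bottlenecked population is measurably poorer than its source
  expect_lt(diversity_summary(d, "Dinaric")$he$mean,
            diversity_summary(d, "Slovakia")$he$mean)
  expect_gt(study$baseline_f |> mean(), 0)
})
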