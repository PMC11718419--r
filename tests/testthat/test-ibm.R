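slovak_like <- function(seed = 11) generate_source_frequencies(seed = seed)

test_that("population initialisation honours size, F distribution and ages", {
  set.seed(1)
  freqs <- slovak_like()
  pop <- initialize_population(freqs, 77)
  expect_s3_class(pop, "lynx_population")
  expect_length(pop$id, 77)
  expect_true(all(pop$f == 0))
  expect_true(all(pop$age >= 0 & pop$age <= 16))
  popf <- initialize_population(freqs, 40, baseline_f = c(0.1, 0.3))
  expect_true(all(popf$f %in% c(0.1, 0.3)))
  # realised allele frequencies converge on the sampling table
  big <- initialize_population(freqs, 1e4)
  for (j in c(1, 10, 19)) {
    p_true <- freqs$freqs[[j]]
    p_obs <- tabulate(c(big$g1[, j], big$g2[, j]),
                      nbins = length(p_true)) / (2e4)
    expect_true(all(abs(p_obs - p_true) < 0.02))
  }
})

test_that("mating: single-sex populations are sterile, inheritance is Mendelian", {
  set.seed(2)
  freqs <- slovak_like()
  pop <- initialize_population(freqs, 30)
  pop$sex[] <- 1L
  expect_equal(mating_step(pop)$n, 0L)

  pop2 <- initialize_population(freqs, 60)
  pop2$age[] <- 5L
  cohort <- mating_step(pop2)
  expect_gt(cohort$n, 0)
  sidx <- match(cohort$sire_id, pop2$id)
  didx <- match(cohort$dam_id, pop2$id)
  for (j in seq_along(pop2$panel)) {
    expect_true(all(cohort$g1[, j] == pop2$g1[sidx, j] |
                      cohort$g1[, j] == pop2$g2[sidx, j]))
    expect_true(all(cohort$g2[, j] == pop2$g1[didx, j] |
                      cohort$g2[, j] == pop2$g2[didx, j]))
  }
  # offspring F equals the pedigree kinship of the parents
  expect_equal(cohort$f, pop2$K[cbind(sidx, didx)])
})

test_that("litter sizes average 2.1 and females mate at most once", {
  set.seed(3)
  freqs <- generate_source_frequencies(seed = 3, n_loci = 2)
  par <- demographic_params(carrying_capacity = 1e6)
  pop <- initialize_population(freqs, 800, params = par)
  pop$age[] <- 5L
  n_females <- sum(pop$sex == 2L)
  kittens <- 0; litters <- 0
  for (rep in 1:15) {
    cohort <- mating_step(pop, par)
    kittens <- kittens + cohort$n
    litters <- litters + n_females
    pairs <- tapply(cohort$sire_id, cohort$dam_id,
                    function(s) length(unique(s)))
    expect_true(all(pairs == 1))
  }
  expect_equal(kittens / litters, 2.1, tolerance = 0.05 / 2.1)
})

test_that("survival applies juvenile mortality and the annual inbreeding load", {
  set.seed(4)
  freqs <- generate_source_frequencies(seed = 4, n_loci = 2)
  par0 <- demographic_params(lethal_equivalents = 0, carrying_capacity = 1e6)
  parB <- demographic_params(lethal_equivalents = 1.1,
                             carrying_capacity = 1e6)
  pop <- initialize_population(freqs, 300, params = par0)
  pop$age[] <- 5L
  surv0 <- survB <- born <- 0
  for (rep in 1:20) {
    cohort <- mating_step(pop, par0)
    born <- born + cohort$n
    surv0 <- surv0 + sum(survival_step(pop, cohort, par0)$age == 1L)
    cohort$f <- rep(0.25, cohort$n)
    survB <- survB + sum(survival_step(pop, cohort, parB)$age == 1L)
  }
  expect_equal(surv0 / born, 0.5 * 0.87, tolerance = 0.05)
  # inbred newborns additionally survive by exp(-B * F)
  expect_equal(survB / born, 0.5 * 0.87 * exp(-1.1 * 0.25),
               tolerance = 0.07)
})

test_that("translocation adds unrelated founders carrying source alleles", {
  set.seed(5)
  freqs <- slovak_like()
  pop <- initialize_population(freqs, 40)
  n0 <- length(pop$id)
  pop2 <- translocate(pop, 2, 2, freqs)
  expect_equal(length(pop2$id), n0 + 4)
  newcomers <- (n0 + 1):(n0 + 4)
  expect_true(all(pop2$f[newcomers] == 0))
  expect_true(all(pop2$trans[newcomers]))
  expect_true(all(pop2$K[newcomers, seq_len(n0)] == 0))
  expect_true(all(pop2$age[newcomers] %in% 2:4))

  big <- translocate(pop, 500, 500, freqs)
  for (j in c(1, 19)) {
    p_true <- freqs$freqs[[j]]
    idx <- (n0 + 1):length(big$id)
    p_obs <- tabulate(c(big$g1[idx, j], big$g2[idx, j]),
                      nbins = length(p_true)) / (2 * length(idx))
    expect_true(all(abs(p_obs - p_true) < 0.05))
  }
  # the translocated-lineage flag is inherited
  pop2$age[] <- 5L
  cohort <- mating_step(pop2)
  si <- match(cohort$sire_id, pop2$id); di <- match(cohort$dam_id, pop2$id)
  expect_equal(cohort$trans, pop2$trans[si] | pop2$trans[di])
})

test_that("fixed seeds reproduce trajectories bit-exactly", {
  freqs <- slovak_like()
  run <- function() run_simulation(
    function() initialize_population(freqs, 50, baseline_f = 0.1),
    n_years = 10, n_replicates = 3, seed = 123, source_he = 0.583)
  expect_identical(run(), run())
})

test_that("the carrying-capacity ceiling binds", {
  freqs <- slovak_like()
  par_census <- demographic_params(carrying_capacity = 60)
  traj <- run_simulation(
    function() initialize_population(freqs, 80, params = par_census),
    params = par_census, n_years = 25, n_replicates = 3, seed = 9)
  expect_true(all(traj$census <= 60))
  expect_true(all(traj$adults <= 60))
  par_adults <- demographic_params(carrying_capacity = 40, k_on = "adults")
  traj2 <- run_simulation(
    function() initialize_population(freqs, 80, params = par_adults),
    params = par_adults, n_years = 25, n_replicates = 3, seed = 9)
  expect_true(all(traj2$adults <= 40))
})

test_that("mean IBD does not decay in a closed population", {
  freqs <- slovak_like()
  traj <- run_simulation(
    function() initialize_population(freqs, 60,
                                     params = demographic_params(
                                       carrying_capacity = 60)),
    params = demographic_params(carrying_capacity = 60),
    n_years = 40, n_replicates = 8, seed = 10)
  s <- summary(traj)
  ibd <- s$ibd[!is.na(s$ibd)]
  # replicate-mean curve rises overall; small local noise allowed
  expect_gt(mean(ibd[(length(ibd) - 4):length(ibd)]),
            mean(ibd[1:5]))
  expect_true(all(diff(ibd) > -0.02))
})

test_that("extinction is declared at zero census or a missing sex", {
  freqs <- generate_source_frequencies(seed = 6, n_loci = 3)
  pop <- initialize_population(freqs, 6)
  pop$sex[] <- 2L
  expect_true(lynxrescue:::is_extinct(pop))
  traj <- run_simulation(
    function() initialize_population(
      freqs, 4, params = demographic_params(natural_mortality = 0.6)),
    params = demographic_params(natural_mortality = 0.6),
    n_years = 30, n_replicates = 5, seed = 11)
  ext <- attr(traj, "extinction")
  expect_true(all(!is.na(ext)))
})

test_that("simulated heterozygosity decay is consistent with the LD-Ne scale", {
  freqs <- slovak_like()
  par <- demographic_params(carrying_capacity = 50)
  traj <- run_simulation(
    function() initialize_population(freqs, 50, params = par),
    params = par, n_years = 30, n_replicates = 10, seed = 12,
    compute_ne = TRUE, ne_years = c(15, 30), ne_sample = 50)
  s <- summary(traj)
  # per-year loss rate -> demographic Ne (generation time ~5 years)
  rate <- 1 - (s$he[30] / s$he[5])^(1 / 25)
  ne_decay <- 1 / (2 * (1 - (1 - rate)^5))
  ne_ld <- mean(traj$ne[is.finite(traj$ne)])
  expect_gt(ne_ld, ne_decay / 4)
  expect_lt(ne_ld, ne_decay * 4)
})
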