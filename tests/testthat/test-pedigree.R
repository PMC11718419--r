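test_that("classical kinship and inbreeding values are exact", {
  p <- pedigree(id = c("a", "b", "o"),
                sire = c(NA, NA, "a"), dam = c(NA, NA, "b"))
  expect_equal(kinship(p, "a", "b"), 0, ignore_attr = TRUE)
  expect_equal(kinship(p, "a", "o"), 0.25, ignore_attr = TRUE)
  expect_equal(inbreeding_coefficient(p, "o"), c(o = 0))

  fs <- generate_test_pedigree("full-sib")
  expect_equal(inbreeding_coefficient(fs, "x"), c(x = 0.25))
  po <- generate_test_pedigree("parent-offspring")
  expect_equal(inbreeding_coefficient(po, "x"), c(x = 0.25))
  cz <- generate_test_pedigree("cousins")
  expect_equal(inbreeding_coefficient(cz, "x"), c(x = 0.0625))
})

test_that("founder baselines and declared founder kinships propagate", {
  p <- pedigree(id = c("f1", "f2", "k"),
                sire = c(NA, NA, "f1"), dam = c(NA, NA, "f2"),
                founder_f = c(f1 = 0.3),
                founder_kinship = data.frame(id1 = "f1", id2 = "f2",
                                             k = 0.25))
  expect_equal(inbreeding_coefficient(p, "f1"), c(f1 = 0.3))
  # offspring F equals the declared parental kinship
  expect_equal(inbreeding_coefficient(p, "k"), c(k = 0.25))
  # self-kinship of an inbred founder is (1 + f) / 2
  expect_equal(kinship(p, "f1", "f1"), 0.65, ignore_attr = TRUE)
  expect_error(pedigree(id = "z", sire = NA, dam = NA,
                        founder_f = c(q = 0.1)), "non-founders")
})

test_that("structural validation: cycles, half parents, unknown ids", {
  expect_error(pedigree(id = c("a", "b"), sire = c("b", "a"),
                        dam = c("b", "a")), "cycle")
  expect_error(pedigree(id = c("a", "b"), sire = c(NA, "a"),
                        dam = c(NA, NA)), "both parents")
  expect_error(pedigree(id = "a", sire = "ghost", dam = "ghost"),
               "unknown parent")
  p <- generate_test_pedigree("random", n = 30, seed = 1)
  expect_error(kinship(p, "r1", "nope"), "unknown id")
})

test_that("tabular kinship agrees with gene-dropping Monte Carlo", {
  set.seed(99)
  for (s in c(4, 17)) {
    ped <- generate_test_pedigree("random", n = 30, seed = s)
    K <- kinship_matrix(ped)
    oracle <- gene_drop_kinship(ped, n_drops = 1e5)
    ids <- sample(ped$id, 6)
    for (i in ids) for (j in ids) {
      expect_lt(abs(K[i, j] - oracle(i, j)), 0.01)
    }
    # per-individual F against the oracle's parental kinship
    non_f <- ped$id[!is.na(ped$sire)]
    pick <- sample(non_f, 4)
    Fv <- inbreeding_coefficient(ped, pick)
    for (i in pick) {
      k <- match(i, ped$id)
      expect_lt(abs(Fv[[i]] - oracle(ped$sire[k], ped$dam[k])), 0.01)
    }
  }
})

test_that("kinship is symmetric and F ratchets up in a closed inbred line", {
  ped <- generate_test_pedigree("random", n = 25, seed = 3)
  K <- kinship_matrix(ped)
  expect_equal(K, t(K))
  # repeated full-sib matings: F is non-decreasing down the line
  id <- c("m0", "f0", "m1", "f1", "m2", "f2", "m3", "f3")
  sire <- c(NA, NA, "m0", "m0", "m1", "m1", "m2", "m2")
  dam <- c(NA, NA, "f0", "f0", "f1", "f1", "f2", "f2")
  line <- pedigree(id, sire, dam)
  Fs <- inbreeding_coefficient(line, c("m1", "m2", "m3"))
  expect_true(all(diff(Fs) > 0))
  expect_equal(unname(Fs["m2"]), 0.25)
})

test_that("pedigree CSV round-trips with founder sidecar", {
  ped <- generate_test_pedigree("random", n = 20, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  ped2 <- read_pedigree(path)
  expect_equal(ped2$id, ped$id)
  expect_equal(ped2$sire, ped$sire)
  expect_equal(ped2$dam, ped$dam)
})
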