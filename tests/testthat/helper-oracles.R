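# Independent oracles kept free of the package's own kinship / Ne code.

# Monte-Carlo gene dropping: founders get unique allele labels, alleles
# descend by fair coin flips; kinship(i, j) is the probability that a
# random allele of i is identical by descent to a random allele of j.
gene_drop_kinship <- function(ped, n_drops = 1e5) {
  ids <- ped$id
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A1 <- matrix(0L, n, n_drops)
  A2 <- matrix(0L, n, n_drops)
  lab <- 0L
  for (i in ped$order) {
    if (is.na(si[i])) {
      A1[i, ] <- lab + 1L
      A2[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A1[i, ] <- ifelse(pick, A1[si[i], ], A2[si[i], ])
      pick <- stats::runif(n_drops) < 0.5
      A2[i, ] <- ifelse(pick, A1[di[i], ], A2[di[i], ])
    }
  }
  function(i, j) {
    ii <- match(i, ids); jj <- match(j, ids)
    mean((A1[ii, ] == A1[jj, ]) + (A1[ii, ] == A2[jj, ]) +
           (A2[ii, ] == A1[jj, ]) + (A2[ii, ] == A2[jj, ])) / 4
  }
}

# Ideal Wright-Fisher population (Ne = N): discrete generations, each
# offspring draws two parents uniformly with replacement.
wf_population <- function(N, gens, L = 19, k = 4) {
  g1 <- matrix(sample.int(k, N * L, TRUE), N, L)
  g2 <- matrix(sample.int(k, N * L, TRUE), N, L)
  for (t in seq_len(gens)) {
    s <- sample.int(N, N, TRUE)
    d <- sample.int(N, N, TRUE)
    m1 <- matrix(stats::runif(N * L) < 0.5, N, L)
    m2 <- matrix(stats::runif(N * L) < 0.5, N, L)
    n1 <- ifelse(m1, g1[s, ], g2[s, ])
    n2 <- ifelse(m2, g1[d, ], g2[d, ])
    g1 <- n1; g2 <- n2
  }
  list(a1 = g1, a2 = g2)
}

# small literal genotype dataset used across io / stats tests
toy_dataset <- function() {
  info <- data.frame(
    individual_id = c("i1", "i2", "i3"),
    population = c("A", "A", "B"),
    year = c(2001L, 2003L, 2002L),
    sex = c("M", "F", "U"),
    translocated = c(FALSE, FALSE, TRUE))
  a1 <- matrix(c("1", "1", "2",
                 "3", "3", "3"), 3, 2,
               dimnames = list(NULL, c("locA", "locB")))
  a2 <- matrix(c("2", "1", "2",
                 "3", "4", NA), 3, 2,
               dimnames = list(NULL, c("locA", "locB")))
  a1[3, 2] <- NA
  genotype_dataset(info, a1, a2)
}
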