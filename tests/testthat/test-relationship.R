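test_that("additive design centers doses at 2p", {
  d <- matrix(c(0L, 1L, 2L), 3, 1)
  expect_equal(unname(build_additive_design(d, 0.5)$values),
               matrix(c(-1, 0, 1), 3, 1))
  expect_equal(unname(build_additive_design(d, 0.2)$values),
               matrix(c(-0.4, 0.6, 1.6), 3, 1))
  # column sums vanish when p comes from the same sample
  withr::with_seed(31, dd <- matrix(rbinom(500, 2, 0.3), 50, 10))
  pp <- estimate_frequencies(dd)
  expect_equal(unname(colSums(build_additive_design(dd, pp)$values)),
               rep(0, 10), tolerance = 1e-10)
  expect_error(build_additive_design(d, 1), "strictly inside")
})

test_that("dominance coding is label-symmetric with zero HWE expectation", {
  d <- matrix(c(0L, 1L, 2L), 3, 1)
  expect_equal(unname(build_dominance_design(d, 0.5)$values),
               matrix(c(-0.5, 0.5, -0.5), 3, 1))
  # E[code] = q^2 (-2p^2) + 2pq (2pq) + p^2 (-2q^2) = 0 for any p
  for (p in seq(0.05, 0.95, by = 0.09)) {
    q <- 1 - p
    codes <- unname(build_dominance_design(d, p)$values)
    expect_equal(q^2 * codes[1] + 2 * p * q * codes[2] + p^2 * codes[3],
                 0, tolerance = 1e-12, label = sprintf("p = %.2f", p))
  }
  # both homozygotes get the same code at p = 0.5
  codes <- build_dominance_design(d, 0.5)$values
  expect_equal(codes[1], codes[3])
})

test_that("single-marker kinship matrices match the hand-computed 3x3 oracles", {
  d <- matrix(c(0L, 1L, 2L), 3, 1)
  G <- build_grm(build_additive_design(d, 0.5))
  expect_equal(G$denominator, 0.5)
  expect_equal(unname(G$values),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3))
  D <- build_grm(build_dominance_design(d, 0.5))
  expect_equal(D$denominator, 0.25)
  expect_equal(unname(D$values),
               matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3, 3))
})

test_that("build_grm equals a naive double-loop on random fixtures", {
  withr::with_seed(32, {
    doses <- matrix(rbinom(500, 2, runif(50, 0.1, 0.9)[rep(1:50, each = 10)]),
                    10, 50)
  })
  p <- pmin(pmax(estimate_frequencies(doses), 0.01), 0.99)
  for (kind in c("additive", "dominance")) {
    builder <- if (kind == "additive") build_additive_design else build_dominance_design
    W <- builder(doses, p)$values
    denom <- if (kind == "additive") 2 * sum(p * (1 - p)) else
      4 * sum(p^2 * (1 - p)^2)
    naive <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      naive[i, j] <- sum(W[i, ] * W[j, ]) / denom
    }
    expect_equal(unname(make_grm(doses, p, kind)$values), naive,
                 tolerance = 1e-10)
  }
})

test_that("kinship matrices are invariant to marker order and allele swaps", {
  pop <- small_pop()
  doses <- pop$pop$genotypes$doses[1:60, 1:200]
  p <- estimate_frequencies(doses)
  ok <- p > 0 & p < 1
  doses <- doses[, ok]; p <- p[ok]
  withr::with_seed(33, {
    perm <- sample(ncol(doses))
    flip <- sample(ncol(doses), 40)
  })
  G1 <- make_grm(doses, p, "additive")
  expect_equal(make_grm(doses[, perm], p[perm], "additive")$values,
               G1$values, tolerance = 1e-10)
  # swapping allele labels at some markers: dose -> 2 - dose, p -> 1 - p
  doses2 <- doses; doses2[, flip] <- 2L - doses2[, flip]
  p2 <- p; p2[flip] <- 1 - p2[flip]
  expect_equal(make_grm(doses2, p2, "additive")$values, G1$values,
               tolerance = 1e-10)
  D1 <- make_grm(doses, p, "dominance")
  expect_equal(make_grm(doses2, p2, "dominance")$values, D1$values,
               tolerance = 1e-10)
})

test_that("block size does not change the result beyond reassociation error", {
  pop <- small_pop()
  doses <- pop$pop$genotypes$doses[1:50, ]
  p <- estimate_frequencies(doses)
  ok <- p > 0 & p < 1
  doses <- doses[, ok]; p <- p[ok]
  ref <- make_grm(doses, p, "additive", block_size = 1e6)$values
  for (bs in c(7, 64, 333)) {
    expect_equal(make_grm(doses, p, "additive", block_size = bs)$values, ref,
                 tolerance = 1e-10)
  }
})

test_that("mean kinship diagonals are near 1 in an unrelated HWE population", {
  withr::with_seed(34, {
    m <- 20000; n <- 200
    p <- runif(m, 0.05, 0.5)
    doses <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  })
  # the generating frequencies make E[diag] = 1 exact; sample-estimated
  # frequencies would shrink the diagonal by a factor (n-1)/n
  G <- make_grm(doses, p, "additive")
  D <- make_grm(doses, p, "dominance")
  off <- G$values[upper.tri(G$values)]
  expect_equal(mean(diag(G$values)), 1,
               tolerance = 3 * sd(diag(G$values)) / sqrt(n))
  expect_equal(mean(diag(D$values)), 1,
               tolerance = 3 * sd(diag(D$values)) / sqrt(n))
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)))
})

test_that("half-sib pairs average 0.25 additive relationship", {
  pop <- small_pop()
  # centering on the generating founder frequencies keeps E[G_ij] = 0.25
  # exact for paternal half-sibs; sample-frequency centering would shift
  # every pair down by the average relatedness in the sample
  G <- make_grm(pop$pop$genotypes$doses, pop$pop$founder_freq,
                "additive")$values
  samp <- pop$pop$samples
  hs <- which(outer(samp$sire_id, samp$sire_id, "==") &
                outer(samp$dam_id, samp$dam_id, "!=") &
                upper.tri(G), arr.ind = TRUE)
  # pairs within a sire family are correlated; take the Monte-Carlo error
  # over independent sire-family means
  fam_means <- tapply(G[hs], samp$sire_id[hs[, 1]], mean)
  expect_equal(mean(fam_means), 0.25,
               tolerance = 3 * sd(fam_means) / sqrt(length(fam_means)))
})

test_that("stabilize adds the ridge and records it", {
  pop <- small_pop()
  doses <- pop$pop$genotypes$doses[1:5, 1:2]
  p <- pmin(pmax(estimate_frequencies(doses), 0.05), 0.95)
  K <- make_grm(doses, p, "additive")     # rank <= 2, n = 5
  expect_lt(min(eigen(K$values, symmetric = TRUE)$values), 1e-10)
  K2 <- stabilize(K, 1e-6)
  expect_gte(min(eigen(K2$values, symmetric = TRUE)$values), 1e-6 - 1e-10)
  expect_equal(K2$ridge, 1e-6)
  expect_identical(stabilize(K, 0)$values, K$values)
})

test_that("kinship text and GCTA binary exports round-trip", {
  pop <- small_pop()
  G <- make_grm(pop$pop$genotypes$doses[1:20, 1:100],
                pmin(pmax(pop$p[1:100], 0.01), 0.99), "additive")
  dir <- withr::local_tempdir()
  f <- file.path(dir, "kin.tsv")
  write_kinship(G, f)
  back <- read_kinship(f)
  expect_equal(back$values, G$values, tolerance = 1e-12)
  expect_equal(back$denominator, G$denominator)
  expect_identical(back$kind, "G")

  write_grm_gcta(G, file.path(dir, "kin"), n_markers = 100)
  gcta <- read_grm_gcta(file.path(dir, "kin"))
  # float32 storage: 1e-6 relative accuracy
  expect_equal(gcta$values, G$values, tolerance = 1e-5)
  expect_identical(rownames(gcta$values), rownames(G$values))
})
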