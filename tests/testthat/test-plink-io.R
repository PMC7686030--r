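test_that("PLINK round-trip preserves doses and missingness", {
  withr::with_seed(11, {
    for (n in c(3, 5, 17)) {
      doses <- matrix(sample(c(0:2, NA), n * 7, replace = TRUE), n, 7)
      geno <- toy_genotypes(doses)
      prefix <- file.path(withr::local_tempdir(), "rt")
      write_plink(geno, prefix)
      back <- read_plink(prefix)
      expect_identical(unname(back$doses), unname(geno$doses))
      expect_identical(back$map$marker_id, geno$map$marker_id)
      expect_identical(back$fam$iid, geno$fam$iid)
    }
  })
})

test_that("re-exporting an imported fileset is byte-identical", {
  withr::with_seed(12, {
    doses <- matrix(sample(c(0:2, NA), 60 * 25, replace = TRUE,
                           prob = c(0.3, 0.3, 0.3, 0.1)), 60, 25)
  })
  geno <- toy_genotypes(doses)
  dir <- withr::local_tempdir()
  write_plink(geno, file.path(dir, "a"))
  write_plink(read_plink(file.path(dir, "a")), file.path(dir, "b"))
  for (ext in c(".bed", ".bim", ".fam")) {
    expect_identical(readBin(file.path(dir, paste0("a", ext)), "raw", 1e5),
                     readBin(file.path(dir, paste0("b", ext)), "raw", 1e5))
  }
})

test_that("hand-built .bed decodes to the expected doses", {
  # n = 3 individuals, m = 2 markers, SNP-major: one byte per marker.
  # marker 1: ind1 hom A1 (00), ind2 het (10), ind3 missing (01)
  #   byte = 00 | 01<<4 | 10<<2 | 00 = 0b00011000 = 0x18
  # marker 2: ind1 hom A2 (11), ind2 hom A1 (00), ind3 het (10)
  #   byte = 0b00100011 = 0x23
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x18, 0x23)),
           paste0(prefix, ".bed"))
  writeLines(c("1\tM1\t0\t100\tA\tB", "1\tM2\t0\t200\tA\tB"),
             paste0(prefix, ".bim"))
  writeLines(c("F 1 0 0 1 -9", "F 2 0 0 1 -9", "F 3 0 0 2 -9"),
             paste0(prefix, ".fam"))
  geno <- read_plink(prefix)
  expect_identical(unname(geno$doses),
                   matrix(c(2L, 1L, NA, 0L, 2L, 1L), 3, 2))
})

test_that("malformed filesets are rejected with informative errors", {
  dir <- withr::local_tempdir()
  geno <- toy_genotypes(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 3, 2))
  prefix <- file.path(dir, "ok")
  write_plink(geno, prefix)

  expect_error(read_plink(file.path(dir, "absent")), "absent\\.bed")

  bad <- readBin(paste0(prefix, ".bed"), "raw", 100)
  writeBin(c(as.raw(c(0x00, 0x1b)), bad[-(1:2)]),
           file.path(dir, "magic.bed"))
  file.copy(paste0(prefix, c(".bim", ".fam")),
            file.path(dir, paste0("magic", c(".bim", ".fam"))))
  expect_error(read_plink(file.path(dir, "magic")), "magic")

  writeBin(c(bad[1:2], as.raw(0x00), bad[-(1:3)]),
           file.path(dir, "indmajor.bed"))
  file.copy(paste0(prefix, c(".bim", ".fam")),
            file.path(dir, paste0("indmajor", c(".bim", ".fam"))))
  expect_error(read_plink(file.path(dir, "indmajor")), "individual-major")

  writeBin(bad[-length(bad)], file.path(dir, "trunc.bed"))
  file.copy(paste0(prefix, c(".bim", ".fam")),
            file.path(dir, paste0("trunc", c(".bim", ".fam"))))
  expect_error(read_plink(file.path(dir, "trunc")), "expected [0-9]+ bytes")
})

test_that("allele frequency estimation matches hand counts", {
  expect_equal(unname(estimate_frequencies(matrix(c(0L, 1L, 2L), 3, 1))), 0.5)
  expect_equal(unname(estimate_frequencies(matrix(c(2L, 2L, 2L), 3, 1))), 1.0)
  # doses 0,1,NA,2,1 -> 4 A1 alleles among 8 called
  expect_equal(unname(estimate_frequencies(
    matrix(c(0L, 1L, NA, 2L, 1L), 5, 1))), 0.5)
  # invariant to individual ordering
  withr::with_seed(5, {
    doses <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 20, 10)
    perm <- sample(20)
  })
  expect_equal(estimate_frequencies(doses),
               estimate_frequencies(doses[perm, ]))
  expect_warning(estimate_frequencies(matrix(NA_integer_, 3, 1)),
                 "no non-missing")
})

test_that("mean imputation fills 2p and leaves observed calls alone", {
  doses <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), 3, 2)
  p <- c(0.5, 0.25)
  imp <- impute_missing(doses, p)
  expect_equal(imp[1, 2], 0.5)          # 2 * 0.25
  expect_equal(imp[-4], as.numeric(doses[-4]))
  # no missing entries: identity
  expect_identical(impute_missing(doses[, 1, drop = FALSE], 0.5),
                   matrix(c(0, 1, 2), 3, 1))
  # column means equal 2p when p is estimated from the data
  withr::with_seed(6, {
    dd <- matrix(sample(c(0:2, NA), 400, replace = TRUE), 40, 10)
  })
  pp <- estimate_frequencies(dd)
  expect_equal(unname(colMeans(impute_missing(dd, pp)) - 2 * pp),
               rep(0, 10), tolerance = 1e-12)
  expect_error(impute_missing(matrix(NA_integer_, 3, 1), NA_real_),
               "undefined")
})
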