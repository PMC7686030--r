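#' Genotype container
#'
#' Bundles an allele-dose matrix with its marker map and sample pedigree
#' records, mirroring a PLINK 1 binary fileset held in memory.
#'
#' @param doses integer matrix, individuals in rows and markers in columns.
#'   Each entry counts copies of the A1 allele (0, 1 or 2); `NA` marks a
#'   missing call. Row names are individual ids, column names marker ids.
#' @param map data.frame with one row per marker: `chrom`, `marker_id`, `cm`,
#'   `pos`, `a1`, `a2` and optionally `freq` (estimated A1 frequency).
#' @param fam data.frame with one row per individual: `fid`, `iid`, `father`,
#'   `mother`, `sex_code`, `phenotype` (PLINK .fam layout).
#'
#' @return An object of class `genotypes`.
#' @export
genotypes <- function(doses, map, fam) {
  doses <- as.matrix(doses)
  storage.mode(doses) <- "integer"
  bad <- !is.na(doses) & !(doses %in% 0:2)
  if (any(bad)) {
    stop("genotype doses must be 0, 1, 2 or NA; found ", doses[bad][1L])
  }
  if (nrow(map) != ncol(doses)) {
    stop("map has ", nrow(map), " markers but dose matrix has ", ncol(doses),
         " columns")
  }
  if (nrow(fam) != nrow(doses)) {
    stop("fam has ", nrow(fam), " individuals but dose matrix has ",
         nrow(doses), " rows")
  }
  if (anyDuplicated(fam$iid)) stop("individual ids must be unique")
  rownames(doses) <- as.character(fam$iid)
  colnames(doses) <- as.character(map$marker_id)
  structure(list(doses = doses, map = as.data.frame(map),
                 fam = as.data.frame(fam)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  miss <- mean(is.na(x$doses))
  cat(sprintf("genotypes: %d individuals x %d markers (%.2f%% missing)\n",
              nrow(x$doses), ncol(x$doses), 100 * miss))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$doses)

# 2-bit PLINK genotype codes, SNP-major:
#   00 -> homozygous A1 (dose 2), 01 -> missing, 10 -> het (1), 11 -> hom A2 (0)
.bed_dose_of_code <- c(2L, NA_integer_, 1L, 0L)
.bed_code_of_dose <- function(d) {
  code <- integer(length(d))            # dose 2 -> 00
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  code
}

#' Read a PLINK 1 binary fileset
#'
#' Decodes the SNP-major 2-bit `.bed` payload together with its `.bim` marker
#' map and `.fam` sample table.
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotypes] object.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) stop("PLINK fileset member not found: ", p)
  }
  fam <- data.table::fread(paths[3L], header = FALSE, data.table = FALSE,
                           colClasses = list(character = 1:4))
  names(fam) <- c("fid", "iid", "father", "mother", "sex_code", "phenotype")
  bim <- data.table::fread(paths[2L], header = FALSE, data.table = FALSE,
                           colClasses = list(character = c(1, 2, 5, 6)))
  names(bim) <- c("chrom", "marker_id", "cm", "pos", "a1", "a2")

  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1L], "raw", n = file.size(paths[1L]))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b)) {
    stop("not a PLINK 1 .bed file (bad magic bytes): ", paths[1L])
  }
  if (raw[3L] == as.raw(0x00)) {
    stop("individual-major .bed files are not supported: ", paths[1L])
  }
  if (raw[3L] != as.raw(0x01)) {
    stop("unrecognised .bed mode byte: ", as.integer(raw[3L]))
  }
  bpm <- ceiling(n / 4)                 # bytes per marker, SNP-major
  expected <- 3L + bpm * m
  if (length(raw) != expected) {
    stop(sprintf(".bed payload truncated or oversized: expected %d bytes, found %d",
                 expected, length(raw)))
  }
  doses <- .bed_decode(raw[-(1:3)], n, m)
  genotypes(doses, bim, fam)
}

.bed_decode <- function(payload, n, m) {
  bpm <- ceiling(n / 4)
  b <- matrix(as.integer(payload), nrow = bpm, ncol = m)
  out <- matrix(NA_integer_, nrow = 4L * bpm, ncol = m)
  for (k in 0:3) {                      # sample k within byte = bits 2k..2k+1
    code <- (b %/% 4L^k) %% 4L
    out[seq.int(k + 1L, by = 4L, length.out = bpm), ] <-
      .bed_dose_of_code[code + 1L]
  }
  out[seq_len(n), , drop = FALSE]
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: emits a SNP-major `.bed` (padding bits zero)
#' plus the `.bim` and `.fam` tables.
#'
#' @param geno a [genotypes] object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotypes"))
  n <- nrow(geno$doses)
  m <- ncol(geno$doses)
  bpm <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4L * bpm, ncol = m)
  codes[seq_len(n), ] <- .bed_code_of_dose(geno$doses)
  b <- matrix(0L, nrow = bpm, ncol = m)
  for (k in 0:3) {
    b <- b + codes[seq.int(k + 1L, by = 4L, length.out = bpm), , drop = FALSE] * 4L^k
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(b), con)
  utils::write.table(geno$map[c("chrom", "marker_id", "cm", "pos", "a1", "a2")],
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(geno$fam[c("fid", "iid", "father", "mother", "sex_code",
                                "phenotype")],
                     paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
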