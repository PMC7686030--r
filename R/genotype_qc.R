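#' Estimate per-marker allele frequencies
#'
#' Frequency of the counted (A1) allele from the non-missing calls:
#' `sum(doses) / (2 * n_called)` per marker.
#'
#' @param x a [genotypes] object or a dose matrix (individuals x markers).
#' @return Named numeric vector of A1 frequencies; `NA` for markers with no
#'   non-missing call (flagged with a warning).
#' @export
estimate_frequencies <- function(x) {
  doses <- if (inherits(x, "genotypes")) x$doses else as.matrix(x)
  n_called <- colSums(!is.na(doses))
  p <- colSums(doses, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  if (anyNA(p)) {
    warning(sum(is.na(p)), " marker(s) have no non-missing call; ",
            "frequency undefined")
  }
  p
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele counts
#' (the SNP-HWE recurrence used by PLINK): the p-value is the total
#' probability of heterozygote counts whose conditional probability does not
#' exceed that of the observed count.
#'
#' @param n_aa,n_ab,n_bb genotype counts (A1 homozygote, heterozygote, A2
#'   homozygote). Vectors are recycled to a common length.
#' @return p-value(s) in (0, 1]. Monomorphic markers return 1 by convention.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  k <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(n_aa, k); n_ab <- rep_len(n_ab, k); n_bb <- rep_len(n_bb, k)
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be non-negative")
  if (any(n_aa + n_ab + n_bb < 1)) stop("at least one genotyped individual required")
  vapply(seq_len(k), function(i) .hwe_exact1(n_aa[i], n_ab[i], n_bb[i]),
         numeric(1))
}

.hwe_exact1 <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  rare <- 2L * min(n_aa, n_bb) + n_ab   # count of the rarer allele
  if (rare == 0L) return(1)             # monomorphic: test undefined
  # conditional distribution of the het count over h in {rare, rare-2, ...}
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hs))
  names(probs) <- hs
  probs[as.character(mid)] <- 1
  h <- mid
  while (h >= 2L) {                     # downward recurrence
    probs[as.character(h - 2L)] <- probs[as.character(h)] *
      h * (h - 1) / ((rare - h + 2) * (2 * n - rare - h + 2))
    h <- h - 2L
  }
  h <- mid
  while (h <= rare - 2L) {              # upward recurrence
    probs[as.character(h + 2L)] <- probs[as.character(h)] *
      (rare - h) * (2 * n - rare - h) / ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  obs <- probs[as.character(n_ab)]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

#' Marker and sample quality-control thresholds
#'
#' @param snp_call_rate_min minimum fraction of non-missing calls per marker.
#' @param hwe_p_min markers with exact HWE p-value below this are removed.
#' @param maf_min minimum minor allele frequency.
#' @param sample_missing_max maximum fraction of missing genotypes per
#'   individual.
#' @param autosomes_only drop markers on sex/mitochondrial/unplaced
#'   chromosomes (labels X, Y, XY, MT, M, 0 or non-numeric).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.95, hwe_p_min = 1e-6,
                          maf_min = 0.01, sample_missing_max = 0.10,
                          autosomes_only = TRUE) {
  fr <- c(snp_call_rate_min = snp_call_rate_min, hwe_p_min = hwe_p_min,
          maf_min = maf_min, sample_missing_max = sample_missing_max)
  if (any(fr < 0 | fr > 1)) {
    stop("QC thresholds must lie in [0, 1]; got ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  }
  structure(list(snp_call_rate_min = snp_call_rate_min, hwe_p_min = hwe_p_min,
                 maf_min = maf_min, sample_missing_max = sample_missing_max,
                 autosomes_only = autosomes_only),
            class = "qc_thresholds")
}

.is_autosome <- function(chrom) {
  lab <- toupper(trimws(as.character(chrom)))
  suppressWarnings(num <- as.numeric(lab))
  !(lab %in% c("X", "Y", "XY", "MT", "M", "0")) & !is.na(num) & num >= 1
}

#' Apply quality control to a genotype set
#'
#' Filter order (each marker/sample is counted once, at the first filter
#' removing it): individual missingness, marker call rate, minor allele
#' frequency, exact Hardy-Weinberg test, autosome restriction. Marker call
#' rate, MAF and HWE are evaluated on the individuals that survive the
#' missingness filter.
#'
#' @param geno a [genotypes] object.
#' @param thresholds a [qc_thresholds] list.
#' @return A list with elements `genotypes` (filtered, with `map$freq` set
#'   from the retained individuals) and `report` (a `qc_report`).
#' @export
apply_qc <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotypes"), inherits(thresholds, "qc_thresholds"))
  doses <- geno$doses
  n_in <- nrow(doses)
  m_in <- ncol(doses)

  samp_miss <- rowMeans(is.na(doses))
  keep_ind <- samp_miss <= thresholds$sample_missing_max
  doses <- doses[keep_ind, , drop = FALSE]

  call_rate <- colMeans(!is.na(doses))
  fail_call <- call_rate < thresholds$snp_call_rate_min

  p <- suppressWarnings(estimate_frequencies(doses))
  maf <- pmin(p, 1 - p)
  fail_maf <- !fail_call & (is.na(maf) | maf < thresholds$maf_min)

  todo <- which(!fail_call & !fail_maf)
  fail_hwe <- logical(m_in)
  if (length(todo)) {
    n_aa <- colSums(doses[, todo, drop = FALSE] == 2L, na.rm = TRUE)
    n_ab <- colSums(doses[, todo, drop = FALSE] == 1L, na.rm = TRUE)
    n_bb <- colSums(doses[, todo, drop = FALSE] == 0L, na.rm = TRUE)
    fail_hwe[todo] <- hwe_exact_test(n_aa, n_ab, n_bb) < thresholds$hwe_p_min
  }

  fail_auto <- if (thresholds$autosomes_only) {
    !fail_call & !fail_maf & !fail_hwe & !.is_autosome(geno$map$chrom)
  } else {
    logical(m_in)
  }

  keep_mrk <- !(fail_call | fail_maf | fail_hwe | fail_auto)
  if (!any(keep_mrk)) stop("no markers survive quality control")
  if (!any(keep_ind)) stop("no individuals survive quality control")

  map <- geno$map[keep_mrk, , drop = FALSE]
  map$freq <- p[keep_mrk]
  out <- genotypes(doses[, keep_mrk, drop = FALSE], map,
                   geno$fam[keep_ind, , drop = FALSE])
  report <- structure(list(
    n_individuals_in = n_in, n_individuals_out = sum(keep_ind),
    n_markers_in = m_in, n_markers_out = sum(keep_mrk),
    removed = data.frame(
      filter = c("sample_missingness", "snp_call_rate", "maf", "hwe",
                 "non_autosomal"),
      axis = c("individual", rep("marker", 4L)),
      n_removed = c(sum(!keep_ind), sum(fail_call), sum(fail_maf),
                    sum(fail_hwe), sum(fail_auto))),
    thresholds = thresholds), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d -> %d individuals, %d -> %d markers\n",
              x$n_individuals_in, x$n_individuals_out,
              x$n_markers_in, x$n_markers_out))
  print(x$removed, row.names = FALSE)
  invisible(x)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing dose at marker i by its marker mean `2 * p_i`;
#' non-missing entries are unchanged. The result is real-valued.
#'
#' @param x a [genotypes] object or dose matrix.
#' @param freq A1 frequencies; taken from `x$map$freq` (or re-estimated) when
#'   omitted.
#' @return Numeric matrix with no missing entries.
#' @export
impute_missing <- function(x, freq = NULL) {
  doses <- if (inherits(x, "genotypes")) x$doses else as.matrix(x)
  if (is.null(freq)) {
    freq <- if (inherits(x, "genotypes") && !is.null(x$map$freq)) {
      x$map$freq
    } else {
      estimate_frequencies(doses)
    }
  }
  if (length(freq) != ncol(doses)) stop("one frequency per marker required")
  if (anyNA(freq)) {
    stop("frequency undefined for marker(s) ",
         paste(utils::head(which(is.na(freq)), 3), collapse = ", "),
         "; run QC first")
  }
  out <- matrix(as.numeric(doses), nrow(doses), ncol(doses),
                dimnames = dimnames(doses))
  idx <- which(is.na(out))
  if (length(idx)) {
    out[idx] <- 2 * freq[(idx - 1L) %/% nrow(out) + 1L]
  }
  out
}

#' Inject missing calls into a genotype set
#'
#' Sets a random fraction of dose entries to `NA`; used to exercise call-rate
#' filters and imputation on simulated data.
#'
#' @param geno a [genotypes] object.
#' @param rate fraction of entries to blank, in [0, 1).
#' @param seed integer seed for reproducibility.
#' @return The modified [genotypes] object.
#' @export
inject_missing <- function(geno, rate, seed = 1L) {
  stopifnot(inherits(geno, "genotypes"), rate >= 0, rate < 1)
  n_cells <- length(geno$doses)
  idx <- withr::with_seed(seed,
    sample.int(n_cells, size = round(rate * n_cells)))
  geno$doses[idx] <- NA_integer_
  geno
}
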