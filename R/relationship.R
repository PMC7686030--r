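#' Additive marker design matrix
#'
#' VanRaden centering: entry (j, i) is `dose(j, i) - 2 * p_i`. A missing dose
#' contributes 0, which is exactly the value obtained by mean-imputing the
#' dose to `2 * p_i` before centering.
#'
#' @param doses individuals x markers dose matrix (0/1/2, `NA` allowed).
#' @param freq A1 frequency per marker, strictly inside (0, 1).
#' @return A `marker_design` object (list: `values`, `kind = "additive"`,
#'   `freq`).
#' @export
build_additive_design <- function(doses, freq) {
  .check_design_inputs(doses, freq)
  w <- sweep(matrix(as.numeric(doses), nrow(doses), ncol(doses),
                    dimnames = dimnames(doses)), 2L, 2 * freq)
  w[is.na(w)] <- 0
  structure(list(values = w, kind = "additive", freq = freq),
            class = "marker_design")
}

#' Dominance marker design matrix
#'
#' Classical dominance-deviation coding: with p the A1 frequency and
#' q = 1 - p, genotypes A1A1 / A1A2 / A2A2 (doses 2 / 1 / 0) are coded
#' `-2q^2` / `2pq` / `-2p^2`. The coded value has expectation 0 under
#' Hardy-Weinberg proportions and is symmetric under allele relabelling.
#' Missing doses are coded 0 (the HWE expectation).
#'
#' @inheritParams build_additive_design
#' @return A `marker_design` object with `kind = "dominance"`.
#' @export
build_dominance_design <- function(doses, freq) {
  .check_design_inputs(doses, freq)
  n <- nrow(doses); m <- ncol(doses)
  p <- matrix(freq, n, m, byrow = TRUE)
  q <- 1 - p
  w <- matrix(0, n, m, dimnames = dimnames(doses))
  w[!is.na(doses) & doses == 2L] <- (-2 * q^2)[!is.na(doses) & doses == 2L]
  w[!is.na(doses) & doses == 1L] <- (2 * p * q)[!is.na(doses) & doses == 1L]
  w[!is.na(doses) & doses == 0L] <- (-2 * p^2)[!is.na(doses) & doses == 0L]
  structure(list(values = w, kind = "dominance", freq = freq),
            class = "marker_design")
}

.check_design_inputs <- function(doses, freq) {
  if (length(freq) != ncol(doses)) stop("one frequency per marker required")
  if (anyNA(freq) || any(freq <= 0 | freq >= 1)) {
    stop("frequencies must lie strictly inside (0, 1); ",
         "fixed or undefined markers should have been MAF-filtered")
  }
  invisible(TRUE)
}

.grm_denominator <- function(kind, freq) {
  d <- switch(kind,
              additive  = 2 * sum(freq * (1 - freq)),
              dominance = 4 * sum(freq^2 * (1 - freq)^2),
              stop("unknown design kind: ", kind))
  if (d <= 0) stop("zero relationship-matrix denominator")
  d
}

#' Genomic relationship matrix from a marker design
#'
#' `W %*% t(W) / denom` with the kind-specific VanRaden denominator:
#' `2 * sum(p_i (1 - p_i))` for the additive design and
#' `4 * sum(p_i^2 (1 - p_i)^2)` for the dominance design. Symmetry is
#' enforced by averaging with the transpose.
#'
#' @param design a `marker_design` from [build_additive_design()] or
#'   [build_dominance_design()].
#' @return A `kinship` object (list: `values`, `kind` ("G" or "D"),
#'   `denominator`, `ridge`).
#' @export
build_grm <- function(design) {
  stopifnot(inherits(design, "marker_design"))
  if (ncol(design$values) == 0L) stop("empty marker design")
  denom <- .grm_denominator(design$kind, design$freq)
  k <- tcrossprod(design$values) / denom
  k <- (k + t(k)) / 2
  structure(list(values = k,
                 kind = if (design$kind == "additive") "G" else "D",
                 denominator = denom, ridge = 0),
            class = "kinship")
}

#' Genomic relationship matrix from doses, in marker blocks
#'
#' Builds G or D without holding the full n x m design in memory: markers are
#' processed in blocks and their cross-products accumulated. The block size
#' changes nothing beyond floating-point reassociation (see tests).
#'
#' @param doses individuals x markers dose matrix (`NA` allowed).
#' @param freq A1 frequency per marker.
#' @param kind `"additive"` (G) or `"dominance"` (D).
#' @param block_size number of markers per block.
#' @return A `kinship` object.
#' @export
make_grm <- function(doses, freq, kind = c("additive", "dominance"),
                     block_size = 2000L) {
  kind <- match.arg(kind)
  .check_design_inputs(doses, freq)
  n <- nrow(doses); m <- ncol(doses)
  builder <- if (kind == "additive") build_additive_design else build_dominance_design
  acc <- matrix(0, n, n)
  for (from in seq.int(1L, m, by = block_size)) {
    to <- min(from + block_size - 1L, m)
    w <- builder(doses[, from:to, drop = FALSE], freq[from:to])
    acc <- acc + tcrossprod(w$values)
  }
  denom <- .grm_denominator(kind, freq)
  k <- (acc + t(acc)) / (2 * denom)
  dimnames(k) <- list(rownames(doses), rownames(doses))
  structure(list(values = k, kind = if (kind == "additive") "G" else "D",
                 denominator = denom, ridge = 0),
            class = "kinship")
}

#' Add a ridge to a kinship matrix diagonal
#'
#' A small diagonal inflation keeps the mixed-model coefficient matrix
#' invertible when n exceeds the effective marker rank; the amount applied is
#' recorded in the object's metadata.
#'
#' @param kinship a `kinship` object.
#' @param ridge non-negative scalar added to the diagonal.
#' @return The stabilized `kinship` object.
#' @export
stabilize <- function(kinship, ridge = 1e-6) {
  stopifnot(inherits(kinship, "kinship"), ridge >= 0)
  if (ridge > 0) {
    diag(kinship$values) <- diag(kinship$values) + ridge
    kinship$ridge <- kinship$ridge + ridge
  }
  kinship
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("%s kinship matrix: %d individuals, denominator %.4f, ridge %g\n",
              x$kind, nrow(x$values), x$denominator, x$ridge))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(x$values)),
              (sum(x$values) - sum(diag(x$values))) /
                (length(x$values) - nrow(x$values))))
  invisible(x)
}

#' Export / import a kinship matrix as delimited text
#'
#' Dense tab-separated matrix with individual ids as header row and first
#' column; kind, denominator and ridge are carried in `#`-prefixed header
#' lines so the object round-trips.
#'
#' @param kinship a `kinship` object.
#' @param path output file.
#' @return `path` invisibly (writer); a `kinship` object (reader).
#' @export
write_kinship <- function(kinship, path) {
  stopifnot(inherits(kinship, "kinship"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", kinship$kind),
               sprintf("# denominator: %.17g", kinship$denominator),
               sprintf("# ridge: %.17g", kinship$ridge)), con)
  df <- data.frame(id = rownames(kinship$values),
                   format(kinship$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE)
  names(df) <- c("id", colnames(kinship$values))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  hdr <- readLines(path, n = 3L)
  if (!all(startsWith(hdr, "#"))) stop("not a kinship text file: ", path)
  val <- function(i) sub("^# [a-z]+: ", "", hdr[i])
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 3L,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(m) <- list(tab$id, tab$id)
  structure(list(values = m, kind = val(1),
                 denominator = as.numeric(val(2)), ridge = as.numeric(val(3))),
            class = "kinship")
}

#' Export / import a kinship matrix in GCTA GRM binary layout
#'
#' `<prefix>.grm.bin` holds the lower triangle (diagonal included,
#' row-major) as little-endian float32, `<prefix>.grm.N.bin` the per-pair
#' marker counts in the same layout, and `<prefix>.grm.id` the FID/IID
#' table.
#'
#' @param kinship a `kinship` object.
#' @param prefix file prefix.
#' @param n_markers marker count written to the N file.
#' @return `prefix` invisibly (writer); a `kinship` object (reader; kind and
#'   denominator are not represented in this format and default to `"G"`/NA).
#' @export
write_grm_gcta <- function(kinship, prefix, n_markers = NA_real_) {
  stopifnot(inherits(kinship, "kinship"))
  n <- nrow(kinship$values)
  lower <- kinship$values[upper.tri(kinship$values, diag = TRUE)]
  # upper.tri of the transpose enumerates the lower triangle row-major;
  # for a symmetric matrix column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_markers), length(lower)), con, size = 4L,
           endian = "little")
  close(con)
  ids <- rownames(kinship$values)
  utils::write.table(data.frame(fid = ids, iid = ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")[[2L]]
  n <- length(ids)
  sz <- n * (n + 1) / 2
  lower <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = sz, size = 4L,
                   endian = "little")
  if (length(lower) != sz) {
    stop(sprintf("GRM binary truncated: expected %d values, found %d",
                 sz, length(lower)))
  }
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m, diag = TRUE)] <- lower
  m <- m + t(m) - diag(diag(m))
  structure(list(values = m, kind = "G", denominator = NA_real_, ridge = 0),
            class = "kinship")
}
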