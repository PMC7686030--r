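# Shared simulated populations, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# Small half-sib population with an additive trait (h2 = 0.5 scale).
small_pop <- function() {
  if (is.null(.fixtures$small)) {
    sc <- sim_scenario(n_progeny = 180, n_sires = 9, n_markers = 600)
    pop <- simulate_founders_and_gametes(sc, seed = 42)
    ph <- simulate_phenotypes(pop, seed = 43)
    p <- estimate_frequencies(pop$genotypes)
    G <- stabilize(make_grm(pop$genotypes$doses, p, "additive"))
    D <- stabilize(make_grm(pop$genotypes$doses, p, "dominance"))
    X <- build_fixed_design(ph$pheno)
    .fixtures$small <- list(pop = pop, pheno = ph$pheno, truth = ph$truth,
                            p = p, G = G, D = D, X = X)
  }
  .fixtures$small
}

# Tiny genotype object built by hand.
toy_genotypes <- function(doses, chrom = NULL) {
  n <- nrow(doses)
  m <- ncol(doses)
  map <- data.frame(chrom = chrom %||% rep(1L, m),
                    marker_id = sprintf("M%02d", seq_len(m)),
                    cm = 0, pos = seq_len(m), a1 = "A", a2 = "B")
  fam <- data.frame(fid = "F1", iid = sprintf("ID%02d", seq_len(n)),
                    father = "0", mother = "0", sex_code = 1L,
                    phenotype = -9L)
  genotypes(doses, map, fam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force restricted log-likelihood via explicit dense inverses and
# determinants -- the independent oracle for the REML objective.
naive_restricted_loglik <- function(y, X, kinships, sigma2) {
  n <- length(y)
  V <- diag(sigma2[["e"]], n)
  for (nm in names(kinships)) V <- V + sigma2[[nm]] * kinships[[nm]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              drop(t(y) %*% P %*% y) + (n - ncol(X)) * log(2 * pi)))
}

# Exact HWE p-value by direct evaluation of the conditional distribution of
# the heterozygote count with log-factorials (independent of the package's
# recurrence implementation).
naive_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab                # A1 allele count
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hs <- seq.int(rare %% 2, rare, by = 2)
  # P(h) proportional to n! 2^h / (hom_rare! h! hom_common!); the
  # rare-allele-count terms cancel in the normalisation over h
  logp <- vapply(hs, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    h * log(2) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}
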