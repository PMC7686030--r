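#' Simulation scenario for a half-sib population
#'
#' Generative parameters emulating a single-generation sheep population:
#' offspring of a modest number of sires mated to mostly-unique dams (so the
#' population is dominated by paternal half-sib families with a small
#' full-sib fraction), distributed over herds and sexes, genotyped at
#' unlinked SNPs whose allele frequencies follow a uniform law. Defaults
#' mirror the study population this package was built around: 498 offspring
#' of 26 sires, 7 herds, 295 males / 203 females, under 12% full-sibs, with
#' a staple-length-like trait architecture (sigma2_a = 40, sigma2_d = 0,
#' sigma2_e = 40, mean 83.5).
#'
#' @param n_progeny number of genotyped, phenotyped offspring.
#' @param n_sires number of sires.
#' @param n_herds number of herds (labelled `H1`, `H2`, ...).
#' @param prop_male fraction of male offspring (assigned exactly).
#' @param full_sib_fraction target fraction of offspring that belong to a
#'   full-sib pair, in [0, 1).
#' @param n_markers number of unlinked SNPs, assigned round-robin to 26
#'   autosomes.
#' @param maf_range allele frequencies are drawn uniformly on this interval;
#'   the lower bound must be positive.
#' @param mean trait intercept (units of the trait).
#' @param sigma2_a,sigma2_d,sigma2_e true additive, dominance and residual
#'   variances (squared trait units).
#' @param sex_effect additive fixed effect of being male (trait units).
#' @param herd_effects fixed effect per herd, length `n_herds`.
#' @return A validated list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_progeny = 498L, n_sires = 26L, n_herds = 7L,
                         prop_male = 295 / 498, full_sib_fraction = 0.08,
                         n_markers = 5000L, maf_range = c(0.05, 0.5),
                         mean = 83.5, sigma2_a = 40, sigma2_d = 0,
                         sigma2_e = 40, sex_effect = 3,
                         herd_effects = seq(-4, 4, length.out = n_herds)) {
  stopifnot(n_progeny >= n_sires, n_sires >= 1, n_herds >= 1,
            prop_male >= 0, prop_male <= 1,
            full_sib_fraction >= 0, full_sib_fraction < 1,
            n_markers >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            sigma2_a >= 0, sigma2_d >= 0, sigma2_e >= 0,
            length(herd_effects) == n_herds)
  structure(as.list(environment()), class = "sim_scenario")
}

#' Simulate founder genotypes and Mendelian gametes
#'
#' Sires and dams are drawn from Hardy-Weinberg proportions at each marker's
#' allele frequency; each offspring receives one allele per marker from its
#' sire and one from its dam by independent Mendelian sampling (unlinked
#' loci). Full-sib pairs are created by letting pairs of offspring of the
#' same sire share a dam until the target full-sib fraction is met; all
#' other dams are unique, making the remaining paternal sibs half-sibs.
#'
#' @param scenario a [sim_scenario].
#' @param seed integer seed.
#' @return List of class `sim_population`: `genotypes` (a [genotypes]
#'   object), `samples` (data.frame: `individual_id`, `sex` ("F"/"M"),
#'   `herd`, `sire_id`, `dam_id`), `founder_freq` (the generating allele
#'   frequencies), `scenario`, `seed`.
#' @export
simulate_founders_and_gametes <- function(scenario = sim_scenario(),
                                          seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  withr::with_seed(seed, {
    m <- sc$n_markers
    n <- sc$n_progeny
    p <- stats::runif(m, sc$maf_range[1], sc$maf_range[2])

    sire_doses <- matrix(stats::rbinom(sc$n_sires * m, 2L, rep(p, each = sc$n_sires)),
                         sc$n_sires, m)
    sizes <- rep(n %/% sc$n_sires, sc$n_sires)
    extra <- n %% sc$n_sires
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sire_of <- rep(seq_len(sc$n_sires), sizes)

    # full-sib pairs: within a sire's progeny, two offspring share a dam
    dam_of <- seq_len(n)
    n_pairs <- floor(round(sc$full_sib_fraction * n) / 2)
    if (n_pairs > 0) {
      avail <- split(seq_len(n), sire_of)
      s <- 1L
      made <- 0L
      while (made < n_pairs) {
        if (length(avail[[s]]) >= 2L) {
          pair <- avail[[s]][1:2]
          dam_of[pair[2L]] <- dam_of[pair[1L]]
          avail[[s]] <- avail[[s]][-(1:2)]
          made <- made + 1L
        }
        s <- s %% sc$n_sires + 1L
        if (all(lengths(avail) < 2L)) break
      }
    }
    dam_ids <- match(dam_of, sort(unique(dam_of)))
    n_dams <- max(dam_ids)
    dam_doses <- matrix(stats::rbinom(n_dams * m, 2L, rep(p, each = n_dams)),
                        n_dams, m)

    sire_gam <- matrix(stats::rbinom(n * m, 1L,
                                     sire_doses[sire_of, , drop = FALSE] / 2),
                       n, m)
    dam_gam <- matrix(stats::rbinom(n * m, 1L,
                                    dam_doses[dam_ids, , drop = FALSE] / 2),
                      n, m)
    doses <- sire_gam + dam_gam

    n_male <- round(sc$prop_male * n)
    sex <- sample(c(rep("M", n_male), rep("F", n - n_male)))
    herd <- paste0("H", sample.int(sc$n_herds, n, replace = TRUE))
    ids <- sprintf("ID%04d", seq_len(n))

    map <- data.frame(chrom = rep_len(1:26, m),
                      marker_id = sprintf("M%05d", seq_len(m)),
                      cm = 0, pos = seq_len(m) * 1000L,
                      a1 = "A", a2 = "B")
    fam <- data.frame(fid = herd, iid = ids,
                      father = sprintf("S%02d", sire_of),
                      mother = sprintf("D%04d", dam_ids),
                      sex_code = ifelse(sex == "M", 1L, 2L), phenotype = -9L)
    samples <- data.frame(individual_id = ids, sex = sex, herd = herd,
                          sire_id = sprintf("S%02d", sire_of),
                          dam_id = sprintf("D%04d", dam_ids))
    structure(list(genotypes = genotypes(doses, map, fam), samples = samples,
                   founder_freq = p, scenario = sc, seed = seed),
              class = "sim_population")
  })
}

#' Realized fraction of full-sib offspring in a simulated population
#' @param pop a `sim_population`.
#' @return Fraction of offspring sharing both parents with another offspring.
#' @export
full_sib_fraction <- function(pop) {
  key <- paste(pop$samples$sire_id, pop$samples$dam_id)
  mean(table(key)[key] >= 2)
}

#' Simulate phenotypes with known additive/dominance architecture
#'
#' Marker effects are scaled by the genomic-relationship denominators so the
#' scenario variances are the true variances under the fitted model:
#' `a_i ~ N(0, sigma2_a / (2 sum p q))`, `d_i ~ N(0, sigma2_d / (4 sum
#' (pq)^2))`, true breeding values `u = W1 a` and dominance deviations
#' `v = W2 d` use the same marker codings as the relationship matrices, and
#' `y = mean + sex/herd effects + u + v + e` with `e ~ N(0, sigma2_e)`.
#' Frequencies are the realized offspring frequencies; markers fixed in the
#' offspring sample carry no effect.
#'
#' @param pop a `sim_population` from [simulate_founders_and_gametes()].
#' @param scenario variance/fixed-effect parameters; defaults to the
#'   scenario the population was simulated under.
#' @param seed integer seed (independent of the genotype seed).
#' @param trait name of the phenotype column.
#' @return List: `pheno` (data.frame `individual_id`, sex, herd, trait) and
#'   `truth` (list: `u`, `v`, `fixed_part`, marker effects `a`, `d`, and the
#'   generating variances).
#' @export
simulate_phenotypes <- function(pop, scenario = pop$scenario, seed = 1L,
                                trait = "y") {
  stopifnot(inherits(pop, "sim_population"), inherits(scenario, "sim_scenario"))
  doses <- pop$genotypes$doses
  n <- nrow(doses)
  p <- suppressWarnings(estimate_frequencies(doses))
  ok <- !is.na(p) & p > 0 & p < 1
  withr::with_seed(seed, {
    u <- numeric(n)
    a <- numeric(sum(ok))
    if (scenario$sigma2_a > 0) {
      den_a <- 2 * sum(p[ok] * (1 - p[ok]))
      a <- stats::rnorm(sum(ok), 0, sqrt(scenario$sigma2_a / den_a))
      u <- drop(build_additive_design(doses[, ok, drop = FALSE], p[ok])$values %*% a)
    }
    v <- numeric(n)
    d <- numeric(sum(ok))
    if (scenario$sigma2_d > 0) {
      den_d <- 4 * sum((p[ok] * (1 - p[ok]))^2)
      d <- stats::rnorm(sum(ok), 0, sqrt(scenario$sigma2_d / den_d))
      v <- drop(build_dominance_design(doses[, ok, drop = FALSE], p[ok])$values %*% d)
    }
    e <- stats::rnorm(n, 0, sqrt(scenario$sigma2_e))
    herd_idx <- as.integer(sub("^H", "", pop$samples$herd))
    fixed_part <- scenario$mean +
      scenario$sex_effect * (pop$samples$sex == "M") +
      scenario$herd_effects[herd_idx]
    y <- fixed_part + u + v + e
    pheno <- data.frame(individual_id = pop$samples$individual_id,
                        sex = pop$samples$sex, herd = pop$samples$herd)
    pheno[[trait]] <- y
    list(pheno = pheno,
         truth = list(u = stats::setNames(u, pheno$individual_id),
                      v = stats::setNames(v, pheno$individual_id),
                      a = a, d = d, fixed_part = fixed_part,
                      sigma2_a = scenario$sigma2_a,
                      sigma2_d = scenario$sigma2_d,
                      sigma2_e = scenario$sigma2_e))
  })
}

#' Export a simulated population as a PLINK fixture plus phenotype table
#'
#' Writes `<prefix>.bed/.bim/.fam`, `<prefix>.pheno.tsv` (individual_id,
#' sex, herd, trait columns) and, when truth is supplied,
#' `<prefix>.truth.tsv` with the true genetic values.
#'
#' @param pop a `sim_population`.
#' @param pheno phenotype data.frame (e.g. `simulate_phenotypes(...)$pheno`),
#'   or `NULL` to write genotypes only.
#' @param prefix output path prefix.
#' @param truth optional truth list to serialize alongside.
#' @return `prefix`, invisibly.
#' @export
export_fixture <- function(pop, pheno = NULL, prefix, truth = NULL) {
  write_plink(pop$genotypes, prefix)
  if (!is.null(pheno)) {
    utils::write.table(pheno, paste0(prefix, ".pheno.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    utils::write.table(
      data.frame(individual_id = names(truth$u), u = truth$u, v = truth$v),
      paste0(prefix, ".truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(prefix)
}

#' Read a delimited phenotype table
#'
#' @param path tab- or whitespace-delimited file with an `individual_id`
#'   column, factor columns (sex, herd) and numeric trait columns.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  out <- data.table::fread(path, data.table = FALSE,
                           colClasses = list(character = "individual_id"))
  if (!"individual_id" %in% names(out)) {
    stop("phenotype file must contain an 'individual_id' column: ", path)
  }
  out
}
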