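#!/usr/bin/env Rscript

# Descriptive statistics and REML variance components for the simulated
# traits: each trait is fitted under the additive-only model (MAG) and the
# additive+dominance model (MADG), with sex and herd as fixed effects.
# Writes the descriptive-statistics report and the variance-component report
# under results/.

library(adgblup)

dir.create("results", showWarnings = FALSE)

geno <- apply_qc(read_plink("results/sim/sim"), qc_thresholds())$genotypes
pheno <- read_phenotypes("results/sim/sim.pheno.tsv")
hz <- harmonize(geno, pheno)
geno <- hz$genotypes; pheno <- hz$pheno
freq <- geno$map$freq

desc <- descriptive_stats(pheno, c("SL_like", "FER_like", "null"))
print(desc, digits = 3)
write.table(format(desc, digits = 8), "results/descriptive_stats.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

G <- stabilize(make_grm(geno$doses, freq, "additive"))
D <- stabilize(make_grm(geno$doses, freq, "dominance"))
X <- build_fixed_design(pheno)

rows <- list()
for (tr in c("SL_like", "FER_like", "null")) {
  y <- pheno[[tr]]
  for (model in c("MAG", "MADG")) {
    fit <- if (model == "MAG") fit_mag(y, X, G) else fit_madg(y, X, G, D)
    vr <- variance_ratios(fit)
    h2 <- vr[vr$component == "a", ]
    d2 <- vr[vr$component == "d", ]
    rows[[paste(tr, model)]] <- data.frame(
      trait = tr, model = model,
      sigma2_a = fit$sigma2[["a"]], se_a = fit$se[["a"]],
      sigma2_d = if (model == "MADG") fit$sigma2[["d"]] else NA,
      se_d = if (model == "MADG") fit$se[["d"]] else NA,
      sigma2_e = fit$sigma2[["e"]], se_e = fit$se[["e"]],
      h2 = h2$ratio, se_h2 = h2$se_ratio,
      d2 = if (nrow(d2)) d2$ratio else NA,
      converged = fit$converged, iterations = fit$iterations)
  }
}
tab2 <- do.call(rbind, rows)
rownames(tab2) <- NULL
print(tab2, digits = 3)
write.table(format(tab2, digits = 8), "results/variance_components.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\nNarrative: the SL-like trait should put ~half the variance on the\n")
cat("additive term under MAG (h2 near 0.5) and pin the dominance term at 0\n")
cat("under MADG; the FER-like trait should do the opposite, assigning the\n")
cat("bulk to dominance; the null trait should carry no genetic variance\n")
cat("beyond sampling noise (estimates within ~2 SE of zero).\n")
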