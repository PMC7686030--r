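#!/usr/bin/env Rscript

# Repeated 5-fold cross-validation of genomic prediction accuracy for the
# simulated traits, under both MAG and MADG: the study design (5 folds of
# ~100 animals, repeated twice, 10 accuracy values per trait x model).
# Writes the accuracy summary report, the per-cell accuracies, and an
# accuracy bar chart under results/.

library(adgblup)

seed <- 7L
dir.create("results", showWarnings = FALSE)

geno <- apply_qc(read_plink("results/sim/sim"), qc_thresholds())$genotypes
pheno <- read_phenotypes("results/sim/sim.pheno.tsv")
hz <- harmonize(geno, pheno)
geno <- hz$genotypes; pheno <- hz$pheno
freq <- geno$map$freq

G <- stabilize(make_grm(geno$doses, freq, "additive"))
D <- stabilize(make_grm(geno$doses, freq, "dominance"))
X <- build_fixed_design(pheno)

summary_rows <- list()
cell_rows <- list()
for (tr in c("SL_like", "FER_like", "null")) {
  y <- pheno[[tr]]
  for (model in c("MAG", "MADG")) {
    ks <- if (model == "MAG") list(a = G) else list(a = G, d = D)
    cv <- suppressWarnings(
      cross_validate(y, X, ks, k = 5, repeats = 2, seed = seed))
    summary_rows[[paste(tr, model)]] <- data.frame(
      trait = tr, model = model, mean_accuracy = cv$mean, se = cv$se,
      n_cells = sum(!is.na(cv$cells$accuracy)))
    cell_rows[[paste(tr, model)]] <- cbind(trait = tr, model = model,
                                           cv$cells)
  }
}
tab3 <- do.call(rbind, summary_rows)
cells <- do.call(rbind, cell_rows)
rownames(tab3) <- rownames(cells) <- NULL
print(tab3, digits = 3)
write.table(format(tab3, digits = 8), "results/cv_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(format(cells, digits = 8), "results/cv_cells.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# accuracy bar chart (MAG vs MADG per trait)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- ggplot2::ggplot(tab3, ggplot2::aes(trait, mean_accuracy,
                                          fill = model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_accuracy - se,
                                        ymax = mean_accuracy + se),
                           position = ggplot2::position_dodge(0.8),
                           width = 0.2) +
    ggplot2::labs(y = "prediction accuracy (mean over 10 CV cells)",
                  x = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave("results/accuracy_comparison.pdf", p,
                  width = 6, height = 4)
}

cat("\nNarrative: accuracy should track the additive architecture (highest\n")
cat("for the SL-like trait, near zero for the null trait) and the dominance\n")
cat("model should show no advantage on the additive trait.\n")
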