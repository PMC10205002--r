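#!/usr/bin/env Rscript

# Stage 3: does protein complexity track lipid complexity? Univariate
# phylogenetic regressions of peak richness (R_P ~ R_L) and Shannon
# entropy (H_P ~ H_L), tested with the same RRPP machinery, with the
# fitted line and its 95% confidence band.

library(glandcov)

ds <- load_dataset("results/data")
tips <- ds$tree$tip.label
cx <- ds$complexity

reg_R <- complexity_regression(setNames(cx$R_P, cx$species)[tips],
                               setNames(cx$R_L, cx$species)[tips],
                               ds$tree, n_perm = 999, seed = 104,
                               xname = "R_L", yname = "R_P")
reg_H <- complexity_regression(setNames(cx$H_P, cx$species)[tips],
                               setNames(cx$H_L, cx$species)[tips],
                               ds$tree, n_perm = 999, seed = 105,
                               xname = "H_L", yname = "H_P")

for (r in list(`R_P ~ R_L` = reg_R, `H_P ~ H_L` = reg_H)) {
  print(r$anova)
}
cat(sprintf("Slopes: R_P~R_L %.3f, H_P~H_L %.3f\n", reg_R$slope, reg_H$slope))

dir.create("results/complexity", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(model = c("R_P~R_L", "H_P~H_L"),
                       slope = c(reg_R$slope, reg_H$slope),
                       pseudo_F = c(reg_R$anova$table$pseudo_F,
                                    reg_H$anova$table$pseudo_F),
                       p_perm = c(reg_R$anova$table$p_perm,
                                  reg_H$anova$table$p_perm)),
            "results/complexity/regressions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(reg_H$line, "results/complexity/line_HP_HL.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(reg_R$line, "results/complexity/line_RP_RL.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Tables written under results/complexity/\n")
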