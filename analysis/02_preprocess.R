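#!/usr/bin/env Rscript
# Quantile normalization, detection filtering against the empirical
# background, and the ANOVA variable-gene screen.

library(macnet)

x <- read_expr_set("results/data/expression.tsv", "results/data/design.tsv")
x <- quantile_normalize(x)
det <- detection_filter(x, background_quantile = 0.25, min_margin = 0.5)
cat(sprintf("detection filter: %d of %d genes expressed in >= 1 condition\n",
            length(det$expressed_genes), nrow(x$values)))

av <- anova_screen(x)
cat(sprintf("ANOVA screen: %d genes differential at q < 0.05\n",
            sum(av$pass)))

dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)
writeLines(det$expressed_genes, "results/preprocess/expressed_genes.txt")
write.table(av, "results/preprocess/anova_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_expr_set(x, "results/preprocess/expression_qn.tsv",
               "results/preprocess/design.tsv")

de <- differential_expression(x, group_a = "IFNg", group_b = "Mb")
cat(sprintf("IFNg vs Mb: %d genes pass FC > 2, q < 0.05\n", sum(de$pass)))
write.table(de, "results/preprocess/de_IFNg_vs_Mb.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
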