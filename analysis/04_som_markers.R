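#!/usr/bin/env Rscript
# SOM portraits of per-condition expression and exclusive-marker selection.

library(macnet)

x <- read_expr_set("results/preprocess/expression_qn.tsv",
                   "results/preprocess/design.tsv")
expressed <- readLines("results/preprocess/expressed_genes.txt")

prof <- condition_profiles(x)
prof <- prof[rownames(prof) %in% expressed, ]
map <- som_fit(prof, grid_w = 10, grid_h = 10, epochs = 50, seed = 421)
map <- som_metaclusters(map, k = 6)
cat(sprintf("SOM: quantization error %.3f -> %.3f over training\n",
            map$quantization_error["initial"],
            map$quantization_error["final"]))

mk <- exclusive_markers(x, margin_min = 1)
cat(sprintf("exclusive markers at margin >= 1 log2: %d genes\n", nrow(mk)))
print(head(mk[, c("gene", "condition", "margin")], 10))

dir.create("results/som", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(gene = names(map$bmu), unit = map$bmu,
                       metacluster = map$gene_clusters),
            "results/som/som_assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(mk, "results/som/exclusive_markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
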