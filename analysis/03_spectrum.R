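#!/usr/bin/env Rscript
# Coregulation analysis: sample correlation graph, Markov clustering, 3D
# layout, condition correlation matrix, and the spectrum displacement
# vectors anchored at baseline macrophages.

library(macnet)

x <- read_expr_set("results/preprocess/expression_qn.tsv",
                   "results/preprocess/design.tsv")
expressed <- readLines("results/preprocess/expressed_genes.txt")

g <- correlation_graph(x, genes = expressed, r_threshold = 0.85)
cat(sprintf("CRA graph: %d samples, %d edges at r >= 0.85\n",
            length(g$nodes), nrow(g$edges)))
cl <- mcl_cluster(g, inflation = 2)
cat(sprintf("MCL: %d sample clusters\n", length(unique(cl))))
g <- layout_3d(g, iterations = 500, seed = 421)

ccm <- condition_ccm(x, top_n = 150, k = 6)
print(ccm$cluster_of)
v <- spectrum_vectors(g, x$design, ccm)
print(v[, c("cluster", "conditions", "x", "y", "z", "magnitude")])
a <- spectrum_angles(v)
cat(sprintf("largest cluster separation: %.1f degrees\n",
            max(a$angle_deg)))

dir.create("results/spectrum", showWarnings = FALSE, recursive = TRUE)
write_sample_graph(g, "results/spectrum/sample_edges.tsv",
                   "results/spectrum/sample_graph.graphml",
                   "results/spectrum/sample_layout.tsv")
write_ccm(ccm, "results/spectrum/ccm.tsv",
          "results/spectrum/ccm_dendrogram.nwk")
write.table(v, "results/spectrum/spectrum_vectors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(a, "results/spectrum/spectrum_angles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
plot_spectrum(v, file = "results/spectrum/spectrum_arrows.png")
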