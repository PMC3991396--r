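#!/usr/bin/env Rscript
# Weighted coexpression module detection and module-eigengene to condition
# correlation; modules are exported as GMT gene sets for enrichment.

library(macnet)

x <- read_expr_set("results/preprocess/expression_qn.tsv",
                   "results/preprocess/design.tsv")
expressed <- readLines("results/preprocess/expressed_genes.txt")
sub <- x$values[expressed, ]

power <- suppressWarnings(pick_soft_threshold(sub))
cat(sprintf("soft threshold: power %d\n", as.integer(power)))
tom <- topological_overlap(adjacency_matrix(sub, power))
dm <- detect_modules(tom, sub, min_size = 20)
cat(sprintf("detected %d modules, sizes: %s\n", length(dm$modules),
            paste(vapply(dm$modules, function(m) length(m$genes), 1L),
                  collapse = ", ")))

mt <- module_trait_correlation(dm$modules, x$design)
for (m in dm$modules)
  cat(sprintf("  module %d (%d genes): strongest trait %s (r = %.2f)\n",
              m$id, length(m$genes), mt$driver[paste0("module", m$id)],
              mt$r[paste0("module", m$id),
                   mt$driver[paste0("module", m$id)]]))

dir.create("results/modules", showWarnings = FALSE, recursive = TRUE)
modules_to_gmt(dm$modules, "results/modules/modules.gmt")
write.table(data.frame(gene = names(dm$membership),
                       module = dm$membership),
            "results/modules/membership.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(module = rownames(mt$r), mt$r, check.names = FALSE),
            "results/modules/module_trait_r.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
plot_module_trait(mt, file = "results/modules/module_trait_heatmap.png")
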