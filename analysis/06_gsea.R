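#!/usr/bin/env Rscript
# Modules-as-gene-sets GSEA: every stimulation condition is contrasted with
# baseline and each detected coexpression module is scored as a gene set.

library(macnet)

x <- read_expr_set("results/preprocess/expression_qn.tsv",
                   "results/preprocess/design.tsv")
sets <- read_gmt("results/modules/modules.gmt")
baseline <- unique(as.character(x$design$condition[x$design$is_baseline]))
contrasts <- setdiff(unique(as.character(x$design$condition)), baseline)

all_res <- do.call(rbind, lapply(contrasts, function(cn) {
  r <- gsea_permutation(x, group_a = cn, group_b = baseline,
                        gene_sets = sets, n_perm = 1000, seed = 421)
  r$contrast <- cn
  r
}))
all_res <- volcano_table(all_res, nes_min = 1, p_max = 0.05)

for (cn in contrasts) {
  sub <- all_res[all_res$contrast == cn, ]
  top <- sub[which.max(sub$nes), ]
  cat(sprintf("%s vs %s: top set %s (NES %.2f, p %.4f)%s; enriched: %s\n",
              cn, baseline, top$set, top$nes, top$p,
              if (top$enriched) " [enriched]" else "",
              paste(sub$set[sub$enriched], collapse = ", ")))
}

dir.create("results/gsea", showWarnings = FALSE, recursive = TRUE)
write.table(all_res[, setdiff(names(all_res), "leading_edge")],
            "results/gsea/gsea_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (cn in contrasts)
  plot_gsea_volcano(all_res[all_res$contrast == cn, ],
                    file = sprintf("results/gsea/volcano_%s.png", cn))
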