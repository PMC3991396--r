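#!/usr/bin/env Rscript
# Generate the synthetic macrophage-activation scenario used throughout the
# analysis: 6 conditions x 10 replicates, six planted coexpression modules
# (including an antagonistic M1-like/M2-like pair), three exclusive markers,
# and a separate hub-structured dataset for network inference.

library(macnet)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

x <- demo_dataset(seed = 421)
write_expr_set(x,
               "results/data/expression.tsv",
               "results/data/design.tsv",
               "results/data/ground_truth.json")
cat(sprintf("expression matrix: %d genes x %d samples, %d conditions\n",
            nrow(x$values), ncol(x$values),
            length(unique(x$design$condition))))

h <- simulate_hub_network_data(50, 1000, hub_fraction = 0.1, seed = 421)
write_expr_set(h$expr, "results/data/hub_expression.tsv",
               "results/data/hub_design.tsv")
jsonlite::write_json(
  list(hubs = h$hubs,
       edges = apply(h$edges, 1, paste, collapse = "|")),
  "results/data/hub_truth.json", auto_unbox = TRUE)
cat(sprintf("hub dataset: %d genes, %d true edges, %d planted hubs\n",
            nrow(h$expr$values), nrow(h$edges), length(h$hubs)))
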