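# Synthetic expression data with planted structure: condition-driven gene
# modules, single-condition exclusive markers, and hub-dominated gene-gene
# dependency graphs. Every downstream stage of the workflow (coregulation
# networks, spectrum vectors, SOM markers, coexpression modules, GSEA,
# MI network inference) can be scored against the planted ground truth.

#' Build a stimulation design table
#'
#' Creates a balanced design of `n_conditions` stimulation conditions with
#' `replicates` samples each, one of which is flagged as the unstimulated
#' baseline (the origin of the activation spectrum). Donors cycle within each
#' condition so that replicate index doubles as a donor label.
#'
#' @param n_conditions Number of condition groups (>= 2; the spectrum needs a
#'   baseline plus at least one stimulus).
#' @param replicates Samples per condition (>= 2).
#' @param baseline_name Label of the baseline condition (default `"Mb"`,
#'   unstimulated macrophages).
#' @param seed Integer seed; the design is fully deterministic but the seed is
#'   recorded so downstream generators can derive their streams from it.
#' @param condition_names Optional character vector of non-baseline condition
#'   names (length `n_conditions - 1`); defaults to `stim01`, `stim02`, ...
#' @param time_h Stimulation time in hours attached to every sample
#'   (default 72, the end-of-activation time point).
#' @return A `data.frame` with columns `sample_id`, `condition`, `time_h`,
#'   `donor`, `is_baseline`.
#' @examples
#' d <- make_design(6, 5, seed = 1)
#' table(d$condition)
#' @export
make_design <- function(n_conditions, replicates, baseline_name = "Mb",
                        seed = 1L, condition_names = NULL, time_h = 72) {
  if (n_conditions < 2)
    stop("n_conditions must be >= 2: the spectrum needs a baseline plus at least one stimulus")
  if (replicates < 2)
    stop("replicates must be >= 2")
  if (is.null(condition_names)) {
    condition_names <- sprintf("stim%02d", seq_len(n_conditions - 1L))
  }
  if (length(condition_names) != n_conditions - 1L)
    stop("condition_names must have length n_conditions - 1")
  conds <- c(baseline_name, condition_names)
  design <- data.frame(
    sample_id = paste0(rep(conds, each = replicates), "_r",
                       rep(seq_len(replicates), times = n_conditions)),
    condition = factor(rep(conds, each = replicates), levels = conds),
    time_h = time_h,
    donor = paste0("D", rep(seq_len(replicates), times = n_conditions)),
    is_baseline = rep(conds == baseline_name, each = replicates),
    stringsAsFactors = FALSE
  )
  attr(design, "seed") <- as.integer(seed)
  attr(design, "baseline") <- baseline_name
  design
}

#' Describe planted structure for the expression simulator
#'
#' @param modules List of planted coexpression modules; each element is a list
#'   with `genes` (character vector) and `effects` (named numeric vector of
#'   log2 shifts, names are driver conditions; negative values model
#'   repression, so antagonistic programs can share a module axis).
#' @param markers List of exclusive markers; each element a list with `gene`,
#'   `condition` and `effect` (log2 elevation in that condition only).
#' @param noise_sd Standard deviation of additive Gaussian noise on the log2
#'   scale (log-normal intensities), default 0.5.
#' @param baseline_mean Grand mean log2 intensity, default 8.
#' @param gene_mean_sd Between-gene spread of baseline log2 means, default 2
#'   (different genes sit at very different intensity levels; this is what
#'   makes unrelated samples of the same tissue correlate strongly, as real
#'   transcriptomes do).
#' @param hub_spec Optional list recording hub-topology parameters next to
#'   the rest of a scenario description; [simulate_hub_network_data()] takes
#'   its parameters directly, so this slot is carried, not consumed.
#' @return An object of class `planted_structure`.
#' @export
planted_structure <- function(modules = list(), markers = list(),
                              noise_sd = 0.5, baseline_mean = 8,
                              gene_mean_sd = 2, hub_spec = NULL) {
  stopifnot(noise_sd >= 0, gene_mean_sd >= 0)
  all_mod_genes <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(all_mod_genes))
    stop("planted module gene sets must be disjoint; duplicated: ",
         paste(unique(all_mod_genes[duplicated(all_mod_genes)]), collapse = ", "))
  for (m in modules) {
    if (!all(is.finite(m$effects))) stop("module effect sizes must be finite")
    if (is.null(names(m$effects)) || any(names(m$effects) == ""))
      stop("module effects must be a named vector (names = driver conditions)")
  }
  structure(list(modules = modules, markers = markers, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, gene_mean_sd = gene_mean_sd,
                 hub_spec = hub_spec),
            class = "planted_structure")
}

#' Simulate a log2 expression matrix with planted structure
#'
#' Module genes share a latent condition-driven factor: every gene in a module
#' receives the same binary condition indicator times the module effect (per
#' gene loading 1), so the within-module gene-gene correlation is controlled
#' by the effect/noise ratio through the variance decomposition
#' r = e^2 v / (e^2 v + sd^2) with v the variance of the indicator across
#' samples. Exclusive markers are elevated only in their condition; background
#' genes are i.i.d. noise around their gene-specific baseline mean.
#'
#' @param design Design table from [make_design()].
#' @param structure A [planted_structure()].
#' @param n_background_genes Number of unstructured background genes.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return An object of class `expr_set`: list with `values` (genes x samples
#'   numeric matrix of log2 intensities), `design`, and `truth` (the planted
#'   structure plus gene roles).
#' @export
simulate_expression <- function(design, structure, n_background_genes = 100,
                                seed = 1L) {
  stopifnot(inherits(structure, "planted_structure"))
  conds <- as.character(unique(design$condition))
  for (m in structure$modules) {
    bad <- setdiff(names(m$effects), conds)
    if (length(bad))
      stop("module driver condition not in design: ", paste(bad, collapse = ", "))
  }
  for (mk in structure$markers) {
    if (!mk$condition %in% conds)
      stop("marker condition not in design: ", mk$condition)
  }
  module_genes <- unlist(lapply(structure$modules, `[[`, "genes"))
  marker_genes <- vapply(structure$markers, `[[`, "", "gene")
  bg_genes <- if (n_background_genes > 0)
    sprintf("bg%04d", seq_len(n_background_genes)) else character()
  genes <- c(module_genes, setdiff(marker_genes, module_genes), bg_genes)
  if (anyDuplicated(genes))
    stop("gene ids collide across modules/markers/background")
  n_g <- length(genes); n_s <- nrow(design)

  set.seed(as.integer(seed))
  mu <- structure$baseline_mean +
    stats::rnorm(n_g, 0, structure$gene_mean_sd)
  names(mu) <- genes
  vals <- matrix(mu, n_g, n_s) +
    matrix(stats::rnorm(n_g * n_s, 0, structure$noise_sd), n_g, n_s)
  dimnames(vals) <- list(genes, design$sample_id)

  cond_of <- as.character(design$condition)
  for (m in structure$modules) {
    shift <- numeric(n_s)
    for (cn in names(m$effects))
      shift[cond_of == cn] <- shift[cond_of == cn] + m$effects[[cn]]
    vals[m$genes, ] <- vals[m$genes, , drop = FALSE] +
      matrix(shift, length(m$genes), n_s, byrow = TRUE)
  }
  for (mk in structure$markers) {
    vals[mk$gene, cond_of == mk$condition] <-
      vals[mk$gene, cond_of == mk$condition] + mk$effect
  }
  role <- setNames(rep("background", n_g), genes)
  if (length(structure$modules))
    role[module_genes] <- rep(paste0("module", seq_along(structure$modules)),
                              vapply(structure$modules, function(m) length(m$genes), 1L))
  role[marker_genes] <- "marker"
  expr_set(vals, design,
           truth = list(structure = structure, role = role,
                        modules = lapply(structure$modules, `[[`, "genes"),
                        markers = structure$markers))
}

#' Expression set container
#'
#' @param values Genes x samples numeric matrix (log2 intensities), with
#'   rownames (gene ids) and colnames (sample ids).
#' @param design Sample annotation table; `design$sample_id` must match the
#'   column names of `values`.
#' @param truth Optional planted ground truth (simulations only).
#' @return Object of class `expr_set`.
#' @export
expr_set <- function(values, design, truth = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (!all(colnames(values) == design$sample_id))
    stop("column names of values must equal design$sample_id, in order")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  structure(list(values = values, design = design, truth = truth),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples, %d conditions\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$condition))))
  invisible(x)
}

# Coerce an expr_set or plain matrix to a values matrix.
expr_values <- function(x) {
  if (inherits(x, "expr_set")) x$values else as.matrix(x)
}

#' Simulate expression data from a sparse hub-dominated dependency graph
#'
#' Draws samples from a multivariate Gaussian whose precision matrix encodes a
#' sparse conditional-dependency graph with designated high-degree hub nodes,
#' giving a heavy-tailed degree distribution. Diagonal dominance of the
#' precision matrix is enforced so the implied covariance is valid. Returns
#' the true edge set for recovery scoring.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_samples Number of samples.
#' @param hub_fraction Fraction of genes designated as hubs, in (0, 1).
#' @param seed Integer seed.
#' @param hub_degree Target degree of each hub, default 5: under diagonal
#'   dominance a node's incident partial correlations must sum below one, so
#'   moderate hub degrees keep each edge's marginal correlation strong
#'   enough to be recoverable at realistic sample sizes.
#' @param background_prob Edge probability among non-hub pairs (default 0.01).
#' @param strength Off-diagonal precision weight before degree normalization
#'   (default 0.9); each entry is `strength / max(d_i, d_j)` with a random
#'   sign, so rows stay diagonally dominant at any degree.
#' @return List with `expr` (an `expr_set`, gene ids `g001`, ...), `edges`
#'   (two-column character matrix of true edges), `hubs` (character vector),
#'   and `sigma` (the true covariance, for oracle checks).
#' @export
simulate_hub_network_data <- function(n_genes, n_samples, hub_fraction,
                                      seed = 1L, hub_degree = 5,
                                      background_prob = 0.01,
                                      strength = 0.9) {
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (hub_fraction <= 0 || hub_fraction >= 1)
    stop("hub_fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  genes <- sprintf("g%03d", seq_len(n_genes))
  n_hub <- max(1L, round(hub_fraction * n_genes))
  hubs <- genes[seq_len(n_hub)]
  nonhub <- setdiff(genes, hubs)

  adj <- matrix(FALSE, n_genes, n_genes, dimnames = list(genes, genes))
  for (h in hubs) {
    nb <- sample(nonhub, min(hub_degree, length(nonhub)))
    adj[h, nb] <- TRUE; adj[nb, h] <- TRUE
  }
  # sparse background among non-hubs
  for (i in seq_along(nonhub)) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < background_prob) {
        adj[nonhub[i], nonhub[j]] <- TRUE
        adj[nonhub[j], nonhub[i]] <- TRUE
      }
    }
  }
  # guarantee hubs strictly dominate the degree ranking
  deg <- rowSums(adj)
  max_nonhub <- if (length(nonhub)) max(deg[nonhub]) else 0
  for (h in hubs) {
    while (deg[h] <= max_nonhub) {
      cand <- nonhub[!adj[h, nonhub]]
      if (!length(cand)) break
      nb <- cand[1L]
      adj[h, nb] <- TRUE; adj[nb, h] <- TRUE
      deg <- rowSums(adj); max_nonhub <- max(deg[nonhub])
    }
  }

  omega <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
  sgn <- matrix(sample(c(-1, 1), n_genes^2, replace = TRUE), n_genes)
  sgn[lower.tri(sgn)] <- t(sgn)[lower.tri(sgn)]
  deg_pair <- outer(pmax(rowSums(adj), 1), pmax(rowSums(adj), 1), pmax)
  omega[adj] <- (strength / deg_pair[adj]) * sgn[adj]
  # forced diagonal dominance => positive definite
  diag(omega) <- 1.02 * pmax(rowSums(abs(omega)), 1)
  sigma <- solve(omega)
  x <- MASS::mvrnorm(n_samples, mu = rep(8, n_genes), Sigma = sigma)
  vals <- t(x)
  dimnames(vals) <- list(genes, sprintf("s%04d", seq_len(n_samples)))
  design <- data.frame(sample_id = colnames(vals), condition = "all",
                       time_h = 72, donor = "D1", is_baseline = TRUE,
                       stringsAsFactors = FALSE)
  ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- cbind(genes[ut[, 1]], genes[ut[, 2]])
  list(expr = expr_set(vals, design), edges = edges, hubs = hubs,
       sigma = sigma)
}

#' Write / read an expression set as plain text
#'
#' The matrix goes to a TSV with gene ids in the first column and sample ids
#' in the header; the design table to a second TSV. Ground truth, when
#' present, is written as JSON.
#'
#' @param x An `expr_set`.
#' @param expr_path,design_path,truth_path Output paths (truth optional).
#' @return Invisibly, the paths written.
#' @export
write_expr_set <- function(x, expr_path, design_path, truth_path = NULL) {
  stopifnot(inherits(x, "expr_set"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(expr_path, design_path)
  if (!is.null(truth_path) && !is.null(x$truth)) {
    tr <- list(modules = x$truth$modules,
               markers = x$truth$markers,
               role = as.list(x$truth$role))
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' @rdname write_expr_set
#' @param expr_path,design_path Paths written by [write_expr_set()].
#' @export
read_expr_set <- function(expr_path, design_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  design$condition <- factor(design$condition,
                             levels = unique(design$condition))
  expr_set(vals, design)
}
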