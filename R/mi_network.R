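# ARACNe-style reverse network engineering: all-vs-all mutual information,
# permutation-null significance threshold with exponential tail
# extrapolation, data-processing-inequality pruning, hub extraction, and
# top-expressed-TF first-neighbor subnetworks.

# Gaussian-copula transform: ranks -> normal scores. Rank-invariant, so the
# closed-form Gaussian MI applies after transformation.
copula_scores <- function(v) {
  stats::qnorm(rank(v, ties.method = "average") / (length(v) + 1))
}

#' Mutual information between two expression profiles
#'
#' Default estimator `"copula"`: both vectors are rank-transformed to normal
#' scores and MI is the closed-form Gaussian value -1/2 ln(1 - r^2) of their
#' correlation -- fast, rank-invariant, and exactly symmetric. Estimator
#' `"bins"` is an equal-frequency discretized plug-in estimate with
#' Miller-Madow bias correction (closer to ARACNe's histogram estimators).
#' Constant vectors give MI = 0 with a `degenerate` attribute.
#'
#' @param x,y Numeric vectors of equal length >= 10.
#' @param estimator `"copula"` (default) or `"bins"`.
#' @param n_bins Bin count for the `"bins"` estimator; default
#'   `floor(length(x)^(1/3))` (keeps the joint histogram well populated).
#' @return MI in nats (non-negative).
#' @export
pairwise_mi <- function(x, y, estimator = c("copula", "bins"),
                        n_bins = NULL) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("MI estimation needs >= 10 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  if (estimator == "copula") {
    r <- stats::cor(copula_scores(x), copula_scores(y))
    r <- min(abs(r), 1 - 1e-12)
    mi <- -0.5 * log(1 - r^2)
  } else {
    if (is.null(n_bins)) n_bins <- max(2L, floor(length(x)^(1 / 3)))
    bx <- cut(rank(x, ties.method = "first"), n_bins, labels = FALSE)
    by <- cut(rank(y, ties.method = "first"), n_bins, labels = FALSE)
    joint <- table(bx, by) / length(x)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    mi <- sum(joint[nz] * log(joint[nz] /
                              outer(px, py)[nz]))
    # Miller-Madow: the plug-in estimate is biased up by ~(cells-1)/(2n)
    mi <- mi - (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * length(x))
    mi <- max(mi, 0)
  }
  mi
}

# All-pairs copula MI matrix (vectorized through cor on normal scores).
mi_matrix <- function(vals) {
  scores <- t(apply(vals, 1, copula_scores))
  sds <- apply(vals, 1, stats::sd)
  r <- stats::cor(t(scores))
  r[sds == 0, ] <- 0; r[, sds == 0] <- 0
  r2 <- pmin(r^2, 1 - 1e-12)
  mi <- -0.5 * log(1 - r2)
  diag(mi) <- 0
  dimnames(mi) <- list(rownames(vals), rownames(vals))
  mi
}

#' Significance threshold for MI edges from a permutation null
#'
#' Estimates the null MI distribution by computing MI between randomly
#' permuted profile pairs drawn from the matrix, then returns the
#' (1 - alpha') quantile with alpha' = alpha / C(n_genes, 2) under
#' Bonferroni. Quantiles deeper than the permutation resolution are obtained
#' by fitting an exponential to the null tail above its 99th percentile
#' (null MI tails are close to exponential); the fit is recorded in
#' attributes.
#'
#' @param x An `expr_set` or matrix.
#' @param alpha Significance level (after correction), default 1e-7.
#' @param n_null Number of permuted pairs, default 10000.
#' @param correction `"bonferroni"` (divide alpha by the number of gene
#'   pairs) or `"none"`.
#' @param seed Integer seed.
#' @return MI cutoff (nats); attributes `alpha_corrected`, `tail_rate`,
#'   `extrapolated`.
#' @export
mi_significance_threshold <- function(x, alpha = 1e-7, n_null = 10000,
                                      correction = c("bonferroni", "none"),
                                      seed = 1L) {
  correction <- match.arg(correction)
  if (alpha <= 0) stop("alpha must be positive")
  vals <- expr_values(x)
  n_pairs <- choose(nrow(vals), 2)
  alpha_c <- if (correction == "bonferroni") alpha / n_pairs else alpha
  alpha_c <- min(alpha_c, 1)
  if (alpha >= 1) {
    return(structure(0, alpha_corrected = alpha_c, tail_rate = NA_real_,
                     extrapolated = FALSE))
  }
  set.seed(as.integer(seed))
  n <- ncol(vals)
  null_mi <- vapply(seq_len(n_null), function(i) {
    g <- sample(nrow(vals), 2)
    a <- copula_scores(vals[g[1], ])[sample(n)]
    b <- copula_scores(vals[g[2], ])
    r2 <- min(stats::cor(a, b)^2, 1 - 1e-12)
    -0.5 * log(1 - r2)
  }, 0)
  target_q <- 1 - alpha_c
  if (alpha_c > 10 / n_null) {
    cutoff <- stats::quantile(null_mi, target_q, names = FALSE)
    extrap <- FALSE
    rate <- NA_real_
  } else {
    # exponential tail fit above the 99th percentile:
    # P(MI > m) ~ 0.01 exp(-(m - q99)/rate)
    q99 <- stats::quantile(null_mi, 0.99, names = FALSE)
    tail <- null_mi[null_mi > q99] - q99
    rate <- mean(tail)   # MLE of the exponential mean
    cutoff <- q99 + rate * log(0.01 / alpha_c)
    extrap <- TRUE
  }
  structure(cutoff, alpha_corrected = alpha_c, tail_rate = rate,
            extrapolated = extrap)
}

#' All-versus-all mutual information network
#'
#' Connects every gene pair whose (copula) MI reaches the cutoff; returns
#' the network with its degree table. A desk-scale guard rejects more than
#' 20,000 genes unless `force = TRUE`.
#'
#' @param x An `expr_set` or matrix.
#' @param genes Gene subset (default all).
#' @param cutoff MI threshold in nats (see [mi_significance_threshold()]).
#' @param force Override the gene-count guard.
#' @return Object of class `mi_network`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `mi`), `degree` (named integer), `hubs` (NULL until
#'   [extract_hubs()]).
#' @export
all_vs_all <- function(x, genes = NULL, cutoff, force = FALSE) {
  vals <- expr_values(x)
  if (!is.null(genes)) vals <- vals[genes, , drop = FALSE]
  if (nrow(vals) < 3) stop("need >= 3 genes")
  if (nrow(vals) > 20000 && !force)
    stop("more than 20,000 genes; set force = TRUE to proceed")
  mi <- mi_matrix(vals)
  idx <- which(upper.tri(mi) & mi >= cutoff, arr.ind = TRUE)
  edges <- data.frame(from = rownames(mi)[idx[, 1]],
                      to = colnames(mi)[idx[, 2]],
                      mi = mi[idx], stringsAsFactors = FALSE)
  new_mi_network(rownames(mi), edges)
}

new_mi_network <- function(nodes, edges) {
  degree <- setNames(rep(0L, length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(list(nodes = nodes, edges = edges, degree = degree,
                 hubs = NULL),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  con <- sum(x$degree > 0)
  avg_all <- if (length(x$nodes)) 2 * nrow(x$edges) / length(x$nodes) else 0
  avg_con <- if (con) 2 * nrow(x$edges) / con else 0
  cat(sprintf(paste0("mi_network: %d nodes, %d edges; average degree %.2f",
                     " (%.2f over connected nodes)\n"),
              length(x$nodes), nrow(x$edges), avg_all, avg_con))
  invisible(x)
}

#' Data-processing-inequality pruning
#'
#' For every fully connected triplet in the original network the weakest
#' edge is marked for removal when its MI is below (1 - tolerance) times the
#' smaller of the other two; all removals are computed against the input
#' network and applied simultaneously.
#'
#' @param network An `mi_network`.
#' @param tolerance DPI tolerance in \[0, 1); default 0.1.
#' @return The pruned `mi_network` (a subgraph of the input).
#' @export
dpi_prune <- function(network, tolerance = 0.1) {
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must be in [0, 1)")
  ed <- network$edges
  if (nrow(ed) < 3) return(network)
  nodes <- network$nodes
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  w[cbind(ed$from, ed$to)] <- ed$mi
  w[cbind(ed$to, ed$from)] <- ed$mi
  adj <- w > 0
  drop <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = dimnames(w))
  neighbors <- lapply(seq_along(nodes), function(i) which(adj[i, ]))
  for (i in seq_along(nodes)) {
    ni <- neighbors[[i]]
    ni <- ni[ni > i]
    for (j in ni) {
      common <- intersect(neighbors[[i]], neighbors[[j]])
      for (k in common) {
        mij <- w[i, j]; mik <- w[i, k]; mjk <- w[j, k]
        # the condition can only hold for the strictly weakest edge of the
        # triangle; weights are tested against the original (unpruned) network
        if (mij < (1 - tolerance) * min(mik, mjk))
          drop[i, j] <- TRUE
        if (mik < (1 - tolerance) * min(mij, mjk))
          drop[min(i, k), max(i, k)] <- TRUE
        if (mjk < (1 - tolerance) * min(mij, mik))
          drop[min(j, k), max(j, k)] <- TRUE
      }
    }
  }
  keep <- !drop[cbind(pmin(match(ed$from, nodes), match(ed$to, nodes)),
                      pmax(match(ed$from, nodes), match(ed$to, nodes)))]
  new_mi_network(nodes, ed[keep, , drop = FALSE])
}

#' Extract hub genes from an MI network
#'
#' Ranks nodes with at least one edge by decreasing degree (ties broken
#' lexicographically) and flags the top `ceiling(fraction * n_connected)` as
#' hubs. The hubs' total incident interactions are reported, matching the
#' "collectively participated" statistic of hub summaries.
#'
#' @param network An `mi_network` with at least one edge.
#' @param fraction Top fraction of connected nodes to flag, in (0, 1\];
#'   default 0.1.
#' @return The network with `hubs` (character vector) and attributes on it:
#'   `n_hubs`, `hub_interactions` (edges incident to at least one hub).
#' @export
extract_hubs <- function(network, fraction = 0.1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!nrow(network$edges)) stop("cannot extract hubs from an empty network")
  deg <- network$degree[network$degree > 0]
  ord <- order(-deg, names(deg))
  n_hub <- ceiling(fraction * length(deg))
  hubs <- names(deg)[ord][seq_len(n_hub)]
  inc <- network$edges$from %in% hubs | network$edges$to %in% hubs
  attr(hubs, "n_hubs") <- n_hub
  attr(hubs, "hub_interactions") <- sum(inc)
  network$hubs <- hubs
  network
}

#' First-neighbor subnetworks of the most expressed hub TFs
#'
#' Intersects the supplied TF list with the network hubs, ranks those TFs by
#' average expression across all samples, keeps the top `top_k`, and returns
#' each TF's first-neighbor subnetwork annotated with per-cluster mean
#' expression when condition clusters are supplied.
#'
#' @param network An `mi_network` after [extract_hubs()].
#' @param tf_list Transcription-factor gene ids (non-empty).
#' @param x The `expr_set` the network came from.
#' @param top_k Number of top TFs, default 5.
#' @param cluster_of Optional named cluster id per condition (e.g.
#'   `ccm$cluster_of`) for mean-expression annotations.
#' @return Named list (one element per selected TF): `tf`, `avg_expr`,
#'   `neighbors`, `edges`, `cluster_means` (genes x clusters or NULL). Empty
#'   list with a note attribute if no TF is a hub.
#' @export
tf_neighborhoods <- function(network, tf_list, x, top_k = 5,
                             cluster_of = NULL) {
  if (!length(tf_list)) stop("tf_list must be non-empty")
  if (is.null(network$hubs)) stop("run extract_hubs() first")
  vals <- expr_values(x)
  tfs <- intersect(tf_list, network$hubs)
  if (!length(tfs)) {
    out <- list()
    attr(out, "note") <- "no TFs among the network hubs"
    return(out)
  }
  avg <- rowMeans(vals[tfs, , drop = FALSE])
  tfs <- tfs[order(-avg, tfs)][seq_len(min(top_k, length(tfs)))]
  design <- if (inherits(x, "expr_set")) x$design else NULL
  lapply(setNames(tfs, tfs), function(tf) {
    ed <- network$edges[network$edges$from == tf | network$edges$to == tf, ,
                        drop = FALSE]
    nbr <- setdiff(unique(c(ed$from, ed$to)), tf)
    members <- c(tf, nbr)
    cm <- NULL
    if (!is.null(cluster_of) && !is.null(design)) {
      cls <- sort(unique(cluster_of))
      cm <- vapply(cls, function(cl) {
        conds <- names(cluster_of)[cluster_of == cl]
        rowMeans(vals[members, design$condition %in% conds, drop = FALSE])
      }, numeric(length(members)))
      dimnames(cm) <- list(members, paste0("cluster", cls))
    }
    list(tf = tf, avg_expr = mean(vals[tf, ]), neighbors = nbr,
         edges = ed, cluster_means = cm)
  })
}

#' Write an MI network as edge-list TSV (and optionally GraphML)
#'
#' @param network An `mi_network`.
#' @param edges_path TSV path (`gene_a`, `gene_b`, `mi_nats`).
#' @param graphml_path Optional GraphML path.
#' @param hubs_path Optional TSV path for the degree/hub table.
#' @return Invisibly, the paths written.
#' @export
write_mi_network <- function(network, edges_path, graphml_path = NULL,
                             hubs_path = NULL) {
  ed <- network$edges
  names(ed) <- c("gene_a", "gene_b", "mi_nats")
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- edges_path
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
    paths <- c(paths, graphml_path)
  }
  if (!is.null(hubs_path)) {
    df <- data.frame(gene = names(network$degree),
                     degree = as.integer(network$degree),
                     is_hub = names(network$degree) %in% network$hubs)
    df <- df[order(-df$degree, df$gene), ]
    utils::write.table(df, hubs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, hubs_path)
  }
  invisible(paths)
}
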