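# Coregulation analysis (CRA): sample-sample Pearson correlation graph,
# Markov clustering of the graph, and a 3D force-directed layout whose
# coordinates feed the spectrum model.

#' Sample-sample Pearson correlation graph
#'
#' Connects two samples when the Pearson correlation of their expression
#' profiles over the chosen gene subset reaches `r_threshold`. Samples with a
#' zero-variance profile cannot be correlated and are dropped with a warning
#' (and listed in the result).
#'
#' @param x An `expr_set` or genes x samples matrix.
#' @param genes Gene ids to correlate over (default: all genes in `x`).
#' @param r_threshold Minimum Pearson r for an edge, in (0, 1); default 0.85.
#' @return Object of class `sample_graph`: `nodes`, `edges` (data.frame
#'   `from`, `to`, `r`), the full `r_matrix`, and `dropped` sample ids.
#' @export
correlation_graph <- function(x, genes = NULL, r_threshold = 0.85) {
  vals <- expr_values(x)
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("r_threshold must be in (0, 1)")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(vals))
    if (length(missing))
      stop("genes not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  if (ncol(vals) < 3) stop("correlation graph needs >= 3 samples")
  sds <- apply(vals, 2, stats::sd)
  dropped <- colnames(vals)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance sample profiles: ",
            paste(dropped, collapse = ", "))
    vals <- vals[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(vals)
  idx <- which(upper.tri(r) & r >= r_threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[idx[, 1]],
                      to = colnames(r)[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  structure(list(nodes = colnames(vals), edges = edges, r_matrix = r,
                 r_threshold = r_threshold, dropped = dropped,
                 layout = NULL),
            class = "sample_graph")
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("sample_graph: %d nodes, %d edges (r >= %.2f)%s\n",
              length(x$nodes), nrow(x$edges), x$r_threshold,
              if (is.null(x$layout)) "" else ", 3D layout"))
  invisible(x)
}

# Weighted adjacency matrix of a sample_graph (0 where no edge).
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  a <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    a[cbind(graph$edges$from, graph$edges$to)] <- graph$edges$r
    a[cbind(graph$edges$to, graph$edges$from)] <- graph$edges$r
  }
  a
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Classic MCL: self-loops are added, the adjacency is made column-stochastic,
#' and expansion (matrix squaring) alternates with inflation (entrywise power
#' followed by column renormalization) until the matrix changes by less than
#' `tol` or `max_iter` iterations. Rows with mass (attractors) define the
#' clusters. Fully deterministic.
#'
#' @param graph A `sample_graph` (or any object with `nodes`/`edges`).
#' @param inflation Inflation exponent, > 1; default 2.
#' @param max_iter Iteration cap, default 200.
#' @param tol Convergence tolerance on the max entry change, default 1e-8.
#' @return Named integer vector: cluster label per node (singletons included).
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 200, tol = 1e-8) {
  if (inflation <= 1) stop("inflation must be > 1")
  n <- length(graph$nodes)
  if (n == 0) return(setNames(integer(0), character(0)))
  m <- graph_adjacency(graph)
  diag(m) <- 1  # self-loops stabilize odd-length cycles
  m <- sweep(m, 2, colSums(m), "/")
  for (i in seq_len(max_iter)) {
    m2 <- m %*% m                 # expansion
    m2 <- m2^inflation            # inflation
    m2 <- sweep(m2, 2, pmax(colSums(m2), .Machine$double.xmin), "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) break
  }
  # attractors: rows with non-negligible mass; each defines a cluster over
  # the columns it feeds. Overlaps (rare, symmetric peripheries) go to the
  # first attractor encountered.
  attractors <- which(rowSums(m) > tol)
  labels <- setNames(rep(NA_integer_, n), graph$nodes)
  cl <- 0L
  for (a in attractors) {
    members <- which(m[a, ] > tol)
    if (!length(members)) next
    new <- members[is.na(labels[members])]
    if (!length(new)) next
    existing <- unique(labels[members][!is.na(labels[members])])
    if (length(existing)) {
      labels[new] <- existing[1]
    } else {
      cl <- cl + 1L
      labels[new] <- cl
    }
  }
  # isolated / unassigned nodes become singletons
  for (i in which(is.na(labels))) {
    cl <- cl + 1L
    labels[i] <- cl
  }
  labels
}

#' 3D force-directed layout (Fruchterman-Reingold)
#'
#' Standard FR layout in three dimensions with the attractive force of each
#' edge scaled by its correlation weight and a linear cooling schedule.
#' Positions are initialized from classical multidimensional scaling of the
#' 1 - r correlation distance (when the graph carries its correlation
#' matrix), which captures the global sample geometry and avoids the poor
#' local minima of purely random starts on densely connected graphs; the
#' force iterations then refine local structure. Random placement from the
#' seed is the fallback, and jitter from the seed breaks exact MDS ties, so
#' the layout is identical across runs for a fixed seed either way. The
#' natural spring length k = (1/n)^(1/3) is returned as an attribute: an
#' isolated two-node pair with unit edge weight equilibrates at distance k.
#' Coordinates are centered on the centroid (the spectrum stage re-anchors
#' at baseline).
#'
#' @param graph A `sample_graph`.
#' @param iterations Number of iterations, default 500.
#' @param seed Integer seed; layout is identical across runs for a fixed seed.
#' @return The graph with `layout`: nodes x 3 matrix (columns x, y, z).
#' @export
layout_3d <- function(graph, iterations = 500, seed = 1L) {
  n <- length(graph$nodes)
  if (n == 0) stop("cannot lay out an empty graph")
  set.seed(as.integer(seed))
  pos <- matrix(stats::runif(n * 3, -0.5, 0.5), n, 3,
                dimnames = list(graph$nodes, c("x", "y", "z")))
  if (!is.null(graph$r_matrix) && n >= 4) {
    mds <- try(stats::cmdscale(stats::as.dist(1 - graph$r_matrix), k = 3),
               silent = TRUE)
    if (!inherits(mds, "try-error") && ncol(mds) == 3 &&
        all(is.finite(mds))) {
      spread <- max(apply(mds, 2, stats::sd))
      if (spread > 0) {
        pos <- mds / spread * 0.25 +
          matrix(stats::rnorm(n * 3, 0, 1e-4), n, 3)
        dimnames(pos) <- list(graph$nodes, c("x", "y", "z"))
      }
    }
  }
  if (n == 1) {
    graph$layout <- pos * 0
    return(graph)
  }
  k <- (1 / n)^(1 / 3)
  w <- graph_adjacency(graph)
  t0 <- 0.1
  for (it in seq_len(iterations)) {
    temp <- t0 * (1 - (it - 1) / iterations)  # linear cooling
    dd1 <- outer(pos[, 1], pos[, 1], "-")
    dd2 <- outer(pos[, 2], pos[, 2], "-")
    dd3 <- outer(pos[, 3], pos[, 3], "-")
    dist2 <- dd1^2 + dd2^2 + dd3^2
    diag(dist2) <- Inf
    dist <- sqrt(pmax(dist2, 1e-12))
    # repulsion k^2/d between all pairs; attraction w*d^2/k along edges;
    # coef = force/dist so that coef * delta is the per-axis contribution
    coef <- k^2 / dist2 - w * dist / k
    diag(coef) <- 0
    disp <- cbind(rowSums(coef * dd1),
                  rowSums(coef * dd2),
                  rowSums(coef * dd3))
    len <- sqrt(rowSums(disp^2))
    step <- pmin(len, temp) / pmax(len, 1e-12)
    pos <- pos + disp * step
  }
  pos <- sweep(pos, 2, colMeans(pos))
  graph$layout <- pos
  attr(graph$layout, "spring_length") <- k
  graph
}

#' Export a sample graph as edge-list TSV and GraphML
#'
#' @param graph A `sample_graph`.
#' @param edges_path TSV path (`source`, `target`, `weight`).
#' @param graphml_path Optional GraphML path (via igraph).
#' @param layout_path Optional TSV path for coordinates (sample, x, y, z).
#' @return Invisibly, the paths written.
#' @export
write_sample_graph <- function(graph, edges_path, graphml_path = NULL,
                               layout_path = NULL) {
  ed <- graph$edges
  names(ed) <- c("source", "target", "weight")
  utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- edges_path
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                       vertices = graph$nodes)
    igraph::E(g)$weight <- graph$edges$r
    igraph::write_graph(g, graphml_path, format = "graphml")
    paths <- c(paths, graphml_path)
  }
  if (!is.null(layout_path) && !is.null(graph$layout)) {
    ld <- data.frame(sample = rownames(graph$layout), graph$layout,
                     row.names = NULL)
    utils::write.table(ld, layout_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, layout_path)
  }
  invisible(paths)
}
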