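# Condition correlation-coefficient matrix (CCM) with hierarchical
# clustering, and the spectrum model: mean 3D displacement vectors of
# condition clusters anchored at the baseline-macrophage centroid.

#' Condition correlation coefficient matrix with hierarchical clustering
#'
#' Builds one mean profile per condition over the `top_n` most variable
#' genes, computes all pairwise Pearson correlations, clusters conditions by
#' average-linkage hierarchical clustering of the 1 - r distance, and cuts
#' the dendrogram into `k` clusters. A z-scored copy of the correlation
#' matrix, clipped symmetrically for display, is attached; it is never used
#' in computation.
#'
#' @param x An `expr_set`.
#' @param design Design table (defaults to the one inside `x`).
#' @param top_n Number of most-variable genes for the condition profiles,
#'   default 1000.
#' @param k Number of condition clusters to cut, default 10.
#' @param linkage Hierarchical clustering linkage, default "average".
#' @param z_clip Display clipping for the z-scored matrix, default 2.78.
#' @return Object of class `ccm`: `conditions`, `r_matrix`, `z_matrix`,
#'   `hclust`, `cluster_of` (named integer), `single_sample` (conditions with
#'   one replicate, flagged).
#' @export
condition_ccm <- function(x, design = NULL, top_n = 1000, k = 10,
                          linkage = "average", z_clip = 2.78) {
  vals <- expr_values(x)
  if (is.null(design)) design <- x$design
  conds <- as.character(unique(design$condition))
  if (k > length(conds)) stop("k exceeds the number of conditions")
  top_n <- min(top_n, nrow(vals))
  genes <- top_variable_genes(vals, top_n)
  single <- conds[vapply(conds, function(cn)
    sum(design$condition == cn) == 1L, TRUE)]
  profiles <- vapply(conds, function(cn)
    rowMeans(vals[genes, design$condition == cn, drop = FALSE]),
    numeric(length(genes)))
  r <- stats::cor(profiles)
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  cluster_of <- stats::cutree(hc, k = k)
  z <- (r - mean(r)) / stats::sd(r)
  z <- pmin(pmax(z, -z_clip), z_clip)
  dimnames(z) <- dimnames(r)
  structure(list(conditions = conds, r_matrix = r, z_matrix = z,
                 hclust = hc, cluster_of = cluster_of, k = k,
                 genes = genes, single_sample = single),
            class = "ccm")
}

#' @export
print.ccm <- function(x, ...) {
  cat(sprintf("ccm: %d conditions in %d clusters (top %d variable genes)\n",
              length(x$conditions), x$k, length(x$genes)))
  invisible(x)
}

#' Spectrum vectors: per-cluster mean 3D displacement from baseline
#'
#' Groups the laid-out samples by the CCM cluster of their condition and
#' computes, for each cluster, the mean of its member sample coordinates
#' minus the mean of the baseline-condition sample coordinates. The baseline
#' cluster is the spectrum origin: its vector is the zero vector by
#' construction (the anchor is the baseline-condition centroid; conditions
#' co-clustered with baseline are listed in `note` but do not move the
#' origin).
#'
#' @param graph A `sample_graph` with a 3D layout (see [layout_3d()]).
#' @param design Design table with `is_baseline`.
#' @param ccm A [condition_ccm()] result.
#' @return `data.frame` with columns `cluster`, `conditions`, `n_samples`,
#'   `x`, `y`, `z`, `magnitude`, `is_baseline`; attribute `note` records
#'   conditions sharing the baseline cluster.
#' @export
spectrum_vectors <- function(graph, design, ccm) {
  if (is.null(graph$layout)) stop("graph has no 3D layout; run layout_3d() first")
  pos <- graph$layout
  design <- design[design$sample_id %in% rownames(pos), , drop = FALSE]
  baseline_cond <- unique(as.character(design$condition[design$is_baseline]))
  if (length(baseline_cond) != 1)
    stop("design must flag exactly one baseline condition")
  cl_of_cond <- ccm$cluster_of
  base_cluster <- cl_of_cond[[baseline_cond]]
  base_idx <- design$sample_id[as.character(design$condition) == baseline_cond]
  origin <- colMeans(pos[base_idx, , drop = FALSE])

  clusters <- sort(unique(cl_of_cond))
  rows <- lapply(clusters, function(cl) {
    conds <- names(cl_of_cond)[cl_of_cond == cl]
    if (cl == base_cluster) {
      members <- base_idx  # origin anchoring: baseline samples only
    } else {
      members <- design$sample_id[as.character(design$condition) %in% conds]
    }
    if (!length(members))
      stop("CCM cluster ", cl, " has no laid-out samples")
    v <- colMeans(pos[members, , drop = FALSE]) - origin
    data.frame(cluster = cl, conditions = paste(conds, collapse = ","),
               n_samples = length(members), x = v[1], y = v[2], z = v[3],
               magnitude = sqrt(sum(v^2)), is_baseline = cl == base_cluster,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  extra <- setdiff(names(cl_of_cond)[cl_of_cond == base_cluster], baseline_cond)
  attr(out, "note") <- if (length(extra))
    paste("conditions co-clustered with baseline:", paste(extra, collapse = ", "))
  else ""
  out
}

#' Pairwise angles between spectrum vectors
#'
#' Angles in degrees via the arccosine of unit-vector dot products. Zero
#' vectors (the baseline) are excluded and listed in the `excluded`
#' attribute.
#'
#' @param vectors Output of [spectrum_vectors()].
#' @return `data.frame` with columns `cluster_a`, `cluster_b`, `angle_deg`.
#' @export
spectrum_angles <- function(vectors) {
  nz <- vectors[vectors$magnitude > 0, , drop = FALSE]
  if (nrow(nz) < 2)
    stop("need >= 2 non-zero spectrum vectors to compute angles")
  u <- as.matrix(nz[, c("x", "y", "z")]) / nz$magnitude
  idx <- which(upper.tri(diag(nrow(nz))), arr.ind = TRUE)
  cosang <- pmin(pmax(rowSums(u[idx[, 1], , drop = FALSE] *
                              u[idx[, 2], , drop = FALSE]), -1), 1)
  out <- data.frame(cluster_a = nz$cluster[idx[, 1]],
                    cluster_b = nz$cluster[idx[, 2]],
                    angle_deg = acos(cosang) * 180 / pi)
  attr(out, "excluded") <- vectors$cluster[vectors$magnitude == 0]
  out
}

#' Write CCM and spectrum artifacts as plain text
#'
#' @param ccm A [condition_ccm()] result.
#' @param r_path TSV path for the correlation matrix.
#' @param newick_path Optional path for the condition dendrogram in Newick
#'   form (via ape).
#' @return Invisibly, the paths written.
#' @export
write_ccm <- function(ccm, r_path, newick_path = NULL) {
  df <- data.frame(condition = rownames(ccm$r_matrix), ccm$r_matrix,
                   check.names = FALSE)
  utils::write.table(df, r_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- r_path
  if (!is.null(newick_path)) {
    # stats::hclust -> nested-parenthesis text via dendrogram traversal
    writeLines(paste0(hclust_to_newick(ccm$hclust), ";"), newick_path)
    paths <- c(paths, newick_path)
  }
  invisible(paths)
}

# Minimal hclust -> Newick string (branch lengths = merge heights).
hclust_to_newick <- function(hc) {
  lab <- hc$labels
  build <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.6g", lab[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.6g", build(hc$merge[i, 1], h),
              build(hc$merge[i, 2], h), parent_h - h)
    }
  }
  n <- length(hc$height)
  h <- hc$height[n]
  sprintf("(%s,%s)", build(hc$merge[n, 1], h), build(hc$merge[n, 2], h))
}
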