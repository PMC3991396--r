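# Self-organizing map clustering of gene expression portraits and selection
# of genes selectively elevated in a single stimulation condition.

#' Per-condition mean expression profiles
#'
#' Convenience: genes x conditions matrix of condition means, the input SOMs
#' are trained on (per-condition portraits).
#'
#' @param x An `expr_set`.
#' @param design Design table (defaults to the one inside `x`).
#' @param standardize Z-score each gene across conditions (default TRUE) so
#'   shape, not level, drives clustering.
#' @return Genes x conditions numeric matrix. Genes constant across
#'   conditions are left at 0 when standardizing.
#' @export
condition_profiles <- function(x, design = NULL, standardize = TRUE) {
  vals <- expr_values(x)
  if (is.null(design)) design <- x$design
  conds <- as.character(unique(design$condition))
  prof <- vapply(conds, function(cn)
    rowMeans(vals[, design$condition == cn, drop = FALSE]),
    numeric(nrow(vals)))
  dimnames(prof) <- list(rownames(vals), conds)
  if (standardize) {
    mu <- rowMeans(prof)
    sd <- apply(prof, 1, stats::sd)
    prof <- (prof - mu) / ifelse(sd > 0, sd, 1)
  }
  prof
}

#' Fit a batch self-organizing map
#'
#' Batch SOM on a rectangular grid with a Gaussian neighborhood whose radius
#' shrinks linearly from max(grid_w, grid_h)/2 to 0.5 over the epochs. The
#' neighborhood is truncated at the current radius, so the final epochs
#' (radius 0.5, below the unit spacing) update only each best-matching unit
#' -- a pure quantization refinement that cannot worsen the fit. Codebooks
#' are initialized deterministically on the plane spanned by the first two
#' principal components of the data (sign-normalized, so initialization does
#' not depend on gene order); the seed argument is accepted for interface
#' symmetry and recorded.
#'
#' @param profiles Genes x conditions matrix (see [condition_profiles()]).
#' @param grid_w,grid_h Grid dimensions; at least 2 units in total (a 2x1
#'   grid degenerates to two-centroid clustering, which is occasionally
#'   useful as a sanity configuration).
#' @param epochs Number of batch epochs, >= 1; default 50.
#' @param seed Recorded in the result (training itself is deterministic).
#' @return Object of class `som_map`: `codebooks` (units x conditions),
#'   `grid` (unit positions), `bmu` (named unit index per gene),
#'   `quantization_error` (mean distance to BMU, initial and final),
#'   `unit_clusters` (NULL until [som_metaclusters()]).
#' @export
som_fit <- function(profiles, grid_w = 10, grid_h = 10, epochs = 50,
                    seed = 1L) {
  if (grid_w * grid_h < 2) stop("grid must have >= 2 units")
  if (epochs < 1) stop("epochs must be >= 1")
  n_units <- grid_w * grid_h
  if (n_units > nrow(profiles))
    warning("more SOM units than genes; proceeding")
  grid <- as.matrix(expand.grid(gx = seq_len(grid_w), gy = seq_len(grid_h)))
  # PCA initialization: units spread over the first two PCs
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  center <- colMeans(profiles)
  fix_sign <- function(v) v * sign(v[which.max(abs(v))])
  d1 <- fix_sign(pc$rotation[, 1]) * pc$sdev[1]
  d2 <- if (ncol(pc$rotation) >= 2)
    fix_sign(pc$rotation[, 2]) * pc$sdev[2] else 0 * d1
  s1 <- if (grid_w > 1) (grid[, 1] - (grid_w + 1) / 2) / ((grid_w - 1) / 2) else rep(0, n_units)
  s2 <- if (grid_h > 1) (grid[, 2] - (grid_h + 1) / 2) / ((grid_h - 1) / 2) else rep(0, n_units)
  codebooks <- matrix(center, n_units, ncol(profiles), byrow = TRUE) +
    outer(s1, d1) + outer(s2, d2)
  colnames(codebooks) <- colnames(profiles)

  bmu_of <- function(cb) {
    # gene x unit squared distances without loops
    d2 <- outer(rowSums(profiles^2), rep(1, nrow(cb))) -
      2 * profiles %*% t(cb) +
      outer(rep(1, nrow(profiles)), rowSums(cb^2))
    max.col(-d2, ties.method = "first")
  }
  qe <- function(cb, bmu) {
    mean(sqrt(rowSums((profiles - cb[bmu, , drop = FALSE])^2)))
  }
  unit_d <- as.matrix(stats::dist(grid))
  r0 <- max(grid_w, grid_h) / 2
  bmu <- bmu_of(codebooks)
  qe_initial <- qe(codebooks, bmu)
  for (e in seq_len(epochs)) {
    radius <- r0 + (0.5 - r0) * (e - 1) / max(epochs - 1, 1)
    h <- exp(-unit_d^2 / (2 * radius^2)) * (unit_d <= radius)
    bmu <- bmu_of(codebooks)
    # batch update: weighted mean of data over BMU neighborhoods
    hw <- h[, bmu, drop = FALSE]           # unit x gene weights
    denom <- rowSums(hw)
    num <- hw %*% profiles
    upd <- denom > 1e-12
    codebooks[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  bmu <- bmu_of(codebooks)
  structure(list(codebooks = codebooks, grid = grid,
                 grid_w = grid_w, grid_h = grid_h,
                 bmu = setNames(bmu, rownames(profiles)),
                 quantization_error = c(initial = qe_initial,
                                        final = qe(codebooks, bmu)),
                 unit_clusters = NULL, seed = as.integer(seed)),
            class = "som_map")
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("som_map: %dx%d grid, %d genes mapped, QE %.3f -> %.3f\n",
              x$grid_w, x$grid_h, length(x$bmu),
              x$quantization_error["initial"], x$quantization_error["final"]))
  invisible(x)
}

#' Meta-cluster SOM units by hierarchical clustering of codebooks
#'
#' Average-linkage hierarchical clustering of the unit codebooks (Euclidean
#' distance), cut into `k` meta-clusters; ties at zero distance merge in unit
#' index order (hclust's deterministic behavior).
#'
#' @param map A `som_map`.
#' @param k Number of meta-clusters, <= number of units.
#' @return The map with `unit_clusters` (integer per unit) and
#'   `gene_clusters` (meta-cluster per gene via its BMU).
#' @export
som_metaclusters <- function(map, k) {
  n_units <- nrow(map$codebooks)
  if (k > n_units) stop("k exceeds the number of SOM units")
  hc <- stats::hclust(stats::dist(map$codebooks), method = "average")
  map$unit_clusters <- stats::cutree(hc, k = k)
  map$gene_clusters <- setNames(map$unit_clusters[map$bmu], names(map$bmu))
  map
}

#' Exclusive condition markers
#'
#' Genes whose mean in the target condition exceeds the maximum mean over
#' every other condition by at least `margin_min` log2 units, ranked by that
#' exclusivity margin. A gene elevated equally in two conditions appears in
#' neither condition's table (for any positive margin).
#'
#' @param x An `expr_set`.
#' @param design Design table (defaults to the one inside `x`).
#' @param condition Target condition; if NULL, tables for all conditions are
#'   concatenated.
#' @param margin_min Minimum exclusivity margin in log2 units, default 1.
#' @return `data.frame` with columns `gene`, `condition`, `target_mean`,
#'   `max_other_mean`, `margin`, `rank`, sorted by descending margin within
#'   condition.
#' @export
exclusive_markers <- function(x, design = NULL, condition = NULL,
                              margin_min = 1) {
  vals <- expr_values(x)
  if (is.null(design)) design <- x$design
  conds <- as.character(unique(design$condition))
  if (length(conds) < 2) stop("need >= 2 conditions")
  prof <- condition_profiles(x, design, standardize = FALSE)
  targets <- if (is.null(condition)) conds else condition
  if (!all(targets %in% conds))
    stop("condition not in design: ",
         paste(setdiff(targets, conds), collapse = ", "))
  out <- lapply(targets, function(cn) {
    others <- prof[, setdiff(conds, cn), drop = FALSE]
    max_other <- apply(others, 1, max)
    margin <- prof[, cn] - max_other
    keep <- margin >= margin_min
    if (!any(keep)) return(NULL)
    d <- data.frame(gene = rownames(prof)[keep], condition = cn,
                    target_mean = prof[keep, cn],
                    max_other_mean = max_other[keep],
                    margin = margin[keep], row.names = NULL,
                    stringsAsFactors = FALSE)
    d <- d[order(-d$margin, d$gene), ]
    d$rank <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(), condition = character(),
                      target_mean = numeric(), max_other_mean = numeric(),
                      margin = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
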