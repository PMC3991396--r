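# Weighted gene coexpression network analysis: soft-thresholded adjacency,
# topological overlap, module detection by hierarchical clustering with a
# static cut and eigengene merging, module eigengenes, and module-eigengene
# to condition correlation.

#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted adjacency |cor|^power between gene expression profiles,
#' zero diagonal.
#'
#' @param x An `expr_set` or genes x samples matrix.
#' @param power Soft-thresholding exponent (>= 1).
#' @param type `"unsigned"` (|r|^power, default) or `"signed"`
#'   (((1+r)/2)^power).
#' @return Genes x genes adjacency matrix with entries in \[0,1\].
#' @export
adjacency_matrix <- function(x, power, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  vals <- expr_values(x)
  r <- stats::cor(t(vals))
  a <- if (type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 0
  a
}

#' Pick the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, connectivities k_i = sum_j a_ij are binned and
#' the fit R^2 of the log10 frequency vs log10 mean-k regression is computed,
#' signed by the slope (a negative slope, i.e. a decreasing degree
#' distribution, is required for a positive index). The smallest power whose
#' signed R^2 reaches `target_r2` is returned. When no candidate reaches the
#' target -- common for strongly modular data, where the fit index keeps
#' rising with power while the network degenerates -- the standard
#' sample-size-based default for unsigned networks is returned with a
#' warning (9 below 20 samples, 8 below 30, 7 below 40, 6 otherwise),
#' rather than the argmax, which would always select the largest candidate.
#'
#' @param x An `expr_set` or matrix with >= 10 genes.
#' @param powers Candidate powers, default `c(1:10, 12, 14, 16, 18, 20)`.
#' @param target_r2 Required signed fit index, default 0.85.
#' @param n_bins Connectivity bins for the fit, default 10.
#' @return The chosen power; attribute `fit_table` holds power, signed R^2
#'   and mean connectivity.
#' @export
pick_soft_threshold <- function(x, powers = c(1:10, 12, 14, 16, 18, 20),
                                target_r2 = 0.85, n_bins = 10) {
  vals <- expr_values(x)
  if (nrow(vals) < 10) stop("scale-free fit is meaningless below 10 genes")
  if (!length(powers)) stop("powers must be non-empty")
  powers <- sort(powers)
  absr <- abs(stats::cor(t(vals)))
  diag(absr) <- 0
  fit <- vapply(powers, function(p) {
    k <- rowSums(absr^p)
    sft_fit_index(k)
  }, numeric(2))
  fit_table <- data.frame(power = powers, signed_r2 = fit[1, ],
                          mean_k = fit[2, ])
  if (target_r2 <= 0) {   # vacuous criterion: every power qualifies
    chosen <- powers[1]
    attr(chosen, "fit_table") <- fit_table
    return(chosen)
  }
  ok <- which(fit_table$signed_r2 >= target_r2)
  if (length(ok)) {
    chosen <- powers[ok[1]]
  } else {
    n_samples <- ncol(vals)
    fallback <- if (n_samples < 20) 9 else if (n_samples < 30) 8
                else if (n_samples < 40) 7 else 6
    chosen <- powers[which.min(abs(powers - fallback))]
    warning("no candidate power reached target_r2 = ", target_r2,
            "; using sample-size default power ", chosen)
  }
  attr(chosen, "fit_table") <- fit_table
  chosen
}

# Signed scale-free fit index of a connectivity vector: R^2 of the
# log10(p(k)) ~ log10(k) regression over equal-width bins of k, multiplied
# by -sign(slope).
sft_fit_index <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 4 || max(k) == min(k)) return(c(0, mean(k)))
  cuts <- cut(k, n_bins)
  df <- data.frame(
    logk = tapply(k, cuts, function(v) log10(mean(v))),
    logp = log10(as.numeric(table(cuts)) / length(k))
  )
  df <- df[is.finite(df$logp) & is.finite(df$logk), ]
  if (nrow(df) < 3) return(c(0, mean(k)))
  fitlm <- stats::lm(logp ~ logk, data = df)
  r2 <- summary(fitlm)$r.squared
  c(-sign(stats::coef(fitlm)[2]) * r2, mean(k))
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j,
#' with k the row sums of the adjacency; unit diagonal. Entries lie in
#' \[0, 1\] for adjacency entries in \[0, 1\].
#'
#' @param adjacency Symmetric genes x genes matrix, entries in \[0,1\], zero
#'   diagonal.
#' @return The TOM matrix (unit diagonal).
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must lie in [0, 1]")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(adjacency)
  shared <- adjacency %*% adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (shared + adjacency) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module eigengene: first principal component of a module
#'
#' Genes are standardized across samples, the first right singular vector of
#' the gene x sample submatrix gives the per-sample eigengene (unit norm).
#' The sign is chosen so that the eigengene correlates positively with the
#' module's mean standardized expression; when that correlation is exactly
#' zero (an anti-correlated pair averaging to a flat profile) the tie is
#' broken by aligning to the first gene, and the result is flagged.
#'
#' @param x An `expr_set` or matrix.
#' @param genes Gene ids of the module (>= 2, present in `x`).
#' @return List with `eigengene` (named per-sample vector, unit norm),
#'   `var_explained` (fraction in \[0,1\]), `sign_indeterminate` (logical).
#' @export
module_eigengene <- function(x, genes) {
  vals <- expr_values(x)
  if (length(genes) < 2) stop("module must have >= 2 genes")
  missing <- setdiff(genes, rownames(vals))
  if (length(missing))
    stop("module genes missing from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- vals[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  sd <- apply(sub, 1, stats::sd)
  if (all(sd == 0)) stop("module submatrix has rank 0 (all genes constant)")
  z <- (sub - mu) / ifelse(sd > 0, sd, 1)
  sv <- svd(z)
  eg <- sv$v[, 1]
  var_explained <- sv$d[1]^2 / sum(sv$d^2)
  avg <- colMeans(z)
  al <- sum(eg * avg)
  sign_indeterminate <- abs(al) < 1e-12
  s <- if (sign_indeterminate) sign(sum(eg * z[1, ])) else sign(al)
  if (s == 0) s <- 1
  eg <- eg * s
  names(eg) <- colnames(vals)
  list(eigengene = eg, var_explained = var_explained,
       sign_indeterminate = sign_indeterminate)
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the 1 - TOM dissimilarity with
#' a static cut at `cut_height`; branches smaller than `min_size` go to
#' module 0 (unassigned, "grey"). Modules whose eigengenes correlate above
#' `merge_r` are merged iteratively until a fixpoint. Final module ids are
#' assigned by decreasing size (1 = largest).
#'
#' @param tom TOM matrix with gene dimnames.
#' @param x The `expr_set` (or matrix) the TOM came from, needed for
#'   eigengene-based merging.
#' @param min_size Minimum module size, >= 3; default 20.
#' @param cut_height Static cut height on the 1 - TOM dendrogram, default
#'   0.995 (TOM dissimilarities concentrate near 1 for weighted networks, so
#'   useful cuts sit close to the top of the tree).
#' @param merge_r Eigengene correlation above which modules merge, default
#'   0.8.
#' @return List with `membership` (named integer vector, 0 = unassigned) and
#'   `modules` (list of `gene_module`: `id`, `genes`, `eigengene`,
#'   `var_explained`, `kme`).
#' @export
detect_modules <- function(tom, x, min_size = 20, cut_height = 0.995,
                           merge_r = 0.8) {
  if (min_size < 3) stop("min_size must be >= 3")
  genes <- rownames(tom)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  membership <- setNames(rep(0L, length(genes)), genes)
  for (i in seq_along(keep)) membership[cl == keep[i]] <- i

  if (!any(membership > 0)) {
    warning("all genes unassigned (module 0); no modules detected")
    return(list(membership = membership, modules = list()))
  }
  vals <- expr_values(x)[genes, , drop = FALSE]

  # iterative eigengene merging until fixpoint
  repeat {
    ids <- sort(unique(membership[membership > 0]))
    if (length(ids) < 2) break
    egs <- vapply(ids, function(i)
      module_eigengene(vals, genes[membership == i])$eigengene,
      numeric(ncol(vals)))
    r <- stats::cor(egs)
    diag(r) <- 0
    mx <- which(r == max(r), arr.ind = TRUE)[1, ]
    if (r[mx[1], mx[2]] <= merge_r) break
    a <- ids[min(mx)]; b <- ids[max(mx)]
    membership[membership == b] <- a
  }

  # relabel by decreasing size
  ids <- sort(unique(membership[membership > 0]))
  sizes <- vapply(ids, function(i) sum(membership == i), 1L)
  ord <- ids[order(-sizes, ids)]
  relab <- membership
  for (i in seq_along(ord)) relab[membership == ord[i]] <- i
  membership <- relab

  modules <- lapply(sort(unique(membership[membership > 0])), function(i) {
    mg <- genes[membership == i]
    eg <- module_eigengene(vals, mg)
    kme <- drop(stats::cor(t(vals[mg, , drop = FALSE]), eg$eigengene))
    names(kme) <- mg
    structure(list(id = i, genes = mg, eigengene = eg$eigengene,
                   var_explained = eg$var_explained, kme = kme),
              class = "gene_module")
  })
  list(membership = membership, modules = modules)
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene_module %d: %d genes, %.1f%% variance explained\n",
              x$id, length(x$genes), 100 * x$var_explained))
  invisible(x)
}

#' Module-eigengene to condition correlation
#'
#' Pearson correlation of each module eigengene against each condition's
#' one-hot indicator across samples, with the Student-t p value and BH
#' correction across the whole module x condition grid.
#'
#' @param modules List of `gene_module`s (from [detect_modules()]).
#' @param design Design table whose rows match the eigengene samples.
#' @return List of modules x conditions matrices `r`, `p`, `q`, plus
#'   `driver` (named character: max-|r| condition per module).
#' @export
module_trait_correlation <- function(modules, design) {
  if (!length(modules)) stop("no modules to correlate")
  conds <- as.character(unique(design$condition))
  if (length(conds) < 2) stop("need >= 2 conditions")
  n <- nrow(design)
  egs <- vapply(modules, `[[`, numeric(n), "eigengene")
  onehot <- vapply(conds, function(cn)
    as.numeric(design$condition == cn), numeric(n))
  r <- suppressWarnings(stats::cor(egs, onehot))  # modules x conditions
  r[is.na(r)] <- 0   # constant eigengene -> zero correlation by convention
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  p[r == 0] <- 1
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
  ids <- vapply(modules, `[[`, 1L, "id")
  dimnames(r) <- dimnames(p) <- dimnames(q) <-
    list(paste0("module", ids), conds)
  driver <- conds[apply(abs(r), 1, which.max)]
  names(driver) <- rownames(r)
  list(r = r, p = p, q = q, driver = driver)
}

#' Correlation subnetwork of module transcription factors
#'
#' Restricts to the supplied transcription factors that belong to the
#' selected modules and connects pairs whose expression correlates with
#' |r| >= `r_min` (edge weight = r, mirrored in an edge-width attribute).
#'
#' @param x An `expr_set` or matrix.
#' @param membership Named module membership vector (see [detect_modules()]).
#' @param module_ids Modules whose TFs to include.
#' @param tf_list Transcription-factor gene ids (non-empty; ids absent from
#'   the matrix raise an error naming them).
#' @param r_min Minimum |r| for an edge, default 0.7.
#' @return `data.frame` with columns `from`, `to`, `r`, `width`; attribute
#'   `tfs` lists the TFs in the selected modules (possibly empty, with a
#'   note).
#' @export
tf_subnetwork_correlations <- function(x, membership, module_ids, tf_list,
                                       r_min = 0.7) {
  if (!length(tf_list)) stop("tf_list must be non-empty")
  vals <- expr_values(x)
  missing <- setdiff(tf_list, rownames(vals))
  if (length(missing))
    stop("TFs not in expression matrix: ", paste(missing, collapse = ", "))
  in_modules <- names(membership)[membership %in% module_ids]
  tfs <- intersect(tf_list, in_modules)
  empty <- data.frame(from = character(), to = character(), r = numeric(),
                      width = numeric(), stringsAsFactors = FALSE)
  if (length(tfs) < 2) {
    attr(empty, "tfs") <- tfs
    attr(empty, "note") <- "fewer than two TFs inside the selected modules"
    return(empty)
  }
  r <- stats::cor(t(vals[tfs, , drop = FALSE]))
  idx <- which(upper.tri(r) & abs(r) >= r_min, arr.ind = TRUE)
  out <- data.frame(from = rownames(r)[idx[, 1]], to = colnames(r)[idx[, 2]],
                    r = r[idx], width = abs(r[idx]),
                    stringsAsFactors = FALSE)
  attr(out, "tfs") <- tfs
  out
}

#' Write modules as a GMT gene-set file
#'
#' One line per module: id, description, member genes (tab-separated) -- the
#' bridge from module detection to gene-set enrichment.
#'
#' @param modules List of `gene_module`s or a named list of gene-id vectors.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
modules_to_gmt <- function(modules, path) {
  sets <- if (length(modules) && inherits(modules[[1]], "gene_module")) {
    setNames(lapply(modules, `[[`, "genes"),
             paste0("module", vapply(modules, `[[`, 1L, "id")))
  } else modules
  write_gmt(sets, path)
}
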