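# Gene-set enrichment analysis with coexpression modules as gene sets
# (weighted Kolmogorov-Smirnov running sum, phenotype or gene-set
# permutations, NES and GSEA-style FDR), plus hypergeometric
# over-representation analysis against a user-supplied annotation map.

#' Rank genes for GSEA
#'
#' Descending ranking of all genes by a two-group metric: `signal2noise`
#' (mu_a - mu_b) / (sd_a + sd_b) with each sd floored at 0.2 |mu| (and 0.2
#' when the mean is 0), per standard GSEA convention, or `tstat` (Welch t).
#' Ties break by gene id so the ranking is deterministic.
#'
#' @param x An `expr_set` or matrix.
#' @param design Design table (defaults to the one inside `x`).
#' @param group_a,group_b Condition labels (a vs b; positive scores mean
#'   higher in a).
#' @param metric `"signal2noise"` (needs >= 3 samples per group) or
#'   `"tstat"` (needs >= 2).
#' @return Named numeric vector of scores, sorted descending.
#' @export
rank_genes <- function(x, design = NULL, group_a, group_b,
                       metric = c("signal2noise", "tstat")) {
  metric <- match.arg(metric)
  vals <- expr_values(x)
  if (is.null(design) && inherits(x, "expr_set")) design <- x$design
  ia <- which(design$condition == group_a)
  ib <- which(design$condition == group_b)
  min_n <- if (metric == "signal2noise") 3L else 2L
  if (length(ia) < min_n || length(ib) < min_n)
    stop(sprintf("metric %s needs >= %d samples per group", metric, min_n))
  a <- vals[, ia, drop = FALSE]; b <- vals[, ib, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  sa <- apply(a, 1, stats::sd); sb <- apply(b, 1, stats::sd)
  if (metric == "signal2noise") {
    floor_a <- pmax(0.2 * abs(ma), 0.2)
    floor_b <- pmax(0.2 * abs(mb), 0.2)
    s <- (ma - mb) / (pmax(sa, floor_a) + pmax(sb, floor_b))
  } else {
    se <- sqrt(sa^2 / ncol(a) + sb^2 / ncol(b))
    s <- (ma - mb) / pmax(se, .Machine$double.eps)
  }
  s[ma == mb] <- 0
  s[order(-s, names(s))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; hits increment the running sum proportionally to
#' |score|^p (normalized over the set's hits), misses decrement by
#' 1/(N - Nh). The enrichment score is the extremum of largest magnitude and
#' the leading edge is the hits up to (for positive ES) or after (negative)
#' the extremum.
#'
#' @param ranked Named numeric vector of scores sorted descending (see
#'   [rank_genes()]).
#' @param gene_set Character vector; must intersect the ranked list and must
#'   not cover it entirely (the miss denominator would vanish).
#' @param p Weighting exponent, default 1 (classic GSEA); `p = 0` gives the
#'   unweighted KS statistic.
#' @return List with `es`, `running` (per-position running sum) and
#'   `leading_edge` (character vector of hit genes).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has empty intersection with the ranked list: ",
                    paste(utils::head(gene_set, 3), collapse = ", "))
  n <- length(ranked)
  if (nh == n) stop("gene set covers the whole ranked list; ES undefined")
  w <- abs(ranked)^p
  hit_mass <- w * hit
  denom <- sum(hit_mass)
  inc <- if (denom > 0) hit_mass / denom else hit / nh  # all-zero scores: uniform
  dec <- (!hit) / (n - nh)
  running <- cumsum(inc - dec)
  i <- which.max(abs(running))
  es <- running[[i]]
  leading <- if (es >= 0) genes[seq_len(i)][hit[seq_len(i)]]
             else genes[i:n][hit[i:n]]
  list(es = unname(es), running = unname(running), leading_edge = leading)
}

#' GSEA with permutation-based significance
#'
#' For each gene set the enrichment score on the observed ranking is
#' compared against permutation null scores: phenotype mode permutes the
#' group labels and recomputes the ranking metric (the default; falls back
#' to gene-set mode with a warning when fewer than 7 samples are available),
#' gene-set mode samples random sets of the same size. NES = ES divided by
#' the mean |permuted ES| of matching sign; nominal p is the fraction of
#' same-sign permuted ES at least as extreme; FDR q follows the GSEA
#' normalized-tail convention (ratio of tail fractions of the pooled
#' permuted NES to observed NES of the same sign, capped at 1). When the
#' requested permutations exceed the number of distinct label assignments,
#' exhaustive enumeration is used instead and noted in the result.
#'
#' @param x An `expr_set`.
#' @param design Design table (defaults to the one inside `x`).
#' @param group_a,group_b Condition labels for the contrast.
#' @param gene_sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations, default 1000 (>= 100 for usable q).
#' @param mode `"phenotype"` or `"geneset"`.
#' @param force_phenotype Keep phenotype mode even below 7 samples (useful
#'   for exhaustive enumeration on tiny balanced designs, where all label
#'   assignments can be enumerated exactly).
#' @param metric Ranking metric, see [rank_genes()].
#' @param p Running-sum weight, default 1.
#' @param seed Integer seed for the permutation stream.
#' @return `data.frame` with columns `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (comma-joined); attributes `mode` and `exhaustive`.
#' @export
gsea_permutation <- function(x, design = NULL, group_a, group_b, gene_sets,
                             n_perm = 1000, mode = c("phenotype", "geneset"),
                             metric = "signal2noise", p = 1, seed = 1L,
                             force_phenotype = FALSE) {
  mode <- match.arg(mode)
  vals <- expr_values(x)
  if (is.null(design) && inherits(x, "expr_set")) design <- x$design
  sub <- design$condition %in% c(group_a, group_b)
  if (mode == "phenotype" && sum(sub) < 7 && !force_phenotype) {
    warning("fewer than 7 samples in the contrast; switching to gene-set permutation")
    mode <- "geneset"
  }
  ranked <- rank_genes(vals, design, group_a, group_b, metric = metric)
  obs <- lapply(gene_sets, function(gs) enrichment_score(ranked, gs, p = p))
  es <- vapply(obs, `[[`, 0, "es")
  sizes <- vapply(gene_sets, function(gs) sum(names(ranked) %in% gs), 0L)

  set.seed(as.integer(seed))
  exhaustive <- FALSE
  if (mode == "phenotype") {
    idx <- which(sub)
    labs <- as.character(design$condition[idx])
    na <- sum(labs == group_a)
    n_distinct <- choose(length(idx), na)
    if (n_perm >= n_distinct && n_distinct <= 1e5) {
      exhaustive <- TRUE
      combs <- utils::combn(length(idx), na)
      perm_assign <- lapply(seq_len(ncol(combs)), function(j) combs[, j])
    } else {
      perm_assign <- lapply(seq_len(n_perm), function(j)
        sample(length(idx), na))
    }
    perm_es <- vapply(perm_assign, function(asel) {
      d2 <- design[idx, , drop = FALSE]
      lab <- rep(group_b, length(idx))
      lab[asel] <- group_a
      d2$condition <- lab
      rk <- rank_genes(vals[, idx, drop = FALSE], d2, group_a, group_b,
                       metric = metric)
      vapply(gene_sets, function(gs) enrichment_score(rk, gs, p = p)$es, 0)
    }, numeric(length(gene_sets)))
  } else {
    universe <- names(ranked)
    perm_es <- vapply(seq_len(n_perm), function(j) {
      vapply(sizes, function(sz)
        enrichment_score(ranked, sample(universe, sz), p = p)$es, 0)
    }, numeric(length(gene_sets)))
  }
  perm_es <- matrix(perm_es, nrow = length(gene_sets))

  nes <- numeric(length(es)); pval <- numeric(length(es))
  perm_nes <- perm_es
  for (i in seq_along(es)) {
    pe <- perm_es[i, ]
    same <- if (es[i] >= 0) pe[pe >= 0] else pe[pe < 0]
    denom_pos <- mean(pe[pe >= 0]); denom_neg <- mean(abs(pe[pe < 0]))
    nes[i] <- if (es[i] >= 0) {
      if (is.finite(denom_pos) && denom_pos > 0) es[i] / denom_pos else 0
    } else {
      if (is.finite(denom_neg) && denom_neg > 0) es[i] / denom_neg else 0
    }
    pval[i] <- if (length(same))
      mean(abs(same) >= abs(es[i])) else 0
    # normalize permuted ES of this set for the FDR pool
    perm_nes[i, ] <- ifelse(pe >= 0,
                            if (is.finite(denom_pos) && denom_pos > 0) pe / denom_pos else 0,
                            if (is.finite(denom_neg) && denom_neg > 0) pe / denom_neg else 0)
  }
  pool <- as.vector(perm_nes)
  q <- vapply(seq_along(nes), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (!is.finite(num)) num <- 1
    if (!is.finite(den) || den == 0) den <- 1 / length(nes)
    min(num / den, 1)
  }, 0)
  res <- data.frame(set = names(gene_sets), size = sizes, es = es, nes = nes,
                    p = pval, q = q,
                    leading_edge = vapply(obs, function(o)
                      paste(o$leading_edge, collapse = ","), ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "mode") <- mode
  attr(res, "exhaustive") <- exhaustive
  attr(res, "n_perm") <- ncol(perm_es)
  res
}

#' Flag enriched and depleted gene sets (volcano thresholds)
#'
#' @param results A [gsea_permutation()] table.
#' @param nes_min NES magnitude threshold, default 1.
#' @param p_max Nominal p threshold, default 0.05.
#' @return The table with logical columns `enriched` (NES > nes_min,
#'   p < p_max) and `depleted` (NES < -nes_min, p < p_max).
#' @export
volcano_table <- function(results, nes_min = 1, p_max = 0.05) {
  results$enriched <- results$nes > nes_min & results$p < p_max
  results$depleted <- results$nes < -nes_min & results$p < p_max
  results
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and each annotation term, against a fixed universe; BH correction across
#' the tested terms. Terms with no genes in the universe are skipped with a
#' note.
#'
#' @param query Gene ids of interest (non-empty, subset of `universe`).
#' @param universe All assayed gene ids.
#' @param annotation Named list: term id -> gene-id vector.
#' @return `data.frame` with columns `term`, `term_size`, `overlap`,
#'   `expected`, `p`, `q`, sorted by p; attribute `skipped` lists terms
#'   outside the universe.
#' @export
ora_hypergeometric <- function(query, universe, annotation) {
  if (!length(query)) stop("empty query gene set")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  n_u <- length(universe); n_q <- length(query)
  term_genes <- lapply(annotation, intersect, universe)
  skipped <- names(annotation)[vapply(term_genes, length, 1L) == 0]
  keep <- vapply(term_genes, length, 1L) > 0
  term_genes <- term_genes[keep]
  rows <- lapply(names(term_genes), function(tm) {
    k_t <- length(term_genes[[tm]])
    ov <- length(intersect(query, term_genes[[tm]]))
    data.frame(term = tm, term_size = k_t, overlap = ov,
               expected = n_q * k_t / n_u,
               p = stats::phyper(ov - 1, k_t, n_u - k_t, n_q,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(structure(data.frame(term = character(), term_size = integer(),
                                overlap = integer(), expected = numeric(),
                                p = numeric(), q = numeric()),
                     skipped = skipped))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
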