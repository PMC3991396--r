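# Preprocessing: quantile normalization, detection filtering against an
# empirical background, variance ranking, and differential-expression /
# ANOVA screens with Benjamini-Hochberg correction.

#' Quantile normalization
#'
#' Forces every sample column onto the common reference distribution given by
#' the row-wise mean of the sorted columns. After normalization every column
#' has identical sorted values; gene order is preserved. Ties within a column
#' are broken by first occurrence, which makes the transform idempotent.
#'
#' @param x An `expr_set` or genes x samples matrix (no missing values).
#' @return Same type as the input, normalized.
#' @export
quantile_normalize <- function(x) {
  vals <- expr_values(x)
  if (ncol(vals) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(vals))
    stop("missing values present: impute upstream before quantile normalization")
  ref <- rowMeans(apply(vals, 2, sort))
  out <- apply(vals, 2, function(col) ref[rank(col, ties.method = "first")])
  dimnames(out) <- dimnames(vals)
  if (inherits(x, "expr_set")) {
    x$values <- out
    x
  } else out
}

#' Detection filter against an empirical background
#'
#' A gene is called detected in a condition when its condition-mean exceeds
#' the empirical background level -- the `background_quantile` of the pooled
#' value distribution -- by at least `min_margin` log2 units. The expressed
#' set is the union over conditions (present in at least one condition).
#'
#' @param x An `expr_set`.
#' @param design Design table (defaults to the one inside `x`).
#' @param background_quantile Quantile of all values defining background,
#'   in (0,1); default 0.25.
#' @param min_margin Required log2 margin above background, default 0.5.
#' @return List with `expressed_genes` (character), `detected` (genes x
#'   conditions logical matrix) and `background` (numeric level used).
#' @export
detection_filter <- function(x, design = NULL,
                             background_quantile = 0.25, min_margin = 0.5) {
  if (background_quantile <= 0 || background_quantile >= 1)
    stop("background_quantile must be in (0, 1)")
  vals <- expr_values(x)
  if (is.null(design)) design <- x$design
  conds <- unique(as.character(design$condition))
  counts <- table(as.character(design$condition))
  if (any(counts == 0)) stop("empty condition group")
  bg <- stats::quantile(vals, background_quantile, names = FALSE)
  cond_means <- vapply(conds, function(cn) {
    rowMeans(vals[, design$condition == cn, drop = FALSE])
  }, numeric(nrow(vals)))
  detected <- cond_means > bg + min_margin
  dimnames(detected) <- list(rownames(vals), conds)
  list(expressed_genes = rownames(vals)[rowSums(detected) > 0],
       detected = detected, background = bg)
}

#' Most variable genes
#'
#' Ranks genes by descending variance across samples; ties are broken by
#' lexicographic gene id so the result is deterministic.
#'
#' @param x An `expr_set` or matrix.
#' @param n Number of genes to return (1..nrow).
#' @return Character vector of gene ids, length `n`.
#' @export
top_variable_genes <- function(x, n) {
  vals <- expr_values(x)
  if (n <= 0) stop("n must be positive")
  if (n > nrow(vals)) stop("n exceeds number of genes")
  v <- apply(vals, 1, stats::var)
  ord <- order(-v, rownames(vals))
  rownames(vals)[ord][seq_len(n)]
}

#' Two-group differential expression screen
#'
#' Per-gene Welch two-sample t test on log2 values. The fold change is
#' computed as 2^(mean_a - mean_b) -- difference of group means on the log2
#' scale, never a ratio of raw means. P values are BH-adjusted over all
#' tested genes; a gene passes when |FC| exceeds `fc_min` (in either
#' direction) and q < `q_max`. Genes with zero variance in both groups get
#' p = 1 and a degenerate flag.
#'
#' @param x An `expr_set`.
#' @param design Design table (defaults to the one inside `x`).
#' @param group_a,group_b Condition labels to compare (a vs b).
#' @param fc_min Fold-change threshold on the natural scale, default 2.
#' @param q_max BH-adjusted significance threshold, default 0.05.
#' @return `data.frame` with columns `gene`, `log2fc`, `p`, `q`, `pass`,
#'   `degenerate`.
#' @export
differential_expression <- function(x, design = NULL, group_a, group_b,
                                    fc_min = 2, q_max = 0.05) {
  vals <- expr_values(x)
  if (is.null(design)) design <- x$design
  ia <- which(design$condition == group_a)
  ib <- which(design$condition == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need >= 2 samples for a variance estimate")
  a <- vals[, ia, drop = FALSE]; b <- vals[, ib, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, 0, (ma - mb) / sqrt(pmax(se2, .Machine$double.eps)))
  df <- ifelse(degenerate, 1,
               se2^2 / pmax((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1),
                            .Machine$double.eps))
  p <- ifelse(degenerate, 1, 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
  q <- stats::p.adjust(p, method = "BH")
  log2fc <- ma - mb
  res <- data.frame(gene = rownames(vals), log2fc = log2fc, p = p, q = q,
                    pass = (2^abs(log2fc) > fc_min) & (q < q_max) & !degenerate,
                    degenerate = degenerate, row.names = NULL,
                    stringsAsFactors = FALSE)
  res[order(res$p, res$gene), ]
}

#' One-way ANOVA screen across all conditions
#'
#' Classic equal-variance one-way F test per gene across the condition groups
#' (deterministic, no resampling), BH-adjusted. Genes constant everywhere are
#' reported non-significant (p = 1) with a degenerate flag rather than NaN.
#'
#' @param x An `expr_set`.
#' @param design Design table (defaults to the one inside `x`).
#' @param q_max BH-adjusted significance threshold, default 0.05.
#' @return `data.frame` with columns `gene`, `F`, `p`, `q`, `pass`,
#'   `degenerate`.
#' @export
anova_screen <- function(x, design = NULL, q_max = 0.05) {
  vals <- expr_values(x)
  if (is.null(design)) design <- x$design
  g <- factor(design$condition)
  counts <- table(g)
  if (length(counts) < 2) stop("anova_screen needs >= 2 conditions")
  if (any(counts < 2)) stop("every condition needs >= 2 samples")
  n <- ncol(vals); k <- length(counts)
  grand <- rowMeans(vals)
  group_means <- vapply(levels(g), function(cn)
    rowMeans(vals[, g == cn, drop = FALSE]), numeric(nrow(vals)))
  ssb <- as.vector(group_means^2 %*% as.numeric(counts)) - n * grand^2
  sst <- rowSums(vals^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  degenerate <- sst < .Machine$double.eps * n
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  Fstat <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(degenerate, 1,
              stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE))
  p[!degenerate & is.infinite(Fstat)] <- 0
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(vals), F = Fstat, p = p, q = q,
             pass = q < q_max & !degenerate, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}
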