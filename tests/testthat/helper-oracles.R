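# Independent brute-force oracles and shared fixture builders. Every oracle
# here is written directly from the defining formula, with plain loops,
# so it stays independent of the vectorized implementations it checks.

# --- fixtures -------------------------------------------------------------

# Six 50-gene modules, one driver condition each (incl. baseline), 60 samples.
planted_module_fixture <- function(seed, effect = 2, noise_sd = 0.5,
                                   module_size = 50, n_background = 0,
                                   gene_mean_sd = 2) {
  conds <- paste0("C", 1:5)
  design <- make_design(6, 10, condition_names = conds, seed = seed)
  drivers <- c("Mb", conds)
  mods <- lapply(1:6, function(i)
    list(genes = sprintf("md%d_%03d", i, seq_len(module_size)),
         effects = setNames(effect, drivers[i])))
  st <- planted_structure(modules = mods, noise_sd = noise_sd,
                          gene_mean_sd = gene_mean_sd)
  x <- simulate_expression(design, st, n_background_genes = n_background,
                           seed = seed)
  truth <- setNames(rep(seq_len(6), each = module_size),
                    unlist(lapply(mods, `[[`, "genes")))
  list(x = x, design = design, truth = truth, drivers = drivers, mods = mods)
}

# Undirected edge keys for recovery scoring.
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# --- brute-force oracles --------------------------------------------------

# BH adjusted q-values: sorted p * m / rank, running minimum from the bottom.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# TOM by literal triple loop over the defining formula.
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) s <- s + a[i, u] * a[u, j]
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# DPI by enumeration of all node triples against the original weights.
dpi_brute <- function(nodes, edges, tolerance) {
  w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  w[cbind(edges$from, edges$to)] <- edges$mi
  w[cbind(edges$to, edges$from)] <- edges$mi
  n <- length(nodes)
  drop <- matrix(FALSE, n, n)
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (w[i, j] > 0 && w[i, k] > 0 && w[j, k] > 0) {
      if (w[i, j] < (1 - tolerance) * min(w[i, k], w[j, k])) drop[i, j] <- TRUE
      if (w[i, k] < (1 - tolerance) * min(w[i, j], w[j, k])) drop[i, k] <- TRUE
      if (w[j, k] < (1 - tolerance) * min(w[i, j], w[i, k])) drop[j, k] <- TRUE
    }
  }
  ij <- cbind(match(edges$from, nodes), match(edges$to, nodes))
  keep <- !drop[cbind(pmin(ij[, 1], ij[, 2]), pmax(ij[, 1], ij[, 2]))]
  edges[keep, , drop = FALSE]
}

# Weighted KS running sum by direct loop.
es_brute <- function(scores, in_set, p) {
  n <- length(scores)
  nh <- sum(in_set)
  denom <- sum(abs(scores[in_set])^p)
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      cur <- cur + (if (denom > 0) abs(scores[i])^p / denom else 1 / nh)
    } else {
      cur <- cur - 1 / (n - nh)
    }
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# Signal-to-noise ranking metric by direct arithmetic (GSEA convention:
# each sd floored at max(0.2 |mean|, 0.2)).
s2n_brute <- function(a, b) {
  sda <- max(stats::sd(a), 0.2 * abs(mean(a)), 0.2)
  sdb <- max(stats::sd(b), 0.2 * abs(mean(b)), 0.2)
  (mean(a) - mean(b)) / (sda + sdb)
}

# Exhaustive phenotype-permutation GSEA p for one gene set on a 3v3 design.
gsea_exact_p <- function(vals, ia, ib, gene_set, p_weight = 1) {
  idx <- c(ia, ib)
  na <- length(ia)
  combs <- utils::combn(length(idx), na)
  rank_once <- function(asel) {
    a <- vals[, idx[asel], drop = FALSE]
    b <- vals[, idx[-asel], drop = FALSE]
    s <- vapply(seq_len(nrow(vals)), function(g) s2n_brute(a[g, ], b[g, ]), 0)
    names(s) <- rownames(vals)
    s[order(-s, names(s))]
  }
  es_of <- function(rk) es_brute(rk, names(rk) %in% gene_set, p_weight)
  obs <- es_of(rank_once(seq_len(na)))
  perm <- vapply(seq_len(ncol(combs)), function(j)
    es_of(rank_once(combs[, j])), 0)
  same <- if (obs >= 0) perm[perm >= 0] else perm[perm < 0]
  list(es = obs, p = mean(abs(same) >= abs(obs)))
}

# Straightforward reference MCL (dense, no pruning) written independently.
mcl_reference <- function(adj, inflation, iterations = 200) {
  diag(adj) <- 1
  m <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iterations)) {
    m <- m %*% m
    m <- m^inflation
    m <- sweep(m, 2, colSums(m), "/")
  }
  cl <- rep(NA_integer_, ncol(m))
  nxt <- 0L
  for (a in which(rowSums(m) > 1e-6)) {
    mem <- which(m[a, ] > 1e-6)
    known <- unique(stats::na.omit(cl[mem]))
    lab <- if (length(known)) known[1] else (nxt <- nxt + 1L)
    cl[mem[is.na(cl[mem])]] <- lab
  }
  cl
}

# Exact hypergeometric upper-tail p by subset enumeration (N <= 20).
hyper_enum <- function(universe_n, term_n, query_n, overlap) {
  combs <- utils::combn(universe_n, query_n)
  hits <- vapply(seq_len(ncol(combs)), function(j)
    sum(combs[, j] <= term_n) >= overlap, TRUE)
  mean(hits)
}
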