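# Mutual-information estimation, significance thresholding, DPI pruning,
# hub extraction and TF neighborhoods.

test_that("MI estimator is symmetric, saturates on self-pairs, and matches
           the Gaussian closed form", {
  set.seed(1)
  x <- rnorm(500); y <- 0.6 * x + rnorm(500, 0, sqrt(1 - 0.36))
  expect_identical(pairwise_mi(x, y), pairwise_mi(y, x))
  expect_gt(pairwise_mi(x, x), pairwise_mi(x, y))
  expect_equal(attr(pairwise_mi(x, rep(1, 500)), "degenerate"), TRUE)
  expect_error(pairwise_mi(x[1:5], y[1:5]), ">= 10")
  expect_error(pairwise_mi(x, y[1:10]), "equal length")

  # closed-form oracle: rho = 0.6 -> -0.5 ln(1 - 0.36) = 0.2231 nats
  mis <- vapply(1:10, function(s) {
    set.seed(s)
    a <- rnorm(5000); b <- 0.6 * a + rnorm(5000, 0, sqrt(1 - 0.36))
    pairwise_mi(a, b)
  }, 0)
  expect_lt(abs(median(mis) - 0.22314) / 0.22314, 0.05)
  # binned estimator agrees within its coarser tolerance
  set.seed(2)
  a <- rnorm(5000); b <- 0.6 * a + rnorm(5000, 0, sqrt(1 - 0.36))
  expect_lt(abs(pairwise_mi(a, b, estimator = "bins") - 0.22314), 0.08)
})

test_that("independent profiles fall below the permutation-derived cutoff", {
  below <- vapply(1:12, function(s) {
    set.seed(s)
    mi <- pairwise_mi(rnorm(1000), rnorm(1000))
    null95 <- quantile(vapply(1:60, function(i) {
      pairwise_mi(rnorm(1000), rnorm(1000))
    }, 0), 0.95)
    mi < null95
  }, TRUE)
  expect_gte(mean(below), 0.8)
})

test_that("the MI significance cutoff behaves at its boundary cases and
           controls false edges", {
  h <- simulate_hub_network_data(30, 200, 0.1, seed = 5)
  expect_equal(as.numeric(mi_significance_threshold(h$expr, alpha = 1)), 0)
  expect_error(mi_significance_threshold(h$expr, alpha = 0), "alpha")

  # null-only data: false edges bounded by the corrected level
  set.seed(6)
  null_x <- matrix(rnorm(40 * 300), 40, 300,
                   dimnames = list(sprintf("n%02d", 1:40), NULL))
  colnames(null_x) <- paste0("s", 1:300)
  cut <- mi_significance_threshold(null_x, alpha = 0.05, n_null = 4000,
                                   seed = 6)
  mi <- suppressWarnings(macnet:::mi_matrix(null_x))
  n_false <- sum(mi[upper.tri(mi)] >= cut)
  expect_lte(n_false, 3)   # expected 0.05 false edges; allow sampling slack
  expect_true(attr(cut, "extrapolated"))
})

test_that("all-vs-all connects exactly the dependent pairs in hand cases", {
  set.seed(3)
  a <- rnorm(100)
  m <- rbind(x = a, y = a, z = rnorm(100))
  colnames(m) <- paste0("s", 1:100)
  net <- all_vs_all(m, cutoff = 0.5)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$from, net$edges$to), c("x", "y"))
  expect_equal(unname(net$degree), c(1L, 1L, 0L))
  net_inf <- all_vs_all(m, cutoff = Inf)
  expect_equal(nrow(net_inf$edges), 0)
  expect_error(all_vs_all(m[1:2, ], cutoff = 1), ">= 3")
})

test_that("DPI prunes the indirect edge of a Markov chain and matches
           brute-force triplet enumeration on random graphs", {
  # x -> y -> z chain: the x-z edge is weakest and must go
  set.seed(9)
  x <- rnorm(1000); y <- 0.8 * x + rnorm(1000, 0, 0.6)
  z <- 0.8 * y + rnorm(1000, 0, 0.6)
  m <- rbind(x = x, y = y, z = z); colnames(m) <- paste0("s", 1:1000)
  net <- all_vs_all(m, cutoff = 0.01)
  expect_equal(nrow(net$edges), 3)
  pruned <- dpi_prune(net, tolerance = 0)
  expect_equal(nrow(pruned$edges), 2)
  expect_false(any(edge_key(pruned$edges$from, pruned$edges$to) ==
                   edge_key("x", "z")))
  # tolerance -> 1 removes nothing
  expect_equal(nrow(dpi_prune(net, tolerance = 0.999)$edges), 3)
  # pruned output is a subgraph; tolerance-0 pruning is idempotent here
  expect_equal(dpi_prune(pruned, 0)$edges, pruned$edges)

  for (s in 1:10) {
    set.seed(s)
    nodes <- sprintf("n%02d", 1:20)
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.25
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        mi = runif(sum(keep), 0.05, 1),
                        stringsAsFactors = FALSE)
    net_r <- macnet:::new_mi_network(nodes, edges)
    tol <- sample(c(0, 0.1, 0.3), 1)
    ours <- dpi_prune(net_r, tol)$edges
    brute <- dpi_brute(nodes, edges, tol)
    expect_equal(edge_key(ours$from, ours$to),
                 edge_key(brute$from, brute$to))
  }
})

test_that("MI(x,z) < min(MI(x,y), MI(y,z)) on Markov chains (data-processing
           inequality)", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(1000); y <- 0.8 * x + rnorm(1000, 0, 0.6)
    z <- 0.8 * y + rnorm(1000, 0, 0.6)
    pairwise_mi(x, z) < min(pairwise_mi(x, y), pairwise_mi(y, z))
  }, TRUE)
  expect_gte(sum(ok), 19)
})

test_that("hub extraction flags the star center and recovers planted hubs", {
  star <- data.frame(from = "hub", to = paste0("leaf", 1:9), mi = 0.5)
  net <- macnet:::new_mi_network(c("hub", paste0("leaf", 1:9)), star)
  net <- extract_hubs(net, 0.1)
  expect_equal(net$hubs, "hub", ignore_attr = TRUE)
  expect_equal(attr(net$hubs, "hub_interactions"), 9)
  expect_error(extract_hubs(macnet:::new_mi_network("a", star[0, ]), 0.1),
               "empty")

  h <- simulate_hub_network_data(50, 1000, 0.1, seed = 3)
  cut <- mi_significance_threshold(h$expr, alpha = 0.05, n_null = 3000,
                                   seed = 3)
  net2 <- all_vs_all(h$expr, cutoff = as.numeric(cut))
  net2 <- extract_hubs(dpi_prune(net2, 0.1), 0.1)
  expect_gte(mean(net2$hubs %in% h$hubs), 0.8)
  # edge recovery F1
  found <- edge_key(net2$edges$from, net2$edges$to)
  truth <- edge_key(h$edges[, 1], h$edges[, 2])
  prec <- mean(found %in% truth); rec <- mean(truth %in% found)
  expect_gte(2 * prec * rec / (prec + rec), 0.8)
  # degree distribution heavier-tailed than an Erdos-Renyi match
  set.seed(4)
  er_var <- replicate(30, {
    er <- igraph::sample_gnm(length(net2$nodes), nrow(net2$edges))
    var(igraph::degree(er))
  })
  expect_gt(var(as.numeric(net2$degree)), mean(er_var))
})

test_that("TF neighborhoods rank hub TFs by expression and annotate
           first neighbors", {
  h <- simulate_hub_network_data(50, 1000, 0.1, seed = 3)
  cut <- mi_significance_threshold(h$expr, alpha = 0.05, n_null = 3000,
                                   seed = 3)
  net <- extract_hubs(dpi_prune(all_vs_all(h$expr, cutoff = as.numeric(cut)), 0.1),
                      0.2)
  tfs <- h$hubs   # treat the planted hubs as the TF list
  nb <- tf_neighborhoods(net, tfs, h$expr, top_k = 2)
  expect_lte(length(nb), 2)
  for (e in nb) {
    expect_true(e$tf %in% net$hubs)
    direct <- net$edges[net$edges$from == e$tf | net$edges$to == e$tf, ]
    expect_setequal(e$neighbors,
                    setdiff(unique(c(direct$from, direct$to)), e$tf))
  }
  # no TFs among hubs: empty result with note
  nb0 <- tf_neighborhoods(net, "absent_gene", h$expr)
  expect_length(nb0, 0)
  expect_match(attr(nb0, "note"), "no TFs")
  expect_error(tf_neighborhoods(net, character(), h$expr), "non-empty")
})
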