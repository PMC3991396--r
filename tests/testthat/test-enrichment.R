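# GSEA machinery (ranking metric, running sum, permutations, volcano flags)
# and hypergeometric over-representation, against brute-force oracles.

test_that("signal-to-noise ranking matches hand arithmetic and contracts", {
  a <- c(8, 9, 10); b <- c(4, 5, 6)
  m <- rbind(g1 = c(a, b), g2 = c(b, a), g3 = rep(5, 6))
  colnames(m) <- paste0("s", 1:6)
  d <- data.frame(sample_id = colnames(m),
                  condition = rep(c("X", "Y"), each = 3),
                  is_baseline = rep(c(FALSE, TRUE), each = 3))
  rk <- rank_genes(m, d, "X", "Y")
  expect_equal(rk[["g1"]], s2n_brute(a, b), tolerance = 1e-12)
  expect_equal(rk[["g2"]], s2n_brute(b, a), tolerance = 1e-12)
  expect_equal(names(rk), c("g1", "g3", "g2"))   # descending, g3 at 0
  # identical groups: zero scores, lexicographic order
  m0 <- m; m0[, 4:6] <- m0[, 1:3]
  rk0 <- rank_genes(m0, d, "X", "Y")
  expect_true(all(rk0 == 0))
  expect_equal(names(rk0), sort(rownames(m)))
  expect_error(rank_genes(m[, 1:5], d[1:5, ], "X", "Y"), ">= 3")
  # planted up-gene ranks first
  fx <- planted_module_fixture(seed = 3, module_size = 5, n_background = 50)
  rk2 <- rank_genes(fx$x$values, fx$design, "C1", "Mb")
  expect_true(names(rk2)[1] %in% names(fx$truth)[fx$truth == 2])
})

test_that("enrichment score equals the brute-force running sum and obeys
           its symmetries", {
  set.seed(5)
  scores <- sort(rnorm(40), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", order(-seq_len(40)))
  names(scores) <- sprintf("g%02d", 1:40)
  set.seed(6)
  for (i in 1:5) {
    gs <- sample(names(scores), sample(3:15, 1))
    es <- enrichment_score(scores, gs, p = 1)
    expect_equal(es$es, es_brute(scores, names(scores) %in% gs, 1),
                 tolerance = 1e-12)
    es0 <- enrichment_score(scores, gs, p = 0)
    expect_equal(es0$es, es_brute(scores, names(scores) %in% gs, 0),
                 tolerance = 1e-12)
    # complement symmetry at p = 0
    comp <- setdiff(names(scores), gs)
    expect_equal(enrichment_score(scores, comp, p = 0)$es, -es0$es,
                 tolerance = 1e-12)
  }
  # set = top k: running sum peaks at exactly 1 for p = 0
  topk <- names(scores)[1:7]
  expect_equal(enrichment_score(scores, topk, p = 0)$es, 1, tolerance = 1e-12)
  # reversed ranking flips the sign for p = 0
  revd <- rev(scores)
  gs <- names(scores)[seq(2, 40, 3)]
  expect_equal(enrichment_score(revd, gs, p = 0)$es,
               -enrichment_score(scores, gs, p = 0)$es, tolerance = 1e-12)
  expect_error(enrichment_score(scores, names(scores)), "whole")
  expect_error(enrichment_score(scores, c("zz1", "zz2")), "intersection")
})

test_that("enrichment score agrees with fgsea's statistic on shared input", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  scores <- sort(rnorm(60), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:60)
  for (i in 1:3) {
    gs <- sample(names(scores), 10)
    ours <- enrichment_score(scores, gs, p = 1)$es
    theirs <- fgsea::calcGseaStat(scores, which(names(scores) %in% gs),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("3v3 phenotype permutation reduces to exact enumeration", {
  set.seed(2)
  vals <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  vals[1:5, 1:3] <- vals[1:5, 1:3] + 2   # a driven set
  d <- data.frame(sample_id = colnames(vals),
                  condition = rep(c("A", "B"), each = 3),
                  is_baseline = rep(c(FALSE, TRUE), each = 3))
  sets <- list(driven = sprintf("g%02d", 1:5),
               random = sprintf("g%02d", 10:14))
  # below 7 samples the default falls back to gene-set mode with a warning
  expect_warning(
    gsea_permutation(vals, d, "A", "B", sets, n_perm = 50,
                     mode = "phenotype", seed = 1),
    "fewer than 7")
  # forcing phenotype mode enumerates all C(6,3) = 20 label assignments
  res <- gsea_permutation(vals, d, "A", "B", sets, n_perm = 10000,
                          mode = "phenotype", seed = 1,
                          force_phenotype = TRUE)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_perm"), choose(6, 3))
  oracle <- lapply(sets, function(gs)
    gsea_exact_p(vals, 1:3, 4:6, gs, p_weight = 1))
  for (nm in names(sets)) {
    expect_equal(res$es[res$set == nm], oracle[[nm]]$es, tolerance = 1e-12)
    expect_equal(res$p[res$set == nm], oracle[[nm]]$p, tolerance = 1e-12)
  }
})

test_that("planted module is the top-NES set in its own contrast", {
  fx <- planted_module_fixture(seed = 41, n_background = 100)
  sets <- setNames(lapply(fx$mods, `[[`, "genes"), paste0("mod", 1:6))
  for (target in c("C1", "C4")) {
    res <- gsea_permutation(fx$x, fx$design, group_a = target,
                            group_b = "Mb", gene_sets = sets,
                            n_perm = 300, seed = 7)
    res <- volcano_table(res)
    want <- paste0("mod", match(target, paste0("C", 1:5)) + 1)
    expect_equal(res$set[which.max(res$nes)], want)
    expect_true(res$enriched[res$set == want])
  }
})

test_that("volcano flags follow the NES and p thresholds", {
  res <- data.frame(set = c("a", "b", "c"), nes = c(1.5, -1.5, 0.5),
                    p = c(0.01, 0.01, 0.001))
  v <- volcano_table(res, nes_min = 1, p_max = 0.05)
  expect_equal(v$enriched, c(TRUE, FALSE, FALSE))
  expect_equal(v$depleted, c(FALSE, TRUE, FALSE))
})

test_that("hypergeometric ORA matches exact subset enumeration and its
           error contracts", {
  universe <- sprintf("u%02d", 1:12)
  annotation <- list(t1 = universe[1:4], t2 = universe[5:12],
                     outside = c("zz1", "zz2"))
  query <- universe[1:4]
  res <- ora_hypergeometric(query, universe, annotation)
  expect_equal(attr(res, "skipped"), "outside")
  # enumeration over all C(12,4) query draws
  p_exact <- hyper_enum(12, 4, 4, 4)
  expect_equal(res$p[res$term == "t1"], p_exact, tolerance = 1e-12)
  expect_equal(p_exact, 1 / choose(12, 4), tolerance = 1e-12)
  p_t2 <- hyper_enum(12, 8, 4, length(intersect(query, annotation$t2)))
  expect_equal(res$p[res$term == "t2"],
               ifelse(p_t2 == 0, res$p[res$term == "t2"], p_t2),
               tolerance = 1e-12)
  expect_equal(res$q, bh_brute(res$p), tolerance = 1e-12)
  expect_error(ora_hypergeometric(character(), universe, annotation), "empty")
  expect_error(ora_hypergeometric("nope", universe, annotation), "subset")
})

test_that("ORA p-values are uniform on average for random queries", {
  set.seed(4)
  universe <- sprintf("u%03d", 1:60)
  annotation <- list(t = universe[1:15])
  ps <- replicate(400, {
    q <- sample(universe, 10)
    ora_hypergeometric(q, universe, annotation)$p
  })
  # upper-tail hypergeometric p on a null query is super-uniform:
  # P(p <= a) <= a; the mean must sit near or above 0.5
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps < 0.05), 0.07)
})
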