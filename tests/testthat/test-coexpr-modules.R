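# Soft threshold, topological overlap, module detection, eigengenes, and
# module-trait correlation.

test_that("power-1 adjacency equals |r| and the chosen power separates
           planted modules", {
  fx <- planted_module_fixture(seed = 2, module_size = 10)
  a1 <- adjacency_matrix(fx$x, power = 1)
  r <- abs(cor(t(fx$x$values)))
  diag(r) <- 0
  expect_equal(a1, r, tolerance = 1e-12)

  pw <- suppressWarnings(pick_soft_threshold(fx$x))
  a <- adjacency_matrix(fx$x, pw)
  same <- outer(fx$truth, fx$truth, "==")
  diag(same) <- NA
  within <- mean(a[which(same)])
  between <- mean(a[which(!same)])
  expect_gte(within, 10 * between)

  expect_equal(as.numeric(pick_soft_threshold(fx$x, powers = c(3, 5, 9),
                                              target_r2 = 0)), 3)
  expect_error(pick_soft_threshold(fx$x$values[1:5, ]), "10 genes")
})

test_that("topological overlap matches hand and brute-force oracles", {
  a2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(topological_overlap(a2)[1, 2], 1)

  z <- matrix(0, 4, 4)
  expect_equal(max(abs(topological_overlap(z) - diag(4))), 0)

  set.seed(7)
  a <- matrix(runif(36), 6); a <- (a + t(a)) / 2; diag(a) <- 0
  expect_equal(unname(topological_overlap(a)), tom_brute(a),
               tolerance = 1e-12)
  tom <- topological_overlap(a)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_true(isSymmetric(tom))
  bad <- a; bad[1, 2] <- bad[2, 1] <- 1.4
  expect_error(topological_overlap(bad), "\\[0, 1\\]")
})

test_that("planted modules are recovered with their driver conditions", {
  fx <- planted_module_fixture(seed = 3)   # effect/noise = 4
  pw <- suppressWarnings(pick_soft_threshold(fx$x))
  tom <- topological_overlap(adjacency_matrix(fx$x, pw))
  dm <- detect_modules(tom, fx$x, min_size = 20)
  expect_equal(length(dm$modules), 6)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(fx$truth, dm$membership[names(fx$truth)])
  expect_gte(ari, 0.9)
  mt <- module_trait_correlation(dm$modules, fx$design)
  # every detected module's max-|r| trait is the planted driver condition
  for (m in dm$modules) {
    planted_id <- as.integer(names(which.max(table(fx$truth[m$genes]))))
    expect_equal(unname(mt$driver[paste0("module", m$id)]),
                 fx$drivers[planted_id])
  }
})

test_that("pure-noise data yields no sizable modules", {
  for (s in 1:3) {
    d <- make_design(4, 5, condition_names = paste0("C", 1:3), seed = s)
    st <- planted_structure(noise_sd = 1, gene_mean_sd = 0)
    x <- simulate_expression(d, st, n_background_genes = 150, seed = s)
    tom <- topological_overlap(adjacency_matrix(x, 6))
    dm <- suppressWarnings(detect_modules(tom, x, min_size = 30))
    expect_length(dm$modules, 0)
  }
})

test_that("module detection is invariant under gene reordering up to
           relabeling", {
  fx <- planted_module_fixture(seed = 17, module_size = 25)
  tom <- topological_overlap(adjacency_matrix(fx$x, 6))
  dm1 <- detect_modules(tom, fx$x, min_size = 15)
  set.seed(1)
  perm <- sample(nrow(fx$x$values))
  xp <- fx$x$values[perm, ]
  tomp <- topological_overlap(adjacency_matrix(xp, 6))
  dm2 <- detect_modules(tomp, xp, min_size = 15)
  skip_if_not_installed("mclust")
  common <- names(dm1$membership)
  expect_equal(mclust::adjustedRandIndex(dm1$membership[common],
                                         dm2$membership[common]), 1)
})

test_that("module eigengene equals the SVD first component with the
           documented sign convention", {
  fx <- planted_module_fixture(seed = 4, module_size = 10)
  g <- names(fx$truth)[fx$truth == 2]
  me <- module_eigengene(fx$x, g)
  # independent check: first right singular vector of the standardized block
  z <- t(scale(t(fx$x$values[g, ])))
  sv <- svd(z)$v[, 1]
  expect_equal(abs(me$eigengene), abs(sv)[seq_along(sv)], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gt(cor(me$eigengene, colMeans(z)), 0)   # sign convention
  expect_equal(sum(me$eigengene^2), 1)

  # identical genes: eigengene proportional to the shared profile, VE = 1
  m <- rbind(a = c(1, 3, 2, 5), b = c(1, 3, 2, 5) + 1)
  colnames(m) <- paste0("s", 1:4)
  me2 <- module_eigengene(m, c("a", "b"))
  expect_equal(me2$var_explained, 1)
  expect_gt(cor(me2$eigengene, m["a", ]), 0.999)

  # anti-correlated pair: VE 1, flat mean, sign tie broken to first gene
  m3 <- rbind(u = c(1, 2, 3), v = c(3, 2, 1))
  colnames(m3) <- paste0("s", 1:3)
  me3 <- module_eigengene(m3, c("u", "v"))
  expect_equal(me3$var_explained, 1)
  expect_true(me3$sign_indeterminate)
  expect_gt(cor(me3$eigengene, m3["u", ]), 0.999)

  expect_error(module_eigengene(m, "a"), ">= 2")
  m4 <- rbind(a = c(1, 1, 1), b = c(2, 2, 2)); colnames(m4) <- paste0("s", 1:3)
  expect_error(module_eigengene(m4, c("a", "b")), "rank")
})

test_that("module-trait correlation matches the point-biserial oracle and a
           permutation null", {
  fx <- planted_module_fixture(seed = 19)
  tom <- topological_overlap(adjacency_matrix(fx$x, 6))
  dm <- detect_modules(tom, fx$x, min_size = 20)
  mt <- module_trait_correlation(dm$modules, fx$design)
  # point-biserial expectation for a driver condition: the eigengene tracks
  # the indicator up to noise; with effect/noise=4 the correlation is high
  for (m in dm$modules) {
    drv <- mt$driver[paste0("module", m$id)]
    expect_gt(abs(mt$r[paste0("module", m$id), drv]), 0.8)
    others <- setdiff(colnames(mt$r), drv)
    expect_lt(max(abs(mt$r[paste0("module", m$id), others])), 0.5)
  }
  # permuting sample labels destroys the association
  set.seed(8)
  null_max <- replicate(50, {
    d2 <- fx$design
    d2$condition <- d2$condition[sample(nrow(d2))]
    max(abs(module_trait_correlation(dm$modules, d2)$r))
  })
  expect_gt(max(abs(mt$r)), max(null_max))

  # constant eigengene: r = 0, p = 1 by convention
  fake <- list(structure(list(id = 1L, genes = c("a", "b"),
                              eigengene = rep(1 / sqrt(60), 60),
                              var_explained = 1, kme = NULL),
                         class = "gene_module"))
  mt0 <- module_trait_correlation(fake, fx$design)
  expect_equal(max(abs(mt0$r)), 0)
  expect_equal(min(mt0$p), 1)
})

test_that("TF subnetworks recover co-driven pairs and honor error contracts", {
  fx <- planted_module_fixture(seed = 23, module_size = 20)
  tom <- topological_overlap(adjacency_matrix(fx$x, 6))
  dm <- detect_modules(tom, fx$x, min_size = 10)
  # treat two genes of one planted module as TFs: they are co-driven
  g2 <- names(fx$truth)[fx$truth == 2][1:2]
  own <- unique(dm$membership[g2])
  own <- own[own > 0]
  net <- tf_subnetwork_correlations(fx$x, dm$membership, own,
                                    tf_list = g2, r_min = 0.5)
  expect_equal(nrow(net), 1)
  expect_setequal(c(net$from, net$to), g2)
  # r_min = 1 keeps only exactly duplicated profiles
  dup <- rbind(fx$x$values, dupg = fx$x$values[g2[1], ])
  memb <- c(dm$membership, dupg = unname(dm$membership[g2[1]]))
  net1 <- tf_subnetwork_correlations(dup, memb, own,
                                     tf_list = c(g2, "dupg"), r_min = 0.99999)
  expect_true(all(abs(net1$r) > 0.99999))
  expect_error(tf_subnetwork_correlations(fx$x, dm$membership, own,
                                          tf_list = c("nope1", "nope2")),
               "nope1")
})
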