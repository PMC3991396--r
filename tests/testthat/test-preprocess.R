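# Normalization, detection filtering, variance ranking and the two
# differential screens, each against a hand or brute-force oracle.

test_that("quantile normalization maps columns onto the mean-of-sorted
           reference and is idempotent", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  set.seed(1)
  m2 <- matrix(rnorm(200), 40, 5,
               dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  m2[3, 2] <- m2[7, 2]  # a tie
  qn2 <- quantile_normalize(m2)
  sorted <- apply(qn2, 2, sort)
  expect_equal(max(sorted - sorted[, 1]), 0)            # identical sorted cols
  expect_equal(quantile_normalize(qn2), qn2)            # idempotent
  expect_equal(quantile_normalize(cbind(a = m[, 1], b = m[, 1])),
               cbind(a = m[, 1], b = m[, 1]))           # identity case

  m2[5, 1] <- NA
  expect_error(quantile_normalize(m2), "missing")
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(4)
  m <- matrix(rnorm(300), 60, 5,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:5)))
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("detection filter finds planted module genes and is monotone in
           the margin", {
  # controlled baseline level: detection should be driven by the planted
  # effect, not by each gene's intensity offset
  fx <- planted_module_fixture(seed = 8, effect = 3, n_background = 200,
                               gene_mean_sd = 0)
  det <- detection_filter(fx$x, background_quantile = 0.25, min_margin = 1)
  for (i in 2:6) {   # modules driven by non-baseline conditions
    g <- names(fx$truth)[fx$truth == i]
    expect_true(all(det$detected[g, fx$drivers[i]]),
                info = paste("module", i))
  }
  det_strict <- detection_filter(fx$x, min_margin = 3)
  expect_true(all(det_strict$expressed_genes %in% det$expressed_genes))

  # everything at the background level: nothing expressed above it
  flat <- matrix(5, 10, 6, dimnames = list(paste0("g", 1:10), fx$design$sample_id[1:6]))
  d6 <- fx$design[1:6, ]
  expect_length(detection_filter(flat, d6, 0.5, 1)$expressed_genes, 0)
})

test_that("top_variable_genes ranks by variance with lexicographic ties", {
  m <- matrix(3, 8, 4, dimnames = list(sprintf("g%02d", 8:1), paste0("s", 1:4)))
  expect_equal(top_variable_genes(m, 5),
               sort(rownames(m))[1:5])   # all-tied: lexicographic contract
  fx <- planted_module_fixture(seed = 6, module_size = 10, n_background = 500)
  top <- top_variable_genes(fx$x, 80)
  expect_true(all(names(fx$truth)[fx$truth %in% 2:6] %in% top))
  expect_error(top_variable_genes(m, 0), "positive")
  expect_error(top_variable_genes(m, 99), "exceeds")
})

test_that("differential expression detects a strong planted marker and is
           null on identical groups", {
  d <- make_design(2, 20, condition_names = "A")
  st <- planted_structure(
    markers = list(list(gene = "mk", condition = "A", effect = 3)),
    noise_sd = 0.5, gene_mean_sd = 0)
  x <- simulate_expression(d, st, n_background_genes = 100, seed = 13)
  de <- differential_expression(x, group_a = "A", group_b = "Mb")
  expect_true(de$pass[de$gene == "mk"])
  # power for effect 3, n=20, sd 0.5 is essentially 1; check across seeds
  for (s in 1:4) {
    xs <- simulate_expression(d, st, n_background_genes = 20, seed = s)
    des <- differential_expression(xs, group_a = "A", group_b = "Mb")
    expect_true(des$pass[des$gene == "mk"], info = paste("seed", s))
  }
  # identical groups: FC exactly 1, nothing passes
  same <- x$values
  same[, d$condition == "A"] <- same[, d$condition == "Mb"]
  de0 <- differential_expression(same, d, "A", "Mb")
  expect_true(all(de0$log2fc == 0))
  expect_false(any(de0$pass))
  expect_error(differential_expression(x$values[, 1:21], d[1:21, ], "A", "Mb"),
               ">= 2 samples")
})

test_that("BH q-values equal the brute-force definition", {
  for (s in 1:3) {
    set.seed(s)
    p <- runif(97)^2
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
  # and the DE table uses exactly that correction
  d <- make_design(2, 5, condition_names = "A")
  st <- planted_structure(noise_sd = 0.5)
  x <- simulate_expression(d, st, n_background_genes = 60, seed = 2)
  de <- differential_expression(x, group_a = "A", group_b = "Mb")
  expect_equal(de$q, bh_brute(de$p), tolerance = 1e-12)
})

test_that("anova screen is calibrated on noise, finds planted modules, and
           flags constant genes", {
  d <- make_design(3, 5, condition_names = c("A", "B"))
  st <- planted_structure(noise_sd = 1, gene_mean_sd = 0)
  x <- simulate_expression(d, st, n_background_genes = 2000, seed = 21)
  av <- anova_screen(x)
  rate <- mean(av$p < 0.05)
  ci <- binom.test(sum(av$p < 0.05), nrow(av), 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2],
              info = sprintf("raw p<0.05 rate %.4f", rate))

  fx <- planted_module_fixture(seed = 9)
  av2 <- anova_screen(fx$x)
  expect_true(all(av2$pass[av2$gene %in% names(fx$truth)]))

  m <- fx$x$values[1:10, ]
  m[1, ] <- 7   # constant gene
  av3 <- anova_screen(m, fx$design)
  expect_true(av3$degenerate[av3$gene == rownames(m)[1]])
  expect_equal(av3$p[av3$gene == rownames(m)[1]], 1)
  expect_error(anova_screen(m, fx$design[fx$design$is_baseline, ]), "conditions")
})

test_that("screen pass sets are invariant under gene-order permutation", {
  fx <- planted_module_fixture(seed = 14, module_size = 10, n_background = 30)
  set.seed(1)
  perm <- sample(nrow(fx$x$values))
  de1 <- differential_expression(fx$x$values, fx$design, "C1", "Mb")
  de2 <- differential_expression(fx$x$values[perm, ], fx$design, "C1", "Mb")
  expect_setequal(de1$gene[de1$pass], de2$gene[de2$pass])
})
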