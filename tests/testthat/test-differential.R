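test_that("size factors recover exact library scaling", {
  m <- matrix(c(10L, 20L, 5L, 40L, 80L, 20L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  sf <- size_factors(m)
  expect_equal(unname(sf["b"] / sf["a"]), 4)
  expect_equal(exp(mean(log(sf))), 1)

  ident <- cbind(a = c(3L, 9L), b = c(3L, 9L))
  expect_equal(unname(size_factors(ident)), c(1, 1))
  expect_error(size_factors(matrix(0L, 2, 2)), "all-zero")
})

test_that("size factors equal hand-computed median-of-ratios", {
  m <- matrix(c(10L, 100L, 30L, 50L, 8L,
                20L, 220L, 70L, 90L, 14L,
                12L, 130L, 28L, 60L, 9L), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), c("s1", "s2", "s3")))
  gm <- exp(rowMeans(log(m)))
  raw <- apply(m / gm, 2, median)
  want <- raw / exp(mean(log(raw)))
  expect_equal(size_factors(m), want)
})

test_that("NB Wald test matches a GLM fit on single features", {
  skip_if_not_installed("MASS")
  cfg <- sim_config(seed = 31, n_genes = 40, effect_size_lfc = 1.5)
  sim <- simulate_counts(cfg)
  res <- nb_wald_test(sim$gene_counts, sim$design, c("constant", "control"))
  keep <- sim$design$condition %in% c("constant", "control")
  des <- sim$design[keep, ]
  sf_all <- size_factors(sim$gene_counts[, sim$design$sample_id])
  for (i in c(2, 7, 19)) {
    y <- sim$gene_counts[i, des$sample_id]
    grp <- factor(des$condition, levels = c("control", "constant"))
    disp <- epireversion:::mom_dispersion(
      sweep(sim$gene_counts[, sim$design$sample_id], 2, sf_all, "/")[i, , drop = FALSE],
      split(seq_len(nrow(sim$design)), sim$design$condition))
    fit <- suppressWarnings(stats::glm(
      y ~ grp + offset(log(sf_all[des$sample_id])),
      family = MASS::negative.binomial(theta = 1 / disp)))
    expect_equal(res$log2FoldChange[i], unname(coef(fit)[2]) / log(2),
                 tolerance = 1e-4)
  }
})

test_that("contrast direction and sample order behave as expected", {
  cfg <- sim_config(seed = 37, n_genes = 120)
  sim <- simulate_counts(cfg)
  fwd <- nb_wald_test(sim$gene_counts, sim$design, c("constant", "control"))
  bwd <- nb_wald_test(sim$gene_counts, sim$design, c("control", "constant"))
  expect_equal(fwd$log2FoldChange, -bwd$log2FoldChange, tolerance = 1e-8)
  expect_equal(fwd$pvalue, bwd$pvalue, tolerance = 1e-10)

  perm <- sample(nrow(sim$design))
  shuf <- nb_wald_test(sim$gene_counts[, sim$design$sample_id[perm]],
                       sim$design[perm, ], c("constant", "control"))
  expect_equal(fwd$log2FoldChange, shuf$log2FoldChange, tolerance = 1e-10)
  expect_equal(fwd$pvalue, shuf$pvalue, tolerance = 1e-10)
})

test_that("identical groups give zero fold change; BH guarantees hold", {
  m <- cbind(a1 = c(10L, 50L, 7L), a2 = c(12L, 48L, 9L),
             b1 = c(10L, 50L, 7L), b2 = c(12L, 48L, 9L))
  rownames(m) <- c("g1", "g2", "g3")
  des <- data.frame(sample_id = colnames(m),
                    condition = c("x", "x", "y", "y"),
                    rnai_target = "ph", replicate = c("r1", "r2", "r1", "r2"),
                    matched_control = c("", "", "x", "x"))
  res <- nb_wald_test(m, des, c("y", "x"))
  expect_equal(res$log2FoldChange, rep(0, 3), tolerance = 1e-10)
  ok <- !is.na(res$padj)
  expect_true(all(res$padj[ok] >= res$pvalue[ok] - 1e-12))

  des2 <- des; des2$condition <- c("x", "y", "x", "y")
  expect_error(nb_wald_test(m[, 1:2], des[1:2, ], c("y", "x")), ">= 2 replicates")
})

test_that("independent filtering leaves low-expression padj missing", {
  cfg <- sim_config(seed = 41, n_genes = 200, base_mean_log_range = c(-1, 2))
  sim <- simulate_counts(cfg)
  res <- nb_wald_test(sim$gene_counts, sim$design, c("constant", "control"),
                      base_mean_floor = 1)
  low <- res$baseMean < 1
  expect_true(any(low))
  expect_true(all(is.na(res$padj[low])))
})

test_that("FPKM follows its definition", {
  m <- matrix(c(10L, 0L), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  fpkm <- compute_fpkm(m, c(g1 = 1000, g2 = 500), lib_sizes = 1e6)
  expect_equal(fpkm["g1", 1], 10)
  expect_equal(fpkm["g2", 1], 0)
  half <- compute_fpkm(m, c(g1 = 1000, g2 = 500), lib_sizes = 2e6)
  expect_equal(half["g1", 1], 5)
  expect_error(compute_fpkm(m, c(g1 = 1000)), "every feature")
  expect_error(compute_fpkm(m, c(g1 = 1000, g2 = -5)), "positive")
})
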