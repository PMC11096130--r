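test_that("toroidal hexagonal unit distances wrap correctly", {
  d <- som_unit_distances(3, 2, toroidal = TRUE)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d[1, 3], 1)  # units 1 and nx on a toroidal row wrap to 1

  flat <- som_unit_distances(3, 1, toroidal = FALSE)
  expect_equal(flat[1, 3], 2)
  wrap <- som_unit_distances(3, 1, toroidal = TRUE)
  expect_equal(wrap[1, 3], 1)
})

test_that("epochs = 0 assigns to the nearest initial codebook", {
  set.seed(7)
  x <- matrix(rnorm(60), ncol = 2)
  m <- train_supersom(list(x), grid = c(2, 1), seed = 5, epochs = 0, restarts = 1)
  d1 <- rowSums((x - matrix(m$codebooks[[1]][1, ], 30, 2, byrow = TRUE))^2)
  d2 <- rowSums((x - matrix(m$codebooks[[1]][2, ], 30, 2, byrow = TRUE))^2)
  expect_equal(m$assignment, ifelse(d1 <= d2, 1L, 2L))
})

test_that("well-separated blobs land on distinct units with full purity", {
  set.seed(11)
  x <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
             matrix(rnorm(100, 5, 0.1), ncol = 2))
  m <- train_supersom(list(x), grid = c(1, 2), seed = 3)
  a <- m$assignment
  expect_equal(length(unique(a[1:50])), 1)
  expect_equal(length(unique(a[51:100])), 1)
  expect_true(a[1] != a[51])
})

test_that("batch update is invariant to duplicating every row", {
  set.seed(13)
  # separated blobs: the converged codebooks are the blob means, which the
  # batch mean update leaves unchanged under row duplication
  x <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
             matrix(rnorm(40, 4, 0.2), ncol = 2))
  m1 <- train_supersom(list(x), grid = c(2, 1), seed = 9, restarts = 1)
  m2 <- train_supersom(list(rbind(x, x)), grid = c(2, 1), seed = 9, restarts = 1)
  cb1 <- m1$codebooks[[1]][order(m1$codebooks[[1]][, 1]), ]
  cb2 <- m2$codebooks[[1]][order(m2$codebooks[[1]][, 1]), ]
  expect_equal(cb1, cb2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("training never increases quantization error over the init", {
  for (sd in 1:20) {
    set.seed(sd)
    x <- matrix(rnorm(300) + rep(c(0, 3, 6), each = 50), ncol = 2)
    m0 <- train_supersom(list(x), grid = c(3, 1), seed = sd, epochs = 0, restarts = 1)
    m1 <- train_supersom(list(x), grid = c(3, 1), seed = sd, epochs = 100, restarts = 1)
    expect_lte(m1$quantization_error, m0$quantization_error + 1e-12)
  }
})

test_that("assignment is invariant to feature row order", {
  set.seed(17)
  x <- matrix(rnorm(120) + rep(c(0, 4), each = 30), ncol = 2)
  m <- train_supersom(list(x), grid = c(1, 2), seed = 21)
  perm <- sample(nrow(x))
  mp <- train_supersom(list(x[perm, ]), grid = c(1, 2), seed = 21)
  # units may be relabeled; compare the induced partitions
  expect_equal(outer(m$assignment[perm], m$assignment[perm], "=="),
               outer(mp$assignment, mp$assignment, "=="))
})

test_that("missing values and undersized grids are rejected", {
  x <- matrix(c(1, NA, 3, 4), 2)
  expect_error(train_supersom(list(x), c(2, 1)), "missing values")
  expect_error(train_supersom(list(matrix(1:4, 2)), c(1, 1)), "at least 2 units")
  expect_error(train_supersom(list(matrix(1:2, 1)), c(2, 1)), "at least 2 rows")
})

test_that("differential gene selection applies all three rule parts", {
  ids <- c("g1", "g2", "g3", "g4")
  base <- fake_contrast(ids)
  cst <- base; cst$padj <- c(0.04, 0.04, 0.5, 0.01); cst$log2FoldChange <- c(1.2, 0.8, 2, 1.5)
  d9 <- base; d11 <- base
  ctrl <- base; ctrl$padj <- c(0.9, 0.9, 0.9, 0.001); ctrl$log2FoldChange <- c(0, 0, 0, 2)
  sel <- select_de_genes(list(constant = cst, transient_d9 = d9,
                              transient_d11 = d11), ctrl)
  # g1 kept; g2 fails |LFC|>1; g3 fails padj; g4 excluded via control contrast
  expect_equal(sel$gene_ids, "g1")
  expect_equal(colnames(sel$lfc), c("constant", "transient_d9", "transient_d11"))

  bad <- ctrl; bad$feature_id <- rev(bad$feature_id)
  expect_error(select_de_genes(list(constant = cst, transient_d9 = d9,
                                    transient_d11 = d11), bad), "mismatched")
})

test_that("percentile clipping is per-column with 10% total clipped mass", {
  set.seed(23)
  m <- cbind(a = runif(100), b = rep(2, 100))
  cl <- clip_percentiles(m)
  q <- quantile(m[, "a"], c(0.05, 0.95), names = FALSE)
  expect_true(all(cl[, "a"] >= q[1] & cl[, "a"] <= q[2]))
  expect_equal(sum(cl[, "a"] != m[, "a"]), 10)  # 5 low + 5 high
  expect_equal(cl[, "b"], m[, "b"])             # constant column unchanged
  expect_error(clip_percentiles(m[0, , drop = FALSE]), "empty")
})

test_that("unit labeling follows the sign patterns and orders down clusters", {
  mk <- function(cm, tm) {
    structure(list(codebooks = list(matrix(cm, ncol = 1),
                                    cbind(tm, tm)),
                   grid = c(3, 2)), class = "som_model")
  }
  lab <- label_gene_clusters(mk(c(2, 2, 0.1, -2, -2, 0), c(1.8, 0.1, 2, -1.9, 0.2, -1.5)))
  expect_equal(lab$cluster,
               c("irreversible", "reversible", "transient_specific",
                 "down1", "down2", "down3"))
  # down1 has the lowest constant mean among the negatives
  expect_true(lab$constant_mean[lab$cluster == "down1"] <=
                min(lab$constant_mean[startsWith(lab$cluster, "down")]))
  expect_warning(label_gene_clusters(mk(c(2, -2, 0, 0, 0, 2), c(1.8, -2, 2, -2, 0, -1.8))),
                 "no labeling rule")
})

test_that("ATAC selection enforces the baseMean floor and sign labels", {
  ids <- sprintf("p%02d", 1:40)
  set.seed(31)
  cst <- fake_contrast(ids, base_mean = 100)
  trn <- fake_contrast(ids, base_mean = 100)
  grp <- rep(c("irr", "rev", "dec", "none"), each = 10)
  cst$log2FoldChange <- c(rnorm(10, 2, 0.1), rnorm(10, 2, 0.1), rnorm(10, -2, 0.1), rnorm(10, 0, 0.05))
  trn$log2FoldChange <- c(rnorm(10, 1.8, 0.1), rnorm(10, 0, 0.1), rnorm(10, -1.8, 0.1), rnorm(10, 0, 0.05))
  cst$padj <- ifelse(grp %in% c("irr", "rev", "dec"), 1e-5, 0.5)
  trn$padj <- ifelse(grp %in% c("irr", "dec"), 1e-5, 0.5)
  cst$baseMean[1] <- 10  # log10 = 1 < 1.25 -> excluded
  out <- select_and_cluster_atac(list(constant = cst, transient = trn), seed = 1)
  expect_false("p01" %in% out$classification$peak)
  got <- out$classification$cluster[match(ids[2:30], out$classification$peak)]
  expect_equal(unname(got), rep(c("irreversible", "reversible", "decreased"),
                                c(9, 10, 10)))
  expect_false(any(ids[31:40] %in% out$classification$peak))
})
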