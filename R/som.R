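#' Hexagonal grid unit coordinates and distances
#'
#' Units are numbered row-major on an `nx` x `ny` hexagonal grid with
#' odd rows offset by half a unit. With `toroidal = TRUE` the grid wraps:
#' the distance between two units is the minimum over the nine x/y
#' translations of the grid, so opposite edges are neighbours
#' (e.g. units 1 and `nx` on a toroidal row are at distance 1).
#'
#' @param nx,ny grid dimensions.
#' @param toroidal wrap the grid edges.
#' @return `som_unit_distances`: symmetric matrix of inter-unit distances.
#' @export
som_unit_distances <- function(nx, ny, toroidal = TRUE) {
  co <- som_unit_coords(nx, ny)
  xspan <- nx
  yspan <- ny * sqrt(3) / 2
  d <- as.matrix(stats::dist(co))
  if (toroidal) {
    for (dx in c(-xspan, 0, xspan)) for (dy in c(-yspan, 0, yspan)) {
      if (dx == 0 && dy == 0) next
      sh <- sweep(co, 2, c(dx, dy), "+")
      dd <- sqrt(outer(co[, 1], sh[, 1], "-")^2 + outer(co[, 2], sh[, 2], "-")^2)
      d <- pmin(d, dd)
    }
  }
  dimnames(d) <- NULL
  d
}

som_unit_coords <- function(nx, ny) {
  row <- rep(seq_len(ny) - 1L, each = nx)
  col <- rep(seq_len(nx) - 1L, times = ny)
  cbind(x = col + 0.5 * (row %% 2), y = row * sqrt(3) / 2)
}

#' Train a multi-layer (super) self-organizing map
#'
#' Batch-trained SOM over several data layers sharing rows. Each layer is
#' scaled by the square root of its total variance (sum of column
#' variances) so that equal `layer_weights` give the layers comparable
#' influence; the distance between a feature and a unit is the weighted
#' sum of per-layer squared Euclidean distances. Codebooks are initialized
#' from a seeded random sample of data rows drawn with a
#' k-means++-style spread (each subsequent row sampled with probability
#' proportional to its squared distance from the rows already chosen),
#' which keeps well-separated clusters from sharing an initial unit. Each
#' epoch assigns every feature to its best-matching unit (ties broken by
#' the lowest unit index) and replaces codebooks by
#' neighbourhood-weighted means, with a bubble neighbourhood (all units
#' within the radius weigh 1) whose radius decays linearly to 0 over
#' `epochs`. The default starting radius is 2/3 of the maximum grid
#' distance but never reaches the nearest neighbouring unit: on the
#' small (six- and three-unit) toroidal grids this pipeline trains, a
#' radius touching the neighbours smooths all codebooks toward the
#' global mean within a few epochs and the map can no longer separate
#' well-separated clusters. With the capped default, batch training on
#' such grids is exact k-means and the grid fixes only the number of
#' units — which is how the clustering is used here; pass `radius0`
#' explicitly for genuinely topographic maps. Training is
#' restarted `restarts` times from consecutive derived seeds and the
#' model with the lowest quantization error is kept, which protects
#' against the occasional local optimum that strands a unit on an
#' outlying row. With `epochs = 0` the model is the initial codebook
#' plus its nearest-unit assignment (lowest-error restart).
#'
#' @param layers list of numeric matrices with identical row counts.
#' @param grid `c(nx, ny)`; the grid must have at least 2 units.
#' @param toroidal wrap the hexagonal grid (default TRUE).
#' @param seed integer seed for initialization.
#' @param epochs training epochs (default 100).
#' @param layer_weights per-layer weights (default equal).
#' @param restarts independent trainings from derived seeds; the lowest
#'   quantization error wins (default 10).
#' @param radius0 starting neighbourhood radius; `NULL` (default) uses
#'   2/3 of the maximum grid distance, capped just below the smallest
#'   positive inter-unit distance.
#' @return object of class `som_model`: codebooks per layer (on the
#'   original data scale), `assignment` (unit per row),
#'   `quantization_error`, grid metadata and scaling constants.
#' @export
train_supersom <- function(layers, grid, toroidal = TRUE, seed = 1L,
                           epochs = 100L, layer_weights = NULL,
                           restarts = 10L, radius0 = NULL) {
  if (!is.list(layers) || !length(layers)) stop("layers must be a non-empty list", call. = FALSE)
  layers <- lapply(layers, as.matrix)
  n <- unique(vapply(layers, nrow, 0L))
  if (length(n) != 1) stop("all layers must have the same row count", call. = FALSE)
  if (any(vapply(layers, anyNA, TRUE)))
    stop("rows with missing values are not allowed", call. = FALSE)
  nx <- grid[1]; ny <- grid[2]; U <- nx * ny
  if (U < 2) stop("grid must have at least 2 units", call. = FALSE)
  if (n < U) stop(sprintf("need at least %d rows for a %dx%d grid", U, nx, ny), call. = FALSE)
  L <- length(layers)
  if (is.null(layer_weights)) layer_weights <- rep(1, L)
  layer_weights <- layer_weights / sum(layer_weights)

  totvar <- vapply(layers, function(m) {
    v <- sum(apply(m, 2, stats::var))
    if (!is.finite(v) || v == 0) 1 else v
  }, 0)
  # fold scaling and weights into per-column multipliers of one matrix
  colmul <- unlist(lapply(seq_len(L), function(l)
    rep(sqrt(layer_weights[l] / totvar[l]), ncol(layers[[l]]))))
  X <- do.call(cbind, layers)
  Xs <- sweep(X, 2, colmul, "*")

  gridd <- som_unit_distances(nx, ny, toroidal)
  r0 <- if (is.null(radius0))
    min((2 / 3) * max(gridd), 0.99 * min(gridd[gridd > 0])) else radius0
  epochs <- as.integer(epochs)
  best <- NULL
  for (rs in seq_len(max(1L, restarts))) {
    set.seed(seed + rs - 1L)
    C <- Xs[kmeanspp_rows(Xs, U), , drop = FALSE]
    for (e in seq_len(epochs)) {
      bmu <- nearest_unit(Xs, C)
      r <- r0 * (epochs - e) / epochs
      H <- (gridd <= r) * 1              # bubble neighbourhood (diag always 1)
      W <- H[bmu, , drop = FALSE]        # n x U neighbourhood weights
      denom <- colSums(W)
      num <- crossprod(W, Xs)            # U x D
      upd <- denom > 0
      C[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
    }
    bmu <- nearest_unit(Xs, C)
    qe <- mean(rowSums((Xs - C[bmu, , drop = FALSE])^2))
    if (is.null(best) || qe < best$qe) best <- list(C = C, bmu = bmu, qe = qe)
  }
  C <- best$C; bmu <- best$bmu; qe <- best$qe

  # codebooks back on the original data scale, split per layer
  Corig <- sweep(C, 2, colmul, "/")
  splits <- rep(seq_len(L), vapply(layers, ncol, 0L))
  codebooks <- lapply(seq_len(L), function(l) {
    cb <- Corig[, splits == l, drop = FALSE]
    colnames(cb) <- colnames(layers[[l]])
    cb
  })
  structure(list(grid = c(nx = nx, ny = ny), toroidal = toroidal,
                 topology = "hexagonal", codebooks = codebooks,
                 layer_weights = layer_weights, layer_totvar = totvar,
                 assignment = bmu, quantization_error = qe,
                 unit_distances = gridd, seed = seed, epochs = epochs),
            class = "som_model")
}

# k-means++-style seeded draw of k spread-out data rows
kmeanspp_rows <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    idx[j] <- if (all(d2 == 0)) sample.int(n, 1) else sample.int(n, 1, prob = d2)
    d2 <- pmin(d2, rowSums((X - matrix(X[idx[j], ], n, ncol(X), byrow = TRUE))^2))
  }
  idx
}

# row-wise argmin of squared distances to codebook rows, ties -> lowest unit
nearest_unit <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  max.col(-d2, ties.method = "first")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %dx%d hexagonal%s grid, %d layer(s), %d features\n",
              x$grid[1], x$grid[2], if (x$toroidal) " toroidal" else "",
              length(x$codebooks), length(x$assignment)))
  cat(sprintf("  quantization error: %.4g\n", x$quantization_error))
  invisible(x)
}

#' Select differentially expressed genes for clustering
#'
#' Keeps genes that are significant (`padj < padj_cut` and
#' `|log2FoldChange| > lfc_cut`) in the constant or either transient
#' contrast, and drops genes significant in the control-vs-control
#' contrast (a missing `padj` counts as not significant). Returns the
#' fold-change matrix the SOM is trained on.
#'
#' @param results named list of contrast results with elements `constant`,
#'   `transient_d9`, `transient_d11` (layouts as [nb_wald_test()]).
#' @param control_contrast control-vs-control contrast result.
#' @param padj_cut,lfc_cut selection thresholds (defaults 0.05 and 1).
#' @return list: `gene_ids`, `lfc` (matrix, columns constant /
#'   transient_d9 / transient_d11).
#' @export
select_de_genes <- function(results, control_contrast,
                            padj_cut = 0.05, lfc_cut = 1) {
  need <- c("constant", "transient_d9", "transient_d11")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop(sprintf("missing contrast(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  ids <- results$constant$feature_id
  for (r in c(results[need], list(control_contrast)))
    if (!identical(r$feature_id, ids))
      stop("contrasts have mismatched feature ids", call. = FALSE)
  sig <- function(r) !is.na(r$padj) & r$padj < padj_cut & abs(r$log2FoldChange) > lfc_cut
  keep <- (sig(results$constant) | sig(results$transient_d9) |
             sig(results$transient_d11)) & !sig(control_contrast)
  lfc <- cbind(constant = results$constant$log2FoldChange,
               transient_d9 = results$transient_d9$log2FoldChange,
               transient_d11 = results$transient_d11$log2FoldChange)[keep, , drop = FALSE]
  rownames(lfc) <- ids[keep]
  list(gene_ids = ids[keep], lfc = lfc)
}

#' Clip matrix columns at empirical percentiles
#'
#' Per-column winsorization at the 5th and 95th percentiles by default.
#' Percentiles use the linear-interpolation convention of
#' `stats::quantile(type = 7)`.
#'
#' @param m numeric matrix.
#' @param lower,upper percentile bounds as probabilities.
#' @return clipped matrix of the same shape.
#' @export
clip_percentiles <- function(m, lower = 0.05, upper = 0.95) {
  m <- as.matrix(m)
  if (!nrow(m)) stop("clip_percentiles: empty matrix", call. = FALSE)
  for (j in seq_len(ncol(m))) {
    q <- stats::quantile(m[, j], c(lower, upper), names = FALSE, type = 7)
    m[, j] <- pmin(pmax(m[, j], q[1]), q[2])
  }
  m
}

GENE_CLUSTER_RULES <- list(
  irreversible = c(1, 1), reversible = c(1, 0), transient_specific = c(0, 1),
  down_both = c(-1, -1), down_constant = c(-1, 0), down_transient = c(0, -1))

#' Label SOM units with gene-cluster semantics
#'
#' Units are labeled from their codebook means (`c` = constant layer,
#' `t` = mean of the transient layer columns): `c > delta` and
#' `t > delta` is irreversible; `c > delta` with `|t| <= delta` is
#' reversible; `|c| <= delta` with `t > delta` is transient-specific; the
#' mirrored negative patterns are down-regulated clusters, numbered
#' `down1..downK` in increasing constant-layer mean. A unit matching no
#' rule is labeled by the nearest rule pattern, with a warning.
#'
#' @param model `som_model` trained on layers (constant; transient).
#' @param delta rule threshold in log2 units (default 0.5).
#' @return `data.frame`: `unit`, `constant_mean`, `transient_mean`,
#'   `cluster`.
#' @export
label_gene_clusters <- function(model, delta = 0.5) {
  stopifnot(inherits(model, "som_model"), length(model$codebooks) >= 2)
  cm <- rowMeans(model$codebooks[[1]])
  tm <- rowMeans(model$codebooks[[2]])
  U <- length(cm)
  lab <- character(U)
  for (u in seq_len(U)) {
    c0 <- cm[u]; t0 <- tm[u]
    lab[u] <- if (c0 > delta && t0 > delta) {
      "irreversible"
    } else if (c0 > delta && abs(t0) <= delta) {
      "reversible"
    } else if (abs(c0) <= delta && t0 > delta) {
      "transient_specific"
    } else if (c0 < -delta && t0 < -delta) {
      "down_both"
    } else if (c0 < -delta && abs(t0) <= delta) {
      "down_constant"
    } else if (abs(c0) <= delta && t0 < -delta) {
      "down_transient"
    } else {
      NA_character_
    }
  }
  amb <- which(is.na(lab))
  if (length(amb)) {
    warning(sprintf("unit(s) %s match no labeling rule; using nearest rule",
                    paste(amb, collapse = ", ")))
    pat <- do.call(rbind, GENE_CLUSTER_RULES) * max(delta * 2, 1)
    for (u in amb) {
      d <- rowSums((pat - matrix(c(cm[u], tm[u]), nrow(pat), 2, byrow = TRUE))^2)
      lab[u] <- names(GENE_CLUSTER_RULES)[which.min(d)]
    }
  }
  # down clusters renamed down1..downK by increasing constant-layer mean
  dn <- which(startsWith(lab, "down"))
  if (length(dn)) lab[dn[order(cm[dn])]] <- paste0("down", seq_along(dn))
  data.frame(unit = seq_len(U), constant_mean = cm, transient_mean = tm,
             cluster = lab, stringsAsFactors = FALSE)
}

#' Classify genes as reversible / irreversible / transient-specific
#'
#' The full gene-side classification chain: select differential genes,
#' clip fold changes at the 5th/95th percentiles, train a two-layer SOM
#' (layer 1: constant knock-down fold change; layer 2: the two transient
#' timepoints) on a hexagonal toroidal grid, and label the units. Genes
#' never selected are reported as `unaffected`.
#'
#' @inheritParams select_de_genes
#' @param seed SOM seed.
#' @param grid SOM grid (default `c(3, 2)`).
#' @param epochs training epochs.
#' @param delta unit-labeling threshold.
#' @param pcg_flags optional named logical vector of Polycomb-target flags
#'   to join into the output.
#' @return list: `classification` (`data.frame` gene_id, cluster,
#'   pcg_bound), `model` (`som_model`), `units` (unit label table),
#'   `lfc` (clipped matrix of selected genes).
#' @export
classify_genes <- function(results, control_contrast, seed = 1L,
                           grid = c(3, 2), epochs = 100L,
                           padj_cut = 0.05, lfc_cut = 1, delta = 0.5,
                           pcg_flags = NULL) {
  sel <- select_de_genes(results, control_contrast, padj_cut, lfc_cut)
  if (length(sel$gene_ids) < prod(grid))
    stop(sprintf("only %d genes selected; too few for a %dx%d SOM",
                 length(sel$gene_ids), grid[1], grid[2]), call. = FALSE)
  lfc <- clip_percentiles(sel$lfc)
  model <- train_supersom(
    list(constant = lfc[, "constant", drop = FALSE],
         transient = lfc[, c("transient_d9", "transient_d11"), drop = FALSE]),
    grid = grid, toroidal = TRUE, seed = seed, epochs = epochs)
  units <- label_gene_clusters(model, delta)
  all_ids <- results$constant$feature_id
  cluster <- stats::setNames(rep("unaffected", length(all_ids)), all_ids)
  cluster[sel$gene_ids] <- units$cluster[model$assignment]
  out <- data.frame(gene_id = all_ids, cluster = unname(cluster),
                    stringsAsFactors = FALSE)
  out$pcg_bound <- if (!is.null(pcg_flags)) unname(pcg_flags[all_ids]) else NA
  list(classification = out, model = model, units = units, lfc = lfc)
}

#' Select and cluster differentially accessible peaks
#'
#' Accessibility-side classification: keep peaks significant
#' (`padj < 1e-3` and `|log2FoldChange| > 1`) after constant or transient
#' knock-down and with `log10(baseMean) >= 1.25`; train a four-layer SOM
#' (clipped constant and transient fold changes; `-log10(padj)` of both
#' contrasts, capped at 20, with missing `padj` entering as 0) on a 1x3
#' hexagonal toroidal grid; label the three units increased-irreversible /
#' increased-reversible / decreased from the codebook fold-change signs
#' (the unit with the lowest constant-layer mean is `decreased`; of the
#' remaining two, the higher transient mean is `irreversible`).
#'
#' @param results named list with contrast results `constant` and
#'   `transient` over the same peak universe.
#' @param seed SOM seed.
#' @param padj_cut,lfc_cut,log10_bm_min selection thresholds (defaults
#'   1e-3, 1, 1.25).
#' @param epochs training epochs.
#' @return list: `classification` (`data.frame` peak, cluster), `model`,
#'   `units`, `selected` (selected peak ids).
#' @export
select_and_cluster_atac <- function(results, seed = 1L, padj_cut = 1e-3,
                                    lfc_cut = 1, log10_bm_min = 1.25,
                                    epochs = 100L) {
  for (nm in c("constant", "transient"))
    if (is.null(results[[nm]])) stop(sprintf("missing contrast '%s'", nm), call. = FALSE)
  rc <- results$constant; rt <- results$transient
  if (!identical(rc$feature_id, rt$feature_id))
    stop("contrasts have mismatched feature ids", call. = FALSE)
  sig <- function(r) !is.na(r$padj) & r$padj < padj_cut & abs(r$log2FoldChange) > lfc_cut
  keep <- (sig(rc) | sig(rt)) & log10(pmax(rc$baseMean, 1e-300)) >= log10_bm_min
  ids <- rc$feature_id[keep]
  if (length(ids) < 3) stop("fewer than 3 peaks selected", call. = FALSE)
  lfc <- clip_percentiles(cbind(constant = rc$log2FoldChange[keep],
                                transient = rt$log2FoldChange[keep]))
  nlp <- function(p) pmin(-log10(pmax(ifelse(is.na(p), 1, p), 1e-300)), 20)
  model <- train_supersom(
    list(lfc_constant = lfc[, "constant", drop = FALSE],
         lfc_transient = lfc[, "transient", drop = FALSE],
         sig_constant = matrix(nlp(rc$padj[keep]), ncol = 1),
         sig_transient = matrix(nlp(rt$padj[keep]), ncol = 1)),
    grid = c(1, 3), toroidal = TRUE, seed = seed, epochs = epochs)
  cm <- rowMeans(model$codebooks[[1]]); tm <- rowMeans(model$codebooks[[2]])
  lab <- character(3)
  dec <- which.min(cm)
  lab[dec] <- "decreased"
  rest <- setdiff(1:3, dec)
  irr <- rest[which.max(tm[rest])]
  lab[irr] <- "irreversible"
  lab[setdiff(rest, irr)] <- "reversible"
  if (cm[dec] > 0 || any(cm[rest] < 0))
    warning("ATAC unit fold-change signs do not match the expected layout")
  units <- data.frame(unit = 1:3, constant_mean = cm, transient_mean = tm,
                      cluster = lab, stringsAsFactors = FALSE)
  list(classification = data.frame(peak = ids,
                                   cluster = lab[model$assignment],
                                   stringsAsFactors = FALSE),
       model = model, units = units, selected = ids)
}
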