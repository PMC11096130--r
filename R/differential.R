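#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median across features of the
#' ratio of each sample's count to the per-feature geometric mean, using
#' only features with nonzero counts in every sample. Factors are
#' renormalized so their geometric mean is 1. `total-count` normalization
#' divides library sizes by their geometric mean instead.
#'
#' @param counts integer matrix, features x samples.
#' @param method `"median-of-ratios"` (default) or `"total-count"`.
#' @return positive numeric vector, one factor per sample, geometric mean 1.
#' @export
size_factors <- function(counts, method = c("median-of-ratios", "total-count")) {
  method <- match.arg(method)
  if (all(counts == 0)) stop("size_factors: all-zero count matrix", call. = FALSE)
  if (method == "total-count") {
    ls <- colSums(counts)
    if (any(ls == 0)) stop("size_factors: sample with zero total count", call. = FALSE)
    sf <- ls / exp(mean(log(ls)))
    return(stats::setNames(sf, colnames(counts)))
  }
  keep <- rowSums(counts == 0) == 0
  if (!any(keep))
    stop("size_factors: no feature has nonzero counts in every sample", call. = FALSE)
  lg <- log(counts[keep, , drop = FALSE])
  gm <- rowMeans(lg)
  sf <- apply(exp(lg - gm), 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Simplified negative-binomial Wald test for one contrast
#'
#' A deliberately simple two-group differential test in the negative
#' binomial family (`variance = mean + dispersion * mean^2`). It is not a
#' DESeq2 clone: the per-feature dispersion is a method-of-moments
#' estimate on normalized counts, with residuals pooled within *every*
#' condition group of the design (not only the two being contrasted),
#' floored at 1e-8, with no shrinkage, no outlier filtering, and no
#' replicate covariate — the two condition groups are compared directly.
#' Group log-means are fitted by Newton iterations with the size factors
#' as offsets; the Wald statistic uses Fisher-information standard errors
#' and is referred to a t distribution with the pooled residual degrees
#' of freedom (total samples minus number of condition groups), which
#' accounts for the sampling error of the plug-in dispersion at
#' few-replicate sample sizes (a normal reference is anti-conservative
#' there). Features whose baseMean falls below
#' `base_mean_floor` are excluded from multiple-testing correction and get
#' a missing `padj` (treated as not significant downstream).
#'
#' @param counts integer matrix, features x samples.
#' @param design design `data.frame` with `sample_id` and `condition`.
#' @param contrast `c(perturbed, control)` condition labels; the reported
#'   log2 fold change is perturbed over control.
#' @param normalization passed to [size_factors()].
#' @param base_mean_floor independent-filtering floor on baseMean
#'   (default 1).
#' @return `data.frame`: `feature_id`, `baseMean`, `log2FoldChange`,
#'   `pvalue`, `padj`.
#' @export
nb_wald_test <- function(counts, design, contrast,
                         normalization = c("median-of-ratios", "total-count"),
                         base_mean_floor = 1) {
  normalization <- match.arg(normalization)
  stopifnot(length(contrast) == 2)
  validate_design(design, counts)
  s1 <- design$sample_id[design$condition == contrast[1]]  # perturbed
  s0 <- design$sample_id[design$condition == contrast[2]]  # control
  if (length(s1) < 2 || length(s0) < 2)
    stop(sprintf("nb_wald_test: each group needs >= 2 replicates (got %d vs %d)",
                 length(s1), length(s0)), call. = FALSE)
  all_samples <- design$sample_id
  m <- counts[, all_samples, drop = FALSE]
  sf <- size_factors(m, normalization)
  z <- sweep(m, 2, sf, "/")
  groups <- split(seq_along(all_samples), design$condition)
  disp <- mom_dispersion(z, groups)
  df_resid <- length(all_samples) - length(groups)

  i1 <- match(s1, all_samples); i0 <- match(s0, all_samples)
  base_mean <- rowMeans(z[, c(i1, i0), drop = FALSE])
  f1 <- nb_group_fit(m[, i1, drop = FALSE], sf[i1], disp)
  f0 <- nb_group_fit(m[, i0, drop = FALSE], sf[i0], disp)
  lfc <- (f1$beta - f0$beta) / log(2)
  se <- sqrt(f1$var + f0$var)
  wald <- (f1$beta - f0$beta) / se
  pvalue <- 2 * stats::pt(-abs(wald), df = df_resid)
  pvalue[!is.finite(wald)] <- NA_real_

  padj <- rep(NA_real_, nrow(m))
  pass <- base_mean >= base_mean_floor & !is.na(pvalue)
  padj[pass] <- bh_fdr(pvalue[pass])
  data.frame(feature_id = rownames(counts), baseMean = base_mean,
             log2FoldChange = lfc, pvalue = pvalue, padj = padj,
             stringsAsFactors = FALSE, row.names = NULL)
}

# method-of-moments NB dispersion on normalized counts: per-condition
# estimates (v - m) / m^2, averaged across groups with df weights
mom_dispersion <- function(z, groups, floor = 1e-8) {
  num <- 0
  den <- 0
  for (g in groups) {
    if (length(g) < 2) next
    zg <- z[, g, drop = FALSE]
    m <- rowMeans(zg)
    v <- rowSums((zg - m)^2) / (length(g) - 1)
    w <- ifelse(m > 0, length(g) - 1, 0)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + w * a
    den <- den + w
  }
  pmax(ifelse(den > 0, num / pmax(den, 1), floor), floor)
}

# vectorized Newton fit of one NB group log-mean with offsets log(sf);
# returns beta-hat and its Fisher-information variance
nb_group_fit <- function(y, sf, disp, iters = 30L) {
  tot <- rowSums(y)
  zero <- tot == 0
  if (any(zero)) {
    # pseudo-mean for empty groups so the fit and its SE stay finite
    y[zero, ] <- y[zero, , drop = FALSE] + 0.5 / ncol(y)
    tot <- rowSums(y)
  }
  beta <- log(tot / sum(sf))
  for (it in seq_len(iters)) {
    mu <- exp(beta) %o% sf
    w <- 1 + disp * mu
    U <- rowSums((y - mu) / w)
    I <- rowSums(mu / w)
    step <- U / I
    step <- pmax(pmin(step, 5), -5)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(beta) %o% sf
  I <- rowSums(mu / (1 + disp * mu))
  list(beta = beta, var = 1 / I)
}

#' Fragments per kilobase per million (FPKM)
#'
#' `FPKM = count / (length/1e3) / (libsize/1e6)`, with the library size
#' taken as the total assigned counts per sample unless supplied.
#'
#' @param counts integer matrix, features x samples.
#' @param feature_lengths named or positionally matched lengths in bp.
#' @param lib_sizes optional per-sample library sizes.
#' @return numeric matrix of FPKM values.
#' @export
compute_fpkm <- function(counts, feature_lengths, lib_sizes = colSums(counts)) {
  if (is.null(feature_lengths) || length(feature_lengths) != nrow(counts))
    stop("compute_fpkm: feature_lengths must cover every feature", call. = FALSE)
  if (!is.null(names(feature_lengths)) && !is.null(rownames(counts))) {
    miss <- setdiff(rownames(counts), names(feature_lengths))
    if (length(miss)) stop(sprintf("compute_fpkm: missing length for %s", miss[1]), call. = FALSE)
    feature_lengths <- feature_lengths[rownames(counts)]
  }
  if (any(is.na(feature_lengths)) || any(feature_lengths <= 0))
    stop("compute_fpkm: lengths must be positive", call. = FALSE)
  sweep(counts / (feature_lengths / 1e3), 2, lib_sizes / 1e6, "/")
}

#' Write a contrast result TSV
#' @param res result of [nb_wald_test()].
#' @param path output path.
#' @export
write_contrast <- function(res, path) {
  utils::write.table(res[, c("feature_id", "baseMean", "log2FoldChange", "pvalue", "padj")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
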