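#' One-sided Fisher's exact test (enrichment direction)
#'
#' Exact upper-tail hypergeometric probability `P(X >= a)` for the 2x2
#' table `(a, b; c, d)` with `a` = in-set and in-cluster, `b` = in-set
#' only, `c` = in-cluster only, `d` = neither. The odds ratio is the
#' unconditional sample OR `ad/bc`, with a Haldane correction (0.5 added
#' to every cell) when a zero cell occurs, flagged in the output.
#'
#' @param a,b,c,d non-negative integer cells.
#' @return list: `p`, `odds_ratio`, `haldane` (logical).
#' @export
fisher_greater <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("fisher_greater: cells must be non-negative integers", call. = FALSE)
  # X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c)
  p <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(p = min(p, 1), odds_ratio = or, haldane = haldane)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Definitional step-up procedure: order p ascending, take
#' `p_(i) * m / i`, enforce monotonicity from the largest rank down, cap
#' at 1, and restore the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed, returned
#'   as NA and excluded from the family size).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  ord <- order(p[ok])
  ranked <- p[ok][ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out[ok[ord]] <- pmin(adj, 1)
  out
}

#' Over-representation of gene sets within clusters
#'
#' One one-sided Fisher test per (set, cluster) pair against the supplied
#' universe, FDR-corrected across all tests of the call (one family per
#' invocation). Significance tiers follow the usual figure-legend cutoffs
#' (FDR < 5e-2 `*`, < 1e-3 `***`, < 1e-5 `****`).
#'
#' @param classification `data.frame` with columns `gene_id` (or `peak`)
#'   and `cluster`; only members of `universe` are considered.
#' @param gene_sets named list of feature-id vectors (subsets of the
#'   universe; ids outside it are dropped).
#' @param universe vector of all eligible feature ids.
#' @return `data.frame`: set, cluster, a, b, c, d, odds_ratio, p, fdr,
#'   tier.
#' @export
overrepresentation_by_cluster <- function(classification, gene_sets, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  idcol <- if ("gene_id" %in% names(classification)) "gene_id" else "peak"
  cls <- classification[classification[[idcol]] %in% universe, , drop = FALSE]
  rows <- list()
  for (set_name in names(gene_sets)) {
    set <- intersect(unique(gene_sets[[set_name]]), universe)
    for (cl in unique(cls$cluster)) {
      members <- cls[[idcol]][cls$cluster == cl]
      a <- length(intersect(set, members))
      b <- length(set) - a
      c_ <- length(members) - a
      d <- length(universe) - a - b - c_
      ft <- fisher_greater(a, b, c_, d)
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, cluster = cl, a = a, b = b, c = c_, d = d,
        odds_ratio = ft$odds_ratio, haldane = ft$haldane, p = ft$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$tier <- cut(out$fdr, breaks = c(-Inf, 1e-5, 1e-3, 5e-2, Inf),
                  labels = c("****", "***", "*", "NS"))
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by full enumeration of rank splits when the combined sample
#' size is at most `exact_limit` (ties handled by enumerating midranks);
#' otherwise the normal approximation with tie and continuity
#' corrections. The two-sided p doubles the smaller tail, capped at 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit largest combined n for the exact branch (default 12).
#' @return list: `p`, `statistic` (rank-sum W of `x`, i.e. U + n_x(n_x+1)/2),
#'   `method`.
#' @export
wilcoxon_ranksum <- function(x, y, exact_limit = 12L) {
  if (!length(x) || !length(y)) stop("wilcoxon_ranksum: empty sample", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  if (n <= exact_limit) {
    splits <- utils::combn(n, nx)
    Ws <- colSums(matrix(r[splits], nrow = nx))
    # two-sided: double the smaller exact tail (including the observed value)
    lo <- mean(Ws <= W); hi <- mean(Ws >= W)
    p <- min(1, 2 * min(lo, hi))
    return(list(p = p, statistic = W, method = "exact"))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(p = 1, statistic = W, method = "normal"))
  z <- (abs(W - mu) - 0.5) / sqrt(sig2)
  z <- max(z, 0)
  list(p = min(1, 2 * stats::pnorm(-abs(z))), statistic = W, method = "normal")
}
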