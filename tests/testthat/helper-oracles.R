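# Independent brute-force oracles used by the property and acceptance
# tests. These deliberately avoid the package's interval/statistics code
# paths: everything here is per-base counting, all-pairs scanning or
# direct enumeration.

# per-base overlap fraction of one gene body with a set of domains
oracle_overlap_fraction <- function(gene_start, gene_end, dom) {
  pos <- seq.int(gene_start, gene_end - 1L)
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(dom)))
    inside <- inside | (pos >= dom$start[i] & pos < dom$end[i])
  mean(inside)
}

# all-pairs nearest-TSS assignment for one peak
oracle_nearest_tss <- function(mid, chrom, genes, max_sep) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene = NA_character_, dist = NA_real_))
  d <- abs(g$tss - mid)
  if (min(d) > max_sep) return(list(gene = NA_character_, dist = NA_real_))
  cand <- which(d == min(d))
  best <- cand[order(g$gene_id[cand])][1]
  list(gene = g$gene_id[best], dist = g$tss[best] - mid)
}

# naive double-loop consolidation + merge
oracle_consolidate <- function(rep1, rep2, merged, gap) {
  pass <- function(df) df$enrichment > 0 & df$qvalue < 0.05
  ovl <- function(a_start, a_end, df)
    any(df$start < a_end & df$end > a_start)
  keep <- logical(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    if (!(merged$enrichment[i] > 2 && merged$qvalue[i] < 0.01)) next
    r1 <- rep1[pass(rep1) & rep1$chrom == merged$chrom[i], , drop = FALSE]
    r2 <- rep2[pass(rep2) & rep2$chrom == merged$chrom[i], , drop = FALSE]
    keep[i] <- ovl(merged$start[i], merged$end[i], r1) &&
      ovl(merged$start[i], merged$end[i], r2)
  }
  k <- merged[keep, c("chrom", "start", "end"), drop = FALSE]
  if (!nrow(k)) return(k)
  k <- k[order(k$chrom, k$start, k$end), , drop = FALSE]
  out <- list()
  cur <- k[1, ]
  for (i in seq_len(nrow(k))[-1]) {
    same <- k$chrom[i] == cur$chrom && (k$start[i] - cur$end) <= gap
    if (same) cur$end <- max(cur$end, k$end[i])
    else { out[[length(out) + 1L]] <- cur; cur <- k[i, ] }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-base active-peak check with strand-aware upstream window
oracle_active_peak <- function(gene, peaks, upstream = 2500) {
  ws <- if (gene$strand == "+") max(gene$start - upstream, 0) else gene$start
  we <- if (gene$strand == "+") gene$end else gene$end + upstream
  p <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
  any(p$start < we & p$end > ws)
}

# exact hypergeometric upper tail by direct summation of choose() terms
oracle_hyper_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- a:min(m, k)
  xs <- xs[k - xs <= n]
  if (!length(xs)) return(0)
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# definitional BH: p_(i) * m / i with step-up monotonicity
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# exact two-sided Wilcoxon by enumerating every rank split
oracle_wilcox_exact <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  Ws <- combn(n, length(x), function(ix) sum(r[ix]))
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# naive per-position PWM rescanning with the same dedup rule
oracle_scan_count <- function(seq, U, threshold) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T"))
  L <- ncol(U)
  if (length(codes) < L) return(0L)
  Urc <- U[c(4, 3, 2, 1), rev(seq_len(L)), drop = FALSE]
  score_at <- function(j, M) {
    s <- 0
    for (i in seq_len(L)) {
      b <- codes[j + i - 1]
      if (is.na(b)) return(-Inf)
      s <- s + M[b, i]
    }
    s
  }
  hits <- list()
  for (j in seq_len(length(codes) - L + 1)) {
    s <- max(score_at(j, U), score_at(j, Urc))
    if (s >= threshold) hits[[length(hits) + 1L]] <- c(j, s)
  }
  if (!length(hits)) return(0L)
  count <- 0L; cur_pos <- -Inf; cur_score <- -Inf
  for (h in hits) {
    if (h[1] >= cur_pos + L) { count <- count + 1L; cur_pos <- h[1]; cur_score <- h[2] }
    else if (h[2] > cur_score) { cur_pos <- h[1]; cur_score <- h[2] }
  }
  count
}

# normalize an interval frame for comparisons (types and row names)
norm_iv <- function(df) {
  out <- data.frame(chrom = as.character(df$chrom),
                    start = as.numeric(df$start), end = as.numeric(df$end),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# random interval helpers for property tests
random_intervals <- function(n, genome_len = 1e5, max_w = 3000, chrom = "chrT") {
  w <- sample.int(max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(genome_len - wi, 1), 1L)
  data.frame(chrom = chrom, start = s, end = s + w, stringsAsFactors = FALSE)
}

random_genes <- function(n, genome_len = 1e5, chrom = "chrT") {
  iv <- random_intervals(n, genome_len, max_w = 4000, chrom = chrom)
  iv <- iv[iv$end - iv$start >= 200, , drop = FALSE]
  strand <- sample(c("+", "-"), nrow(iv), replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(nrow(iv))), iv, strand = strand,
             tss = ifelse(strand == "+", iv$start, iv$end - 1L),
             stringsAsFactors = FALSE)
}

random_peak_calls <- function(n, genome_len = 1e5) {
  iv <- random_intervals(n, genome_len, max_w = 800)
  data.frame(iv, name = sprintf("p%03d", seq_len(n)),
             enrichment = runif(n, 0, 6), qvalue = 10^runif(n, -6, 0),
             stringsAsFactors = FALSE)
}

# one-row variant-record builder
mkvar <- function(vtype, af = NA, support = NA, ratio = NA, sample = "t1",
                  pos = 100, feature = "exon") {
  data.frame(sample_id = sample, chrom = "c1", pos = pos, ref = "A", alt = "T",
             vtype = vtype, af = af, support = support, ratio = ratio,
             feature = feature, deleterious = FALSE, stringsAsFactors = FALSE)
}

# tiny contrast-result builder for selection tests
fake_contrast <- function(ids, lfc = 0, padj = 1, base_mean = 100) {
  data.frame(feature_id = ids, baseMean = rep_len(base_mean, length(ids)),
             log2FoldChange = rep_len(lfc, length(ids)),
             pvalue = rep_len(padj, length(ids)),
             padj = rep_len(padj, length(ids)), stringsAsFactors = FALSE)
}
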