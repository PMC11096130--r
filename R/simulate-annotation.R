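#' Simulate gene models, repressive domains, peak calls and motifs
#'
#' Builds the annotation side of the synthetic dataset:
#'
#' * gene bodies placed uniformly and non-overlapping (>= 1 kb spacing),
#'   one uniform strand each; Polycomb-target genes (planted with higher
#'   probability among the up-regulated classes) sit fully inside planted
#'   repressive-mark domains, so the >= 50% body-overlap rule recovers the
#'   flags exactly;
#' * a split-domain variant plus assembly-gap intervals such that gap-aware
#'   stitching reconstructs the clean domains;
#' * per-replicate and merged peak calls in which planted confident peaks
#'   pass the consolidation rule (both replicates enrichment > 0 and
#'   q < 0.05; merged enrichment > 2 and q < 0.01) and planted noise peaks
#'   fail exactly one criterion, chosen uniformly;
#' * a synthetic PWM collection (each motif tied to a simulated TF gene)
#'   and 500-bp peak-window sequences with the planted motif occurrences
#'   embedded at their planted counts.
#'
#' @param config a [sim_config()].
#' @return list with `genes`, `domains`, `domains_split`, `assembly_gaps`,
#'   `peak_intervals`, `noise_peak_intervals`, `peak_calls` (list
#'   rep1/rep2/merged), `pwms`, `peak_sequences`, and `truth`
#'   (`pcg_flag`, per-peak confident flag).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  gene_class <- planted_gene_classes(config)
  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))

  set.seed(sim_seed(config, "annotation"))
  lens <- sample(1000:4000, config$n_genes, replace = TRUE)
  placed <- place_nonoverlapping(lens, config$chrom_lengths, min_gap = 1000)
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- data.frame(gene_id = gene_ids, chrom = placed$chrom,
                      start = placed$start, end = placed$end, strand = strand,
                      tss = ifelse(strand == "+", placed$start, placed$end - 1L),
                      stringsAsFactors = FALSE)

  up_classes <- c("irreversible", "reversible", "transient_specific")
  p_pcg <- ifelse(gene_class %in% up_classes,
                  config$pcg_prob_perturbed, config$pcg_prob_background)
  pcg <- stats::runif(config$n_genes) < p_pcg

  # domains fully covering their target gene bodies (±400 bp); spacing of
  # >= 1 kb between genes keeps neighbours out of foreign domains entirely
  dom <- genes[pcg, , drop = FALSE]
  domains <- genomic_intervals(
    dom$chrom,
    pmax(dom$start - 400L, 0),
    pmin(dom$end + 400L, config$chrom_lengths[dom$chrom]),
    name = sprintf("domain%04d", seq_len(nrow(dom))))
  domains <- sort_intervals(domains)

  split <- split_domains_with_gaps(domains)

  # peak placement: confident features and noise calls share one
  # non-overlapping layout so the consolidation outcome is unambiguous
  n_all <- config$n_peaks + config$n_noise_peaks
  set.seed(sim_seed(config, "peak_calls"))
  pw <- sample(200:600, n_all, replace = TRUE)
  pplaced <- place_nonoverlapping(pw, config$chrom_lengths, min_gap = 1200)
  conf_idx <- seq_len(config$n_peaks)
  peak_names <- c(sprintf("peak%05d", conf_idx),
                  if (config$n_noise_peaks > 0) sprintf("noise%05d", seq_len(config$n_noise_peaks)))
  peaks_all <- data.frame(chrom = pplaced$chrom, start = pplaced$start,
                          end = pplaced$end, name = peak_names,
                          stringsAsFactors = FALSE)
  confident <- c(rep(TRUE, config$n_peaks), rep(FALSE, config$n_noise_peaks))
  peak_calls <- emit_peak_calls(peaks_all, confident, config$chrom_lengths)

  pwms <- simulate_pwms(config, gene_ids)
  seqs <- simulate_peak_sequences(config, peaks_all[conf_idx, , drop = FALSE], pwms)

  list(genes = genes,
       domains = domains,
       domains_split = split$domains,
       assembly_gaps = split$gaps,
       peak_intervals = peaks_all[conf_idx, , drop = FALSE],
       noise_peak_intervals = peaks_all[-conf_idx, , drop = FALSE],
       peak_calls = peak_calls,
       pwms = pwms,
       peak_sequences = seqs,
       truth = list(pcg_flag = stats::setNames(pcg, gene_ids),
                    confident = stats::setNames(confident, peak_names)))
}

# uniform non-overlapping placement with a minimum inter-feature gap;
# features are allotted to chromosomes proportionally to length
place_nonoverlapping <- function(lens, chrom_lengths, min_gap) {
  n <- length(lens)
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  if (max(lens) + 2 * min_gap > max(chrom_lengths))
    stop("feature longer than any chromosome", call. = FALSE)
  probs <- chrom_lengths / sum(chrom_lengths)
  alloc <- floor(probs * n)
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  ord <- sample.int(n)  # shuffle so classes are not chromosome-stratified
  out <- data.frame(chrom = character(n), start = integer(n), end = integer(n),
                    stringsAsFactors = FALSE)
  pos <- 1L
  for (ci in seq_along(chrom_lengths)) {
    k <- alloc[ci]
    if (k == 0) next
    idx <- ord[pos:(pos + k - 1L)]; pos <- pos + k
    L <- chrom_lengths[ci]
    l <- lens[idx]
    free <- L - sum(l) - min_gap * (k + 1)
    if (free < 0)
      stop(sprintf("chromosome %s too short for %d features", names(chrom_lengths)[ci], k), call. = FALSE)
    extra <- as.integer(stats::rmultinom(1, free, rep(1, k + 1)))
    starts <- min_gap + extra[1] + c(0L, cumsum(l + min_gap + extra[2:(k + 1)]))[seq_len(k)]
    out$chrom[idx] <- names(chrom_lengths)[ci]
    out$start[idx] <- starts
    out$end[idx] <- starts + l
  }
  out
}

# split a subset of wide domains in two, covering the hole with a planted
# assembly-gap interval; stitching over the gaps restores the originals
split_domains_with_gaps <- function(domains, split_frac = 0.3, hole = 200L) {
  n <- nrow(domains)
  if (n == 0)
    return(list(domains = domains, gaps = genomic_intervals(character(), integer(), integer())))
  wide <- which(domains$end - domains$start > 4 * hole)
  pick <- wide[stats::runif(length(wide)) < split_frac]
  keep <- domains[setdiff(seq_len(n), pick), , drop = FALSE]
  pieces <- list(); gaps <- list()
  for (i in pick) {
    mid <- floor((domains$start[i] + domains$end[i]) / 2)
    g1 <- mid - floor(hole / 2); g2 <- g1 + hole
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = domains$chrom[i], start = c(domains$start[i], g2),
      end = c(g1, domains$end[i]), strand = ".",
      name = paste0(domains$name[i], c("_a", "_b")), stringsAsFactors = FALSE)
    gaps[[length(gaps) + 1L]] <- data.frame(chrom = domains$chrom[i],
                                            start = g1, end = g2, strand = ".",
                                            stringsAsFactors = FALSE)
  }
  dsplit <- sort_intervals(rbind(keep, do.call(rbind, pieces)))
  gdf <- if (length(gaps)) sort_intervals(do.call(rbind, gaps)) else
    genomic_intervals(character(), integer(), integer())
  list(domains = dsplit, gaps = gdf)
}

emit_peak_calls <- function(peaks, confident, chrom_lengths) {
  n <- nrow(peaks)
  runif_log <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))
  merged <- data.frame(peaks, strand = ".",
                       enrichment = numeric(n), qvalue = numeric(n),
                       replicate = "merged", stringsAsFactors = FALSE)
  rep1 <- merged; rep1$replicate <- "rep1"
  rep2 <- merged; rep2$replicate <- "rep2"
  # replicate intervals jittered a little; widths >= 200 keep >= 1 bp overlap
  jitter_iv <- function(df) {
    off <- sample(-50:50, n, replace = TRUE)
    df$start <- pmax(df$start + off, 0)
    df$end <- pmin(df$end + off, chrom_lengths[df$chrom])
    df
  }
  rep1 <- jitter_iv(rep1); rep2 <- jitter_iv(rep2)

  merged$enrichment <- stats::runif(n, 2.05, 8)
  merged$qvalue <- runif_log(n, 1e-10, 1e-3)
  for (df_name in c("rep1", "rep2")) {
    df <- get(df_name)
    df$enrichment <- stats::runif(n, 0.1, 5)
    df$qvalue <- runif_log(n, 1e-8, 0.04)
    assign(df_name, df)
  }
  fail_mode <- sample.int(4, n, replace = TRUE)
  ni <- which(!confident)
  for (i in ni) {
    switch(fail_mode[i],
           rep1$qvalue[i] <- stats::runif(1, 0.06, 0.9),
           rep2$qvalue[i] <- stats::runif(1, 0.06, 0.9),
           merged$enrichment[i] <- stats::runif(1, 0.05, 1.9),
           merged$qvalue[i] <- stats::runif(1, 0.02, 0.5))
  }
  list(rep1 = rep1, rep2 = rep2, merged = merged)
}

simulate_pwms <- function(config, gene_ids) {
  set.seed(sim_seed(config, "pwms"))
  tf_genes <- sample(gene_ids, config$n_motifs)
  pwms <- list()
  for (k in seq_len(config$n_motifs)) {
    L <- sample(6:10, 1)
    cons <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = config$background)
    m <- matrix(0.05, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_len(L)) m[cons[j], j] <- 0.85
    id <- sprintf("MOTIF%d", k)
    pwms[[id]] <- list(id = id, name = tf_genes[k], matrix = m,
                       consensus = paste(cons, collapse = ""))
  }
  pwms
}

simulate_peak_sequences <- function(config, peak_intervals, pwms) {
  X <- planted_motif_counts(config)
  set.seed(sim_seed(config, "sequences"))
  bases <- c("A", "C", "G", "T")
  n <- nrow(peak_intervals)
  win <- 500L
  slot_w <- 25L
  n_slots <- win %/% slot_w
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- sample(bases, win, replace = TRUE, prob = config$background)
    inst <- rep(names(pwms), X[i, names(pwms)])
    if (length(inst) > n_slots) inst <- inst[seq_len(n_slots)]
    if (length(inst)) {
      slots <- sample.int(n_slots, length(inst))
      for (k in seq_along(inst)) {
        cons <- strsplit(pwms[[inst[k]]]$consensus, "")[[1]]
        if (stats::runif(1) < 0.5)
          cons <- rev(c(A = "T", C = "G", G = "C", T = "A")[cons])
        off <- (slots[k] - 1L) * slot_w + sample.int(slot_w - length(cons) + 1L, 1)
        s[off:(off + length(cons) - 1L)] <- cons
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- peak_intervals$name
  seqs
}
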