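#' Consolidate replicate and merged peak calls into confident peaks
#'
#' A merged-call peak is retained iff it has enrichment > 2 and q < 0.01
#' and overlaps (by at least 1 bp) a passing peak (enrichment > 0 and
#' q < 0.05) in *both* replicates. Retained intervals are then fused
#' whenever the gap between neighbours is at most 250 bp (`narrow` mode)
#' or 2,500 bp (`broad` mode, for broad repressive marks).
#'
#' @param rep1,rep2,merged peak `data.frame`s ([read_narrowpeak()] layout).
#' @param mode `"narrow"` or `"broad"`.
#' @return sorted, non-overlapping interval `data.frame`.
#' @export
consolidate_peaks <- function(rep1, rep2, merged, mode = c("narrow", "broad")) {
  mode <- match.arg(mode)
  gap <- if (mode == "narrow") 250L else 2500L
  pass_rep <- function(df) df[df$enrichment > 0 & df$qvalue < 0.05, , drop = FALSE]
  keep <- merged[merged$enrichment > 2 & merged$qvalue < 0.01, , drop = FALSE]
  if (nrow(keep)) {
    kg <- gi2gr(keep)
    hit1 <- IRanges::overlapsAny(kg, gi2gr(pass_rep(rep1)), ignore.strand = TRUE)
    hit2 <- IRanges::overlapsAny(kg, gi2gr(pass_rep(rep2)), ignore.strand = TRUE)
    keep <- keep[hit1 & hit2, , drop = FALSE]
  }
  merge_intervals(keep, gap)
}

#' Fuse intervals separated by at most `gap` bp
#' @param intervals interval `data.frame`.
#' @param gap largest inter-interval separation (bp) that is still fused.
#' @return sorted, non-overlapping interval `data.frame`.
#' @export
merge_intervals <- function(intervals, gap = 0L) {
  if (nrow(intervals) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  red <- GenomicRanges::reduce(gi2gr(intervals), min.gapwidth = gap + 1L,
                               ignore.strand = TRUE)
  sort_intervals(gr2gi(red))
}

#' Stitch domains split by assembly gaps
#'
#' Two neighbouring domains on the same chromosome are fused iff the
#' region between them is entirely covered by assembly-gap intervals
#' (touching domains count as trivially covered). Fusion is transitive.
#'
#' @param domains interval `data.frame` (non-overlapping).
#' @param assembly_gaps interval `data.frame`, may be empty or `NULL`.
#' @return stitched interval `data.frame`.
#' @export
stitch_domains <- function(domains, assembly_gaps = NULL) {
  if (is.null(assembly_gaps) || nrow(assembly_gaps) == 0)
    return(sort_intervals(domains[, c("chrom", "start", "end", intersect("strand", names(domains)))]))
  d <- sort_intervals(domains)
  gaps <- merge_intervals(assembly_gaps, gap = 0L)
  out <- list()
  for (chr in unique(d$chrom)) {
    dc <- d[d$chrom == chr, , drop = FALSE]
    gc_ <- gaps[gaps$chrom == chr, , drop = FALSE]
    cur_start <- dc$start[1]; cur_end <- dc$end[1]
    for (i in seq_len(nrow(dc))[-1]) {
      between_covered <- dc$start[i] <= cur_end ||
        covered_by(cur_end, dc$start[i], gc_)
      if (between_covered) {
        cur_end <- max(cur_end, dc$end[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = chr, start = cur_start,
                                              end = cur_end, strand = ".")
        cur_start <- dc$start[i]; cur_end <- dc$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = chr, start = cur_start,
                                          end = cur_end, strand = ".")
  }
  sort_intervals(do.call(rbind, out))
}

# is [start, end) fully covered by the merged per-chromosome gaps?
# merged gaps are disjoint, so full coverage means one gap contains it
covered_by <- function(start, end, gaps) {
  if (start >= end) return(TRUE)
  any(gaps$start <= start & gaps$end >= end)
}

#' Classify genes as direct Polycomb targets
#'
#' A gene is a direct Polycomb target iff at least 50% of its gene body
#' overlaps a repressive-mark (H3K27me3) domain; the boundary (exactly
#' 50%) is inclusive.
#'
#' @param genes gene annotation `data.frame` (see [read_gene_models()]).
#' @param domains non-overlapping interval `data.frame`.
#' @param min_fraction overlap fraction threshold (default 0.5).
#' @return `data.frame`: `gene_id`, `overlap_bp`, `overlap_fraction`,
#'   `pcg_target`.
#' @export
classify_pcg_targets <- function(genes, domains, min_fraction = 0.5) {
  validate_genes(genes)
  widths <- genes$end - genes$start
  if (any(widths <= 0)) stop("classify_pcg_targets: zero-length gene body", call. = FALSE)
  ov_bp <- numeric(nrow(genes))
  if (nrow(domains)) {
    gg <- gi2gr(genes); dg <- GenomicRanges::reduce(gi2gr(domains), ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(gg, dg, ignore.strand = TRUE)
    if (length(hits)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gg)[S4Vectors::queryHits(hits)],
        IRanges::ranges(dg)[S4Vectors::subjectHits(hits)]))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      ov_bp[as.integer(names(agg))] <- agg
    }
  }
  frac <- ov_bp / widths
  data.frame(gene_id = genes$gene_id, overlap_bp = ov_bp,
             overlap_fraction = frac, pcg_target = frac >= min_fraction,
             stringsAsFactors = FALSE)
}

#' Does a gene carry an activating-mark peak?
#'
#' True iff any confident peak overlaps the gene body or the strand-aware
#' upstream window (default 2.5 kb 5' of the TSS; to the left of the body
#' on `+` genes, to the right on `-` genes), clipped at position 0 and at
#' the chromosome end when lengths are given.
#'
#' @param genes gene annotation `data.frame`.
#' @param peaks interval `data.frame` of confident peaks.
#' @param upstream window size in bp (default 2500).
#' @param chrom_lengths optional named chromosome lengths for clipping.
#' @return logical vector, one flag per gene.
#' @export
gene_has_active_peak <- function(genes, peaks, upstream = 2500L,
                                 chrom_lengths = NULL) {
  validate_genes(genes)
  ws <- ifelse(genes$strand == "+", pmax(genes$start - upstream, 0), genes$start)
  we <- ifelse(genes$strand == "+", genes$end, genes$end + upstream)
  if (!is.null(chrom_lengths))
    we <- pmin(we, chrom_lengths[genes$chrom])
  win <- genomic_intervals(genes$chrom, ws, we)
  if (nrow(peaks) == 0) return(rep(FALSE, nrow(genes)))
  IRanges::overlapsAny(gi2gr(win), gi2gr(peaks), ignore.strand = TRUE)
}

#' Assign peaks to the nearest transcription start site
#'
#' Each peak is anchored at its midpoint and assigned to the gene whose
#' TSS is nearest on the same chromosome; peaks whose nearest TSS lies
#' more than `max_sep` bp away stay unassigned. Equidistant ties go to the
#' lexicographically smaller `gene_id`. The reported `distance` is signed
#' (`tss - midpoint`), and `tss_distal` flags assigned peaks more than
#' `distal_cut` bp from their TSS.
#'
#' @param peaks interval `data.frame` with a `name` column.
#' @param genes gene annotation `data.frame`.
#' @param max_sep maximum assignment distance (bp, default 25000).
#' @param distal_cut TSS-distal threshold (bp, default 1000).
#' @return `data.frame`: `peak`, `gene_id` (`NA` when unassigned),
#'   `distance`, `tss_distal`.
#' @export
assign_peaks_to_tss <- function(peaks, genes, max_sep = 25000L,
                                distal_cut = 1000L) {
  validate_genes(genes)
  n <- nrow(peaks)
  nm <- if ("name" %in% names(peaks)) peaks$name else sprintf("peak_%d", seq_len(n))
  mid <- floor((peaks$start + peaks$end) / 2)
  gene_id <- rep(NA_character_, n); distance <- rep(NA_real_, n)
  for (chr in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (!length(gi)) next
    ord <- order(genes$tss[gi], genes$gene_id[gi])
    tss <- genes$tss[gi][ord]; gid <- genes$gene_id[gi][ord]
    for (k in pi) {
      d <- abs(tss - mid[k])
      dmin <- min(d)
      if (dmin > max_sep) next
      cand <- which(d == dmin)
      best <- cand[order(gid[cand])[1]]
      gene_id[k] <- gid[best]
      distance[k] <- tss[best] - mid[k]
    }
  }
  data.frame(peak = nm, gene_id = gene_id, distance = distance,
             tss_distal = ifelse(is.na(distance), NA, abs(distance) > distal_cut),
             stringsAsFactors = FALSE)
}
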