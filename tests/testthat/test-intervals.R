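pk <- function(chrom, start, end, enr, q, name = "p") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             enrichment = enr, qvalue = q, stringsAsFactors = FALSE)
}

test_that("peak consolidation applies both replicate and merged thresholds", {
  merged <- pk("c1", 100, 300, 3, 0.001)
  r1 <- pk("c1", 120, 280, 1, 0.01)
  r2 <- pk("c1", 90, 260, 1, 0.01)
  expect_equal(nrow(consolidate_peaks(r1, r2, merged, "narrow")), 1)

  r2bad <- pk("c1", 90, 260, 1, 0.2)
  expect_equal(nrow(consolidate_peaks(r1, r2bad, merged, "narrow")), 0)

  mbad <- pk("c1", 100, 300, 1.5, 0.001)
  expect_equal(nrow(consolidate_peaks(r1, r2, mbad, "narrow")), 0)
})

test_that("retained peaks merge across gaps up to the mode threshold", {
  r <- pk("c1", c(0, 300), c(100, 400), 1, 0.01, c("a", "b"))
  merged <- pk("c1", c(0, 300), c(100, 400), 3, 0.001, c("a", "b"))
  out <- consolidate_peaks(r, r, merged, "narrow")  # gap 200 <= 250
  expect_equal(norm_iv(out), norm_iv(data.frame(chrom = "c1", start = 0, end = 400)))

  far <- pk("c1", c(0, 400), c(100, 500), 3, 0.001, c("a", "b"))
  rfar <- pk("c1", c(0, 400), c(100, 500), 1, 0.01, c("a", "b"))
  out2 <- consolidate_peaks(rfar, rfar, far, "narrow")  # gap 300 > 250
  expect_equal(nrow(out2), 2)
  out3 <- consolidate_peaks(rfar, rfar, far, "broad")   # gap 300 <= 2500
  expect_equal(nrow(out3), 1)
  expect_error(consolidate_peaks(rfar, rfar, far, "bogus"))
})

test_that("consolidation is idempotent under re-merging", {
  set.seed(91)
  r1 <- random_peak_calls(40); r2 <- random_peak_calls(40)
  merged <- random_peak_calls(40)
  out <- consolidate_peaks(r1, r2, merged, "narrow")
  again <- merge_intervals(out, gap = 250)
  expect_equal(out[, c("chrom", "start", "end")],
               again[, c("chrom", "start", "end")])
})

test_that("domain stitching fuses only gap-covered splits", {
  dom <- genomic_intervals("c1", c(0, 200), c(100, 300))
  gap_full <- genomic_intervals("c1", 100, 200)
  fused <- stitch_domains(dom, gap_full)
  expect_equal(norm_iv(fused), norm_iv(data.frame(chrom = "c1", start = 0, end = 300)))

  gap_part <- genomic_intervals("c1", 120, 180)
  expect_equal(nrow(stitch_domains(dom, gap_part)), 2)
  expect_equal(norm_iv(stitch_domains(dom, NULL)), norm_iv(dom))
})

test_that("Polycomb classification is boundary-inclusive at 50%", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                      start = c(0, 2000), end = c(1000, 3000), strand = "+",
                      tss = c(0, 2000), stringsAsFactors = FALSE)
  dom <- genomic_intervals("c1", c(0, 2000), c(500, 2499))
  out <- classify_pcg_targets(genes, dom)
  expect_equal(out$overlap_fraction, c(0.5, 0.499))
  expect_equal(out$pcg_target, c(TRUE, FALSE))
})

test_that("Polycomb classification is invariant to splitting domains", {
  genes <- data.frame(gene_id = "g", chrom = "c1", start = 100, end = 1100,
                      strand = "+", tss = 100, stringsAsFactors = FALSE)
  whole <- genomic_intervals("c1", 0, 700)
  split <- genomic_intervals("c1", c(0, 350), c(350, 700))
  expect_equal(classify_pcg_targets(genes, whole)$overlap_fraction,
               classify_pcg_targets(genes, split)$overlap_fraction)
})

test_that("active-peak window is strand-aware around the TSS", {
  gp <- data.frame(gene_id = "g", chrom = "c1", start = 10000, end = 12000,
                   strand = "+", tss = 10000, stringsAsFactors = FALSE)
  hit <- genomic_intervals("c1", 7600, 7700)    # 2.4 kb upstream
  mis <- genomic_intervals("c1", 7300, 7400)    # 2.6 kb upstream
  expect_true(gene_has_active_peak(gp, hit))
  expect_false(gene_has_active_peak(gp, mis))

  gm <- gp; gm$strand <- "-"; gm$tss <- 11999
  right <- genomic_intervals("c1", 13000, 13100)  # 1 kb past body end
  expect_true(gene_has_active_peak(gm, right))
  expect_false(gene_has_active_peak(gp, right))
})

test_that("peak-to-TSS assignment respects distance cap and ties", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                      start = c(5000, 40000), end = c(6000, 41000),
                      strand = "+", tss = c(5000, 40000), stringsAsFactors = FALSE)
  peaks <- genomic_intervals("c1", 9950, 10050, name = "p1")
  asg <- assign_peaks_to_tss(peaks, genes)
  expect_equal(asg$gene_id, "gA")
  expect_equal(asg$distance, -5000)
  expect_true(asg$tss_distal)

  lone <- data.frame(gene_id = "gC", chrom = "c1", start = 40001, end = 41001,
                     strand = "+", tss = 40001, stringsAsFactors = FALSE)
  far <- assign_peaks_to_tss(genomic_intervals("c1", 9980, 10020, name = "p"), lone)
  expect_true(is.na(far$gene_id))  # nearest TSS 30,001 bp away

  tie <- data.frame(gene_id = c("gZ", "gA"), chrom = "c1",
                    start = c(11000, 8000), end = c(12000, 9001),
                    strand = c("+", "-"), tss = c(11000, 9000),
                    stringsAsFactors = FALSE)
  t_asg <- assign_peaks_to_tss(genomic_intervals("c1", 9950, 10050, name = "p"), tie)
  expect_equal(t_asg$gene_id, "gA")  # equidistant, lexicographically smaller
})

test_that("interval operations match brute-force oracles on random genomes", {
  set.seed(1234)
  for (rep in 1:25) {
    genes <- random_genes(12)
    dom <- merge_intervals(random_intervals(8), gap = 0)
    out <- classify_pcg_targets(genes, dom)
    want <- vapply(seq_len(nrow(genes)), function(i)
      oracle_overlap_fraction(genes$start[i], genes$end[i], dom), 0)
    expect_equal(out$overlap_fraction, want, tolerance = 1e-12)
    expect_equal(out$pcg_target, want >= 0.5)

    peaks <- random_intervals(10)
    peaks$name <- sprintf("p%02d", seq_len(nrow(peaks)))
    asg <- assign_peaks_to_tss(peaks, genes, max_sep = 25000)
    for (i in seq_len(nrow(peaks))) {
      o <- oracle_nearest_tss(floor((peaks$start[i] + peaks$end[i]) / 2),
                              peaks$chrom[i], genes, 25000)
      expect_identical(asg$gene_id[i], o$gene)
      if (!is.na(o$gene)) expect_equal(asg$distance[i], o$dist)
    }

    hits <- gene_has_active_peak(genes, peaks)
    want_hits <- vapply(seq_len(nrow(genes)), function(i)
      oracle_active_peak(genes[i, ], peaks), TRUE)
    expect_identical(hits, want_hits)

    r1 <- random_peak_calls(15); r2 <- random_peak_calls(15)
    merged <- random_peak_calls(15)
    got <- consolidate_peaks(r1, r2, merged, "narrow")
    want_c <- oracle_consolidate(r1, r2, merged, 250)
    expect_equal(norm_iv(got), norm_iv(want_c))
  }
})
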