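test_that("config validation rejects bad fractions, labels and dispersion", {
  expect_error(sim_config(class_fractions = c(unaffected = 0.5)), "sum to 1")
  expect_error(sim_config(class_fractions = c(mystery = 1)), "unknown gene class")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(chrom_lengths = c(chr1 = -5)), "chrom_lengths")
  expect_error(sim_config(conditions = "control"), "at least one perturbed")
})

test_that("identical config and seed give byte-identical datasets", {
  cfg <- sim_config(seed = 11, n_genes = 150, n_peaks = 60, n_noise_peaks = 20,
                    n_motifs = 3, n_tumours = 3, n_controls = 1,
                    variant_private_rate = 5, variant_shared_count = 2)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(serialize(a, NULL, version = 2), serialize(b, NULL, version = 2))
})

test_that("control-group counts match planted negative-binomial moments", {
  cfg <- sim_config(seed = 5, n_genes = 2000, effect_size_lfc = 2)
  sim <- simulate_counts(cfg)
  ctrl <- sim$design$sample_id[sim$design$condition == "control"]
  sf <- sim$truth$size_factors[ctrl]
  z <- sweep(sim$gene_counts[, ctrl], 2, sf, "/")
  mu <- sim$truth$gene_base_mean
  disp <- sim$truth$gene_dispersion
  # SE of the mean of 3 normalized NB draws
  se <- sqrt(rowMeans(outer(mu, 1 / sf) + disp * mu^2) / length(ctrl))
  within3 <- abs(rowMeans(z) - mu) <= 3 * se
  expect_gt(mean(within3), 0.985)  # ~0.3% exceed 3 SE by chance
})

test_that("null simulation yields near-nominal false-positive rate", {
  cfg <- sim_config(seed = 21, n_genes = 2000, effect_size_lfc = 0,
                    class_fractions = c(unaffected = 1))
  sim <- simulate_counts(cfg)
  res <- nb_wald_test(sim$gene_counts, sim$design, c("constant", "control"))
  expect_gt(mean(res$pvalue < 0.05, na.rm = TRUE), 0.03)
  expect_lt(mean(res$pvalue < 0.05, na.rm = TRUE), 0.07)
})

test_that("planted Polycomb flags are recomputable from the emitted files", {
  cfg <- sim_config(seed = 13, n_genes = 300, n_peaks = 50, n_noise_peaks = 20)
  ann <- simulate_annotation(cfg)
  pcg <- classify_pcg_targets(ann$genes, ann$domains)
  expect_identical(stats::setNames(pcg$pcg_target, pcg$gene_id),
                   ann$truth$pcg_flag)
  # flagged genes sit fully inside a domain by construction
  expect_true(all(pcg$overlap_fraction[pcg$pcg_target] == 1))
})

test_that("gap-aware stitching restores the unsplit domains", {
  cfg <- sim_config(seed = 17, n_genes = 400, n_peaks = 50, n_noise_peaks = 0)
  ann <- simulate_annotation(cfg)
  stitched <- stitch_domains(ann$domains_split, ann$assembly_gaps)
  expect_equal(norm_iv(stitched), norm_iv(ann$domains))
})

test_that("consolidation recovers exactly the planted confident peaks", {
  cfg <- sim_config(seed = 19, n_genes = 200, n_peaks = 100, n_noise_peaks = 100)
  ann <- simulate_annotation(cfg)
  got <- consolidate_peaks(ann$peak_calls$rep1, ann$peak_calls$rep2,
                           ann$peak_calls$merged, mode = "narrow")
  want <- ann$peak_intervals[order(ann$peak_intervals$chrom,
                                   ann$peak_intervals$start), ]
  expect_equal(nrow(got), 100)
  expect_equal(norm_iv(got), norm_iv(want))
})

test_that("variant simulation honours sharing and allele-fraction structure", {
  cfg <- sim_config(seed = 23, n_tumours = 5, n_controls = 2,
                    variant_private_rate = 40, variant_shared_count = 6)
  vs <- simulate_variants(cfg)
  # planted carriers appear with exactly their planted multiplicity
  sh <- sharing_spectrum(vs$variants[vs$variants$vtype %in% c("SNV", "InDel"), ],
                         vs$truth$tumour_samples)
  for (key in names(vs$truth$variant_carriers)) {
    expect_equal(sh$carriers$n_samples[sh$carriers$key == key],
                 length(vs$truth$variant_carriers[[key]]))
  }
  # no shared variants planted -> spectrum is all-private
  cfg0 <- sim_config(seed = 23, n_tumours = 5, n_controls = 2,
                     variant_shared_count = 0)
  vs0 <- simulate_variants(cfg0)
  sh0 <- sharing_spectrum(vs0$variants[vs0$variants$vtype %in% c("SNV", "InDel"), ],
                          vs0$truth$tumour_samples)
  expect_true(all(sh0$carriers$n_samples == 1))
  expect_equal(sh0$fraction_private, 1)
})

test_that("written simulation files read back consistently", {
  cfg <- sim_config(seed = 29, n_genes = 120, n_peaks = 40, n_noise_peaks = 10,
                    n_motifs = 2, n_tumours = 3, n_controls = 1,
                    variant_private_rate = 4, variant_shared_count = 1)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_identical(read_counts(file.path(dir, "gene_counts.tsv")), sim$gene_counts)
  genes <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_equal(genes$gene_id, sim$genes$gene_id)
  dom <- read_bed(file.path(dir, "h3k27me3_domains.bed"))
  expect_equal(dom$start, sim$domains$start)
  pw <- read_pwms(file.path(dir, "motifs.jaspar"))
  expect_equal(names(pw), names(sim$pwms))
  expect_equal(pw[[1]]$matrix, sim$pwms[[1]]$matrix, tolerance = 1e-5)
})
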