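#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Inputs
#' come either from `input_dir` (a directory in the layout written by
#' [write_simulation()]) or, when `input_dir` is `NULL`, from an in-memory
#' simulation parameterized by `simulation` (arguments to [sim_config()];
#' the pipeline seed is used as the simulation seed unless overridden).
#' All thresholds default to the analysis constants: DE selection padj
#' 0.05 and |LFC| 1; ATAC selection padj 1e-3, |LFC| 1, log10 baseMean
#' 1.25; Polycomb-target overlap 0.5; TSS assignment 25 kb; upstream
#' window 2.5 kb; merge gaps 250 bp (narrow) / 2.5 kb (broad); motif
#' p-cutoff 5e-4; top 25 motifs; linear-model p 1e-5; allele-fraction cut
#' 0.2; SV support 5; CNV ratio 1.5 / 0.66.
#'
#' @param seed integer master seed.
#' @param input_dir optional directory of input files.
#' @param simulation named list of [sim_config()] overrides.
#' @param thresholds named list of threshold overrides.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L, input_dir = NULL,
                            simulation = list(), thresholds = list()) {
  defaults <- list(de_padj = 0.05, de_lfc = 1,
                   atac_padj = 1e-3, atac_lfc = 1, atac_log10_bm = 1.25,
                   pcg_overlap = 0.5, tss_max_sep = 25000, upstream = 2500,
                   gap_narrow = 250, gap_broad = 2500,
                   motif_p_cutoff = 5e-4, motif_top_k = 25, motif_p_sig = 1e-5,
                   af_cut = 0.2, sv_support = 5,
                   cnv_gain = 1.5, cnv_loss = 0.66,
                   base_mean_floor = 1, som_epochs = 100, label_delta = 0.5)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stop(sprintf("pipeline_config: unknown threshold(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  th <- utils::modifyList(defaults, thresholds)
  if (any(vapply(th, function(x) !is.numeric(x) || x <= 0, TRUE)))
    stop("pipeline_config: thresholds must be positive numbers", call. = FALSE)
  if (!is.null(input_dir)) {
    need <- c("gene_counts.tsv", "peak_counts.tsv", "design.tsv", "genes.tsv",
              "h3k27me3_domains.bed", "variants.tsv", "motifs.jaspar",
              "peak_windows.fa")
    missing <- need[!file.exists(file.path(input_dir, need))]
    if (length(missing))
      stop(sprintf("pipeline_config: missing input file(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(seed = as.integer(seed), input_dir = input_dir,
                 simulation = simulation, thresholds = th),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Stage order: input (read or simulate) -> differential testing (gene and
#' peak contrasts against the matched control) -> gene-side SOM
#' classification with Polycomb-target flags -> ATAC-side SOM
#' classification -> peak-to-gene assignment and TSS-distal fractions ->
#' over-representation tables (Polycomb targets per RNA cluster; ATAC
#' clusters against RNA clusters) -> motif counting and the two-stage
#' motif effect model with dose-response summaries -> somatic-variant
#' spectra. When ground truth is available (simulated input) a
#' truth-comparison section with confusion matrices is added. Every
#' stage's tables are written under `outdir`; a plain-text log records
#' per-stage timing and an input content digest. All floating point
#' output is rounded to 6 decimals so repeated runs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir report directory (created; existing files overwritten).
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  log_path <- file.path(outdir, "pipeline.log")
  cat(sprintf("epireversion pipeline, seed %d\n", config$seed), file = log_path)
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    cat(sprintf("stage %-14s %6.2fs  digest %s\n", name,
                proc.time()[["elapsed"]] - t0, stage_digest(res)),
        file = log_path, append = TRUE)
    res
  }

  dat <- stage("input", load_pipeline_inputs(config))
  truth <- dat$truth

  diffres <- stage("differential", {
    gene_contrasts <- list(
      constant = nb_wald_test(dat$gene_counts, dat$design, c("constant", "control"),
                              base_mean_floor = th$base_mean_floor),
      transient_d9 = nb_wald_test(dat$gene_counts, dat$design, c("transient_d9", "control"),
                                  base_mean_floor = th$base_mean_floor),
      transient_d11 = nb_wald_test(dat$gene_counts, dat$design, c("transient_d11", "control"),
                                   base_mean_floor = th$base_mean_floor))
    control <- nb_wald_test(dat$gene_counts, dat$design, c("no_kd", "control"),
                            base_mean_floor = th$base_mean_floor)
    peak_contrasts <- list(
      constant = nb_wald_test(dat$peak_counts, dat$design, c("constant", "control"),
                              base_mean_floor = th$base_mean_floor),
      transient = nb_wald_test(dat$peak_counts, dat$design, c("transient_d11", "control"),
                               base_mean_floor = th$base_mean_floor))
    list(gene = gene_contrasts, control = control, peak = peak_contrasts)
  })

  intervals <- stage("intervals", {
    domains <- if (!is.null(dat$assembly_gaps) && nrow(dat$assembly_gaps))
      stitch_domains(dat$domains, dat$assembly_gaps) else dat$domains
    pcg <- classify_pcg_targets(dat$genes, domains, th$pcg_overlap)
    consolidated <- if (!is.null(dat$peak_calls))
      consolidate_peaks(dat$peak_calls$rep1, dat$peak_calls$rep2,
                        dat$peak_calls$merged, mode = "narrow") else NULL
    list(domains = domains, pcg = pcg, consolidated = consolidated)
  })
  pcg_flags <- stats::setNames(intervals$pcg$pcg_target, intervals$pcg$gene_id)

  genes_cls <- stage("classify_genes",
    classify_genes(diffres$gene, diffres$control, seed = config$seed,
                   epochs = th$som_epochs, padj_cut = th$de_padj,
                   lfc_cut = th$de_lfc, delta = th$label_delta,
                   pcg_flags = pcg_flags))

  atac_cls <- stage("classify_peaks",
    select_and_cluster_atac(diffres$peak, seed = config$seed,
                            padj_cut = th$atac_padj, lfc_cut = th$atac_lfc,
                            log10_bm_min = th$atac_log10_bm,
                            epochs = th$som_epochs))

  assignment <- stage("assign_peaks", {
    sel <- dat$peak_intervals[dat$peak_intervals$name %in% atac_cls$selected, , drop = FALSE]
    asg <- assign_peaks_to_tss(sel, dat$genes, max_sep = th$tss_max_sep)
    asg$cluster <- atac_cls$classification$cluster[
      match(asg$peak, atac_cls$classification$peak)]
    distal <- stats::aggregate(tss_distal ~ cluster, asg,
                               function(x) mean(x, na.rm = TRUE))
    names(distal)[2] <- "fraction_tss_distal"
    list(assignment = asg, distal = distal)
  })

  enrich <- stage("enrichment", {
    universe <- diffres$gene$constant$feature_id[!is.na(diffres$gene$constant$padj)]
    pcg_set <- list(pcg_targets = intervals$pcg$gene_id[intervals$pcg$pcg_target])
    pcg_tab <- overrepresentation_by_cluster(genes_cls$classification, pcg_set, universe)
    atac_sets <- split(assignment$assignment$gene_id[!is.na(assignment$assignment$gene_id)],
                       assignment$assignment$cluster[!is.na(assignment$assignment$gene_id)])
    names(atac_sets) <- paste0("atac_", names(atac_sets))
    atac_tab <- if (length(atac_sets))
      overrepresentation_by_cluster(genes_cls$classification, atac_sets, universe) else NULL
    list(pcg = pcg_tab, atac = atac_tab, universe = universe)
  })

  motifs <- stage("motif_model", {
    counts <- count_motif_hits(dat$peak_sequences, dat$pwms,
                               p_cutoff = th$motif_p_cutoff)
    tf_gene <- vapply(dat$pwms, `[[`, "", "name")
    mask <- tf_gene %in% enrich$universe
    peak_order <- match(rownames(counts), diffres$peak$constant$feature_id)
    model <- fit_motif_effect_model(
      counts, diffres$peak$constant$log2FoldChange[peak_order],
      diffres$peak$transient$log2FoldChange[peak_order],
      seed = config$seed, expressed_mask = mask,
      top_k = th$motif_top_k, p_sig = th$motif_p_sig)
    dose <- list()
    sel <- model[model$selected, , drop = FALSE]
    for (m in sel$motif)
      dose[[m]] <- motif_dose_response(
        diffres$peak$transient$log2FoldChange[peak_order], counts[, m])
    list(counts = counts, model = model, dose = dose)
  })

  variants <- stage("variants", {
    tum <- if (!is.null(truth$tumour_samples)) truth$tumour_samples else
      grep("^tumour", unique(dat$variants$sample_id), value = TRUE)
    ctl <- if (!is.null(truth$control_samples)) truth$control_samples else
      grep("^control", unique(dat$variants$sample_id), value = TRUE)
    retained <- retention_filter(dat$variants, th$af_cut, th$sv_support,
                                 th$cnv_gain, th$cnv_loss)
    spec <- af_spectrum(dat$variants, cut = th$af_cut)
    shr <- sharing_spectrum(retained[retained$vtype %in% c("SNV", "InDel"), ], tum)
    feat <- feature_distribution(dat$variants, tum, ctl)
    list(retained = retained, af = spec, sharing = shr, features = feat,
         tumour_samples = tum, control_samples = ctl)
  })

  truth_cmp <- if (!is.null(truth$gene_class))
    stage("truth_compare", compare_to_truth(genes_cls, atac_cls, motifs,
                                            variants, intervals, truth))
  else NULL

  res <- list(config = config, data = dat, differential = diffres,
              intervals = intervals, genes = genes_cls, atac = atac_cls,
              assignment = assignment, enrichment = enrich, motifs = motifs,
              variants = variants, truth_comparison = truth_cmp)
  stage("report", write_pipeline_report(res, outdir))
  cat(sprintf("total %.2fs\n", proc.time()[["elapsed"]] - t_all),
      file = log_path, append = TRUE)
  invisible(res)
}

load_pipeline_inputs <- function(config) {
  if (is.null(config$input_dir)) {
    args <- config$simulation
    if (is.null(args$seed)) args$seed <- config$seed
    sim <- simulate_dataset(do.call(sim_config, args))
    return(sim)
  }
  d <- config$input_dir
  gaps_path <- file.path(d, "assembly_gaps.bed")
  list(gene_counts = read_counts(file.path(d, "gene_counts.tsv")),
       peak_counts = read_counts(file.path(d, "peak_counts.tsv")),
       design = read_design(file.path(d, "design.tsv")),
       genes = read_gene_models(file.path(d, "genes.tsv")),
       domains = read_bed(file.path(d, "h3k27me3_domains.bed")),
       assembly_gaps = if (file.exists(gaps_path)) read_bed(gaps_path) else NULL,
       peak_calls = local({
         paths <- file.path(d, sprintf("atac_peaks_%s.narrowPeak", c("rep1", "rep2", "merged")))
         if (!all(file.exists(paths))) return(NULL)
         list(rep1 = read_narrowpeak(paths[1], replicate = "rep1"),
              rep2 = read_narrowpeak(paths[2], replicate = "rep2"),
              merged = read_narrowpeak(paths[3]))
       }),
       peak_intervals = local({
         fa <- Biostrings::readDNAStringSet(file.path(d, "peak_windows.fa"))
         pk <- read_narrowpeak(file.path(d, "atac_peaks_merged.narrowPeak"))
         pk[pk$name %in% names(fa), c("chrom", "start", "end", "name")]
       }),
       peak_sequences = local({
         fa <- Biostrings::readDNAStringSet(file.path(d, "peak_windows.fa"))
         stats::setNames(as.character(fa), names(fa))
       }),
       pwms = read_pwms(file.path(d, "motifs.jaspar")),
       variants = read_variants(file.path(d, "variants.tsv")),
       truth = local({
         tp <- file.path(d, "truth.json")
         if (!file.exists(tp)) return(NULL)
         tr <- jsonlite::read_json(tp, simplifyVector = TRUE)
         tr$gene_class <- unlist(tr$gene_class)
         tr$pcg_flag <- unlist(tr$pcg_flag)
         tr
       }))
}

compare_to_truth <- function(genes_cls, atac_cls, motifs, variants, intervals, truth) {
  canon <- c(irreversible = "irreversible", reversible = "reversible",
             transient_specific = "transient_specific",
             down1 = "down", down2 = "down", down3 = "down",
             control_confound = "unaffected", unaffected = "unaffected")
  pred <- genes_cls$classification
  true_cls <- canon[truth$gene_class[pred$gene_id]]
  pred_cls <- ifelse(startsWith(pred$cluster, "down"), "down", pred$cluster)
  gene_confusion <- table(truth = true_cls, predicted = pred_cls)
  pcg_agree <- mean(intervals$pcg$pcg_target ==
                      truth$pcg_flag[intervals$pcg$gene_id])
  sel <- motifs$model$motif[motifs$model$selected]
  list(gene_confusion = gene_confusion,
       gene_class_recovery = class_recovery(gene_confusion),
       pcg_flag_agreement = pcg_agree,
       selected_motifs = sel)
}

class_recovery <- function(confusion) {
  classes <- intersect(rownames(confusion), colnames(confusion))
  out <- vapply(classes, function(cl) {
    tot <- sum(confusion[cl, ])
    if (tot == 0) NA_real_ else confusion[cl, cl] / tot
  }, 0)
  stats::setNames(out, classes)
}

stage_digest <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  sprintf("%08x", sum(raw * (seq_along(raw) %% 97 + 1)) %% .Machine$integer.max)
}

round_numeric <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_pipeline_report <- function(res, outdir) {
  p <- function(...) file.path(outdir, ...)
  wt <- function(df, name)
    utils::write.table(round_numeric(df), p(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(res$genes$classification, "gene_classification.tsv")
  wt(res$atac$classification, "peak_classification.tsv")
  wt(res$genes$units, "gene_som_units.tsv")
  wt(res$atac$units, "peak_som_units.tsv")
  cl_sizes <- as.data.frame(table(res$genes$classification$cluster),
                            stringsAsFactors = FALSE)
  names(cl_sizes) <- c("cluster", "n_genes")
  pk_sizes <- as.data.frame(table(res$atac$classification$cluster),
                            stringsAsFactors = FALSE)
  names(pk_sizes) <- c("cluster", "n_peaks")
  wt(cl_sizes, "gene_cluster_sizes.tsv")
  wt(pk_sizes, "peak_cluster_sizes.tsv")
  wt(res$intervals$pcg, "pcg_targets.tsv")
  wt(res$enrichment$pcg, "enrichment_pcg_by_cluster.tsv")
  if (!is.null(res$enrichment$atac))
    wt(res$enrichment$atac, "enrichment_atac_by_rna_cluster.tsv")
  wt(res$assignment$assignment, "peak_to_gene.tsv")
  wt(res$assignment$distal, "tss_distal_fractions.tsv")
  wt(res$motifs$model, "motif_effect_model.tsv")
  for (m in names(res$motifs$dose))
    wt(res$motifs$dose[[m]], sprintf("dose_response_%s.tsv", m))
  wt(res$variants$af$histogram, "variant_af_histogram.tsv")
  wt(res$variants$sharing$spectrum, "variant_sharing_spectrum.tsv")
  wt(res$variants$features, "variant_feature_distribution.tsv")
  summary <- list(
    seed = res$config$seed,
    n_genes_selected = sum(res$genes$classification$cluster != "unaffected"),
    n_peaks_selected = nrow(res$atac$classification),
    af_fraction_below_cut = res$variants$af$fraction_below,
    sharing_fraction_private = res$variants$sharing$fraction_private)
  if (!is.null(res$truth_comparison)) {
    summary$gene_class_recovery <- as.list(res$truth_comparison$gene_class_recovery)
    summary$pcg_flag_agreement <- res$truth_comparison$pcg_flag_agreement
    conf <- as.data.frame(res$truth_comparison$gene_confusion)
    wt(conf, "truth_gene_confusion.tsv")
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 6, pretty = TRUE)
  invisible(outdir)
}
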