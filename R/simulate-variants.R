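#' Simulate per-sample somatic variant tables
#'
#' Emulates the variant landscape of tumours arising without recurrent
#' drivers: each tumour and control sample carries mostly private SNVs and
#' InDels with Beta-distributed allele fractions concentrated below 0.2,
#' plus a configurable number of variants planted into two or more tumour
#' samples, and a few structural-variant and copy-number records per
#' tumour. Each record is annotated with a feature category.
#'
#' @param config a [sim_config()] (requires >= 2 tumours, >= 1 control).
#' @return list: `variants` (record `data.frame` in the native TSV layout)
#'   and `truth$variant_carriers` (named list: planted shared-variant key ->
#'   carrier sample ids).
#' @export
simulate_variants <- function(config) {
  validate_sim_config(config)
  if (config$n_tumours < 2 || config$n_controls < 1)
    stop("simulate_variants: need >= 2 tumour and >= 1 control samples", call. = FALSE)
  set.seed(sim_seed(config, "variants"))
  tumours <- sprintf("tumour%02d", seq_len(config$n_tumours))
  controls <- sprintf("control%02d", seq_len(config$n_controls))
  chroms <- names(config$chrom_lengths)
  feats <- c("exon", "intron", "UTR", "intergenic", "other")
  fprob <- c(0.25, 0.40, 0.10, 0.20, 0.05)
  a <- config$af_beta_params[1]; b <- config$af_beta_params[2]
  draw_af <- function(n) pmin(pmax(stats::rbeta(n, a, b), 1e-6), 1)
  new_site <- function(n) {
    chrom <- sample(chroms, n, replace = TRUE)
    pos <- floor(stats::runif(n, 1, config$chrom_lengths[chrom]))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  # private SNV/InDel variants, one Poisson draw per sample
  for (s in c(tumours, controls)) {
    k <- stats::rpois(1, config$variant_private_rate)
    if (k == 0) next
    site <- new_site(k)
    vtype <- sample(c("SNV", "InDel"), k, replace = TRUE, prob = c(0.8, 0.2))
    ins <- vtype == "InDel"
    site$alt[ins] <- paste0(site$ref[ins], "A")
    add(data.frame(sample_id = s, site, vtype = vtype, af = draw_af(k),
                   support = NA_real_, ratio = NA_real_,
                   feature = sample(feats, k, replace = TRUE, prob = fprob),
                   deleterious = stats::runif(k) < 0.05,
                   stringsAsFactors = FALSE))
  }

  # planted shared variants: carried by 2..n_tumours tumour samples
  carriers <- list()
  if (config$variant_shared_count > 0) {
    site <- new_site(config$variant_shared_count)
    for (i in seq_len(config$variant_shared_count)) {
      k <- sample(2:config$n_tumours, 1,
                  prob = 0.5^(seq_len(config$n_tumours - 1)))
      who <- sample(tumours, k)
      af <- draw_af(k)
      key <- sprintf("%s:%d:%s>%s", site$chrom[i], site$pos[i], site$ref[i], site$alt[i])
      carriers[[key]] <- sort(who)
      add(data.frame(sample_id = who, site[rep(i, k), ], vtype = "SNV", af = af,
                     support = NA_real_, ratio = NA_real_,
                     feature = sample(feats, 1, prob = fprob),
                     deleterious = FALSE, stringsAsFactors = FALSE))
    }
  }

  # a few SV / CNV records per tumour
  for (s in tumours) {
    if (config$n_sv > 0) {
      site <- new_site(config$n_sv)
      site$alt <- "<SV>"
      add(data.frame(sample_id = s, site, vtype = "SV", af = NA_real_,
                     support = sample(1:20, config$n_sv, replace = TRUE),
                     ratio = NA_real_,
                     feature = sample(feats, config$n_sv, replace = TRUE, prob = fprob),
                     deleterious = FALSE, stringsAsFactors = FALSE))
    }
    if (config$n_cnv > 0) {
      site <- new_site(config$n_cnv)
      site$alt <- "<CNV>"
      add(data.frame(sample_id = s, site, vtype = "CNV", af = NA_real_,
                     support = NA_real_,
                     ratio = 2^stats::runif(config$n_cnv, -1.5, 1.5),
                     feature = sample(feats, config$n_cnv, replace = TRUE, prob = fprob),
                     deleterious = FALSE, stringsAsFactors = FALSE))
    }
  }

  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  validate_variants(variants, where = "simulate_variants")
  list(variants = variants,
       truth = list(variant_carriers = carriers,
                    tumour_samples = tumours, control_samples = controls))
}

#' Simulate the complete synthetic dataset
#'
#' Convenience wrapper running [simulate_counts()], [simulate_annotation()]
#' and [simulate_variants()] under one config and merging their truth
#' records.
#'
#' @param config a [sim_config()].
#' @return list with all generator outputs plus a merged `truth`.
#' @export
simulate_dataset <- function(config) {
  cnt <- simulate_counts(config)
  ann <- simulate_annotation(config)
  var <- simulate_variants(config)
  truth <- c(cnt$truth, ann$truth, var$truth)
  c(cnt[setdiff(names(cnt), "truth")],
    ann[setdiff(names(ann), "truth")],
    var["variants"],
    list(truth = truth, config = config))
}

#' Write a simulated dataset to disk
#'
#' Emits every file the pipeline reads: gene models TSV, domain and
#' assembly-gap BED, per-replicate narrowPeak-like TSVs, counts and design
#' TSVs, variants TSV, JASPAR-like PWM text, peak-window FASTA, and a
#' ground-truth JSON.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_gene_models(sim$genes, p("genes.tsv"))
  write_bed(sim$domains, p("h3k27me3_domains.bed"))
  write_bed(sim$domains_split, p("h3k27me3_domains_split.bed"))
  if (nrow(sim$assembly_gaps)) write_bed(sim$assembly_gaps, p("assembly_gaps.bed"))
  for (r in names(sim$peak_calls))
    write_narrowpeak(sim$peak_calls[[r]], p(sprintf("atac_peaks_%s.narrowPeak", r)))
  write_counts(sim$gene_counts, p("gene_counts.tsv"))
  write_counts(sim$peak_counts, p("peak_counts.tsv"))
  write_design(sim$design, p("design.tsv"))
  write_variants(sim$variants, p("variants.tsv"))
  write_pwms(sim$pwms, p("motifs.jaspar"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$peak_sequences), p("peak_windows.fa"))
  truth <- sim$truth
  truth$peak_motif_counts <- as.data.frame(truth$peak_motif_counts)
  truth$gene_lfc <- as.data.frame(truth$gene_lfc)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
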