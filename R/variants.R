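#' Retention filter for somatic variants
#'
#' Post-calling retention rules: SNVs and InDels are kept iff their allele
#' fraction is strictly greater than `af_cut` (default 0.2); structural
#' variants iff supported by at least `sv_support` reads (default 5,
#' boundary inclusive); CNVs iff the copy ratio is strictly above
#' `cnv_gain` (duplication, default 1.5) or strictly below `cnv_loss`
#' (deletion, default 0.66).
#'
#' @param variants variant `data.frame` ([read_variants()] layout).
#' @param af_cut,sv_support,cnv_gain,cnv_loss thresholds.
#' @return the retained subset of `variants`.
#' @export
retention_filter <- function(variants, af_cut = 0.2, sv_support = 5,
                             cnv_gain = 1.5, cnv_loss = 0.66) {
  validate_variants(variants, where = "retention_filter")
  if (!nrow(variants)) return(variants)
  sn <- variants$vtype %in% c("SNV", "InDel")
  sv <- variants$vtype == "SV"
  cn <- variants$vtype == "CNV"
  if (any(sn & is.na(variants$af)))
    stop("retention_filter: SNV/InDel record without allele fraction", call. = FALSE)
  if (any(sv & is.na(variants$support)))
    stop("retention_filter: SV record without support reads", call. = FALSE)
  if (any(cn & is.na(variants$ratio)))
    stop("retention_filter: CNV record without copy ratio", call. = FALSE)
  keep <- (sn & variants$af > af_cut) |
    (sv & variants$support >= sv_support) |
    (cn & (variants$ratio > cnv_gain | variants$ratio < cnv_loss))
  variants[keep, , drop = FALSE]
}

#' Allele-fraction spectrum of SNVs and InDels
#'
#' Histogram of allele fractions plus the fraction strictly below `cut`
#' (reported as `NA` for empty input).
#'
#' @param variants variant `data.frame`; only SNV/InDel rows are used.
#' @param cut low-fraction threshold (default 0.2).
#' @param breaks histogram breaks over (0, 1].
#' @return list: `histogram` (`data.frame` bin_lo, bin_hi, n),
#'   `fraction_below` (of `cut`), `n`.
#' @export
af_spectrum <- function(variants, cut = 0.2, breaks = seq(0, 1, by = 0.05)) {
  af <- variants$af[variants$vtype %in% c("SNV", "InDel")]
  af <- af[!is.na(af)]
  if (!length(af))
    return(list(histogram = data.frame(bin_lo = numeric(), bin_hi = numeric(),
                                       n = integer()),
                fraction_below = NA_real_, n = 0L))
  n_bin <- as.integer(table(cut(af, breaks, include.lowest = TRUE, right = TRUE)))
  list(histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1], n = n_bin),
       fraction_below = mean(af < cut), n = length(af))
}

#' Cross-sample sharing spectrum
#'
#' For every distinct variant key `(chrom, pos, ref, alt)`, the number of
#' distinct tumour samples carrying it, plus the histogram over carrier
#' counts and the fraction of variants private to one sample. Duplicate
#' `(sample, key)` pairs are deduplicated with a warning; records from
#' non-tumour samples are ignored.
#'
#' @param variants variant `data.frame`.
#' @param tumour_samples character vector of tumour sample ids.
#' @return list: `carriers` (`data.frame` key, n_samples),
#'   `spectrum` (`data.frame` n_samples, n_variants),
#'   `fraction_private`.
#' @export
sharing_spectrum <- function(variants, tumour_samples) {
  v <- variants[variants$sample_id %in% tumour_samples, , drop = FALSE]
  key <- sprintf("%s:%d:%s>%s", v$chrom, as.integer(v$pos), v$ref, v$alt)
  pair <- paste(v$sample_id, key, sep = "|")
  if (anyDuplicated(pair)) {
    warning("duplicate (sample, variant) records deduplicated")
    keep <- !duplicated(pair)
    v <- v[keep, , drop = FALSE]; key <- key[keep]
  }
  if (!nrow(v))
    return(list(carriers = data.frame(key = character(), n_samples = integer()),
                spectrum = data.frame(n_samples = integer(), n_variants = integer()),
                fraction_private = NA_real_))
  cnt <- tapply(v$sample_id, key, function(s) length(unique(s)))
  carriers <- data.frame(key = names(cnt), n_samples = as.integer(cnt),
                         row.names = NULL, stringsAsFactors = FALSE)
  carriers <- carriers[order(carriers$key), , drop = FALSE]
  tab <- table(carriers$n_samples)
  list(carriers = carriers,
       spectrum = data.frame(n_samples = as.integer(names(tab)),
                             n_variants = as.integer(tab)),
       fraction_private = mean(carriers$n_samples == 1))
}

#' Feature-category distribution of variant groups
#'
#' Normalized proportions over feature categories (exon, intron, UTR,
#' intergenic, other) for two groups: variants found in any control
#' sample, and variants shared between at least `min_shared` tumour
#' samples. Unknown categories are bucketed as `other` with a warning;
#' empty groups yield all-`NA` proportions.
#'
#' @param variants variant `data.frame`.
#' @param tumour_samples,control_samples sample id vectors.
#' @param min_shared tumour-sharing threshold for the second group
#'   (default 2).
#' @return `data.frame`: group, feature, n, proportion.
#' @export
feature_distribution <- function(variants, tumour_samples, control_samples,
                                 min_shared = 2L) {
  cats <- c("exon", "intron", "UTR", "intergenic", "other")
  feat <- variants$feature
  if (any(!feat %in% cats)) {
    warning("unknown feature categor(ies) bucketed as 'other'")
    feat[!feat %in% cats] <- "other"
  }
  key <- sprintf("%s:%d:%s>%s", variants$chrom, as.integer(variants$pos),
                 variants$ref, variants$alt)
  in_control <- key %in% key[variants$sample_id %in% control_samples]
  sh <- sharing_spectrum(variants, tumour_samples)
  shared_keys <- sh$carriers$key[sh$carriers$n_samples >= min_shared]
  groups <- list(control_found = which(in_control & !duplicated(key)),
                 shared_tumours = which(key %in% shared_keys & !duplicated(key)))
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    n <- as.integer(table(factor(feat[idx], levels = cats)))
    prop <- if (length(idx)) n / length(idx) else rep(NA_real_, length(cats))
    data.frame(group = g, feature = cats, n = n, proportion = prop,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
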