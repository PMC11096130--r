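#' Simulation configuration
#'
#' Parameterizes the synthetic multi-omic dataset: a reference condition
#' (`control`, the temperature-matched RNAi-against-an-irrelevant-gene
#' group), a `no_kd` control (used for the control-vs-control exclusion
#' contrast), a `constant` knock-down and two `transient` knock-down
#' timepoints. Gene classes are planted with log2 fold-change patterns
#' relative to `control`:
#'
#' * `irreversible`: up in constant and both transient timepoints
#' * `reversible`: up in constant only
#' * `transient_specific`: up in transient only
#' * `down1` / `down2` / `down3`: the mirrored down-regulated patterns
#' * `unaffected`: no change
#' * `control_confound`: changed in the no-KD control contrast only
#'   (exercises the exclusion path of gene selection; fraction 0 by default)
#'
#' Counts are negative binomial with `variance = mean + dispersion * mean^2`.
#' Per-gene dispersions are gamma-distributed with mean `dispersion` and
#' shape `dispersion_shape` (`Inf` gives a constant dispersion).
#'
#' All randomness flows from `seed` through fixed substreams (one per
#' generated layer: gene counts, peak counts, annotation, motif counts,
#' sequences, variants), so the generators can be called in any order and
#' still agree on shared structures such as planted motif counts.
#'
#' @param seed integer root seed.
#' @param n_genes,n_peaks numbers of gene and accessibility-peak features.
#' @param n_noise_peaks peaks planted to fail the consolidation rule.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param class_fractions named gene-class fractions summing to 1.
#' @param peak_class_fractions named peak-class fractions summing to 1
#'   (classes `irreversible`, `reversible`, `decreased`, `unaffected`).
#' @param n_replicates replicates per condition.
#' @param conditions condition labels; the first is the reference.
#' @param base_mean_log_range log10 bounds for baseline mean counts.
#' @param dispersion mean NB dispersion.
#' @param dispersion_shape gamma shape for per-gene dispersion (`Inf` =
#'   constant).
#' @param effect_size_lfc planted |log2 fold change| for perturbed classes.
#' @param n_motifs number of PWMs in the synthetic collection.
#' @param motif_betas named numeric: per-count linear effect of each motif
#'   on peak log2 fold change (motifs not named have effect 0).
#' @param motif_count_rate Poisson rate of planted occurrences per peak.
#' @param peak_lfc_noise_sd s.d. of the noise on peak log2 fold changes.
#' @param background nucleotide frequencies (A, C, G, T) of the synthetic
#'   genome sequence.
#' @param pcg_prob_perturbed,pcg_prob_background probability that a
#'   perturbed-class (resp. other) gene is planted as a Polycomb target.
#' @param n_tumours,n_controls samples in the variant simulation.
#' @param variant_private_rate mean private SNV/InDel variants per sample.
#' @param variant_shared_count variants planted in two or more tumours.
#' @param af_beta_params `c(a, b)` of the Beta allele-fraction law.
#' @param n_sv,n_cnv structural / copy-number records per tumour sample.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_peaks = 1000L,
                       n_noise_peaks = 200L,
                       chrom_lengths = c(chr2L = 8e6, chr2R = 8e6, chr3L = 8e6),
                       class_fractions = c(irreversible = 0.05, reversible = 0.05,
                                           transient_specific = 0.05,
                                           down1 = 0.05, down2 = 0.05, down3 = 0.05,
                                           control_confound = 0, unaffected = 0.70),
                       peak_class_fractions = c(irreversible = 0.10, reversible = 0.25,
                                                decreased = 0.15, unaffected = 0.50),
                       n_replicates = 3L,
                       conditions = c("control", "no_kd", "constant",
                                      "transient_d9", "transient_d11"),
                       base_mean_log_range = c(1, 3),
                       dispersion = 0.05,
                       dispersion_shape = Inf,
                       effect_size_lfc = 2,
                       n_motifs = 8L,
                       motif_betas = c(MOTIF1 = 0.5, MOTIF2 = -0.5),
                       motif_count_rate = 0.5,
                       peak_lfc_noise_sd = 0.5,
                       background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       pcg_prob_perturbed = 0.8,
                       pcg_prob_background = 0.10,
                       n_tumours = 12L,
                       n_controls = 4L,
                       variant_private_rate = 30,
                       variant_shared_count = 15,
                       af_beta_params = c(1, 9),
                       n_sv = 3L,
                       n_cnv = 3L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

GENE_CLASSES <- c("irreversible", "reversible", "transient_specific",
                  "down1", "down2", "down3", "control_confound", "unaffected")
PEAK_CLASSES <- c("irreversible", "reversible", "decreased", "unaffected")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_genes", "n_peaks", "n_noise_peaks", "n_replicates",
              "n_motifs", "n_tumours", "n_controls", "n_sv", "n_cnv")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("sim_config: %s must be a non-negative count", f), call. = FALSE)
  if (any(cfg$chrom_lengths <= 0) || is.null(names(cfg$chrom_lengths)))
    stop("sim_config: chrom_lengths must be named and positive", call. = FALSE)
  unknown <- setdiff(names(cfg$class_fractions), GENE_CLASSES)
  if (length(unknown))
    stop(sprintf("sim_config: unknown gene class label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9)
    stop("sim_config: class_fractions must sum to 1", call. = FALSE)
  unknownp <- setdiff(names(cfg$peak_class_fractions), PEAK_CLASSES)
  if (length(unknownp))
    stop(sprintf("sim_config: unknown peak class label(s): %s",
                 paste(unknownp, collapse = ", ")), call. = FALSE)
  if (abs(sum(cfg$peak_class_fractions) - 1) > 1e-9)
    stop("sim_config: peak_class_fractions must sum to 1", call. = FALSE)
  if (cfg$dispersion <= 0)
    stop("sim_config: dispersion must be positive", call. = FALSE)
  if (length(cfg$conditions) < 2)
    stop("sim_config: need a control and at least one perturbed condition", call. = FALSE)
  if (!all(c("control", "constant") %in% cfg$conditions))
    stop("sim_config: conditions must include 'control' and 'constant'", call. = FALSE)
  if (any(cfg$af_beta_params <= 0))
    stop("sim_config: af_beta_params must be positive", call. = FALSE)
  if (abs(sum(cfg$background) - 1) > 1e-6 || any(cfg$background <= 0))
    stop("sim_config: background must be positive and sum to 1", call. = FALSE)
  invisible(cfg)
}

# Substream scheme: every generated layer seeds R's RNG with
# (seed * 1009 + stream) mod 2^31-1, streams fixed per layer below.
SIM_STREAMS <- c(gene_counts = 1L, peak_counts = 2L, annotation = 3L,
                 motif_counts = 4L, sequences = 5L, variants = 6L,
                 pwms = 7L, peak_calls = 8L, gene_classes = 9L,
                 peak_classes = 10L)

sim_seed <- function(cfg, stream) {
  s <- SIM_STREAMS[[stream]]
  as.integer((as.numeric(cfg$seed) * 1009 + s) %% (2^31 - 1))
}

# planted log2 fold change of each gene class under each non-reference
# condition (relative to 'control')
gene_class_lfc <- function(class, condition, effect) {
  up_const <- class %in% c("irreversible", "reversible")
  up_trans <- class %in% c("irreversible", "transient_specific")
  dn_const <- class %in% c("down1", "down2")
  dn_trans <- class %in% c("down1", "down3")
  lfc <- numeric(length(class))
  if (condition == "no_kd") {
    lfc[class == "control_confound"] <- effect
    return(lfc)
  }
  if (condition == "constant") {
    lfc[up_const] <- effect
    lfc[dn_const] <- -effect
  } else if (grepl("^transient", condition)) {
    lfc[up_trans] <- effect
    lfc[dn_trans] <- -effect
  }
  lfc
}

peak_class_lfc <- function(class, condition, effect) {
  lfc <- numeric(length(class))
  if (condition == "constant") {
    lfc[class %in% c("irreversible", "reversible")] <- effect
    lfc[class == "decreased"] <- -effect
  } else if (grepl("^transient", condition)) {
    lfc[class == "irreversible"] <- effect
    lfc[class == "decreased"] <- -effect
  }
  lfc
}
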