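#' Simulate gene- and peak-level count matrices with planted truth
#'
#' Draws negative-binomial counts for every gene and accessibility peak
#' under every condition of the design. The mean for feature i in sample j
#' is `baseline_i * 2^lfc(class_i, condition_j) * size_factor_j`, with
#' `size = 1/dispersion_i` (so `variance = mean + dispersion * mean^2`).
#' Sample size factors are log-uniform in `[0.5, 2]`. Peak fold changes
#' additionally carry a linear motif-dose term `X beta` plus Gaussian
#' noise, where `X` are the planted per-peak motif counts (shared, via a
#' fixed RNG substream, with the sequence generator).
#'
#' @param config a [sim_config()].
#' @return list with elements `gene_counts`, `peak_counts` (integer
#'   matrices), `design` (`data.frame`), and `truth` (planted gene classes,
#'   Polycomb flags are added by [simulate_annotation()], planted peak
#'   classes/effects and motif counts).
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  design <- sim_design(config)
  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  peak_ids <- sprintf("peak%05d", seq_len(config$n_peaks))

  gene_class <- planted_gene_classes(config)
  set.seed(sim_seed(config, "gene_counts"))
  base_mean <- 10^stats::runif(config$n_genes, config$base_mean_log_range[1],
                               config$base_mean_log_range[2])
  disp <- draw_dispersions(config$n_genes, config$dispersion, config$dispersion_shape)
  sf <- 2^stats::runif(nrow(design), -1, 1)
  names(sf) <- design$sample_id

  gene_lfc <- sapply(config$conditions, function(cond) {
    if (cond == "control") numeric(config$n_genes)
    else gene_class_lfc(gene_class, cond, config$effect_size_lfc)
  })
  gene_counts <- draw_nb_matrix(base_mean, disp, gene_lfc, design, sf)
  dimnames(gene_counts) <- list(gene_ids, design$sample_id)

  # planted motif counts (substream shared with the sequence generator)
  X <- planted_motif_counts(config)
  rownames(X) <- peak_ids

  peak_class <- planted_peak_classes(config)
  set.seed(sim_seed(config, "peak_counts"))
  peak_base <- 10^stats::runif(config$n_peaks, config$base_mean_log_range[1],
                               config$base_mean_log_range[2])
  peak_disp <- draw_dispersions(config$n_peaks, config$dispersion, config$dispersion_shape)
  beta <- numeric(config$n_motifs)
  names(beta) <- colnames(X)
  common <- intersect(names(config$motif_betas), names(beta))
  beta[common] <- config$motif_betas[common]
  dose <- as.numeric(X %*% beta)
  eff_const <- dose + stats::rnorm(config$n_peaks, 0, config$peak_lfc_noise_sd)
  eff_trans <- dose + stats::rnorm(config$n_peaks, 0, config$peak_lfc_noise_sd)
  peak_lfc <- sapply(config$conditions, function(cond) {
    base <- peak_class_lfc(peak_class, cond, config$effect_size_lfc)
    if (cond == "constant") base + eff_const
    else if (grepl("^transient", cond)) base + eff_trans
    else base
  })
  peak_counts <- draw_nb_matrix(peak_base, peak_disp, peak_lfc, design, sf)
  dimnames(peak_counts) <- list(peak_ids, design$sample_id)

  truth <- list(
    gene_class = stats::setNames(gene_class, gene_ids),
    gene_base_mean = stats::setNames(base_mean, gene_ids),
    gene_dispersion = stats::setNames(disp, gene_ids),
    gene_lfc = structure(gene_lfc, dimnames = list(gene_ids, config$conditions)),
    size_factors = sf,
    peak_class = stats::setNames(peak_class, peak_ids),
    peak_motif_counts = X,
    peak_effect_constant = stats::setNames(eff_const + peak_class_lfc(peak_class, "constant", config$effect_size_lfc), peak_ids),
    peak_effect_transient = stats::setNames(eff_trans + peak_class_lfc(peak_class, "transient_d11", config$effect_size_lfc), peak_ids))

  list(gene_counts = gene_counts, peak_counts = peak_counts,
       design = design, truth = truth)
}

sim_design <- function(config) {
  grid <- expand.grid(replicate = sprintf("rep%d", seq_len(config$n_replicates)),
                      condition = config$conditions, stringsAsFactors = FALSE)
  data.frame(sample_id = paste(grid$condition, grid$replicate, sep = "_"),
             condition = grid$condition,
             rnai_target = ifelse(grid$condition == "control", "w",
                           ifelse(grid$condition == "no_kd", "none", "ph")),
             replicate = grid$replicate,
             matched_control = ifelse(grid$condition == "control", "", "control"),
             stringsAsFactors = FALSE)
}

planted_gene_classes <- function(config) {
  set.seed(sim_seed(config, "gene_classes"))
  plant_classes(config$n_genes, config$class_fractions)
}

planted_peak_classes <- function(config) {
  set.seed(sim_seed(config, "peak_classes"))
  plant_classes(config$n_peaks, config$peak_class_fractions)
}

plant_classes <- function(n, fractions) {
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    # leftover features go to the largest class (deterministic)
    k <- which.max(fractions)
    counts[k] <- counts[k] + rem
  }
  cls <- rep(names(fractions), counts)
  sample(cls)
}

draw_dispersions <- function(n, mean_disp, shape) {
  if (is.infinite(shape)) return(rep(mean_disp, n))
  d <- stats::rgamma(n, shape = shape, scale = mean_disp / shape)
  pmax(d, 1e-6)
}

draw_nb_matrix <- function(base_mean, disp, lfc_by_cond, design, sf) {
  n <- length(base_mean)
  m <- matrix(0L, nrow = n, ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    mu <- base_mean * 2^lfc_by_cond[, design$condition[j]] * sf[design$sample_id[j]]
    m[, j] <- stats::rnbinom(n, mu = mu, size = 1 / disp)
  }
  storage.mode(m) <- "integer"
  m
}

planted_motif_counts <- function(config) {
  set.seed(sim_seed(config, "motif_counts"))
  X <- matrix(stats::rpois(config$n_peaks * config$n_motifs, config$motif_count_rate),
              nrow = config$n_peaks, ncol = config$n_motifs)
  colnames(X) <- sprintf("MOTIF%d", seq_len(config$n_motifs))
  X
}
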