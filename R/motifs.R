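#' @title PWM scanning with exact p-value thresholds
#' @description Log-odds position-weight-matrix matching. Scores are
#'   discretized at a fixed granularity (default 1e-3, floor rounding) and
#'   the match statistic is the discretized score sum; the background
#'   score distribution of that statistic is then computed by *exact*
#'   dynamic programming, so the threshold's tail probability never
#'   exceeds the requested p-cutoff. Scanning uses the same discretized
#'   scores on both strands.
#' @name motif_scanning
NULL

BASES <- c("A", "C", "G", "T")

# discretized integer log2-odds scores (4 x L), floor rounding
pwm_int_scores <- function(pwm, background, pseudocount = 0.008,
                           granularity = 1e-3) {
  m <- pwm$matrix
  stopifnot(nrow(m) == 4)
  if (any(abs(colSums(m) - 1) > 1e-6))
    stop(sprintf("PWM %s: position probabilities must sum to 1", pwm$id), call. = FALSE)
  if (any(background <= 0)) stop("background frequencies must be positive", call. = FALSE)
  if (pseudocount <= 0 && any(m == 0))
    stop(sprintf("PWM %s: zero probability cell and no pseudocount", pwm$id), call. = FALSE)
  p <- sweep(m + pseudocount, 2, colSums(m + pseudocount), "/")
  lo <- log2(p / background)
  matrix(as.integer(floor(lo / granularity)), 4, ncol(m),
         dimnames = list(BASES, NULL))
}

#' Exact score threshold at a match p-value cutoff
#'
#' Computes, by dynamic programming over the exact distribution of the
#' discretized log-odds score under the background model, the minimal
#' threshold `t` with `P_bg(score >= t) <= p_cutoff`.
#'
#' @param pwm a PWM (list with `id` and 4 x L probability `matrix`).
#' @param p_cutoff match p-value cutoff (default 5e-4).
#' @param background nucleotide frequencies (A, C, G, T).
#' @param pseudocount added to probabilities before log-odds (default
#'   0.008).
#' @param granularity score discretization step (default 1e-3).
#' @return list: `threshold` (integer, on the discretized scale),
#'   `granularity`, `scores` (4 x L integer matrix), `p_attained` (exact
#'   tail probability at the threshold).
#' @export
pwm_threshold <- function(pwm, p_cutoff = 5e-4,
                          background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          pseudocount = 0.008, granularity = 1e-3) {
  if (p_cutoff <= 0 || p_cutoff > 1) stop("p_cutoff must lie in (0, 1]", call. = FALSE)
  U <- pwm_int_scores(pwm, background, pseudocount, granularity)
  L <- ncol(U)
  # exact distribution of the integer score sum, by positionwise convolution
  cur_lo <- min(U[, 1]); cur <- numeric(max(U[, 1]) - cur_lo + 1L)
  for (b in 1:4) cur[U[b, 1] - cur_lo + 1L] <- cur[U[b, 1] - cur_lo + 1L] + background[b]
  if (L > 1) for (j in 2:L) {
    new_lo <- cur_lo + min(U[, j])
    new <- numeric(length(cur) + max(U[, j]) - min(U[, j]))
    for (b in 1:4) {
      off <- U[b, j] - min(U[, j])
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + background[b] * cur
    }
    cur <- new; cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(cur)))
  # minimal *achievable* score whose exact tail fits under the cutoff
  ok <- which(tail <= p_cutoff & cur > 0)
  if (length(ok)) {
    k <- ok[1]
    thr <- cur_lo + k - 1L
    p_att <- tail[k]
  } else {
    thr <- cur_lo + length(cur)  # above the maximum: nothing matches
    p_att <- 0
  }
  if (p_cutoff >= 1) { thr <- cur_lo; p_att <- 1 }
  list(threshold = as.integer(thr), granularity = granularity, scores = U,
       p_attained = unname(p_att))
}

# integer scores of every window position on one strand; NA bases -> -Inf
scan_scores <- function(codes, U) {
  L <- ncol(U); np <- length(codes) - L + 1L
  if (np < 1) return(numeric(0))
  s <- numeric(np)
  for (i in seq_len(L)) {
    v <- U[, i][codes[i:(i + np - 1L)]]
    v[is.na(v)] <- -1e9
    s <- s + v
  }
  s
}

revcomp_scores <- function(U) {
  U[c(4, 3, 2, 1), rev(seq_len(ncol(U))), drop = FALSE]
}

#' Count motif hits in peak-window sequences
#'
#' Scans every sequence with every PWM on both strands at the exact
#' p-value threshold of [pwm_threshold()]. A position matching on both
#' strands counts once; overlapping hits of the same motif are collapsed
#' greedily left-to-right to the best-scoring position. Sequences shorter
#' than a motif contribute a zero count with a warning.
#'
#' @param sequences named character vector of window sequences (typically
#'   peak centre +/- 250 bp).
#' @param pwms list of PWMs.
#' @param background nucleotide frequencies; defaults to the frequencies
#'   observed in `sequences` ("genome" background).
#' @param p_cutoff match p-value cutoff (default 5e-4).
#' @param pseudocount,granularity see [pwm_threshold()].
#' @return integer matrix, sequences x motifs.
#' @export
count_motif_hits <- function(sequences, pwms,
                             background = NULL, p_cutoff = 5e-4,
                             pseudocount = 0.008, granularity = 1e-3) {
  if (is.null(background)) background <- sequence_background(sequences)
  codes_list <- lapply(strsplit(toupper(sequences), ""), match, BASES)
  out <- matrix(0L, length(sequences), length(pwms),
                dimnames = list(names(sequences), names(pwms)))
  warned <- FALSE
  for (k in seq_along(pwms)) {
    th <- pwm_threshold(pwms[[k]], p_cutoff, background, pseudocount, granularity)
    U <- th$scores; Urc <- revcomp_scores(U); L <- ncol(U)
    for (i in seq_along(codes_list)) {
      codes <- codes_list[[i]]
      if (length(codes) < L) {
        if (!warned) { warning("sequence shorter than motif; counted 0"); warned <- TRUE }
        next
      }
      fs <- scan_scores(codes, U)
      rs <- scan_scores(codes, Urc)
      sc <- pmax(fs, rs)
      hits <- which(sc >= th$threshold)
      out[i, k] <- dedup_hits(hits, sc[hits], L)
    }
  }
  out
}

# greedy left-to-right collapse of overlapping hits to the best scorer
dedup_hits <- function(pos, score, L) {
  if (!length(pos)) return(0L)
  count <- 0L
  cur_pos <- -Inf; cur_score <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] >= cur_pos + L) {
      count <- count + 1L
      cur_pos <- pos[i]; cur_score <- score[i]
    } else if (score[i] > cur_score) {
      cur_pos <- pos[i]; cur_score <- score[i]
    }
  }
  count
}

#' Nucleotide background frequencies of a sequence set
#' @param sequences character vector.
#' @return named frequencies over A, C, G, T (positive, summing to 1).
#' @export
sequence_background <- function(sequences) {
  tab <- table(factor(unlist(strsplit(toupper(sequences), "")), levels = BASES))
  f <- as.numeric(tab) + 1  # +1 keeps all four strictly positive
  stats::setNames(f / sum(f), BASES)
}

#' Two-stage motif effect model on accessibility fold changes
#'
#' Stage one fits two LASSO regressions (one per contrast) of peak log2
#' fold change on motif counts over the lambda grid
#' `10^seq(2, -3, by = -0.1)` with standardized predictors and 5-fold
#' cross-validation (seeded fold split; penalty at the CV-minimum
#' lambda). Motifs are ranked by the larger of their two absolute LASSO
#' coefficients; the top `top_k` (default 25; coefficient pairs that are
#' both zero are never ranked in) are carried into stage two, which
#' refits two ordinary least-squares models and reports per-motif t
#' values and two-sided p-values. A motif is `selected` when its OLS p
#' falls below `p_sig` (default 1e-5) in at least one model.
#'
#' @param counts integer matrix, peaks x motifs.
#' @param lfc_constant,lfc_transient numeric responses per peak.
#' @param seed seed for the CV fold split.
#' @param expressed_mask optional logical/character selector of motifs
#'   whose transcription factor passed expression filtering; other motifs
#'   are excluded before fitting.
#' @param top_k motifs carried into the OLS refit (default 25).
#' @param p_sig OLS significance cutoff (default 1e-5).
#' @return `data.frame` (one row per fitted motif): `motif`,
#'   `coef_constant`, `coef_transient`, `t_constant`, `t_transient`,
#'   `p_constant`, `p_transient`, `in_top`, `selected`.
#' @export
fit_motif_effect_model <- function(counts, lfc_constant, lfc_transient,
                                   seed = 1L, expressed_mask = NULL,
                                   top_k = 25L, p_sig = 1e-5) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (n < 50) stop("fit_motif_effect_model: fewer than 50 peaks (unstable CV)", call. = FALSE)
  stopifnot(length(lfc_constant) == n, length(lfc_transient) == n)
  if (!is.null(expressed_mask)) counts <- counts[, expressed_mask, drop = FALSE]
  motifs <- colnames(counts)
  res <- data.frame(motif = motifs,
                    coef_constant = 0, coef_transient = 0,
                    t_constant = NA_real_, t_transient = NA_real_,
                    p_constant = NA_real_, p_transient = NA_real_,
                    in_top = FALSE, selected = FALSE,
                    stringsAsFactors = FALSE)
  informative <- apply(counts, 2, function(x) stats::var(x) > 0)
  if (sum(informative) >= 2) {
    x <- counts[, informative, drop = FALSE]
    lambdas <- 10^seq(2, -3, by = -0.1)
    set.seed(seed)
    foldid <- sample(rep_len(1:5, n))
    coef_at_min <- function(y) {
      cv <- glmnet::cv.glmnet(x, y, lambda = lambdas, standardize = TRUE,
                              foldid = foldid)
      as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    }
    res$coef_constant[informative] <- coef_at_min(lfc_constant)
    res$coef_transient[informative] <- coef_at_min(lfc_transient)
  }
  strength <- pmax(abs(res$coef_constant), abs(res$coef_transient))
  nonzero <- which(strength > 0)
  top <- nonzero[order(strength[nonzero], decreasing = TRUE)]
  top <- top[seq_len(min(top_k, length(top)))]
  res$in_top[top] <- TRUE
  if (length(top)) {
    xt <- counts[, top, drop = FALSE]
    for (contrast in c("constant", "transient")) {
      y <- if (contrast == "constant") lfc_constant else lfc_transient
      fit <- summary(stats::lm(y ~ xt))$coefficients
      rows <- match(paste0("xt", res$motif[top]), rownames(fit))
      res[top, paste0("t_", contrast)] <- fit[rows, "t value"]
      res[top, paste0("p_", contrast)] <- fit[rows, "Pr(>|t|)"]
    }
    res$selected <- res$in_top &
      (pmin(res$p_constant, res$p_transient, na.rm = TRUE) < p_sig) &
      !(is.na(res$p_constant) & is.na(res$p_transient))
  }
  res
}

#' Dose-response of fold change on motif count
#'
#' Bins peaks by their motif count (0, 1, 2, 3+), summarizes the fold
#' changes per bin (median and quartiles) and tests each positive bin
#' against the zero-count bin with a two-sided Wilcoxon rank-sum test.
#'
#' @param lfc numeric fold changes per peak.
#' @param counts integer motif counts per peak (same length).
#' @param max_bin counts at or above this collapse into one bin
#'   (default 3, i.e. "3+").
#' @return `data.frame`: bin, n, median, q25, q75, p_vs_zero.
#' @export
motif_dose_response <- function(lfc, counts, max_bin = 3L) {
  stopifnot(length(lfc) == length(counts))
  binv <- pmin(counts, max_bin)
  labels <- c(as.character(seq_len(max_bin) - 1L), paste0(max_bin, "+"))
  present <- sort(unique(binv))
  if (length(present) < max_bin + 1)
    warning("empty motif-count bin(s) dropped")
  rows <- lapply(present, function(bv) {
    v <- lfc[binv == bv]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    p <- if (bv == 0 || !any(binv == 0)) NA_real_ else
      wilcoxon_ranksum(v, lfc[binv == 0])$p
    data.frame(bin = labels[bv + 1L], n = length(v), median = q[2],
               q25 = q[1], q75 = q[3], p_vs_zero = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
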