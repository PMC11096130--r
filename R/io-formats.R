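#' @title File readers and writers
#' @description Strict readers for every external format the pipeline
#'   touches: BED3/BED6, narrowPeak-like peak tables, counts TSV, sample
#'   design TSV, variants TSV (plus a minimal VCF), JASPAR-like PWM text and
#'   YAML configs. All readers reject malformed input with the offending
#'   file and line rather than coercing; coordinates are converted to the
#'   internal 0-based half-open convention at this boundary.
#' @name io_formats
NULL

stop_at <- function(path, line, fmt, ...) {
  stop(sprintf("%s:%d: %s", path, line, sprintf(fmt, ...)), call. = FALSE)
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open, matching the internal convention, so no shift
#' is applied. Three columns are required; `name` (4th) and `strand` (6th)
#' are kept when present.
#'
#' @param path file path.
#' @return `read_bed`: a validated interval `data.frame`
#'   (see [genomic_intervals()]); `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines))
    return(genomic_intervals(character(), integer(), integer()))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_at(path, i, "BED record has %d field(s), need >= 3", length(f))
    start <- suppressWarnings(as.numeric(f[2])); end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start != floor(start) || end != floor(end) || start < 0)
      stop_at(path, i, "non-integer or negative coordinate ('%s', '%s')", f[2], f[3])
    if (start >= end) stop_at(path, i, "start >= end (%s >= %s)", f[2], f[3])
    strand <- if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "."
    out[[i]] <- data.frame(chrom = f[1], start = start, end = end, strand = strand,
                           name = if (length(f) >= 4) f[4] else NA_character_,
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (all(is.na(df$name))) df$name <- NULL
  validate_intervals(df, path)
  df
}

#' @param intervals interval `data.frame`.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  n <- nrow(intervals)
  nm <- if ("name" %in% names(intervals)) intervals$name else sprintf("iv_%d", seq_len(n))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep(".", n)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end), nm, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read narrowPeak-like peak calls
#'
#' Expected columns: chrom, start, end, name, enrichment, qvalue. The
#' q-value column may be on the raw linear scale or as -log10(q); the
#' dialect is chosen by `qvalue_scale`, never guessed from the values.
#' Q-values are stored on the linear scale in `[0, 1]`.
#'
#' @param path file path.
#' @param qvalue_scale `"log10"` (narrowPeak convention, default) or
#'   `"linear"`.
#' @param replicate replicate label attached to every record.
#' @return `data.frame` with columns chrom, start, end, name, enrichment,
#'   qvalue, replicate.
#' @export
read_narrowpeak <- function(path, qvalue_scale = c("log10", "linear"),
                            replicate = "merged") {
  qvalue_scale <- match.arg(qvalue_scale)
  lines <- read_tsv_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6)
      stop_at(path, i, "peak record has %d field(s); need 6 (chrom, start, end, name, enrichment, qvalue)", length(f))
    start <- as.numeric(f[2]); end <- as.numeric(f[3])
    enr <- suppressWarnings(as.numeric(f[5])); qv <- suppressWarnings(as.numeric(f[6]))
    if (is.na(start) || is.na(end) || start >= end)
      stop_at(path, i, "malformed coordinates")
    if (is.na(enr) || enr < 0) stop_at(path, i, "negative or missing enrichment '%s'", f[5])
    if (is.na(qv)) stop_at(path, i, "missing qvalue column value '%s'", f[6])
    if (qvalue_scale == "log10") {
      if (qv < 0) stop_at(path, i, "-log10(q) must be >= 0, got %s", f[6])
      qv <- 10^(-qv)
    } else if (qv < 0 || qv > 1) {
      stop_at(path, i, "linear qvalue outside [0,1]: %s", f[6])
    }
    out[[i]] <- data.frame(chrom = f[1], start = start, end = end, name = f[4],
                           enrichment = enr, qvalue = qv, stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), enrichment = numeric(), qvalue = numeric())
  df$strand <- rep(".", nrow(df))
  df$replicate <- rep(replicate, nrow(df))
  df
}

#' @rdname read_narrowpeak
#' @param peaks peak `data.frame` as returned by [read_narrowpeak()].
#' @export
write_narrowpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.6g\t%.6g",
                   peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                   peaks$name, peaks$enrichment, -log10(pmax(peaks$qvalue, 1e-300)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a counts matrix (features x samples)
#'
#' First column holds feature ids, the header row holds sample ids. Every
#' cell must parse as a non-negative integer; the first offending cell is
#' reported with its coordinates.
#'
#' @param path file path.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) < 2) stop(sprintf("%s: counts file needs a header and >= 1 feature row", path), call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (!length(samples)) stop(sprintf("%s:1: no sample columns in header", path), call. = FALSE)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  m <- matrix(0L, nrow = length(body), ncol = length(samples),
              dimnames = list(character(length(body)), samples))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != length(samples) + 1L)
      stop_at(path, i + 1L, "expected %d fields, got %d", length(samples) + 1L, length(f))
    rownames(m)[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop_at(path, i + 1L, "non-integer count '%s' in column '%s'",
              f[-1][bad[1]], samples[bad[1]])
    m[i, ] <- as.integer(v)
  }
  if (anyDuplicated(rownames(m))) stop(sprintf("%s: duplicated feature ids", path), call. = FALSE)
  m
}

#' @rdname read_counts
#' @param counts integer matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design sheet
#'
#' Required columns: `sample_id`, `condition`, `rnai_target`, `replicate`,
#' `matched_control` (the condition label of the temperature-matched
#' control group; empty for control groups themselves). Every non-control
#' condition must name an existing control group.
#'
#' @param path file path.
#' @param counts optional counts matrix; every design sample must be a
#'   column of it.
#' @return `data.frame` of the design.
#' @export
read_design <- function(path, counts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "condition", "rnai_target", "replicate", "matched_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("%s: missing design column(s) %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  validate_design(df, counts, where = path)
  df
}

validate_design <- function(design, counts = NULL, where = "design") {
  if (anyDuplicated(design$sample_id))
    stop(sprintf("%s: duplicated sample_id", where), call. = FALSE)
  ctrl <- design$condition[!nzchar(design$matched_control) | is.na(design$matched_control)]
  refs <- unique(design$matched_control[nzchar(design$matched_control) & !is.na(design$matched_control)])
  orphan <- setdiff(refs, design$condition)
  if (length(orphan))
    stop(sprintf("%s: matched_control refers to absent condition(s): %s",
                 where, paste(orphan, collapse = ", ")), call. = FALSE)
  if (!length(ctrl))
    stop(sprintf("%s: design has no control group", where), call. = FALSE)
  if (!is.null(counts)) {
    absent <- setdiff(design$sample_id, colnames(counts))
    if (length(absent))
      stop(sprintf("%s: design sample(s) not in counts matrix: %s",
                   where, paste(absent, collapse = ", ")), call. = FALSE)
  }
  invisible(design)
}

#' @rdname read_design
#' @param design design `data.frame`.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene models
#'
#' Gene model TSV: `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' Coordinates are 0-based half-open; the TSS is the strand-aware 5' end
#' (`start` on `+`, `end - 1` on `-`) and is checked against the body.
#'
#' @param path file path.
#' @return `data.frame` of gene annotations.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  validate_genes(df, where = path)
  df
}

validate_genes <- function(genes, where = "genes") {
  validate_intervals(genes, where)
  if (!all(genes$strand %in% c("+", "-")))
    stop(sprintf("%s: gene strand must be '+' or '-'", where), call. = FALSE)
  want <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  bad <- which(genes$tss != want)
  if (length(bad))
    stop(sprintf("%s: tss inconsistent with strand at gene %s", where, genes$gene_id[bad[1]]), call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop(sprintf("%s: duplicated gene_id", where), call. = FALSE)
  invisible(genes)
}

#' @rdname read_gene_models
#' @param genes gene annotation `data.frame`.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "start", "end", "strand", "tss")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write position weight matrices (JASPAR-like text)
#'
#' Format: a `>id name` header line followed by four rows `A [ n n n ]`,
#' `C [...]`, `G [...]`, `T [...]` (brackets optional). Rows may hold
#' counts or probabilities; each position is normalized to probabilities.
#'
#' @param path file path.
#' @return named list of PWMs; each a list with `id`, `name` and `matrix`
#'   (4 x L probability matrix, rows A, C, G, T).
#' @export
read_pwms <- function(path) {
  lines <- read_tsv_lines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop(sprintf("%s: no '>' motif headers found", path), call. = FALSE)
  ends <- c(hdr[-1] - 1L, length(lines))
  pwms <- list()
  for (k in seq_along(hdr)) {
    h <- sub("^>\\s*", "", lines[hdr[k]])
    toks <- strsplit(h, "\\s+")[[1]]
    id <- toks[1]; name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1]
    block <- lines[(hdr[k] + 1L):ends[k]]
    if (length(block) < 4) stop(sprintf("%s: motif %s has fewer than 4 base rows", path, id), call. = FALSE)
    rows <- matrix(NA_real_, 4, 0)
    got <- character()
    for (b in block[1:4]) {
      base <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", b))
      nums <- as.numeric(strsplit(gsub("^[^\\[0-9.]*\\[?|\\]\\s*$", "", b), "\\s+")[[1]])
      nums <- nums[!is.na(nums)]
      if (!base %in% c("A", "C", "G", "T") || !length(nums))
        stop(sprintf("%s: malformed PWM row for motif %s: '%s'", path, id, b), call. = FALSE)
      if (ncol(rows) == 0) rows <- matrix(NA_real_, 4, length(nums), dimnames = list(c("A", "C", "G", "T"), NULL))
      if (length(nums) != ncol(rows))
        stop(sprintf("%s: motif %s rows have unequal lengths", path, id), call. = FALSE)
      rows[base, ] <- nums
      got <- c(got, base)
    }
    if (!setequal(got, c("A", "C", "G", "T")))
      stop(sprintf("%s: motif %s missing base row(s)", path, id), call. = FALSE)
    cs <- colSums(rows)
    if (any(cs <= 0)) stop(sprintf("%s: motif %s has a zero-sum position", path, id), call. = FALSE)
    pwms[[id]] <- list(id = id, name = name, matrix = sweep(rows, 2, cs, "/"))
  }
  pwms
}

#' @rdname read_pwms
#' @param pwms list of PWMs as returned by [read_pwms()].
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b, paste(sprintf("%.6f", p$matrix[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write somatic variant tables
#'
#' Native format is a TSV with columns `sample_id`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `vtype` (SNV/InDel/SV/CNV), `af`, `support`,
#' `ratio`, `feature`, `deleterious`. The evidence field matching the
#' variant type must be present: `af` for SNV/InDel, `support` for SV,
#' `ratio` for CNV.
#'
#' @param path file path.
#' @return `data.frame` of variant records.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "vtype", "af", "support", "ratio", "feature")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("%s: missing variant column(s) %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  if (!"deleterious" %in% names(df)) df$deleterious <- FALSE
  validate_variants(df, where = path)
  df
}

validate_variants <- function(df, where = "variants") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$pos < 1)) stop(sprintf("%s: variant pos must be >= 1", where), call. = FALSE)
  bad <- which(!df$vtype %in% c("SNV", "InDel", "SV", "CNV"))
  if (length(bad)) stop(sprintf("%s: unknown vtype '%s'", where, df$vtype[bad[1]]), call. = FALSE)
  sn <- df$vtype %in% c("SNV", "InDel")
  if (any(sn & (is.na(df$af) | df$af <= 0 | df$af > 1)))
    stop(sprintf("%s: SNV/InDel allele fraction must lie in (0, 1]", where), call. = FALSE)
  if (any(df$vtype == "SV" & is.na(df$support)))
    stop(sprintf("%s: SV records need support_reads", where), call. = FALSE)
  if (any(df$vtype == "CNV" & (is.na(df$ratio) | df$ratio <= 0)))
    stop(sprintf("%s: CNV records need a positive copy ratio", where), call. = FALSE)
  invisible(df)
}

#' @rdname read_variants
#' @param variants variant `data.frame`.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal per-sample VCF
#'
#' Only CHROM, POS, REF, ALT and an allele fraction are consumed. The
#' fraction is taken from the first sample's FORMAT `AF` field when
#' present, else from `AD` (alt / total), else from an INFO `AF=` tag.
#' Records are typed SNV when REF and ALT are single bases, InDel
#' otherwise. Multi-allelic ALT fields are split into one record each.
#'
#' @param path VCF path (plain text).
#' @param sample_id sample label to attach.
#' @return variant `data.frame` in the native TSV layout.
#' @export
read_variants_vcf <- function(path, sample_id) {
  lines <- read_tsv_lines(path)
  body <- lines[!startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop_at(path, i, "VCF record has %d field(s), need >= 8", length(f))
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    af <- rep(NA_real_, length(alts))
    if (length(f) >= 10) {
      keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      vals <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      if ("AF" %in% keys) {
        af <- as.numeric(strsplit(vals[match("AF", keys)], ",", fixed = TRUE)[[1]])
        af <- rep_len(af, length(alts))
      } else if ("AD" %in% keys) {
        ad <- as.numeric(strsplit(vals[match("AD", keys)], ",", fixed = TRUE)[[1]])
        if (length(ad) >= 2 && sum(ad) > 0) af <- ad[-1][seq_along(alts)] / sum(ad)
      }
    }
    if (anyNA(af)) {
      m <- regmatches(f[8], regexec("(?:^|;)AF=([0-9.eE,+-]+)", f[8]))[[1]]
      if (length(m) == 2) af <- rep_len(as.numeric(strsplit(m[2], ",")[[1]]), length(alts))
    }
    if (anyNA(af)) stop_at(path, i, "no allele fraction (FORMAT AF/AD or INFO AF) found")
    for (k in seq_along(alts)) {
      vt <- if (nchar(f[4]) == 1 && nchar(alts[k]) == 1) "SNV" else "InDel"
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = f[1], pos = as.numeric(f[2]),
        ref = f[4], alt = alts[k], vtype = vt, af = af[k],
        support = NA_real_, ratio = NA_real_, feature = "other",
        deleterious = FALSE, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    utils::read.delim(text = "sample_id\tchrom\tpos\tref\talt\tvtype\taf\tsupport\tratio\tfeature\tdeleterious")
  validate_variants(df, where = path)
  df
}

#' Read a pipeline / simulation YAML config
#' @param path YAML file.
#' @return named list.
#' @export
read_yaml_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}
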