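#' Genomic intervals, 0-based half-open
#'
#' All coordinates inside the package follow a single convention: 0-based,
#' half-open `[start, end)`, the native convention of BED and narrowPeak.
#' Readers for 1-based external dialects convert at the boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval (recycled).
#' @param name optional interval names.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (and `name` when given), validated.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NULL) {
  n <- length(chrom)
  strand <- rep_len(as.character(strand), n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = strand, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, where = "intervals") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", where, paste(miss, collapse = ", ")))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(sprintf("%s: NA coordinates", where))
  if (any(df$start < 0)) stop(sprintf("%s: negative start", where))
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("%s: start >= end at record %d (%s:%d-%d)", where, bad[1],
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop(sprintf("%s: strand must be one of '+', '-', '.'", where))
  invisible(df)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
gi2gr <- function(df) {
  strand <- if ("strand" %in% names(df)) sub("^\\.$", "*", df$strand)
            else rep("*", nrow(df))
  strand <- rep_len(strand, nrow(df))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  gr
}

gr2gi <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = sub("^\\*$", ".", as.character(GenomicRanges::strand(gr))),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% colnames(mc)) df$name <- as.character(mc$name)
  rownames(df) <- NULL
  df
}

# canonical sort order used for IntervalSets
sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
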