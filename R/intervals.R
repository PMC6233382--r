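#' Build a table of genomic intervals
#'
#' Intervals are the coordinate currency of the whole package: a plain
#' `data.frame` with columns `chrom`, `start`, `end`, `strand`, where `start`
#' is 0-based inclusive and `end` exclusive, so `end - start` is the width in
#' bp.  Strand is one of `"+"`, `"-"`, `"."`; `"."` is tolerated for features
#' such as repeat annotations that frequently omit strand.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors, 0-based half-open, `0 <= start < end`.
#' @param strand character vector in `c("+", "-", ".")`, recycled.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  gi <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(gi)
  gi
}

validate_intervals <- function(gi, what = "interval") {
  if (!all(c("chrom", "start", "end", "strand") %in% names(gi)))
    stop(what, " table must have columns chrom, start, end, strand")
  if (nrow(gi) == 0) return(invisible(gi))
  if (any(is.na(gi$chrom)) || any(!nzchar(gi$chrom)))
    stop(what, ": chrom must be non-empty")
  bad <- which(!(gi$start >= 0 & gi$start < gi$end))
  if (length(bad))
    stop(what, ": need 0 <= start < end (row ", bad[1], ")")
  if (any(!gi$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'")
  invisible(gi)
}

# Internal 0-based half-open table -> GRanges (1-based closed).
as_granges <- function(gi) {
  str <- if (is.null(gi$strand)) rep(".", nrow(gi)) else gi$strand
  str[str == "."] <- "*"
  GenomicRanges::GRanges(gi$chrom,
                         IRanges::IRanges(gi$start + 1L, gi$end),
                         strand = str)
}

# GRanges -> internal 0-based table.
from_granges <- function(gr) {
  str <- as.character(BiocGenerics::strand(gr))
  str[str == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = str,
             stringsAsFactors = FALSE)
}

# All overlapping pairs (>= 1 bp) between two interval tables, strand-blind.
# Returns a data.frame with query/subject row indices and overlap widths.
interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  data.frame(query = qi, subject = si, overlap_bp = as.integer(ov))
}
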