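#' Exon-structured transcript models
#'
#' A `transcript_set` bundles two tables: `transcripts` (one row per
#' transcript: `transcript_id`, `locus_id`, `chrom`, `start`, `end`,
#' `strand`, `biotype`) and `exons` (one row per exon: `transcript_id`,
#' `chrom`, `start`, `end`, `strand`).  Exons of a transcript are sorted,
#' pairwise disjoint, on one chromosome and strand, and contained in the
#' transcript span.  Biotype is one of `PCG`, `lncRNA_candidate`, `lincRNA`,
#' `NAT`, `intronic`, `excluded`.
#'
#' @param transcripts data.frame as described above (`locus_id` and `biotype`
#'   optional; missing locus IDs are filled by [assign_loci()] semantics when
#'   `group_loci = TRUE`).
#' @param exons data.frame with at least `transcript_id`, `start`, `end`
#'   (`chrom`/`strand` are filled from the transcript table if absent).
#' @param group_loci merge transcripts lacking a `locus_id` into loci by
#'   same-strand exonic overlap.
#' @return an object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons, group_loci = FALSE) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (is.null(transcripts$biotype)) transcripts$biotype <- "lncRNA_candidate"
  if (is.null(transcripts$locus_id)) transcripts$locus_id <- NA_character_
  idx <- match(exons$transcript_id, transcripts$transcript_id)
  if (anyNA(idx))
    stop("exon refers to unknown transcript: ",
         exons$transcript_id[which(is.na(idx))[1]])
  if (is.null(exons$chrom)) exons$chrom <- transcripts$chrom[idx]
  if (is.null(exons$strand)) exons$strand <- transcripts$strand[idx]
  exons <- exons[order(idx, exons$start), , drop = FALSE]
  rownames(exons) <- rownames(transcripts) <- NULL
  ts <- structure(list(transcripts = transcripts, exons = exons),
                  class = "transcript_set")
  validate_transcript_set(ts)
  if (group_loci || anyNA(transcripts$locus_id)) ts <- assign_loci(ts)
  ts
}

validate_transcript_set <- function(ts) {
  tr <- ts$transcripts
  ex <- ts$exons
  validate_intervals(tr, "transcript")
  validate_intervals(ex, "exon")
  if (any(!tr$strand %in% c("+", "-")))
    stop("transcripts require explicit strand '+' or '-'")
  idx <- match(ex$transcript_id, tr$transcript_id)
  if (any(ex$chrom != tr$chrom[idx]) || any(ex$strand != tr$strand[idx]))
    stop("exon chrom/strand differ from their transcript")
  if (any(ex$start < tr$start[idx] | ex$end > tr$end[idx]))
    stop("exon outside declared transcript span: ",
         ex$transcript_id[which(ex$start < tr$start[idx] |
                                  ex$end > tr$end[idx])[1]])
  # sorted and pairwise disjoint within each transcript
  same <- which(ex$transcript_id[-1] == ex$transcript_id[-nrow(ex)])
  if (length(same) && any(ex$start[same + 1] < ex$end[same]))
    stop("overlapping or unsorted exons in transcript ",
         ex$transcript_id[same[which(ex$start[same + 1] < ex$end[same])[1]]])
  invisible(ts)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$locus_id)), "loci,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Group transcripts into loci
#'
#' Transcripts that already carry a `locus_id` keep it.  Transcripts without
#' one are merged into a locus when their exons overlap on the same strand
#' (transitively), mirroring assembler locus grouping when assembler locus
#' IDs are unavailable.
#'
#' @param ts a [transcript_set()].
#' @return the transcript set with a complete `locus_id` column.
#' @export
assign_loci <- function(ts) {
  tr <- ts$transcripts
  need <- which(is.na(tr$locus_id) | !nzchar(tr$locus_id))
  if (!length(need)) return(ts)
  ids <- tr$transcript_id[need]
  ex <- ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE]
  gr <- as_granges(ex)
  # same-strand exonic overlap (strand-aware by construction of the GRanges)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  pos <- match(ex$transcript_id, ids)
  comp <- union_components(length(ids),
                           pos[S4Vectors::queryHits(hits)],
                           pos[S4Vectors::subjectHits(hits)])
  tr$locus_id[need] <- sprintf("LOC%05d", comp)
  ts$transcripts <- tr
  ts
}

# Connected components by union-find over 1..n (no graph dependency needed).
union_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Spliced (mature) transcript lengths
#'
#' @param ts a [transcript_set()].
#' @return named integer vector, summed exon widths per transcript.
#' @export
spliced_lengths <- function(ts) {
  w <- ts$exons$end - ts$exons$start
  s <- tapply(w, ts$exons$transcript_id, sum)
  out <- as.integer(s[ts$transcripts$transcript_id])
  stats::setNames(out, ts$transcripts$transcript_id)
}

#' Locus spans
#'
#' One interval per locus: the union span of its transcripts.
#'
#' @param ts a [transcript_set()].
#' @return data.frame with `locus_id`, `chrom`, `start`, `end`, `strand`.
#' @export
locus_spans <- function(ts) {
  tr <- ts$transcripts
  sp <- do.call(rbind, lapply(split(tr, tr$locus_id), function(d) {
    data.frame(locus_id = d$locus_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp[order(sp$chrom, sp$start), , drop = FALSE]
}

#' Subset a transcript set by transcript IDs
#'
#' @param ts a [transcript_set()].
#' @param transcript_ids IDs to keep.
#' @return a `transcript_set` restricted to the given transcripts.
#' @export
subset_transcripts <- function(ts, transcript_ids) {
  keep <- ts$transcripts$transcript_id %in% transcript_ids
  structure(list(transcripts = ts$transcripts[keep, , drop = FALSE],
                 exons = ts$exons[ts$exons$transcript_id %in%
                                    ts$transcripts$transcript_id[keep], ,
                                  drop = FALSE]),
            class = "transcript_set")
}

# Introns of each transcript: gaps between consecutive exons.
transcript_introns <- function(ts) {
  ex <- ts$exons
  if (nrow(ex) < 2)
    return(data.frame(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  same <- which(ex$transcript_id[-1] == ex$transcript_id[-nrow(ex)])
  gap <- same[ex$start[same + 1] > ex$end[same]]
  data.frame(transcript_id = ex$transcript_id[gap],
             chrom = ex$chrom[gap],
             start = ex$end[gap],
             end = ex$start[gap + 1],
             strand = ex$strand[gap],
             stringsAsFactors = FALSE)
}
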