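#' Built-in coding-potential score
#'
#' A documented stand-in score for transcripts lacking an external
#' coding-potential value, following the same sign convention (positive =
#' coding).  The score is positive iff the longest open reading frame across
#' all six frames reaches `min_codons` codons:
#' `score = (longest ORF codons - min_codons) / min_codons`.
#' An ORF starts at ATG and runs to the first in-frame stop (excluded) or
#' the sequence end (open ORFs count).
#'
#' @param sequence nucleotide sequence (character scalar or
#'   [Biostrings::DNAString]); only A, C, G, T, N allowed.
#' @param min_codons ORF length at which a transcript is deemed coding.
#' @return numeric score; `> 0` means coding.
#' @export
builtin_coding_score <- function(sequence, min_codons = 100) {
  s <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", s)) stop("non-ACGTN symbol in sequence")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  longest <- 0L
  for (seq in c(s, rc)) for (frame in 0:2) {
    n_codon <- (nchar(seq) - frame) %/% 3
    if (n_codon < 1) next
    codons <- substring(seq, frame + 1 + 3 * (seq_len(n_codon) - 1),
                        frame + 3 * seq_len(n_codon))
    open_at <- NA_integer_
    for (k in seq_len(n_codon)) {
      if (codons[k] %in% c("TAA", "TAG", "TGA")) {
        if (!is.na(open_at)) longest <- max(longest, k - open_at)
        open_at <- NA_integer_
      } else if (is.na(open_at) && codons[k] == "ATG") {
        open_at <- k
      }
    }
    if (!is.na(open_at)) longest <- max(longest, n_codon - open_at + 1L)
  }
  (longest - min_codons) / min_codons
}

#' Spliced transcript sequences from genome sequences
#'
#' Concatenates exon sequences per transcript (5' to 3'; minus-strand
#' transcripts are reverse-complemented).
#'
#' @param ts a [transcript_set()].
#' @param genome named list or character vector of chromosome sequences.
#' @return named character vector of spliced sequences per transcript.
#' @export
transcript_sequences <- function(ts, genome) {
  vapply(ts$transcripts$transcript_id, function(tid) {
    ex <- ts$exons[ts$exons$transcript_id == tid, , drop = FALSE]
    s <- paste(vapply(seq_len(nrow(ex)), function(k)
      substr(genome[[ex$chrom[k]]], ex$start[k] + 1L, ex$end[k]),
      character(1)), collapse = "")
    if (ex$strand[1] == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    s
  }, character(1))
}

#' Assign transcript class codes against a coding-gene annotation
#'
#' Mirrors assembler class codes: `u` (intergenic) when a transcript's exons
#' overlap no protein-coding locus span; `x` (antisense) when its exons
#' overlap a coding exon on the opposite strand, or when it lies antisense
#' inside an intron; `i` (intronic) when it lies entirely within one intron
#' of a same-strand coding gene; `sense_overlap` otherwise (excluded
#' downstream).
#'
#' @param ts candidate [transcript_set()].
#' @param pcgs protein-coding [transcript_set()] on the same genome.
#' @param chroms optional character vector of valid chromosome names; a
#'   candidate on a chromosome outside it raises an error.
#' @return named character vector of class codes per transcript.
#' @export
assign_class_code <- function(ts, pcgs, chroms = NULL) {
  tr <- ts$transcripts
  if (!is.null(chroms)) {
    bad <- setdiff(unique(tr$chrom), chroms)
    if (length(bad))
      stop("transcript chromosome absent from the genome: ", bad[1])
  }
  code <- stats::setNames(rep("u", nrow(tr)), tr$transcript_id)
  spans <- locus_spans(pcgs)
  ex <- ts$exons
  # exonic overlap with any PCG locus span (strand-blind) -> not 'u'
  ov_span <- interval_overlaps(ex, spans)
  touched <- unique(ex$transcript_id[ov_span$query])
  if (!length(touched)) return(code)
  pex <- pcgs$exons
  ov_ex <- interval_overlaps(ex, pex)
  anti <- ex$strand[ov_ex$query] != pex$strand[ov_ex$subject]
  x_ids <- unique(ex$transcript_id[ov_ex$query[anti]])
  sense_ids <- unique(ex$transcript_id[ov_ex$query[!anti]])
  introns <- transcript_introns(pcgs)
  in_intron_same <- in_intron_anti <- character()
  if (nrow(introns)) {
    ov_in <- interval_overlaps(tr, introns)
    contained <- tr$start[ov_in$query] >= introns$start[ov_in$subject] &
      tr$end[ov_in$query] <= introns$end[ov_in$subject]
    same <- tr$strand[ov_in$query] == introns$strand[ov_in$subject]
    in_intron_same <- unique(tr$transcript_id[ov_in$query[contained & same]])
    in_intron_anti <- unique(tr$transcript_id[ov_in$query[contained & !same]])
  }
  for (id in touched) {
    code[id] <- if (id %in% x_ids && !(id %in% sense_ids)) "x"
    else if (id %in% in_intron_anti && !(id %in% sense_ids)) "x"
    else if (id %in% in_intron_same && !(id %in% sense_ids)) "i"
    else "sense_overlap"
  }
  code
}

#' Filter lncRNA candidates
#'
#' The candidate filter chain: keep a transcript iff its spliced length is at
#' least `min_length` nt, its class code is `u`, `x` or `i`, its coding score
#' is not positive, and it has no protein-domain hit; then collapse each
#' locus to its single longest surviving isoform (spliced length; ties broken
#' by transcript ID).  Kept transcripts get biotype `lincRNA` (`u`), `NAT`
#' (`x`) or `intronic` (`i`).
#'
#' The criteria form a pure conjunction, so their order does not affect the
#' kept set.  Transcripts with no coding-evidence record are treated as
#' non-coding (a message notes how many).
#'
#' @param candidates candidate [transcript_set()].
#' @param class_codes named vector from [assign_class_code()]; computed from
#'   `pcgs` when omitted.
#' @param evidence optional data.frame `transcript_id`, `coding_score`,
#'   `has_domain_hit` (external coding-potential and domain-search results).
#' @param pcgs coding annotation, used when `class_codes` is missing.
#' @param min_length minimum spliced length in nt.
#' @return the filtered `transcript_set`, one transcript per locus, with a
#'   `filter_log` attribute recording every candidate's fate.
#' @export
filter_lncrna <- function(candidates, class_codes = NULL, evidence = NULL,
                          pcgs = NULL, min_length = 200) {
  if (is.null(class_codes)) {
    if (is.null(pcgs)) stop("provide class_codes or pcgs")
    class_codes <- assign_class_code(candidates, pcgs)
  }
  tr <- candidates$transcripts
  len <- spliced_lengths(candidates)
  score <- rep(0, nrow(tr))
  domain <- rep(FALSE, nrow(tr))
  if (!is.null(evidence)) {
    m <- match(tr$transcript_id, evidence$transcript_id)
    n_missing <- sum(is.na(m))
    if (n_missing)
      message(n_missing,
              " transcripts without coding evidence treated as non-coding")
    score[!is.na(m)] <- evidence$coding_score[m[!is.na(m)]]
    domain[!is.na(m)] <- as.logical(evidence$has_domain_hit[m[!is.na(m)]])
  }
  code <- class_codes[tr$transcript_id]
  keep <- len >= min_length & code %in% c("u", "x", "i") & score <= 0 & !domain
  log <- data.frame(transcript_id = tr$transcript_id, locus_id = tr$locus_id,
                    spliced_length = as.integer(len), class_code = code,
                    coding_score = score, has_domain_hit = domain,
                    kept = keep, stringsAsFactors = FALSE)
  surv <- tr[keep, , drop = FALSE]
  if (nrow(surv)) {
    slen <- len[surv$transcript_id]
    ord <- order(surv$locus_id, -slen, surv$transcript_id)
    surv <- surv[ord, , drop = FALSE]
    surv <- surv[!duplicated(surv$locus_id), , drop = FALSE]
  }
  out <- subset_transcripts(candidates, surv$transcript_id)
  bt <- c(u = "lincRNA", x = "NAT", i = "intronic")
  out$transcripts$biotype <-
    unname(bt[code[out$transcripts$transcript_id]])
  attr(out, "filter_log") <- log
  out
}
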