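#' Read a transcript annotation (GTF or GFF3)
#'
#' Exon features are grouped per transcript and converted to the internal
#' 0-based half-open coordinate model.  For GTF, exons must carry
#' `transcript_id` and `gene_id` attributes; for GFF3 the `Parent` chain
#' (exon -> transcript -> gene) is followed.  If the file declares transcript
#' spans, exons falling outside them raise an error.
#'
#' @param path file path.
#' @param format `"GTF"` or `"GFF3"`.
#' @param default_biotype biotype assigned when the file carries none.
#' @return a [transcript_set()].
#' @export
read_annotation <- function(path, format = c("GTF", "GFF3"),
                            default_biotype = "lncRNA_candidate") {
  format <- match.arg(format)
  prevalidate_tabular(path, min_fields = 8, comment = "#")
  gr <- rtracklayer::import(path, format = tolower(format))
  typ <- as.character(gr$type)
  ex <- gr[typ == "exon"]
  if (length(ex) == 0) stop("no exon features in ", path)
  if (format == "GTF") {
    tid <- as.character(ex$transcript_id)
    gid <- as.character(ex$gene_id)
    bt <- if (!is.null(ex$biotype)) as.character(ex$biotype) else
      rep(NA_character_, length(ex))
    tr_rows <- gr[typ == "transcript"]
    tr_span <- if (length(tr_rows))
      data.frame(transcript_id = as.character(tr_rows$transcript_id),
                 from_granges(tr_rows), stringsAsFactors = FALSE)
    else NULL
  } else {
    par <- ex$Parent
    if (any(lengths(par) != 1))
      stop("GFF3 exon without single Parent in ", path)
    tid <- as.character(unlist(par))
    feats <- gr[typ %in% c("mRNA", "transcript", "lnc_RNA", "ncRNA")]
    fid <- as.character(feats$ID)
    fpar <- vapply(as.list(feats$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
    gid <- fpar[match(tid, fid)]
    gid[is.na(gid)] <- tid[is.na(gid)]
    bt <- rep(NA_character_, length(ex))
    tr_span <- if (length(feats))
      data.frame(transcript_id = fid, from_granges(feats),
                 stringsAsFactors = FALSE)
    else NULL
  }
  if (anyNA(tid)) stop("exon lacking transcript identifier in ", path)
  exdf <- cbind(data.frame(transcript_id = tid, stringsAsFactors = FALSE),
                from_granges(ex))
  ord <- order(exdf$transcript_id, exdf$start)
  exdf <- exdf[ord, , drop = FALSE]
  first <- !duplicated(exdf$transcript_id)
  agg_start <- tapply(exdf$start, exdf$transcript_id, min)
  agg_end <- tapply(exdf$end, exdf$transcript_id, max)
  tids <- exdf$transcript_id[first]
  tr <- data.frame(transcript_id = tids,
                   locus_id = gid[ord][first],
                   chrom = exdf$chrom[first],
                   start = as.integer(agg_start[tids]),
                   end = as.integer(agg_end[tids]),
                   strand = exdf$strand[first],
                   biotype = ifelse(is.na(bt[ord][first]), default_biotype,
                                    bt[ord][first]),
                   stringsAsFactors = FALSE)
  if (!is.null(tr_span)) {
    m <- match(tr$transcript_id, tr_span$transcript_id)
    has <- !is.na(m)
    tr$start[has] <- tr_span$start[m[has]]
    tr$end[has] <- tr_span$end[m[has]]
  }
  transcript_set(tr, exdf)
}

# Cheap structural check so malformed lines are reported with their number.
prevalidate_tabular <- function(path, min_fields, comment = "#") {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, comment) & nzchar(lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nf < min_fields)) {
    lineno <- which(keep)[which(nf < min_fields)[1]]
    stop("malformed line ", lineno, " in ", path,
         " (expected >= ", min_fields, " tab-separated fields)")
  }
  invisible(TRUE)
}

#' Write a transcript annotation
#'
#' @param ts a [transcript_set()].
#' @param path output file.
#' @param format `"GTF"` or `"GFF3"`.
#' @export
write_annotation <- function(ts, path, format = c("GTF", "GFF3")) {
  format <- match.arg(format)
  tr <- ts$transcripts
  ex <- ts$exons
  m <- match(ex$transcript_id, tr$transcript_id)
  if (format == "GTF") {
    gr_tr <- as_granges(tr)
    gr_tr$type <- "transcript"
    gr_tr$gene_id <- tr$locus_id
    gr_tr$transcript_id <- tr$transcript_id
    gr_tr$biotype <- tr$biotype
    gr_ex <- as_granges(ex)
    gr_ex$type <- "exon"
    gr_ex$gene_id <- tr$locus_id[m]
    gr_ex$transcript_id <- ex$transcript_id
    gr_ex$biotype <- tr$biotype[m]
    out <- c(gr_tr, gr_ex)
    out <- out[order(as.character(GenomicRanges::seqnames(out)),
                     BiocGenerics::start(out),
                     out$type == "exon")]
    rtracklayer::export(out, path, format = "gtf")
  } else {
    gr_tr <- as_granges(tr)
    gr_tr$type <- "transcript"
    gr_tr$ID <- tr$transcript_id
    gr_tr$Parent <- IRanges::CharacterList(as.list(tr$locus_id))
    gr_tr$biotype <- tr$biotype
    gr_ex <- as_granges(ex)
    gr_ex$type <- "exon"
    gr_ex$ID <- NA_character_
    gr_ex$Parent <- IRanges::CharacterList(as.list(ex$transcript_id))
    gr_ex$biotype <- tr$biotype[m]
    sp <- locus_spans(ts)
    gr_g <- as_granges(sp)
    gr_g$type <- "gene"
    gr_g$ID <- sp$locus_id
    gr_g$Parent <- IRanges::CharacterList(vector("list", nrow(sp)))
    gr_g$biotype <- NA_character_
    rtracklayer::export(c(gr_g, gr_tr, gr_ex), path, format = "gff3")
  }
  invisible(path)
}

#' Read transposable-element features from BED6
#'
#' Column 4 carries `family:te_id`; families outside the fixed vocabulary
#' (`Gypsy`, `Copia`, `LTR_other`, `LINE`, `SINE`, `DNA`, `unknown`, `other`)
#' raise an error.  Strand `"."` is permitted.
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end`, `strand`, `family`, `te_id`.
#' @export
read_te_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  gi <- from_granges(gr)
  nm <- as.character(gr$name)
  parts <- strsplit(nm, ":", fixed = TRUE)
  fam <- vapply(parts, `[`, character(1), 1)
  tid <- vapply(parts, function(p)
    if (length(p) > 1) paste(p[-1], collapse = ":") else p[1], character(1))
  bad <- setdiff(unique(fam), TE_FAMILIES)
  if (length(bad)) stop("unknown TE family in ", path, ": ", bad[1])
  cbind(gi, data.frame(family = fam, te_id = tid, stringsAsFactors = FALSE))
}

#' Write transposable-element features to BED6
#'
#' @param te data.frame as returned by [read_te_bed()].
#' @param path output file.
#' @export
write_te_bed <- function(te, path) {
  gr <- as_granges(te)
  gr$name <- paste0(te$family, ":", te$te_id)
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read small-RNA read intervals from BED6
#'
#' Column 4 is the read identifier and column 5 the number of loci the read
#' mapped to (multi-mapping multiplicity).
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end`, `strand`, `read_id`,
#'   `length`, `n_mapped_loci`.
#' @export
read_srna_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  gi <- from_granges(gr)
  gi$read_id <- as.character(gr$name)
  gi$length <- gi$end - gi$start
  gi$n_mapped_loci <- as.integer(gr$score)
  gi
}

#' Write small-RNA read intervals to BED6
#'
#' @param reads data.frame as returned by [read_srna_bed()].
#' @param path output file.
#' @export
write_srna_bed <- function(reads, path) {
  gr <- as_granges(reads)
  gr$name <- reads$read_id
  gr$score <- as.integer(reads$n_mapped_loci)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a per-cytosine methylation report (CX style)
#'
#' Seven tab-separated columns: chrom, 1-based position, strand, count of
#' methylated calls, count of unmethylated calls, context (`CG`/`CHG`/`CHH`),
#' trinucleotide context.  Positions are converted to 0-based.
#'
#' @param path report file.
#' @return data.frame `chrom`, `pos` (0-based), `strand`, `context`,
#'   `n_meth`, `n_total`.
#' @export
read_cx_report <- function(path) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      n_meth = integer(), n_total = integer(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3, 6, 7)),
                          data.table = FALSE)
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) != 7) stop("CX report must have 7 columns: ", path)
  names(dt) <- c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context",
                 "tricontext")
  bad <- setdiff(unique(dt$context), METH_CONTEXTS)
  if (length(bad)) stop("unknown methylation context '", bad[1], "' in ", path)
  if (any(dt$n_meth < 0) || any(dt$n_unmeth < 0))
    stop("negative counts in ", path)
  data.frame(chrom = dt$chrom, pos = as.integer(dt$pos) - 1L,
             strand = dt$strand, context = dt$context,
             n_meth = as.integer(dt$n_meth),
             n_total = as.integer(dt$n_meth + dt$n_unmeth),
             stringsAsFactors = FALSE)
}

#' Write a per-cytosine methylation report (CX style)
#'
#' @param cx data.frame as returned by [read_cx_report()].
#' @param path output file.
#' @export
write_cx_report <- function(cx, path) {
  out <- data.frame(chrom = cx$chrom, pos = cx$pos + 1L, strand = cx$strand,
                    n_meth = cx$n_meth, n_unmeth = cx$n_total - cx$n_meth,
                    context = cx$context,
                    tricontext = if (!is.null(cx$tricontext)) cx$tricontext
                    else cx$context)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read 12-column tabular homology hits
#'
#' The standard tabular local-alignment hit format: query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query start,
#' query end, subject start, subject end, E-value, bit score (1-based
#' inclusive coordinates).  Reversed subject coordinates (minus-strand hits)
#' are normalised to `s_start < s_end` with `s_strand = "-"`.
#'
#' @param path hits file.
#' @return data.frame with normalised 0-based half-open coordinates.
#' @export
read_hits_tabular <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (nrow(dt) == 0)
    return(empty_hits())
  if (ncol(dt) != 12) stop("hit table must have 12 columns: ", path)
  names(dt) <- c("query_id", "subject_id", "pident", "alen", "mm", "go",
                 "qs", "qe", "ss", "se", "evalue", "bits")
  num <- c("pident", "alen", "mm", "go", "qs", "qe", "ss", "se", "evalue",
           "bits")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(dt[[cn]]))
    if (anyNA(v)) stop("non-numeric value in column ", cn, " of ", path)
    dt[[cn]] <- v
  }
  if (any(dt$pident < 0 | dt$pident > 100))
    stop("percent identity outside [0,100] in ", path)
  if (any(dt$evalue < 0)) stop("negative E-value in ", path)
  s_rev <- dt$ss > dt$se
  q_rev <- dt$qs > dt$qe
  data.frame(query_id = as.character(dt$query_id),
             subject_id = as.character(dt$subject_id),
             percent_identity = dt$pident,
             aln_length = as.integer(dt$alen),
             mismatches = as.integer(dt$mm),
             gap_opens = as.integer(dt$go),
             q_start = as.integer(pmin(dt$qs, dt$qe)) - 1L,
             q_end = as.integer(pmax(dt$qs, dt$qe)),
             s_start = as.integer(pmin(dt$ss, dt$se)) - 1L,
             s_end = as.integer(pmax(dt$ss, dt$se)),
             s_strand = ifelse(xor(s_rev, q_rev), "-", "+"),
             evalue = dt$evalue,
             bitscore = dt$bits,
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), aln_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             s_strand = character(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

#' Write 12-column tabular homology hits
#'
#' @param hits data.frame as returned by [read_hits_tabular()].
#' @param path output file.
#' @export
write_hits_tabular <- function(hits, path) {
  minus <- hits$s_strand == "-"
  out <- data.frame(hits$query_id, hits$subject_id, hits$percent_identity,
                    hits$aln_length, hits$mismatches, hits$gap_opens,
                    hits$q_start + 1L, hits$q_end,
                    ifelse(minus, hits$s_end, hits$s_start + 1L),
                    ifelse(minus, hits$s_start + 1L, hits$s_end),
                    hits$evalue, hits$bitscore)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Construct a count matrix
#'
#' @param counts non-negative integer matrix, loci in rows (rownames set),
#'   samples in columns (colnames set).
#' @param library_sizes per-sample sequencing depths; defaults to the column
#'   sums.  Unassigned reads mean the library size may exceed the column sum.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have locus rownames and sample colnames")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- stats::setNames(as.numeric(library_sizes),
                                   colnames(counts))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "loci x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Read a tab-delimited count matrix
#'
#' First column `locus_id`, one column per sample.  An optional leading
#' comment line `# library_sizes: sample=size ...` restores per-sample
#' depths; otherwise column sums are used.
#'
#' @param path count file.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  first <- readLines(path, n = 1)
  lib <- NULL
  if (startsWith(first, "# library_sizes:")) {
    spec <- strsplit(trimws(sub("# library_sizes:", "", first)), "[ \t]+")[[1]]
    kv <- strsplit(spec, "=", fixed = TRUE)
    lib <- stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                           vapply(kv, `[`, character(1), 1))
  }
  df <- data.table::fread(path, sep = "\t", header = TRUE, skip = if
                          (is.null(lib)) 0 else 1, data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.null(lib)) lib <- lib[colnames(m)]
  count_matrix(m, lib)
}

#' Write a tab-delimited count matrix
#'
#' @param cm a [count_matrix()].
#' @param path output file.
#' @export
write_count_matrix <- function(cm, path) {
  hdr <- paste0("# library_sizes: ",
                paste(names(cm$library_sizes), cm$library_sizes,
                      sep = "=", collapse = "\t"))
  writeLines(hdr, path)
  df <- data.frame(locus_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read differentially methylated regions from TSV
#'
#' Columns: chrom, start (0-based), end, context, direction (`hyper`/`hypo`),
#' delta, p.  This import path lets externally derived DMR sets bypass the
#' built-in caller.
#'
#' @param path DMR file.
#' @return data.frame of DMRs.
#' @export
read_dmrs <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "start", "end", "context", "direction", "delta", "p")
  if (!all(need %in% names(df)))
    stop("DMR file must have columns: ", paste(need, collapse = ", "))
  if (any(!df$context %in% METH_CONTEXTS)) stop("unknown DMR context")
  if (any(!df$direction %in% c("hyper", "hypo")))
    stop("DMR direction must be 'hyper' or 'hypo'")
  df
}

#' Write differentially methylated regions to TSV
#'
#' @param dmrs data.frame as produced by [call_dmrs()].
#' @param path output file.
#' @export
write_dmrs <- function(dmrs, path) {
  data.table::fwrite(dmrs, path, sep = "\t")
  invisible(path)
}
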