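# Small builders used across test files.

mk_ts <- function(...) {
  # mk_ts(list(id, chrom, strand, exons=list(c(s,e), ...), locus=NULL), ...)
  specs <- list(...)
  tr <- do.call(rbind, lapply(specs, function(s) {
    ex <- do.call(rbind, s$exons)
    data.frame(transcript_id = s$id,
               locus_id = if (is.null(s$locus)) s$id else s$locus,
               chrom = s$chrom, start = min(ex[, 1]), end = max(ex[, 2]),
               strand = s$strand, biotype = if (is.null(s$biotype))
                 "lncRNA_candidate" else s$biotype,
               stringsAsFactors = FALSE)
  }))
  ex <- do.call(rbind, lapply(specs, function(s) {
    e <- do.call(rbind, s$exons)
    data.frame(transcript_id = s$id, chrom = s$chrom,
               start = e[, 1], end = e[, 2], strand = s$strand,
               stringsAsFactors = FALSE)
  }))
  transcript_set(tr, ex)
}

random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 1000,
                             max_len = 50) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

small_cfg <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_chroms = 1, chrom_length = 80000,
                   n_pcg = 10, n_lnc = 24, read_depth = 5e4,
                   srna_depth = 5000, meth_coverage = 10,
                   te_density = c(Gypsy = 0.08, Copia = 0.03,
                                  LTR_other = 0.01, LINE = 0.012,
                                  SINE = 0.004, DNA = 0.015,
                                  unknown = 0.005))
  do.call(sim_config, utils::modifyList(defaults, args))
}
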