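test_that("interval validation enforces the coordinate model", {
  gi <- genomic_intervals("chr1", 9, 100)
  expect_equal(gi$end - gi$start, 91)
  expect_error(genomic_intervals("chr1", 10, 10), "start < end")
  expect_error(genomic_intervals("chr1", -1, 5), "start < end")
  expect_error(genomic_intervals("", 1, 5), "non-empty")
  expect_error(genomic_intervals("chr1", 1, 5, "x"), "strand")
})

test_that("interval overlap kernel matches the quadratic oracle", {
  set.seed(42)
  for (rep in 1:25) {
    q <- random_intervals(sample(1:30, 1))
    s <- random_intervals(sample(1:30, 1))
    got <- polylnc:::interval_overlaps(q, s)
    want <- bf_overlaps(q, s)
    ord <- function(d) d[order(d$query, d$subject), , drop = FALSE]
    expect_equal(unname(as.matrix(ord(got))), unname(as.matrix(ord(want))))
  }
})

test_that("GTF coordinates convert to the internal 0-based half-open model", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "exon", 10, 100, ".", "+", ".",
                   'gene_id "g1"; transcript_id "t1";', sep = "\t"), p)
  ts <- read_annotation(p)
  expect_equal(ts$exons$start, 9L)
  expect_equal(ts$exons$end, 100L)
  expect_equal(spliced_lengths(ts)[["t1"]], 91L)
})

test_that("annotation round-trips through GTF and GFF3", {
  ts <- mk_ts(list(id = "t1", chrom = "chr1", strand = "+",
                   exons = list(c(9, 100), c(200, 300)), locus = "L1"),
              list(id = "t2", chrom = "chr2", strand = "-",
                   exons = list(c(50, 400)), locus = "L2",
                   biotype = "PCG"))
  for (fmt in c("GTF", "GFF3")) {
    p <- withr::local_tempfile(fileext = paste0(".", tolower(fmt)))
    write_annotation(ts, p, format = fmt)
    back <- read_annotation(p, format = fmt)
    ord <- function(d) {
      d <- d[order(d$transcript_id, d$start), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    expect_equal(ord(back$transcripts)[c("transcript_id", "chrom", "start",
                                         "end", "strand")],
                 ord(ts$transcripts)[c("transcript_id", "chrom", "start",
                                       "end", "strand")])
    expect_equal(ord(back$exons), ord(ts$exons))
  }
  # biotype survives the GTF round trip
  p <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(ts, p)
  expect_equal(sort(read_annotation(p)$transcripts$biotype),
               c("PCG", "lncRNA_candidate"))
})

test_that("a mixed-strand fixture parses identically to an ad-hoc parser", {
  p <- withr::local_tempfile(fileext = ".gtf")
  rows <- c(
    'chr1\tx\texon\t11\t60\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\tx\texon\t101\t160\t.\t-\t.\tgene_id "gB"; transcript_id "tB";',
    'chr1\tx\texon\t201\t260\t.\t-\t.\tgene_id "gB"; transcript_id "tB";',
    'chr2\tx\texon\t11\t40\t.\t+\t.\tgene_id "gC"; transcript_id "tC";',
    'chr2\tx\texon\t61\t90\t.\t+\t.\tgene_id "gC"; transcript_id "tC";',
    'chr2\tx\texon\t111\t140\t.\t+\t.\tgene_id "gC"; transcript_id "tC";')
  writeLines(rows, p)
  ts <- read_annotation(p)
  ref <- bf_parse_gtf_exons(p)
  expect_equal(as.list(table(ts$exons$transcript_id)),
               as.list(table(ref$transcript_id)))
  ord <- function(d) {
    d <- d[order(d$transcript_id, d$start),
           c("transcript_id", "chrom", "start", "end", "strand")]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(ts$exons), ord(ref))
})

test_that("malformed annotation lines are reported with their line number", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t11\t60\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    "chr1 broken line"), p)
  expect_error(read_annotation(p), "line 2")
})

test_that("exons outside the declared transcript span raise an error", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\ttranscript\t11\t50\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr1\tx\texon\t11\t80\t.\t+\t.\tgene_id "g"; transcript_id "t";'), p)
  expect_error(read_annotation(p), "outside declared transcript span")
})

test_that("CX reports parse, validate and round-trip", {
  p <- withr::local_tempfile(fileext = ".cx")
  writeLines("chr1\t5\t+\t3\t1\tCG\tCGA", p)
  cx <- read_cx_report(p)
  expect_equal(cx$pos, 4L)
  expect_equal(cx$n_meth, 3L)
  expect_equal(cx$n_total, 4L)

  writeLines(character(), p)
  expect_equal(nrow(read_cx_report(p)), 0)

  writeLines("chr1\t5\t+\t3\t1\tCCC\tCCC", p)
  expect_error(read_cx_report(p), "unknown methylation context")
  writeLines("chr1\t5\t+\t-3\t1\tCG\tCGA", p)
  expect_error(read_cx_report(p), "negative")

  set.seed(7)
  cx <- data.frame(chrom = "c1", pos = sort(sample.int(500, 10)) - 1L,
                   strand = sample(c("+", "-"), 10, TRUE),
                   context = sample(c("CG", "CHG", "CHH"), 10, TRUE),
                   n_meth = rbinom(10, 8, 0.4), n_total = 8L,
                   stringsAsFactors = FALSE)
  write_cx_report(cx, p)
  back <- read_cx_report(p)
  expect_equal(back, cx)
  # per-context tallies match a hand count
  expect_equal(as.vector(table(back$context)[c("CG", "CHG", "CHH")]),
               as.vector(table(cx$context)[c("CG", "CHG", "CHH")]))
})

test_that("tabular hits normalise orientation and round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t95.5\t100\t4\t1\t1\t100\t200\t101\t1e-30\t180",
               "q2\ts1\t100.0\t50\t0\t0\t1\t50\t10\t59\t0\t95"), p)
  h <- read_hits_tabular(p)
  expect_equal(h$s_start[1], 100L)
  expect_equal(h$s_end[1], 200L)
  expect_equal(h$s_strand[1], "-")
  expect_equal(h$s_strand[2], "+")
  expect_equal(h$evalue[2], 0)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tabular(h, p2)
  expect_equal(read_hits_tabular(p2), h)

  writeLines("q1\ts1\t95.5\t100\t4\t1\t1\t100\tabc\t101\t1e-30\t180", p)
  expect_error(read_hits_tabular(p), "non-numeric")
})

test_that("best hit per query by bit score equals a manual pick", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tsA\t90\t100\t0\t0\t1\t100\t1\t100\t1e-20\t120",
               "q1\tsB\t95\t100\t0\t0\t1\t100\t1\t100\t1e-40\t150",
               "q1\tsC\t92\t100\t0\t0\t1\t100\t1\t100\t1e-30\t130",
               "q2\tsA\t99\t100\t0\t0\t1\t100\t1\t100\t1e-50\t190",
               "q2\tsB\t91\t100\t0\t0\t1\t100\t1\t100\t1e-25\t125"), p)
  h <- read_hits_tabular(p)
  best <- do.call(rbind, lapply(split(h, h$query_id), function(d)
    d[which.max(d$bitscore), ]))
  expect_equal(best$subject_id, c("sB", "sA"))
})

test_that("TE BED and sRNA BED round-trip with family vocabulary checks", {
  te <- data.frame(chrom = "c1", start = c(0L, 500L), end = c(300L, 900L),
                   strand = c(".", "+"), family = c("Gypsy", "LINE"),
                   te_id = c("te1", "te2"), stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".bed")
  write_te_bed(te, p)
  expect_equal(read_te_bed(p), te)
  writeLines("c1\t0\t10\tBadFam:te9\t0\t+", p)
  expect_error(read_te_bed(p), "unknown TE family")

  reads <- data.frame(chrom = "c1", start = c(10L, 50L), end = c(31L, 74L),
                      strand = c("+", "-"), read_id = c("r1", "r2"),
                      length = c(21L, 24L), n_mapped_loci = c(1L, 60L),
                      stringsAsFactors = FALSE)
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_srna_bed(reads, p2)
  expect_equal(read_srna_bed(p2), reads)
})

test_that("count matrices round-trip with library sizes", {
  set.seed(3)
  m <- matrix(rpois(20, 50), 5, 4,
              dimnames = list(paste0("L", 1:5), paste0("s", 1:4)))
  cm <- count_matrix(m, c(s1 = 1e5, s2 = 2e5, s3 = 1.5e5, s4 = 9e4))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, p)
  back <- read_count_matrix(p)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$library_sizes, cm$library_sizes)
  expect_error(count_matrix(matrix(-1, 1, 1,
                                   dimnames = list("a", "b"))),
               "non-negative")
})

test_that("DMR tables round-trip through the import path", {
  dmrs <- data.frame(chrom = "c1", start = c(0L, 400L), end = c(200L, 600L),
                     context = c("CG", "CHH"),
                     direction = c("hypo", "hyper"),
                     delta = c(-0.4, 0.2), p = c(1e-5, 1e-3),
                     stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_dmrs(dmrs, p)
  expect_equal(read_dmrs(p), dmrs)
  dmrs$direction[1] <- "sideways"
  write_dmrs(dmrs, p)
  expect_error(read_dmrs(p), "direction")
})

test_that("locus grouping merges same-strand exonic overlap", {
  tr <- data.frame(transcript_id = c("t1", "t2", "t3", "t4"),
                   chrom = "c1", start = c(0L, 50L, 200L, 45L),
                   end = c(100L, 150L, 300L, 120L),
                   strand = c("+", "+", "+", "-"),
                   stringsAsFactors = FALSE)
  ex <- tr
  names(ex)[1] <- "transcript_id"
  ts <- transcript_set(tr[, c("transcript_id", "chrom", "start", "end",
                              "strand")],
                       ex[, c("transcript_id", "chrom", "start", "end",
                              "strand")])
  loc <- ts$transcripts$locus_id
  expect_equal(loc[1], loc[2])      # overlapping, same strand
  expect_false(loc[1] == loc[3])    # disjoint
  expect_false(loc[1] == loc[4])    # antisense overlap stays separate
})
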