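mk_hits <- function(q, s, bits, evalue = 1e-30) {
  data.frame(query_id = q, subject_id = s, percent_identity = 90,
             aln_length = 100L, mismatches = 0L, gap_opens = 0L,
             q_start = 0L, q_end = 100L, s_start = 0L, s_end = 100L,
             s_strand = "+", evalue = evalue, bitscore = bits,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best pairs require mutual top hits under the cutoff", {
  ab <- mk_hits("A1", "B1", 200)
  ba <- mk_hits("B1", "A1", 200)
  expect_equal(reciprocal_best_pairs(ab, ba)$gene_a, "A1")

  # reciprocity broken: A1 -> B1 but B1 -> A2
  ba2 <- mk_hits("B1", "A2", 300)
  expect_equal(nrow(reciprocal_best_pairs(ab, ba2)), 0)

  # E-value gate applies to both directions
  ba3 <- mk_hits("B1", "A1", 200, evalue = 1e-5)
  expect_equal(nrow(reciprocal_best_pairs(ab, ba3)), 0)
  expect_equal(nrow(reciprocal_best_pairs(ab[0, ], ba[0, ])), 0)
})

test_that("reciprocal best pairs with paralogs equal brute-force enumeration", {
  set.seed(13)
  genes_a <- paste0("A", 1:8)
  genes_b <- paste0("B", 1:8)
  # every A hits two B genes (a paralog pair), with random scores
  ab <- do.call(rbind, lapply(1:8, function(i) {
    tg <- c(i, ifelse(i %% 2 == 0, i - 1, i + 1))
    mk_hits(genes_a[i], genes_b[tg], round(runif(2, 50, 300), 1))
  }))
  ba <- do.call(rbind, lapply(1:8, function(i) {
    tg <- c(i, ifelse(i %% 2 == 0, i - 1, i + 1))
    mk_hits(genes_b[i], genes_a[tg], round(runif(2, 50, 300), 1))
  }))
  got <- reciprocal_best_pairs(ab, ba)
  # oracle: literal definition
  top <- function(h, q) {
    d <- h[h$query_id == q & h$evalue < 1e-10, ]
    d$subject_id[which.max(d$bitscore)]
  }
  want <- list()
  for (a in genes_a) {
    b <- top(ab, a)
    if (length(b) && length(top(ba, b)) && top(ba, b) == a)
      want[[a]] <- b
  }
  expect_setequal(paste(got$gene_a, got$gene_b),
                  paste(names(want), unlist(want)))
})

mk_loci <- function(ids, chrom, starts) {
  data.frame(locus_id = ids, chrom = chrom, start = starts,
             end = starts + 100L, strand = "+", stringsAsFactors = FALSE)
}

test_that("perfectly collinear anchors chain into one block", {
  ids_a <- paste0("A", 1:5)
  ids_b <- paste0("B", 1:5)
  pairs <- data.frame(gene_a = ids_a, gene_b = ids_b, score = 100)
  la <- mk_loci(ids_a, "ca", seq(0, 4000, by = 1000))
  lb <- mk_loci(ids_b, "cb", seq(0, 4000, by = 1000))
  bl <- chain_collinear_blocks(pairs, la, lb)
  expect_equal(nrow(bl$blocks), 1)
  expect_equal(bl$blocks$n_anchors, 5L)
  expect_equal(bl$blocks$orientation, "same")
  # 4 anchors do not reach the min_anchors = 5 threshold
  bl4 <- chain_collinear_blocks(pairs[1:4, ], la, lb)
  expect_equal(nrow(bl4$blocks), 0)
  # inverted order in B gives an inverted block
  lb_inv <- mk_loci(ids_b, "cb", seq(4000, 0, by = -1000))
  bl_inv <- chain_collinear_blocks(pairs, la, lb_inv)
  expect_equal(bl_inv$blocks$orientation, "inverted")
  expect_warning(chain_collinear_blocks(rbind(pairs, pairs[1, ]), la, lb),
                 "duplicate")
})

test_that("DP chaining equals exhaustive enumeration on random anchor sets", {
  set.seed(29)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    max_gap <- sample(c(2, 3, 25), 1)
    min_anchors <- sample(2:3, 1)
    ids_a <- paste0("A", 1:n)
    ids_b <- paste0("B", 1:n)
    perm <- sample(n)
    pairs <- data.frame(gene_a = ids_a, gene_b = ids_b[perm],
                        score = round(runif(n, 10, 100), 4))
    la <- mk_loci(ids_a, "ca", (1:n) * 500L)
    lb <- mk_loci(ids_b, "cb", (1:n) * 500L)
    got <- chain_collinear_blocks(pairs, la, lb, min_anchors = min_anchors,
                                  max_gap = max_gap)
    got_sets <- lapply(split(got$anchors$gene_a, got$anchors$block_id),
                       sort)
    anc <- data.frame(gene_a = pairs$gene_a,
                      rank_a = 1:n, rank_b = match(pairs$gene_b, ids_b),
                      score = pairs$score)
    want_sets <- bf_chain_blocks(anc, min_anchors, max_gap)
    expect_equal(unname(got_sets[order(vapply(got_sets, `[`, "", 1))]),
                 unname(want_sets[order(vapply(want_sets, `[`, "", 1))]),
                 info = paste("fixture", rep))
  }
})

syn_fixture <- function() {
  # anchors A1..A6 <-> B1..B6 at matching positions on one chromosome pair
  ids_a <- paste0("A", 1:6)
  ids_b <- paste0("B", 1:6)
  pairs <- data.frame(gene_a = ids_a, gene_b = ids_b, score = 100)
  la <- mk_loci(ids_a, "ca", seq(1000, 26000, by = 5000))
  lb <- mk_loci(ids_b, "cb", seq(1000, 26000, by = 5000))
  blocks <- chain_collinear_blocks(pairs, la, lb)
  list(blocks = blocks, la = la, lb = lb)
}

lnc_hit <- function(q, chrom, s, e, bits = 500, evalue = 1e-40) {
  data.frame(query_id = q, subject_id = chrom, percent_identity = 88,
             aln_length = e - s, mismatches = 0L, gap_opens = 0L,
             q_start = 0L, q_end = e - s, s_start = s, s_end = e,
             s_strand = "+", evalue = evalue, bitscore = bits,
             stringsAsFactors = FALSE)
}

test_that("lncRNA placement assigns ST, SA, SYN_PCG and NON_SYN correctly", {
  fx <- syn_fixture()
  lnc_a <- mk_loci(c("la1", "la2", "la3", "la4", "la5"), "ca",
                   c(3500, 8500, 13500, 18500, 27000))
  lnc_b <- mk_loci(c("lb1"), "cb", 3500)
  pcg_b <- mk_ts(list(id = "B2_t", chrom = "cb", strand = "+",
                      biotype = "PCG", exons = list(c(8500, 8900))))
  hits <- rbind(
    lnc_hit("la1", "cb", 3500, 3600),    # onto transcribed B lncRNA -> ST
    lnc_hit("la2", "cb", 8550, 8650),    # onto a B coding exon -> SYN_PCG
    lnc_hit("la3", "cb", 13500, 13600),  # homology, nothing transcribed -> SA
    lnc_hit("la4", "cb", 18500, 18600, evalue = 1e-3))  # hit fails cutoff
  calls <- place_lncrna(lnc_a, fx$blocks, hits, lnc_b = lnc_b,
                        pcg_b = pcg_b, expressed_b = "lb1")
  expect_equal(stats::setNames(calls$label, calls$lnc_locus_id),
               c(la1 = "ST", la2 = "SYN_PCG", la3 = "SA", la4 = "NON_SYN",
                 la5 = "NON_SYN"))
  expect_equal(calls$partner_locus_id[calls$lnc_locus_id == "la1"], "lb1")
  # every locus gets exactly one label
  expect_equal(nrow(calls), nrow(lnc_a))
  expect_true(all(calls$label %in% c("ST", "SA", "SYN_PCG", "NON_SYN")))
  # the same homologous site without a transcribed partner becomes SA
  calls2 <- place_lncrna(lnc_a[1, ], fx$blocks, hits, lnc_b = lnc_b,
                         pcg_b = pcg_b, expressed_b = character())
  expect_equal(calls2$label, "SA")
})

test_that("placement recovers the planted truth on a 12-locus fixture", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_genomes(cfg)
  hits <- simulate_hits(sim)
  pairs <- reciprocal_best_pairs(hits$pcg_ab, hits$pcg_ba)
  ann <- sim$annotation
  pcg_a <- subset_transcripts(ann$A, ann$A$transcripts$transcript_id[
    ann$A$transcripts$biotype == "PCG"])
  pcg_d <- subset_transcripts(ann$D, ann$D$transcripts$transcript_id[
    ann$D$transcripts$biotype == "PCG"])
  blocks <- chain_collinear_blocks(pairs, locus_spans(pcg_a),
                                   locus_spans(pcg_d))
  lnc_a <- ann$A$transcripts[ann$A$transcripts$biotype ==
                               "lncRNA_candidate", ]
  lnc_a <- data.frame(locus_id = lnc_a$locus_id, chrom = lnc_a$chrom,
                      start = lnc_a$start, end = lnc_a$end,
                      strand = lnc_a$strand)
  lnc_d <- ann$D$transcripts[ann$D$transcripts$biotype ==
                               "lncRNA_candidate", ]
  lnc_d <- data.frame(locus_id = lnc_d$locus_id, chrom = lnc_d$chrom,
                      start = lnc_d$start, end = lnc_d$end,
                      strand = lnc_d$strand)
  calls <- place_lncrna(lnc_a[1:12, ], blocks, hits$lnc_a, lnc_b = lnc_d,
                        pcg_b = pcg_d,
                        expressed_b = lnc_d$locus_id)
  truth <- stats::setNames(sim$truth$category, sim$truth$locus_a)
  expect_equal(unname(calls$label), unname(truth[calls$lnc_locus_id]))
})

test_that("homology presence profiles count genome subsets", {
  h1 <- lnc_hit("l1", "cx", 0, 100)
  h2 <- rbind(lnc_hit("l1", "cy", 0, 100), lnc_hit("l2", "cy", 0, 100))
  hp <- homology_presence(c("l1", "l2", "l3"),
                          list(G1 = h1, G2 = h2), self = "G0")
  expect_equal(unname(hp$profile["l1", ]), c(TRUE, TRUE, TRUE))
  expect_equal(unname(hp$profile["l2", ]), c(TRUE, FALSE, TRUE))
  expect_equal(unname(hp$profile["l3", ]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(hp$summary[["G0"]]), 1)
  expect_equal(unname(hp$summary[["G0+G1+G2"]]), 1)
})

test_that("SA fraction reproduces printed proportions and edge cases", {
  calls <- data.frame(label = c(rep("SA", 1269), rep("ST", 248)))
  saf <- sa_fraction(calls)
  expect_equal(round(saf$percent, 2), 83.65)
  expect_gte(saf$percent, 80)
  expect_equal(sa_fraction(data.frame(label = rep("ST", 5)))$fraction, 0)
  expect_warning(out <- sa_fraction(data.frame(label = "NON_SYN")),
                 "undefined")
  expect_true(is.na(out$fraction))
})
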