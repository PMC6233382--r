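#' Reciprocal best hit pairs between two gene sets
#'
#' A pair (a, b) is kept iff b is a's best hit by bit score in the A-vs-B
#' table, a is b's best hit in the B-vs-A table, and both hits pass the
#' E-value cutoff.  Ties on bit score are broken by lower E-value, then by
#' subject ID, for determinism.
#'
#' @param hits_ab,hits_ba hit tables from [read_hits_tabular()] (queries of
#'   `hits_ab` are genome-A genes, subjects genome-B genes, and vice versa).
#' @param max_evalue E-value cutoff applied to both directions.
#' @return data.frame `gene_a`, `gene_b`, `score` (mean of the two bit
#'   scores).
#' @export
reciprocal_best_pairs <- function(hits_ab, hits_ba, max_evalue = 1e-10) {
  best <- function(h) {
    h <- h[h$evalue < max_evalue, , drop = FALSE]
    if (nrow(h) == 0) return(h)
    h <- h[order(h$query_id, -h$bitscore, h$evalue, h$subject_id), ,
           drop = FALSE]
    h[!duplicated(h$query_id), , drop = FALSE]
  }
  ab <- best(hits_ab)
  ba <- best(hits_ba)
  if (nrow(ab) == 0 || nrow(ba) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  m <- match(ab$subject_id, ba$query_id)
  recip <- !is.na(m) & ba$subject_id[m] == ab$query_id
  out <- data.frame(gene_a = ab$query_id[recip],
                    gene_b = ab$subject_id[recip],
                    score = (ab$bitscore[recip] + ba$bitscore[m[recip]]) / 2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chain collinear anchor pairs into synteny blocks
#'
#' Anchor genes are ranked by position along each chromosome; a
#' maximal-scoring chain is found by dynamic programming over rank space.  A
#' chain may step from anchor i to j iff `0 < rank_A(j) - rank_A(i) <=
#' max_gap` and `0 < |rank_B(j) - rank_B(i)| <= max_gap` with a consistent
#' sign (same or inverted orientation throughout the chain).  Chains with at
#' least `min_anchors` anchors are reported best-first; each anchor belongs
#' to at most one block.
#'
#' @param pairs data.frame from [reciprocal_best_pairs()].
#' @param loci_a,loci_b locus tables (`locus_id`, `chrom`, `start`, ...) for
#'   the two genomes, e.g. from [locus_spans()]; used to rank anchors.
#' @param min_anchors minimum anchors per block.
#' @param max_gap maximum rank gap between consecutive anchors.
#' @return object of class `synteny_blocks`: list with `blocks` (one row per
#'   block: spans in both genomes, orientation, anchor count) and `anchors`
#'   (per-anchor membership with coordinates in both genomes).
#' @export
chain_collinear_blocks <- function(pairs, loci_a, loci_b, min_anchors = 5,
                                   max_gap = 25) {
  dup <- duplicated(pairs[c("gene_a", "gene_b")])
  if (any(dup)) {
    warning(sum(dup), " duplicate anchor pairs collapsed")
    pairs <- pairs[!dup, , drop = FALSE]
  }
  ra <- anchor_ranks(loci_a)
  rb <- anchor_ranks(loci_b)
  ma <- match(pairs$gene_a, ra$locus_id)
  mb <- match(pairs$gene_b, rb$locus_id)
  if (anyNA(ma) || anyNA(mb))
    stop("anchor gene absent from its locus table")
  anc <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    score = pairs$score,
                    chrom_a = ra$chrom[ma], rank_a = ra$rank[ma],
                    start_a = ra$start[ma], end_a = ra$end[ma],
                    chrom_b = rb$chrom[mb], rank_b = rb$rank[mb],
                    start_b = rb$start[mb], end_b = rb$end[mb],
                    stringsAsFactors = FALSE)
  blocks <- list()
  anchors <- list()
  bid <- 0L
  for (key in unique(paste(anc$chrom_a, anc$chrom_b))) {
    sub <- anc[paste(anc$chrom_a, anc$chrom_b) == key, , drop = FALSE]
    repeat {
      ch <- best_chain(sub, max_gap)
      if (length(ch$idx) < min_anchors) break
      bid <- bid + 1L
      picked <- sub[ch$idx, , drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = sprintf("block_%03d", bid),
        chrom_a = picked$chrom_a[1],
        start_a = min(picked$start_a), end_a = max(picked$end_a),
        chrom_b = picked$chrom_b[1],
        start_b = min(picked$start_b), end_b = max(picked$end_b),
        n_anchors = nrow(picked),
        orientation = ch$orientation,
        score = sum(picked$score),
        stringsAsFactors = FALSE)
      picked$block_id <- sprintf("block_%03d", bid)
      anchors[[bid]] <- picked
      sub <- sub[-ch$idx, , drop = FALSE]
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(), chrom_a = character(),
               start_a = integer(), end_a = integer(),
               chrom_b = character(), start_b = integer(),
               end_b = integer(), n_anchors = integer(),
               orientation = character(), score = numeric(),
               stringsAsFactors = FALSE)
  anchors <- if (length(anchors)) do.call(rbind, anchors) else
    cbind(anc[0, ], data.frame(block_id = character()))
  rownames(blocks) <- rownames(anchors) <- NULL
  structure(list(blocks = blocks, anchors = anchors),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks:", nrow(x$blocks), "blocks,",
      nrow(x$anchors), "anchors\n")
  invisible(x)
}

# Rank loci by start position within each chromosome.
anchor_ranks <- function(loci) {
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(loci)), loci$chrom, FUN = seq_along)
  data.frame(locus_id = loci$locus_id, chrom = loci$chrom,
             start = loci$start, end = loci$end, rank = rank,
             stringsAsFactors = FALSE)
}

# Highest-scoring collinear chain among anchors of one chromosome pair.
# DP over anchors sorted by rank_a, run for both orientations.
best_chain <- function(sub, max_gap) {
  n <- nrow(sub)
  if (n == 0) return(list(idx = integer(), orientation = "same"))
  ord <- order(sub$rank_a, sub$rank_b)
  best <- list(idx = integer(), score = -Inf, orientation = "same")
  for (orientation in c("same", "inverted")) {
    sgn <- if (orientation == "same") 1 else -1
    score <- sub$score[ord]
    prev <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1)) {
        da <- sub$rank_a[ord[j]] - sub$rank_a[ord[i]]
        db <- sgn * (sub$rank_b[ord[j]] - sub$rank_b[ord[i]])
        if (da > 0 && da <= max_gap && db > 0 && db <= max_gap) {
          cand <- score[i] + sub$score[ord[j]]
          if (cand > score[j]) {
            score[j] <- cand
            prev[j] <- i
          }
        }
      }
    }
    jmax <- which.max(score)
    if (score[jmax] > best$score) {
      idx <- integer()
      j <- jmax
      while (!is.na(j)) {
        idx <- c(j, idx)
        j <- prev[j]
      }
      best <- list(idx = sort(ord[idx]), score = score[jmax],
                   orientation = orientation)
    }
  }
  best[c("idx", "orientation")]
}

# Map a genome-A position into genome B by linear interpolation between the
# flanking anchors of a block (extrapolation clamps to the block span).
map_to_partner <- function(block_anchors, pos) {
  a <- block_anchors[order(block_anchors$start_a), , drop = FALSE]
  xa <- (a$start_a + a$end_a) / 2
  xb <- (a$start_b + a$end_b) / 2
  if (nrow(a) == 1) return(xb[1])
  y <- stats::approx(xa, xb, xout = pos, rule = 2, ties = mean)$y
  unname(y)
}

#' Swap the genome roles of a synteny block set
#'
#' Blocks are symmetric; this exchanges the A/B columns so the same blocks
#' can be used for the reverse comparison direction.
#'
#' @param blocks a `synteny_blocks` object.
#' @return a `synteny_blocks` object with genomes A and B exchanged.
#' @export
swap_synteny_blocks <- function(blocks) {
  b <- blocks$blocks
  a <- blocks$anchors
  bl <- data.frame(block_id = b$block_id,
                   chrom_a = b$chrom_b, start_a = b$start_b,
                   end_a = b$end_b,
                   chrom_b = b$chrom_a, start_b = b$start_a,
                   end_b = b$end_a,
                   n_anchors = b$n_anchors, orientation = b$orientation,
                   score = b$score, stringsAsFactors = FALSE)
  an <- a
  an$gene_a <- a$gene_b; an$gene_b <- a$gene_a
  an$chrom_a <- a$chrom_b; an$chrom_b <- a$chrom_a
  an$rank_a <- a$rank_b; an$rank_b <- a$rank_a
  an$start_a <- a$start_b; an$start_b <- a$start_a
  an$end_a <- a$end_b; an$end_b <- a$end_a
  structure(list(blocks = bl, anchors = an), class = "synteny_blocks")
}

#' Place lncRNA loci into synteny blocks and classify them
#'
#' Every genome-A lncRNA locus receives exactly one label.  A locus inside a
#' block's A-span whose best passing hit (by bit score, `evalue <
#' max_evalue`, subject on the block's B chromosome, inside the block's
#' B-span) overlaps a transcribed genome-B lncRNA locus is `ST` (syntenic
#' and transcribed in both genomes); if the best in-span hit instead overlaps
#' a genome-B coding exon it is `SYN_PCG`; if homologous sequence exists in
#' the B-span but no genome-B lncRNA is transcribed there it is `SA`
#' (syntenic, allelic-transcribed).  Loci outside all blocks, or with no
#' in-span hit, are `NON_SYN`.
#'
#' @param lnc_a locus table (`locus_id`, `chrom`, `start`, `end`, `strand`)
#'   of genome-A lncRNAs (NATs and intronic RNAs should be excluded first).
#' @param blocks a `synteny_blocks` object from [chain_collinear_blocks()].
#' @param lnc_hits hit table of A-lncRNA sequences against genome B (query =
#'   lncRNA locus ID, subject = genome-B chromosome).
#' @param lnc_b locus table of genome-B lncRNA loci.
#' @param pcg_b genome-B coding [transcript_set()].
#' @param expressed_b IDs of genome-B lncRNA loci considered transcribed
#'   (conventionally RPKM > 0.5 in at least one sample).
#' @param max_evalue hit E-value cutoff.
#' @return data.frame of synteny calls: `lnc_locus_id`, `label`,
#'   `partner_locus_id`, `block_id` and the placement interval in genome B
#'   (interpolated midpoint position as `placed_pos`).
#' @export
place_lncrna <- function(lnc_a, blocks, lnc_hits, lnc_b = NULL,
                         pcg_b = NULL, expressed_b = character(),
                         max_evalue = 1e-10) {
  bl <- blocks$blocks
  hits <- lnc_hits[lnc_hits$evalue < max_evalue, , drop = FALSE]
  pex <- if (!is.null(pcg_b)) pcg_b$exons else NULL
  calls <- lapply(seq_len(nrow(lnc_a)), function(k) {
    loc <- lnc_a[k, ]
    out <- data.frame(lnc_locus_id = loc$locus_id, label = "NON_SYN",
                      partner_locus_id = NA_character_,
                      block_id = NA_character_,
                      placed_chrom = NA_character_,
                      placed_start = NA_integer_, placed_end = NA_integer_,
                      placed_pos = NA_real_, stringsAsFactors = FALSE)
    inb <- which(bl$chrom_a == loc$chrom & bl$start_a < loc$end &
                   bl$end_a > loc$start)
    if (!length(inb)) return(out)
    b <- bl[inb[1], ]
    out$block_id <- b$block_id
    ba <- blocks$anchors[blocks$anchors$block_id == b$block_id, ,
                         drop = FALSE]
    out$placed_pos <- map_to_partner(ba, (loc$start + loc$end) / 2)
    h <- hits[hits$query_id == loc$locus_id &
                hits$subject_id == b$chrom_b &
                hits$s_start < b$end_b & hits$s_end > b$start_b, ,
              drop = FALSE]
    if (nrow(h) == 0) return(out)
    h <- h[order(-h$bitscore, h$evalue, h$s_start), , drop = FALSE][1, ]
    out$placed_chrom <- h$subject_id
    out$placed_start <- h$s_start
    out$placed_end <- h$s_end
    hit_iv <- data.frame(chrom = h$subject_id, start = h$s_start,
                         end = h$s_end, strand = ".",
                         stringsAsFactors = FALSE)
    if (!is.null(lnc_b) && nrow(lnc_b)) {
      expr_b <- lnc_b[lnc_b$locus_id %in% expressed_b, , drop = FALSE]
      ov <- interval_overlaps(hit_iv, expr_b)
      if (nrow(ov)) {
        out$label <- "ST"
        out$partner_locus_id <-
          expr_b$locus_id[ov$subject[which.max(ov$overlap_bp)]]
        return(out)
      }
    }
    if (!is.null(pex) && nrow(interval_overlaps(hit_iv, pex))) {
      out$label <- "SYN_PCG"
      return(out)
    }
    out$label <- "SA"
    out
  })
  do.call(rbind, calls)
}

#' Homology presence profile across genomes
#'
#' For each locus, the subset of target genomes with at least one passing
#' hit (the locus' own genome is always present).
#'
#' @param locus_ids character vector of query locus IDs.
#' @param hits_list named list of hit tables, one per target genome.
#' @param self label of the loci's own genome.
#' @param max_evalue hit E-value cutoff.
#' @return list with `profile` (logical matrix loci x genomes) and `summary`
#'   (counts per genome subset).
#' @export
homology_presence <- function(locus_ids, hits_list, self = "self",
                              max_evalue = 1e-10) {
  genomes <- names(hits_list)
  prof <- matrix(FALSE, length(locus_ids), length(genomes) + 1,
                 dimnames = list(locus_ids, c(self, genomes)))
  prof[, self] <- TRUE
  for (g in genomes) {
    h <- hits_list[[g]]
    ok <- unique(h$query_id[h$evalue < max_evalue])
    prof[locus_ids %in% ok, g] <- TRUE
  }
  subset_key <- apply(prof, 1, function(r)
    paste(colnames(prof)[r], collapse = "+"))
  list(profile = prof, summary = table(subset_key))
}

#' Fraction of SA calls among syntenic lncRNA homologs
#'
#' @param calls data.frame from [place_lncrna()] (possibly concatenated over
#'   both comparison directions).
#' @return list `n_sa`, `n_st`, `fraction` (`n_sa / (n_sa + n_st)`),
#'   `percent`; fraction and percent are `NA` with a warning when no ST or
#'   SA calls exist.
#' @export
sa_fraction <- function(calls) {
  n_sa <- sum(calls$label == "SA")
  n_st <- sum(calls$label == "ST")
  if (n_sa + n_st == 0) {
    warning("no ST or SA calls; SA fraction undefined")
    return(list(n_sa = n_sa, n_st = n_st, fraction = NA_real_,
                percent = NA_real_))
  }
  f <- n_sa / (n_sa + n_st)
  list(n_sa = n_sa, n_st = n_st, fraction = f, percent = 100 * f)
}
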