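#' Simulate RNA-seq counts for parents, F1 and allotetraploid
#'
#' Locus-level counts over the union of annotated loci: two replicates each
#' of parent A, parent D, the F1 hybrid and the allotetraploid.  Parent
#' samples cover only their own genome's loci.  F1 (and allotetraploid)
#' means sit at the depth-normalised mid-parent, multiplied by the planted
#' reprogramming effect (`2^f1_log2_effect`) for reprogrammed lncRNA loci,
#' then rescaled to the library depth; counts are negative-binomial with
#' dispersion `nb_dispersion` (Poisson at dispersion 0).
#'
#' @param sim a `polylnc_sim` from [simulate_genomes()].
#' @param n_reps replicates per group (default 2).
#' @return a [count_matrix()] with samples `A_1..`, `D_1..`, `F1_1..`,
#'   `T_1..`; library sizes are the nominal `read_depth`.
#' @export
simulate_counts <- function(sim, n_reps = 2) {
  cfg <- sim$config
  truth <- sim$truth
  with_seed(stream_seed(cfg$seed, 2L), {
    n_genes <- nrow(sim$pcg_layout)
    mu_pcg <- stats::rlnorm(n_genes, log(cfg$pcg_mean_expr), cfg$expr_sdlog)
    mu_lnc <- stats::rlnorm(nrow(truth), log(cfg$lnc_mean_expr),
                            cfg$expr_sdlog)
    ids_pcg_a <- sprintf("A_pcg%03d", seq_len(n_genes))
    ids_pcg_d <- sprintf("D_pcg%03d", seq_len(n_genes))
    lnc_a <- truth$locus_a[truth$annotated_a]
    lnc_d <- truth$locus_b[truth$annotated_b]
    universe <- c(ids_pcg_a, lnc_a, ids_pcg_d, lnc_d)
    mu_a <- mu_d <- stats::setNames(numeric(length(universe)), universe)
    mu_a[ids_pcg_a] <- mu_pcg
    mu_a[lnc_a] <- mu_lnc[truth$annotated_a]
    mu_d[ids_pcg_d] <- mu_pcg
    mu_d[lnc_d] <- mu_lnc[truth$annotated_b]
    mu_a <- mu_a / sum(mu_a) * cfg$read_depth
    mu_d <- mu_d / sum(mu_d) * cfg$read_depth
    eff <- stats::setNames(rep(1, length(universe)), universe)
    eff[lnc_a] <- 2^truth$f1_log2_effect[truth$annotated_a]
    eff[lnc_d] <- 2^truth$f1_log2_effect[truth$annotated_b]
    mu_f <- (mu_a + mu_d) / 2 * eff
    mu_f <- mu_f / sum(mu_f) * cfg$read_depth
    draw <- function(mu) {
      if (cfg$nb_dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
      else stats::rpois(length(mu), mu)
    }
    groups <- list(A = mu_a, D = mu_d, F1 = mu_f, T = mu_f)
    cols <- list()
    for (g in names(groups)) for (r in seq_len(n_reps))
      cols[[paste0(g, "_", r)]] <- draw(groups[[g]])
    counts <- do.call(cbind, cols)
    rownames(counts) <- universe
    count_matrix(counts, stats::setNames(rep(cfg$read_depth, ncol(counts)),
                                         colnames(counts)))
  })
}

#' Spliced locus lengths of a simulation's annotation
#'
#' @param sim a `polylnc_sim`.
#' @return named vector of spliced lengths for every annotated locus.
#' @export
sim_locus_lengths <- function(sim) {
  ts <- sim$annotation$F1
  len <- spliced_lengths(ts)
  stats::setNames(as.integer(len), ts$transcripts$locus_id)
}

# per-bp feature class for methylation baselines; later assignments win
meth_class_vector <- function(sim, genome, chrom) {
  L <- sim$chrom_lengths[[chrom]]
  cls <- rep(1L, L)  # background
  paint <- function(start, end, value) {
    s <- pmax(start, 0L) + 1L
    e <- pmin(end, L)
    for (k in seq_along(s)) if (e[k] >= s[k]) cls[s[k]:e[k]] <<- value
  }
  ann <- sim$annotation[[genome]]$transcripts
  pcg <- ann[ann$biotype == "PCG" & ann$chrom == chrom, ]
  paint(pcg$start, pcg$end, 2L)
  lnc <- ann[ann$biotype != "PCG" & ann$chrom == chrom, ]
  paint(lnc$start, lnc$end, 3L)
  te <- sim$te[[genome]]
  te <- te[te$chrom == chrom, ]
  bg <- te[!te$on_lnc, ]
  paint(bg$start, bg$end, 4L)
  lte <- te[te$on_lnc & te$family != "LINE", ]
  paint(lte$start, lte$end, 5L)
  lline <- te[te$on_lnc & te$family == "LINE", ]
  paint(lline$start, lline$end, 6L)
  cls
}

#' Simulate per-cytosine methylomes for the mid-parent and the F1
#'
#' Cytosines (both strands) are located in the actual simulated sequence and
#' classified into CG/CHG/CHH by their trinucleotide context.  Baseline
#' methylation probabilities follow the feature class under each cytosine
#' (background, coding-gene body, lncRNA body, TE, lncRNA-overlapped TE,
#' lncRNA-overlapped LINE).  In the F1 sample the planted per-pair
#' methylation delta (anticorrelated with the expression change) shifts the
#' probability over each annotated lncRNA locus and its planted TE.
#' Coverage is Poisson(`meth_coverage`); methylated calls are binomial.
#'
#' @param sim a `polylnc_sim`.
#' @return list with elements `parent` and `f1`, each a cytosine record
#'   table in the format of [read_cx_report()], over the F1 chromosome set.
#' @export
simulate_methylome <- function(sim) {
  cfg <- sim$config
  truth <- sim$truth
  base <- do.call(rbind, cfg$meth_baseline[c("background", "pcg_body",
                                             "lnc_body", "te", "lnc_te",
                                             "lnc_te_line")])
  with_seed(stream_seed(cfg$seed, 3L), {
    out_parent <- list()
    out_f1 <- list()
    for (genome in c("A", "D")) {
      ann_col <- if (genome == "A") "annotated_a" else "annotated_b"
      for (chrom in sim$chroms[[genome]]) {
        s <- sim$genomes[[genome]][[chrom]]
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        L <- length(ch)
        posC <- which(ch == "C")
        posG <- which(ch == "G")
        nxt1 <- c(ch[-1], "N")[posC]
        nxt2 <- c(ch[-(1:2)], "N", "N")[posC]
        ctxC <- ifelse(nxt1 == "G", "CG", ifelse(nxt2 == "G", "CHG", "CHH"))
        prv1 <- c("N", ch[-L])[posG]
        prv2 <- c("N", "N", ch[-((L - 1):L)])[posG]
        ctxG <- ifelse(prv1 == "C", "CG", ifelse(prv2 == "C", "CHG", "CHH"))
        pos <- c(posC, posG)
        strand <- rep(c("+", "-"), c(length(posC), length(posG)))
        ctx <- c(ctxC, ctxG)
        cls <- meth_class_vector(sim, genome, chrom)[pos]
        ctx_col <- match(ctx, METH_CONTEXTS)
        pi0 <- base[cbind(cls, ctx_col)]
        # planted delta over annotated lncRNA loci (locus span + its TE)
        delta_bp <- matrix(0, length(pos), 3)
        rows <- which(truth[[ann_col]] &
                        sim$chroms[[genome]][truth$chrom_idx] == chrom)
        chrom_idx_local <- match(chrom, sim$chroms[[genome]])
        te_g <- sim$te[[genome]]
        for (i in rows) {
          s0 <- truth$start[i]
          e0 <- truth$end[i]
          tei <- which(te_g$on_lnc & !is.na(te_g$pair_id) &
                         te_g$pair_id == truth$pair_id[i] &
                         te_g$chrom == chrom)
          if (length(tei)) {
            s0 <- min(s0, te_g$start[tei])
            e0 <- max(e0, te_g$end[tei])
          }
          hit <- which(pos > s0 & pos <= e0)
          if (!length(hit)) next
          delta_bp[hit, 1] <- truth$delta_cg[i]
          delta_bp[hit, 2] <- truth$delta_chg[i]
          delta_bp[hit, 3] <- truth$delta_chh[i]
        }
        delta <- delta_bp[cbind(seq_along(pos), ctx_col)]
        mk <- function(pi_site) {
          n_tot <- stats::rpois(length(pos), cfg$meth_coverage)
          n_met <- stats::rbinom(length(pos), n_tot,
                                 pmin(0.99, pmax(0.01, pi_site)))
          data.frame(chrom = chrom, pos = pos - 1L, strand = strand,
                     context = ctx, n_meth = n_met, n_total = n_tot,
                     stringsAsFactors = FALSE)
        }
        out_parent[[chrom]] <- mk(pi0)
        out_f1[[chrom]] <- mk(pi0 + delta)
        rm(delta_bp)
      }
    }
    sort_cx <- function(l) {
      d <- do.call(rbind, l)
      d <- d[order(d$chrom, d$pos), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    list(parent = sort_cx(out_parent), f1 = sort_cx(out_f1))
  })
}

#' Simulate small-RNA reads over the F1 genome
#'
#' Read starts are sampled from a per-bp weight landscape: high over TE
#' bodies, lower over their flanks; coding genes the other way around
#' (flanks above body); background lowest.  lncRNA-overlapped TEs are
#' depleted by `srna_lnc_te_depletion` (LINEs further, by
#' `srna_lnc_te_line_depletion`).  Read lengths are mostly 20-25 nt with a
#' small out-of-range tail, and a small fraction of reads carries high
#' multi-mapping multiplicity, so [filter_srna()] has work to do.
#'
#' @param sim a `polylnc_sim`.
#' @return data.frame of reads in the format of [read_srna_bed()].
#' @export
simulate_srna <- function(sim) {
  cfg <- sim$config
  w <- cfg$srna_weights
  with_seed(stream_seed(cfg$seed, 4L), {
    chroms <- c(sim$chroms$A, sim$chroms$D)
    weights <- lapply(chroms, function(chrom) {
      genome <- if (chrom %in% sim$chroms$A) "A" else "D"
      L <- sim$chrom_lengths[[chrom]]
      wv <- rep(w[["background"]], L)
      paint <- function(start, end, value) {
        s <- pmax(start, 0L) + 1L
        e <- pmin(end, L)
        for (k in seq_along(s)) if (e[k] >= s[k]) wv[s[k]:e[k]] <<- value
      }
      ann <- sim$annotation[[genome]]$transcripts
      pcg <- ann[ann$biotype == "PCG" & ann$chrom == chrom, ]
      paint(pcg$start - 500L, pcg$end + 500L, w[["pcg_flank"]])
      paint(pcg$start, pcg$end, w[["pcg_body"]])
      te <- sim$te[[genome]]
      te <- te[te$chrom == chrom, ]
      bg <- te[!te$on_lnc, ]
      paint(bg$start - 500L, bg$end + 500L, w[["te_flank"]])
      paint(bg$start, bg$end, w[["te_body"]])
      lte <- te[te$on_lnc & te$family != "LINE", ]
      paint(lte$start, lte$end, w[["te_body"]] * w[["lnc_te_depletion"]])
      lline <- te[te$on_lnc & te$family == "LINE", ]
      paint(lline$start, lline$end,
            w[["te_body"]] * w[["lnc_te_line_depletion"]])
      wv
    })
    names(weights) <- chroms
    per_chrom <- proportional_counts(cfg$srna_depth,
                                     vapply(weights, sum, numeric(1)))
    reads <- list()
    counter <- 0L
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      n <- per_chrom[ci]
      if (n == 0) next
      L <- sim$chrom_lengths[[chrom]]
      start <- sample.int(L, n, replace = TRUE, prob = weights[[chrom]]) - 1L
      len <- sample(c(20:25, 18L, 19L, 26L, 27L), n, replace = TRUE,
                    prob = c(rep(0.94 / 6, 6), rep(0.06 / 4, 4)))
      nml <- 1L + stats::rpois(n, 0.2)
      hi <- stats::runif(n) < 0.02
      nml[hi] <- sample(45:80, sum(hi), replace = TRUE)
      reads[[chrom]] <- data.frame(
        chrom = chrom, start = start,
        end = pmin(start + len, L),
        strand = sample(c("+", "-"), n, replace = TRUE),
        read_id = sprintf("sr%07d", counter + seq_len(n)),
        length = len, n_mapped_loci = nml, stringsAsFactors = FALSE)
      counter <- counter + n
    }
    out <- do.call(rbind, reads)
    out$length <- out$end - out$start
    rownames(out) <- NULL
    out
  })
}

#' Derive homology hit tables from the simulated sequences
#'
#' Emits 12-column-style hit tables (in the internal normalised format of
#' [read_hits_tabular()]) for the anchor genes (reciprocal, both directions)
#' and for each genome's annotated lncRNA loci against the partner genome.
#' Percent identity is measured from the actual simulated sequences; loci
#' planted without a homolog yield no hit.  A few weak decoy hits (low bit
#' score, outside the anchor span) exercise best-hit selection.
#'
#' @param sim a `polylnc_sim`.
#' @return list `pcg_ab`, `pcg_ba`, `lnc_a`, `lnc_b`.
#' @export
simulate_hits <- function(sim) {
  cfg <- sim$config
  truth <- sim$truth
  pcg <- sim$pcg_layout
  with_seed(stream_seed(cfg$seed, 5L), {
    hit_row <- function(qid, sid, qlen, s_start, s_end, pident, evalue,
                        bitscore) {
      data.frame(query_id = qid, subject_id = sid,
                 percent_identity = round(pident, 2),
                 aln_length = as.integer(qlen), mismatches = 0L,
                 gap_opens = 0L, q_start = 0L, q_end = as.integer(qlen),
                 s_start = as.integer(s_start), s_end = as.integer(s_end),
                 s_strand = "+", evalue = evalue, bitscore = bitscore,
                 stringsAsFactors = FALSE)
    }
    n_genes <- nrow(pcg)
    ids_a <- sprintf("A_pcg%03d", seq_len(n_genes))
    ids_d <- sprintf("D_pcg%03d", seq_len(n_genes))
    pid <- vapply(seq_len(n_genes), function(i) {
      cha <- sim$chroms$A[pcg$chrom_idx[i]]
      chd <- sim$chroms$D[pcg$chrom_idx[i]]
      seq_identity(substr(sim$genomes$A[[cha]], pcg$start[i] + 1,
                          pcg$end[i]),
                   substr(sim$genomes$D[[chd]], pcg$start[i] + 1,
                          pcg$end[i]))
    }, numeric(1))
    glen <- pcg$end - pcg$start
    bits <- round(1.8 * glen * pid / 100, 1)
    ab <- do.call(rbind, lapply(seq_len(n_genes), function(i)
      hit_row(ids_a[i], ids_d[i], glen[i], 0, glen[i], pid[i], 1e-180,
              bits[i])))
    ba <- do.call(rbind, lapply(seq_len(n_genes), function(i)
      hit_row(ids_d[i], ids_a[i], glen[i], 0, glen[i], pid[i], 1e-180,
              bits[i])))
    # weak paralog decoys (never reciprocal best)
    for (i in seq_len(min(5, n_genes - 1))) {
      ab <- rbind(ab, hit_row(ids_a[i], ids_d[i + 1], glen[i], 0, glen[i],
                              70, 1e-15, 0.3 * bits[i]))
      ba <- rbind(ba, hit_row(ids_d[i + 1], ids_a[i], glen[i], 0, glen[i],
                              70, 1e-15, 0.3 * bits[i]))
    }
    lnc_hits <- function(from) {
      ann_col <- if (from == "A") "annotated_a" else "annotated_b"
      id_col <- if (from == "A") "locus_a" else "locus_b"
      to <- if (from == "A") "D" else "A"
      rows <- which(truth[[ann_col]] & !is.na(truth$hom_start))
      h <- do.call(rbind, lapply(rows, function(i) {
        ch_from <- sim$chroms[[from]][truth$chrom_idx[i]]
        ch_to <- sim$chroms[[to]][truth$chrom_idx[i]]
        q <- substr(sim$genomes[[from]][[ch_from]], truth$start[i] + 1,
                    truth$end[i])
        s <- substr(sim$genomes[[to]][[ch_to]], truth$hom_start[i] + 1,
                    truth$hom_end[i])
        pidl <- seq_identity(q, s)
        hit_row(truth[[id_col]][i], ch_to, truth$end[i] - truth$start[i],
                truth$hom_start[i], truth$hom_end[i], pidl, 1e-60,
                round(2 * nchar(q) * pidl / 100, 1))
      }))
      # weak decoy hits near the chromosome start, outside any anchor span
      if (length(rows)) {
        dec <- rows[seq_len(min(5, length(rows)))]
        h <- rbind(h, do.call(rbind, lapply(dec, function(i) {
          ch_to <- sim$chroms[[to]][truth$chrom_idx[i]]
          hit_row(truth[[id_col]][i], ch_to, 60, 100, 160, 78, 1e-12, 45)
        })))
      }
      h
    }
    list(pcg_ab = ab, pcg_ba = ba,
         lnc_a = lnc_hits("A"), lnc_b = lnc_hits("D"))
  })
}

tet_chrom <- function(chrom) {
  sub("^A", "At", sub("^D", "Dt", chrom))
}

relabel_tetraploid <- function(ts) {
  ts$transcripts$chrom <- tet_chrom(ts$transcripts$chrom)
  ts$exons$chrom <- tet_chrom(ts$exons$chrom)
  ts
}

#' Write a simulation to disk in standard formats
#'
#' FASTA per genome (A, D, F1 = both chromosome sets, T = relabelled
#' allotetraploid), GTF annotations, TE BED files and the truth table TSV.
#' Everything written here re-reads through the package's own readers.
#'
#' @param sim a `polylnc_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  seq_a <- unlist(sim$genomes$A)
  seq_d <- unlist(sim$genomes$D)
  fastas <- list(A = seq_a, D = seq_d, F1 = c(seq_a, seq_d),
                 T = stats::setNames(c(seq_a, seq_d),
                                     tet_chrom(names(c(seq_a, seq_d)))))
  for (g in names(fastas)) {
    p <- file.path(dir, paste0(g, ".fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(fastas[[g]]), p)
    paths[[paste0("fasta_", g)]] <- p
  }
  anns <- list(A = sim$annotation$A, D = sim$annotation$D,
               F1 = sim$annotation$F1,
               T = relabel_tetraploid(sim$annotation$F1))
  for (g in names(anns)) {
    p <- file.path(dir, paste0(g, ".gtf"))
    write_annotation(anns[[g]], p)
    paths[[paste0("gtf_", g)]] <- p
  }
  for (g in c("A", "D", "F1")) {
    p <- file.path(dir, paste0(g, "_te.bed"))
    write_te_bed(sim$te[[g]], p)
    paths[[paste0("te_", g)]] <- p
  }
  p <- file.path(dir, "truth.tsv")
  data.table::fwrite(sim$truth, p, sep = "\t")
  paths$truth <- p
  invisible(paths)
}
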