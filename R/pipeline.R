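#' Default analysis thresholds
#'
#' The numeric constants of the analysis, each a named key: minimum lncRNA
#' length 200 nt, coding-score cutoff 0, homology E-value 1e-10, at least 5
#' anchors per synteny block (gap at most 25 gene ranks), expressed at
#' RPKM > 0.5, differential expression at p < 0.01 with fold change > 2 (or
#' < 0.5), 2 kb feature flanks, and the DMR stand-in caller's window
#' parameters.
#'
#' @return named list of thresholds.
#' @export
pipeline_thresholds <- function() {
  list(min_length = 200, coding_score_max = 0, domain_evalue = 0.001,
       hit_evalue = 1e-10, min_anchors = 5, max_gap = 25,
       expressed_rpkm = 0.5, de_alpha = 0.01, de_fc = 2, flank = 2000,
       dmr_window = 100, dmr_step = 50, dmr_min_cyt = 4, dmr_alpha = 0.01,
       dmr_min_delta = 0.1)
}

subset_biotype <- function(ts, biotypes) {
  subset_transcripts(ts,
    ts$transcripts$transcript_id[ts$transcripts$biotype %in% biotypes])
}

expressed_loci <- function(rpkm_mat, threshold = 0.5) {
  rownames(rpkm_mat)[apply(rpkm_mat, 1, max) > threshold]
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> write -> re-read -> classify -> synteny ->
#' TE overlap -> expression -> methylation/DMR -> profiles, and assembles a
#' machine-readable summary.  Every intermediate is written to `out_dir`
#' in a standard text format and the analysis consumes the re-read files,
#' so the report is reproducible from the directory alone.  Deterministic
#' for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param thresholds analysis thresholds, see [pipeline_thresholds()].
#' @return a `polylnc_report` list: per-stage tallies, synteny calls and SA
#'   fraction, DE summaries, TE composition and enrichment, DMR
#'   composition and association, methylation-expression correlations, and
#'   profile summaries.  Also written as `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         thresholds = pipeline_thresholds()) {
  issues <- validate_config(config)
  if (length(issues))
    stop("configuration invalid: ", paste(issues, collapse = "; "))
  th <- thresholds
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## ---- simulate and write every input ----
  sim <- simulate_genomes(config)
  paths <- write_simulation(sim, out_dir)
  counts <- simulate_counts(sim)
  write_count_matrix(counts, file.path(out_dir, "counts.tsv"))
  hits <- simulate_hits(sim)
  for (h in names(hits))
    write_hits_tabular(hits[[h]], file.path(out_dir,
                                            paste0("hits_", h, ".tsv")))
  meth <- simulate_methylome(sim)
  write_cx_report(meth$parent, file.path(out_dir, "parent.cx"))
  write_cx_report(meth$f1, file.path(out_dir, "f1.cx"))
  srna <- simulate_srna(sim)
  write_srna_bed(srna, file.path(out_dir, "srna.bed"))

  ## ---- read everything back through the package readers ----
  ann <- list(A = read_annotation(file.path(out_dir, "A.gtf")),
              D = read_annotation(file.path(out_dir, "D.gtf")))
  te_f1 <- read_te_bed(file.path(out_dir, "F1_te.bed"))
  cm <- read_count_matrix(file.path(out_dir, "counts.tsv"))
  cx_parent <- read_cx_report(file.path(out_dir, "parent.cx"))
  cx_f1 <- read_cx_report(file.path(out_dir, "f1.cx"))
  hits <- lapply(stats::setNames(names(hits), names(hits)), function(h)
    read_hits_tabular(file.path(out_dir, paste0("hits_", h, ".tsv"))))
  srna <- read_srna_bed(file.path(out_dir, "srna.bed"))
  genome_seq <- c(sim$genomes$A, sim$genomes$D)

  ## ---- lncRNA classification per genome ----
  lnc <- list()
  classify_tally <- list()
  for (g in c("A", "D")) {
    cand <- subset_biotype(ann[[g]], "lncRNA_candidate")
    pcgs <- subset_biotype(ann[[g]], "PCG")
    codes <- assign_class_code(cand, pcgs)
    seqs <- transcript_sequences(cand, genome_seq)
    evid <- data.frame(
      transcript_id = names(seqs),
      coding_score = vapply(seqs, builtin_coding_score, numeric(1)),
      has_domain_hit = FALSE, stringsAsFactors = FALSE)
    lnc[[g]] <- filter_lncrna(cand, class_codes = codes, evidence = evid,
                              min_length = th$min_length)
    classify_tally[[g]] <- list(
      n_candidates = nrow(cand$transcripts),
      n_kept = nrow(lnc[[g]]$transcripts),
      codes = as.list(table(codes)))
  }

  ## ---- expression: mid-parent mix and DE classes ----
  lengths <- sim_locus_lengths(sim)
  grp <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_"), colnames(cm$counts), value = TRUE)
    count_matrix(cm$counts[, cols, drop = FALSE], cm$library_sizes[cols])
  }
  cm_a <- grp("A"); cm_d <- grp("D"); cm_f1 <- grp("F1")
  mix <- in_silico_mix(cm_a, cm_d)
  rpkm_f1 <- rpkm(cm_f1, lengths)
  rpkm_mix <- rpkm(mix, lengths)
  rpkm_a <- rpkm(cm_a, lengths)
  rpkm_d <- rpkm(cm_d, lengths)
  de <- de_test(cm_f1$counts, mix$counts)
  cls <- classify_de(de, rpkm_f1, rpkm_mix, alpha = th$de_alpha,
                     fc = th$de_fc, expressed_rpkm = th$expressed_rpkm)
  lnc_ids <- c(lnc$A$transcripts$locus_id, lnc$D$transcripts$locus_id)
  pcg_ids <- setdiff(rownames(cm$counts), lnc_ids)
  rec_lnc <- cls$records[cls$records$locus_id %in% lnc_ids, ]
  de_summary_lnc <- list(
    n_up = sum(rec_lnc$de_class == "Up"),
    n_down = sum(rec_lnc$de_class == "Down"),
    n_de = sum(rec_lnc$de_class %in% c("Up", "Down")),
    n_expressed = sum(rec_lnc$expressed))
  de_summary_lnc$percent_de <- percent_de(de_summary_lnc$n_de,
                                          de_summary_lnc$n_expressed)
  spearman <- list(
    lnc = expression_correlation(rowMeans(rpkm_mix)[lnc_ids],
                                 rowMeans(rpkm_f1)[lnc_ids]),
    pcg = expression_correlation(rowMeans(rpkm_mix)[pcg_ids],
                                 rowMeans(rpkm_f1)[pcg_ids]))

  ## ---- synteny: blocks and ST/SA calls in both directions ----
  pairs <- reciprocal_best_pairs(hits$pcg_ab, hits$pcg_ba,
                                 max_evalue = th$hit_evalue)
  pcg_spans <- lapply(ann, function(a) locus_spans(subset_biotype(a, "PCG")))
  blocks <- chain_collinear_blocks(pairs, pcg_spans$A, pcg_spans$D,
                                   min_anchors = th$min_anchors,
                                   max_gap = th$max_gap)
  lnc_spans <- lapply(lnc, function(l)
    locus_spans(subset_biotype(l, "lincRNA")))
  expr_a <- expressed_loci(rpkm_a, th$expressed_rpkm)
  expr_d <- expressed_loci(rpkm_d, th$expressed_rpkm)
  calls_ad <- place_lncrna(lnc_spans$A, blocks, hits$lnc_a,
                           lnc_b = lnc_spans$D,
                           pcg_b = subset_biotype(ann$D, "PCG"),
                           expressed_b = expr_d,
                           max_evalue = th$hit_evalue)
  calls_da <- place_lncrna(lnc_spans$D, swap_synteny_blocks(blocks),
                           hits$lnc_b, lnc_b = lnc_spans$A,
                           pcg_b = subset_biotype(ann$A, "PCG"),
                           expressed_b = expr_a,
                           max_evalue = th$hit_evalue)
  calls <- rbind(calls_ad, calls_da)
  # ST homolog pairs are recovered from both comparison directions;
  # deduplicate to unordered pairs so the SA fraction counts locus pairs
  pair_key <- ifelse(calls$label == "ST" & !is.na(calls$partner_locus_id),
                     paste(pmin(calls$lnc_locus_id, calls$partner_locus_id),
                           pmax(calls$lnc_locus_id, calls$partner_locus_id)),
                     calls$lnc_locus_id)
  calls_pairs <- calls[!duplicated(paste(calls$label, pair_key)), ,
                       drop = FALSE]
  saf <- sa_fraction(calls_pairs)
  truth_label <- c(stats::setNames(sim$truth$category, sim$truth$locus_a),
                   stats::setNames(sim$truth$category, sim$truth$locus_b))
  conf <- table(truth = truth_label[calls$lnc_locus_id],
                called = calls$label)
  recall_by_label <- vapply(SYNTENY_LABELS, function(l) {
    n <- sum(conf[rownames(conf) == l, ])
    if (n == 0) return(NA_real_)
    sum(conf[rownames(conf) == l, colnames(conf) == l]) / n
  }, numeric(1))
  data.table::fwrite(calls, file.path(out_dir, "synteny_calls.tsv"),
                     sep = "\t")
  data.table::fwrite(blocks$blocks, file.path(out_dir, "blocks.tsv"),
                     sep = "\t")

  ## ---- TE landscape ----
  lnc_all <- transcript_set(rbind(lnc$A$transcripts, lnc$D$transcripts),
                            rbind(lnc$A$exons, lnc$D$exons))
  regions <- decompose_regions(lnc_all, flank = th$flank,
                               chrom_lengths = sim$chrom_lengths)
  assigns <- assign_te(regions, te_f1)
  comp <- te_composition(assigns)
  st_ids <- calls$lnc_locus_id[calls$label == "ST"]
  sa_ids <- calls$lnc_locus_id[calls$label == "SA"]
  enrich <- family_enrichment(st_ids, sa_ids, assigns)
  data.table::fwrite(assigns, file.path(out_dir, "te_assignments.tsv"),
                     sep = "\t")

  ## ---- methylation: per-locus deltas, DMRs, association ----
  all_lnc_spans <- rbind(lnc_spans$A, lnc_spans$D)
  delta_meth <- data.frame(locus_id = all_lnc_spans$locus_id,
                           stringsAsFactors = FALSE)
  for (ctx in METH_CONTEXTS) {
    lv_p <- weighted_methylation(cx_parent, all_lnc_spans, ctx)
    lv_f <- weighted_methylation(cx_f1, all_lnc_spans, ctx)
    delta_meth[[ctx]] <- lv_f - lv_p
  }
  dmrs <- call_dmrs(cx_parent, cx_f1, window = th$dmr_window,
                    step = th$dmr_step, min_cyt = th$dmr_min_cyt,
                    alpha = th$dmr_alpha, min_delta = th$dmr_min_delta,
                    chrom_lengths = sim$chrom_lengths)
  write_dmrs(dmrs, file.path(out_dir, "dmrs.tsv"))
  dmr_comp <- dmr_context_composition(dmrs)
  assoc <- dmr_expression_association(dmrs, all_lnc_spans, cls$records,
                                      flank = th$flank)
  de_lnc_ids <- rec_lnc$locus_id[rec_lnc$de_class %in% c("Up", "Down")]
  with_dmr <- if (nrow(assoc$assignments)) assoc$assignments$locus_id else
    character()
  subset_ids <- intersect(de_lnc_ids, with_dmr)
  if (length(subset_ids) < 10) subset_ids <- de_lnc_ids
  fc_vec <- stats::setNames(cls$records$log2fc, cls$records$locus_id)
  meth_expr_rho <- methylation_expression_correlation(
    delta_meth, fc_vec, subset = subset_ids)

  ## ---- coverage profiles ----
  sirna <- filter_srna(srna)
  track <- coverage_track(sirna, sim$chrom_lengths)
  te_feats <- function(d) data.frame(chrom = d$chrom, start = d$start,
                                     end = d$end, strand = d$strand,
                                     stringsAsFactors = FALSE)
  is_lnc_te <- startsWith(te_f1$te_id, "lte")
  prof_te <- metaprofile(track, te_feats(te_f1[!is_lnc_te, ]),
                         flank = 500, flank_bin = 50, body_bins = 50,
                         label = "TE")
  prof_lnc_te <- metaprofile(track, te_feats(te_f1[is_lnc_te, ]),
                             flank = 500, flank_bin = 50, body_bins = 50,
                             label = "lnc_TE")
  srna_body <- list(te = profile_body_mean(prof_te),
                    lnc_te = profile_body_mean(prof_lnc_te))
  meth_body <- list()
  for (ctx in METH_CONTEXTS) {
    mt <- meth_track(cx_f1, ctx, sim$chrom_lengths)
    pg <- metaprofile(mt, te_feats(te_f1[is_lnc_te &
                                           te_f1$family == "Gypsy", ]),
                      flank = 500, flank_bin = 50, body_bins = 50)
    pl <- metaprofile(mt, te_feats(te_f1[is_lnc_te &
                                           te_f1$family == "LINE", ]),
                      flank = 500, flank_bin = 50, body_bins = 50)
    meth_body[[ctx]] <- list(lnc_gypsy = profile_body_mean(pg),
                             lnc_line = profile_body_mean(pl))
  }

  report <- list(
    seed = config$seed,
    thresholds = th,
    classify = classify_tally,
    synteny = list(calls = as.list(table(calls$label)),
                   n_blocks = nrow(blocks$blocks),
                   sa_fraction = saf,
                   recall_by_label = as.list(recall_by_label)),
    expression = list(lnc = de_summary_lnc,
                      spearman = spearman),
    te = list(composition = comp, enrichment = enrich),
    methylation = list(dmr_n = nrow(dmrs),
                       dmr_composition = dmr_comp,
                       meth_expr_rho = as.list(meth_expr_rho),
                       n_rho_loci = length(subset_ids)),
    profiles = list(srna_body = srna_body,
                    srna_lnc_te_ratio = srna_body$lnc_te / srna_body$te,
                    n_te_features = attr(prof_te, "n_features"),
                    n_lnc_te_features = attr(prof_lnc_te, "n_features"),
                    meth_body = meth_body))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  structure(c(report,
              list(calls = calls, de_records = cls$records,
                   delta_meth = delta_meth, dmrs = dmrs, sim = sim)),
            class = "polylnc_report")
}

#' @export
print.polylnc_report <- function(x, ...) {
  cat("polylnc_report (seed", x$seed, ")\n")
  cat("  lncRNA kept: A", x$classify$A$n_kept, "/ D",
      x$classify$D$n_kept, "\n")
  cat("  synteny SA fraction:", round(x$synteny$sa_fraction$fraction, 3),
      "over", x$synteny$sa_fraction$n_sa + x$synteny$sa_fraction$n_st,
      "syntenic loci\n")
  cat("  lncRNA percent DE (F1 vs mid-parent):",
      round(x$expression$lnc$percent_de, 2), "%\n")
  cat("  methylation-expression rho:",
      paste(names(x$methylation$meth_expr_rho),
            vapply(x$methylation$meth_expr_rho,
                   function(v) sprintf("%.2f", v), character(1)),
            collapse = ", "), "\n")
  invisible(x)
}
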