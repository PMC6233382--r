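#' Decompose a locus into feature regions
#'
#' Splits each locus (one representative transcript per locus) into the four
#' feature regions used for TE attribution: a strand-aware upstream flank
#' (5' side, `flank` bp), exons, introns, and a downstream flank.  Flanks
#' are clipped at chromosome boundaries when `chrom_lengths` is supplied.
#'
#' @param ts a [transcript_set()], one transcript per locus (run
#'   [filter_lncrna()] or pick representatives first).
#' @param flank flank width in bp (default 2000).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   clipping the downstream ends.
#' @return data.frame `locus_id`, `region` (`upstream2k`, `exon`, `intron`,
#'   `downstream2k`), `chrom`, `start`, `end`, `strand`.
#' @export
decompose_regions <- function(ts, flank = 2000, chrom_lengths = NULL) {
  tr <- ts$transcripts
  ex <- ts$exons
  m <- match(ex$transcript_id, tr$transcript_id)
  exon_rows <- data.frame(locus_id = tr$locus_id[m], region = "exon",
                          chrom = ex$chrom, start = ex$start, end = ex$end,
                          strand = ex$strand, stringsAsFactors = FALSE)
  introns <- transcript_introns(ts)
  intron_rows <- if (nrow(introns)) {
    mi <- match(introns$transcript_id, tr$transcript_id)
    data.frame(locus_id = tr$locus_id[mi], region = "intron",
               chrom = introns$chrom, start = introns$start,
               end = introns$end, strand = introns$strand,
               stringsAsFactors = FALSE)
  } else NULL
  plus <- tr$strand == "+"
  up_start <- ifelse(plus, tr$start - flank, tr$end)
  up_end <- ifelse(plus, tr$start, tr$end + flank)
  dn_start <- ifelse(plus, tr$end, tr$start - flank)
  dn_end <- ifelse(plus, tr$end + flank, tr$start)
  clip <- function(start, end, chrom) {
    start <- pmax(start, 0L)
    if (!is.null(chrom_lengths)) {
      lim <- chrom_lengths[chrom]
      end <- pmin(end, ifelse(is.na(lim), end, lim))
    }
    list(start = as.integer(start), end = as.integer(end))
  }
  up <- clip(up_start, up_end, tr$chrom)
  dn <- clip(dn_start, dn_end, tr$chrom)
  up_rows <- data.frame(locus_id = tr$locus_id, region = "upstream2k",
                        chrom = tr$chrom, start = up$start, end = up$end,
                        strand = tr$strand, stringsAsFactors = FALSE)
  dn_rows <- data.frame(locus_id = tr$locus_id, region = "downstream2k",
                        chrom = tr$chrom, start = dn$start, end = dn$end,
                        strand = tr$strand, stringsAsFactors = FALSE)
  out <- rbind(up_rows, exon_rows, intron_rows, dn_rows)
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute one TE family per feature region (longest-TE rule)
#'
#' Among TEs overlapping a region by at least 1 bp, the TE of greatest
#' annotated feature length wins; ties are broken by leftmost start, then by
#' TE identifier.  At most one assignment per (locus, region kind).
#'
#' @param regions data.frame from [decompose_regions()].
#' @param tes TE feature table from [read_te_bed()].
#' @return data.frame `locus_id`, `region`, `family`, `te_id`, `overlap_bp`
#'   (summed over the region kind's intervals), one row per assigned
#'   (locus, region).
#' @export
assign_te <- function(regions, tes) {
  empty <- data.frame(locus_id = character(), region = character(),
                      family = character(), te_id = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0 || nrow(tes) == 0) return(empty)
  ov <- interval_overlaps(regions, tes)
  if (nrow(ov) == 0) return(empty)
  d <- data.frame(locus_id = regions$locus_id[ov$query],
                  region = regions$region[ov$query],
                  te_idx = ov$subject,
                  overlap_bp = ov$overlap_bp,
                  stringsAsFactors = FALSE)
  # total overlap of each TE with each (locus, region kind)
  key <- paste(d$locus_id, d$region, d$te_idx, sep = "\r")
  agg <- rowsum(d$overlap_bp, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  cand <- data.frame(locus_id = vapply(parts, `[`, character(1), 1),
                     region = vapply(parts, `[`, character(1), 2),
                     te_idx = as.integer(vapply(parts, `[`, character(1), 3)),
                     overlap_bp = as.integer(agg[, 1]),
                     stringsAsFactors = FALSE)
  cand$te_len <- tes$end[cand$te_idx] - tes$start[cand$te_idx]
  cand$te_start <- tes$start[cand$te_idx]
  cand$te_id <- tes$te_id[cand$te_idx]
  cand$family <- tes$family[cand$te_idx]
  ord <- order(cand$locus_id, cand$region, -cand$te_len, cand$te_start,
               cand$te_id)
  cand <- cand[ord, , drop = FALSE]
  win <- cand[!duplicated(cand[c("locus_id", "region")]), , drop = FALSE]
  out <- win[, c("locus_id", "region", "family", "te_id", "overlap_bp")]
  rownames(out) <- NULL
  out
}

#' TE family composition per feature region
#'
#' @param assignments data.frame from [assign_te()].
#' @param by column to stratify on (default `"region"`).
#' @return data.frame `region`, `family`, `n`, `proportion`; proportions sum
#'   to 1 over assigned loci within each region kind.
#' @export
te_composition <- function(assignments, by = "region") {
  if (nrow(assignments) == 0)
    return(data.frame(region = character(), family = character(),
                      n = integer(), proportion = numeric(),
                      stringsAsFactors = FALSE))
  tab <- as.data.frame(table(region = assignments[[by]],
                             family = assignments$family),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  if (by == "region") {
    missing <- setdiff(REGION_KINDS, tab$region)
    if (length(missing))
      message("no TE assignments in region kind(s): ",
              paste(missing, collapse = ", "))
  }
  tot <- tapply(tab$n, tab$region, sum)
  tab$proportion <- tab$n / as.numeric(tot[tab$region])
  rownames(tab) <- NULL
  tab[order(tab$region, -tab$n), , drop = FALSE]
}

#' TE family enrichment between ST and SA lncRNAs
#'
#' For each family, a 2x2 table (locus has/lacks the family, ST vs SA) is
#' tested with the two-sided Fisher exact test, and the effect reported as
#' `log2((p_ST + eps_ST) / (p_SA + eps_SA))`, where `p_g` is the within-group
#' proportion of loci carrying the family and `eps_g = 0.5 / n_g` is a
#' half-count pseudo-proportion guard against empty cells.
#' Benjamini-Hochberg q-values accompany the raw p-values.
#'
#' @param st_ids,sa_ids disjoint sets of lncRNA locus IDs.
#' @param assignments data.frame from [assign_te()]; a locus "has" a family
#'   when any of its regions (or the regions in `region`) carries it.
#' @param region optional region kinds to restrict the attribution to.
#' @return data.frame per family: counts, `log2_ratio`, `fisher_p`, `q`.
#'   Families absent from both groups are skipped.
#' @export
family_enrichment <- function(st_ids, sa_ids, assignments, region = NULL) {
  if (length(intersect(st_ids, sa_ids)))
    stop("ST and SA locus sets must be disjoint")
  if (!is.null(region))
    assignments <- assignments[assignments$region %in% region, , drop = FALSE]
  fams <- intersect(TE_FAMILIES, unique(assignments$family))
  n_st <- length(st_ids)
  n_sa <- length(sa_ids)
  rows <- lapply(fams, function(fam) {
    with_fam <- unique(assignments$locus_id[assignments$family == fam])
    a <- sum(st_ids %in% with_fam)
    b <- sum(sa_ids %in% with_fam)
    if (a + b == 0) return(NULL)
    tab <- matrix(c(a, n_st - a, b, n_sa - b), 2, 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    lr <- log2((a / n_st + 0.5 / n_st) / (b / n_sa + 0.5 / n_sa))
    data.frame(family = fam, n_ST_with = a, n_ST_without = n_st - a,
               n_SA_with = b, n_SA_without = n_sa - b,
               log2_ratio = lr, fisher_p = p, stringsAsFactors = FALSE)
  })
  skipped <- fams[vapply(rows, is.null, logical(1))]
  if (length(skipped))
    message("families absent from both groups skipped: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(family = character(), n_ST_with = integer(),
                      n_ST_without = integer(), n_SA_with = integer(),
                      n_SA_without = integer(), log2_ratio = numeric(),
                      fisher_p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  out$q <- stats::p.adjust(out$fisher_p, method = "BH")
  rownames(out) <- NULL
  out
}
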