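#' Weighted methylation level over intervals
#'
#' For each interval, `sum(n_meth) / sum(n_total)` over the covered
#' cytosines of the requested context inside it — the coverage-weighted
#' estimator, not a mean of per-cytosine ratios.  Intervals with no covered
#' cytosine are masked (`NA`).
#'
#' @param cx cytosine records from [read_cx_report()].
#' @param intervals data.frame of intervals (`chrom`, `start`, `end`).
#' @param context one of `CG`, `CHG`, `CHH`.
#' @return numeric vector of levels in `[0, 1]`, one per interval row.
#' @export
weighted_methylation <- function(cx, intervals, context) {
  stopifnot(context %in% METH_CONTEXTS)
  cx <- cx[cx$context == context & cx$n_total > 0, , drop = FALSE]
  out <- rep(NA_real_, nrow(intervals))
  if (nrow(cx) == 0 || nrow(intervals) == 0) return(out)
  cxi <- data.frame(chrom = cx$chrom, start = cx$pos, end = cx$pos + 1L,
                    strand = ".", stringsAsFactors = FALSE)
  ov <- interval_overlaps(intervals, cxi)
  if (nrow(ov) == 0) return(out)
  num <- rowsum(cx$n_meth[ov$subject], ov$query)
  den <- rowsum(cx$n_total[ov$subject], ov$query)
  out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  out
}

#' Call differentially methylated regions between two samples
#'
#' A documented stand-in caller for workflows that do not import an external
#' DMR set (see [read_dmrs()] for the import path).  Per context, sliding
#' windows (`window` bp, `step` bp) with at least `min_cyt` covered
#' cytosines in both samples are tested with the Fisher exact test on the
#' pooled (methylated, unmethylated) counts; windows with `p < alpha` and
#' `|delta| >= min_delta` are merged when they overlap and share direction.
#' `delta` is the level in sample B minus sample A; direction `hyper` means
#' B gained methylation.
#'
#' @param cx_a,cx_b cytosine records for samples A and B.
#' @param window,step window and step size in bp.
#' @param min_cyt minimum covered cytosines per window, each sample.
#' @param alpha p-value threshold.
#' @param min_delta minimum absolute level difference.
#' @param chrom_lengths optional named vector of chromosome lengths (else
#'   inferred from the data).
#' @return data.frame `chrom`, `start`, `end`, `context`, `direction`,
#'   `delta`, `p` (minimum window p inside each merged region; delta
#'   recomputed over the merged region).
#' @export
call_dmrs <- function(cx_a, cx_b, window = 100, step = 50, min_cyt = 4,
                      alpha = 0.01, min_delta = 0.1, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chroms <- union(unique(cx_a$chrom), unique(cx_b$chrom))
    chrom_lengths <- vapply(chroms, function(ch)
      max(cx_a$pos[cx_a$chrom == ch], cx_b$pos[cx_b$chrom == ch], 0) + 1,
      numeric(1))
  }
  res <- list()
  for (ctx in METH_CONTEXTS) {
    a <- cx_a[cx_a$context == ctx & cx_a$n_total > 0, , drop = FALSE]
    b <- cx_b[cx_b$context == ctx & cx_b$n_total > 0, , drop = FALSE]
    for (ch in names(chrom_lengths)) {
      ach <- a[a$chrom == ch, , drop = FALSE]
      bch <- b[b$chrom == ch, , drop = FALSE]
      if (nrow(ach) < min_cyt || nrow(bch) < min_cyt) next
      hits <- dmr_windows(ach, bch, chrom_lengths[[ch]], window, step,
                          min_cyt, alpha, min_delta)
      if (is.null(hits) || nrow(hits) == 0) next
      merged <- merge_dmr_windows(hits)
      merged$chrom <- ch
      merged$context <- ctx
      # recompute delta over the merged span
      for (r in seq_len(nrow(merged))) {
        ia <- ach$pos >= merged$start[r] & ach$pos < merged$end[r]
        ib <- bch$pos >= merged$start[r] & bch$pos < merged$end[r]
        merged$delta[r] <- sum(bch$n_meth[ib]) / sum(bch$n_total[ib]) -
          sum(ach$n_meth[ia]) / sum(ach$n_total[ia])
      }
      merged$direction <- ifelse(merged$delta >= 0, "hyper", "hypo")
      res[[length(res) + 1]] <- merged
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      direction = character(), delta = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[, c("chrom", "start", "end", "context", "direction", "delta",
                 "p")]
  out <- out[order(out$chrom, out$start, out$context), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Significant sliding windows on one chromosome/context.
dmr_windows <- function(a, b, L, window, step, min_cyt, alpha, min_delta) {
  starts <- seq(0, max(0, L - 1), by = step)
  ends <- pmin(starts + window, L)
  # windowed sums via cumulative sums over sorted positions
  a <- a[order(a$pos), , drop = FALSE]
  b <- b[order(b$pos), , drop = FALSE]
  cum <- function(d) list(pos = d$pos, m = cumsum(d$n_meth),
                          t = cumsum(d$n_total))
  ca <- cum(a)
  cb <- cum(b)
  wsum <- function(cc, s, e) {
    i0 <- findInterval(s - 0.5, cc$pos) + 1L
    i1 <- findInterval(e - 0.5, cc$pos)
    n <- i1 - i0 + 1L
    if (n <= 0) return(c(0, 0, 0))
    c(n,
      cc$m[i1] - if (i0 > 1) cc$m[i0 - 1] else 0,
      cc$t[i1] - if (i0 > 1) cc$t[i0 - 1] else 0)
  }
  rows <- lapply(seq_along(starts), function(k) {
    sa <- wsum(ca, starts[k], ends[k])
    sb <- wsum(cb, starts[k], ends[k])
    if (sa[1] < min_cyt || sb[1] < min_cyt) return(NULL)
    if (sa[3] == 0 || sb[3] == 0) return(NULL)
    delta <- sb[2] / sb[3] - sa[2] / sa[3]
    if (abs(delta) < min_delta) return(NULL)
    p <- stats::fisher.test(matrix(c(sa[2], sa[3] - sa[2],
                                     sb[2], sb[3] - sb[2]), 2, 2))$p.value
    if (p >= alpha) return(NULL)
    data.frame(start = starts[k], end = ends[k], delta = delta, p = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

merge_dmr_windows <- function(w) {
  w <- w[order(w$start), , drop = FALSE]
  n <- nrow(w)
  grp <- integer(n)
  g <- 1L
  grp[1] <- 1L
  cur_end <- w$end[1]
  cur_dir <- sign(w$delta[1])
  if (n > 1) for (i in 2:n) {
    if (w$start[i] < cur_end && sign(w$delta[i]) == cur_dir) {
      cur_end <- max(cur_end, w$end[i])
    } else {
      g <- g + 1L
      cur_end <- w$end[i]
      cur_dir <- sign(w$delta[i])
    }
    grp[i] <- g
  }
  do.call(rbind, lapply(split(w, grp), function(d)
    data.frame(start = min(d$start), end = max(d$end),
               delta = NA_real_, p = min(d$p))))
}

#' Context composition of a DMR set
#'
#' @param dmrs data.frame with a `context` column ([call_dmrs()] or
#'   [read_dmrs()]).
#' @return data.frame `context`, `n`, `proportion` over CG/CHG/CHH;
#'   proportions sum to 1.
#' @export
dmr_context_composition <- function(dmrs) {
  n <- vapply(METH_CONTEXTS, function(cx) sum(dmrs$context == cx),
              numeric(1))
  data.frame(context = METH_CONTEXTS, n = as.integer(n),
             proportion = if (sum(n) > 0) n / sum(n) else rep(NA_real_, 3),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Associate DMRs with lncRNA loci and expression classes
#'
#' A DMR is assigned to a lncRNA locus when it overlaps the locus span
#' extended by `flank` bp on both sides; a DMR overlapping several loci goes
#' to the locus with the greatest overlap (exact ties go to all tied loci
#' and are flagged).  Per expression class (`Up`/`Down`/`Equal`), the
#' context composition and the hyper/hypo split of the assigned DMRs are
#' reported.
#'
#' @param dmrs DMR table ([call_dmrs()] or [read_dmrs()]).
#' @param lnc_loci locus table (`locus_id`, `chrom`, `start`, `end`).
#' @param de_records per-locus records from [classify_de()].
#' @param flank assignment flank in bp (default 2000).
#' @return list with `assignments` (DMR-locus pairs with class) and
#'   `by_class` (per class and context: counts and hyper/hypo proportions).
#' @export
dmr_expression_association <- function(dmrs, lnc_loci, de_records,
                                       flank = 2000) {
  empty <- list(assignments = data.frame(), by_class = data.frame())
  if (nrow(dmrs) == 0 || nrow(lnc_loci) == 0) return(empty)
  ext <- lnc_loci
  ext$start <- pmax(0L, ext$start - as.integer(flank))
  ext$end <- ext$end + as.integer(flank)
  ext$strand <- "."
  div <- dmrs
  div$strand <- "."
  ov <- interval_overlaps(div, ext)
  if (nrow(ov) == 0) return(empty)
  best <- tapply(ov$overlap_bp, ov$query, max)
  keep <- ov$overlap_bp == best[as.character(ov$query)]
  asg <- data.frame(dmr_idx = ov$query[keep],
                    locus_id = ext$locus_id[ov$subject[keep]],
                    overlap_bp = ov$overlap_bp[keep],
                    stringsAsFactors = FALSE)
  asg$tied <- asg$dmr_idx %in% asg$dmr_idx[duplicated(asg$dmr_idx)]
  asg <- cbind(dmrs[asg$dmr_idx, c("chrom", "start", "end", "context",
                                   "direction", "delta", "p")], asg)
  cls <- de_records$de_class[match(asg$locus_id, de_records$locus_id)]
  asg$de_class <- ifelse(is.na(cls), "Unclassified", cls)
  by_class <- do.call(rbind, lapply(split(asg, asg$de_class), function(d) {
    comp <- dmr_context_composition(d)
    data.frame(de_class = d$de_class[1], context = comp$context,
               n = comp$n, proportion = comp$proportion,
               hypo_proportion = vapply(comp$context, function(cx) {
                 dd <- d[d$context == cx, ]
                 if (nrow(dd) == 0) NA_real_ else
                   mean(dd$direction == "hypo")
               }, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(by_class) <- NULL
  list(assignments = asg, by_class = by_class)
}

#' Correlate methylation change with expression change
#'
#' Per context, the correlation between per-locus methylation-level change
#' and expression log2 fold change, over a caller-supplied subset
#' (conventionally the differentially expressed loci whose methylation
#' changed significantly).
#'
#' @param delta_meth data.frame with `locus_id` and one column per context
#'   (`CG`, `CHG`, `CHH`) of methylation-level differences.
#' @param log2fc named vector of log2 fold changes per locus.
#' @param subset locus IDs to restrict to (default: all in `delta_meth`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return named numeric vector of correlations per context; contexts with
#'   fewer than 3 usable loci are `NA`-flagged with a warning.
#' @export
methylation_expression_correlation <- function(delta_meth, log2fc,
                                               subset = NULL,
                                               method = c("spearman",
                                                          "pearson")) {
  method <- match.arg(method)
  if (!is.null(subset))
    delta_meth <- delta_meth[delta_meth$locus_id %in% subset, , drop = FALSE]
  fc <- log2fc[delta_meth$locus_id]
  out <- stats::setNames(rep(NA_real_, length(METH_CONTEXTS)),
                         METH_CONTEXTS)
  for (cx in METH_CONTEXTS) {
    if (!cx %in% names(delta_meth)) next
    dm <- delta_meth[[cx]]
    ok <- is.finite(dm) & is.finite(fc)
    if (sum(ok) < 3) {
      warning("fewer than 3 loci for context ", cx,
              "; correlation undefined")
      next
    }
    out[cx] <- stats::cor(dm[ok], fc[ok], method = method)
  }
  out
}
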