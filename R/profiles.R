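#' Filter small-RNA reads to the siRNA set
#'
#' Keeps reads whose length lies in `[min_len, max_len]` nt and that map to
#' at most `max_loci` loci.  An optional blacklist of read IDs (e.g. reads
#' annotated as miRNA/tRNA/rRNA/snoRNA) is removed first.
#'
#' @param reads data.frame from [read_srna_bed()] (needs `length` and
#'   `n_mapped_loci`).
#' @param min_len,max_len length bounds in nt (defaults 20 and 25).
#' @param max_loci multi-mapping cutoff (default 50; reads mapping to more
#'   loci are removed).
#' @param blacklist optional read IDs to drop regardless of length.
#' @return the filtered read table.
#' @export
filter_srna <- function(reads, min_len = 20, max_len = 25, max_loci = 50,
                        blacklist = NULL) {
  if (!is.null(blacklist))
    reads <- reads[!reads$read_id %in% blacklist, , drop = FALSE]
  keep <- reads$length >= min_len & reads$length <= max_len &
    reads$n_mapped_loci <= max_loci
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base coverage track from read intervals
#'
#' Multi-mapped reads are down-weighted by `1 / n_mapped_loci` so each read
#' contributes one unit of signal genome-wide.
#'
#' @param reads data.frame of read intervals (`chrom`, `start`, `end`,
#'   optionally `n_mapped_loci`).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param weight_multimapped down-weight multi-mapped reads (default TRUE).
#' @return object of class `coverage_track`: per-chromosome numeric vectors
#'   of per-bp depth.
#' @export
coverage_track <- function(reads, chrom_lengths, weight_multimapped = TRUE) {
  w <- if (weight_multimapped && !is.null(reads$n_mapped_loci))
    1 / pmax(reads$n_mapped_loci, 1) else rep(1, nrow(reads))
  vals <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    sel <- which(reads$chrom == ch)
    for (k in sel) {
      i0 <- max(reads$start[k], 0L) + 1L
      i1 <- min(reads$end[k], chrom_lengths[[ch]])
      if (i1 >= i0) v[i0:i1] <- v[i0:i1] + w[k]
    }
    v
  })
  names(vals) <- names(chrom_lengths)
  structure(list(values = vals), class = "coverage_track")
}

#' Per-base methylation track for one context
#'
#' Holds per-bp methylated and total call counts; any window's value is the
#' weighted methylation level `sum(n_meth) / sum(n_total)` over the window.
#'
#' @param cx cytosine records from [read_cx_report()].
#' @param context one of `CG`, `CHG`, `CHH`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return object of class `meth_track`.
#' @export
meth_track <- function(cx, context, chrom_lengths) {
  cx <- cx[cx$context == context, , drop = FALSE]
  num <- den <- lapply(chrom_lengths, function(L) numeric(L))
  for (ch in names(chrom_lengths)) {
    sel <- which(cx$chrom == ch & cx$pos < chrom_lengths[[ch]])
    if (!length(sel)) next
    num[[ch]] <- as.numeric(unname(
      rowsum_vector(cx$pos[sel] + 1L, cx$n_meth[sel], chrom_lengths[[ch]])))
    den[[ch]] <- as.numeric(unname(
      rowsum_vector(cx$pos[sel] + 1L, cx$n_total[sel], chrom_lengths[[ch]])))
  }
  structure(list(num = num, den = den), class = "meth_track")
}

rowsum_vector <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Value of a track over a (possibly fractional) window [x0, x1) on `chrom`.
# Fractional base-pair ends are weighted by their covered fraction.
track_window_value <- function(track, chrom, x0, x1) {
  UseMethod("track_window_value")
}

window_weights <- function(x0, x1, L) {
  if (x1 <= 0 || x0 >= L || x1 <= x0) return(NULL)
  x0 <- max(x0, 0); x1 <- min(x1, L)
  i0 <- floor(x0) + 1L
  i1 <- ceiling(x1)
  idx <- i0:i1
  w <- pmin(idx, x1) - pmax(idx - 1, x0)
  list(idx = idx[w > 0], w = w[w > 0])
}

#' @export
track_window_value.coverage_track <- function(track, chrom, x0, x1) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(NA_real_)
  ww <- window_weights(x0, x1, length(v))
  if (is.null(ww)) return(NA_real_)
  sum(v[ww$idx] * ww$w) / sum(ww$w)
}

#' @export
track_window_value.meth_track <- function(track, chrom, x0, x1) {
  num <- track$num[[chrom]]
  if (is.null(num)) return(NA_real_)
  ww <- window_weights(x0, x1, length(num))
  if (is.null(ww)) return(NA_real_)
  den <- sum(track$den[[chrom]][ww$idx] * ww$w)
  if (den == 0) return(NA_real_)
  sum(num[ww$idx] * ww$w) / den
}

#' Metaprofile of a signal track over scaled feature bodies with flanks
#'
#' Feature bodies are scaled to `body_bins` equal fractions; flanks are cut
#' into fixed `flank_bin`-bp bins.  Each feature contributes its per-bin
#' track value oriented 5' to 3' (minus-strand features are reversed), and
#' the profile is the across-feature mean per bin (missing data masked).
#' Features shorter than `body_bins` bp are binned with a repetition-free
#' fractional scheme: each body bin covers `length / body_bins` bp, possibly
#' less than one, with fractional base pairs weighted by coverage.
#'
#' @param track a [coverage_track()] or [meth_track()].
#' @param features data.frame of feature intervals (`chrom`, `start`, `end`,
#'   `strand`).
#' @param body_bins number of body bins (default 100).
#' @param flank flank width in bp (default 2000).
#' @param flank_bin flank bin width in bp (default 50).
#' @param label optional label stored on the result.
#' @return object of class `metaprofile`: data.frame `bin`, `segment`
#'   (`upstream`/`body`/`downstream`), `position`, `value`, `n`, plus
#'   attributes `n_features` and `label`.
#' @export
metaprofile <- function(track, features, body_bins = 100, flank = 2000,
                        flank_bin = 50, label = NULL) {
  if (nrow(features) == 0) stop("no features to profile")
  n_flank <- flank %/% flank_bin
  total <- 2L * n_flank + body_bins
  acc <- matrix(NA_real_, nrow(features), total)
  for (f in seq_len(nrow(features))) {
    ch <- features$chrom[f]
    s <- features$start[f]
    e <- features$end[f]
    minus <- identical(features$strand[f], "-")
    len <- e - s
    up <- vapply(seq_len(n_flank), function(k) {
      x0 <- s - flank + (k - 1) * flank_bin
      track_window_value(track, ch, x0, x0 + flank_bin)
    }, numeric(1))
    body <- vapply(seq_len(body_bins), function(k) {
      track_window_value(track, ch, s + len * (k - 1) / body_bins,
                         s + len * k / body_bins)
    }, numeric(1))
    dn <- vapply(seq_len(n_flank), function(k) {
      x0 <- e + (k - 1) * flank_bin
      track_window_value(track, ch, x0, x0 + flank_bin)
    }, numeric(1))
    row <- c(up, body, dn)
    if (minus) row <- rev(row)
    acc[f, ] <- row
  }
  value <- colMeans(acc, na.rm = TRUE)
  value[is.nan(value)] <- NA_real_
  n_obs <- colSums(!is.na(acc))
  out <- data.frame(
    bin = seq_len(total),
    segment = rep(c("upstream", "body", "downstream"),
                  c(n_flank, body_bins, n_flank)),
    position = c(seq(-flank + flank_bin / 2, -flank_bin / 2,
                     by = flank_bin),
                 (seq_len(body_bins) - 0.5) / body_bins,
                 seq(flank_bin / 2, flank - flank_bin / 2, by = flank_bin)),
    value = value, n = n_obs, stringsAsFactors = FALSE)
  structure(out, class = c("metaprofile", "data.frame"),
            n_features = nrow(features), label = label)
}

#' Mean body signal of a metaprofile
#'
#' @param profile a [metaprofile()].
#' @return mean of the body-segment bin values (missing bins ignored).
#' @export
profile_body_mean <- function(profile) {
  mean(profile$value[profile$segment == "body"], na.rm = TRUE)
}
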