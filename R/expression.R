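#' RPKM normalisation
#'
#' `rpkm = count * 1e9 / (length_bp * library_size)` — reads per kilobase of
#' transcript per million mapped reads.
#'
#' @param cm a [count_matrix()].
#' @param lengths named vector of spliced locus lengths in bp.
#' @return numeric matrix of RPKM values, same shape as the counts.
#' @export
rpkm <- function(cm, lengths) {
  len <- lengths[rownames(cm$counts)]
  if (anyNA(len)) stop("missing length for locus ",
                       rownames(cm$counts)[which(is.na(len))[1]])
  if (any(len <= 0)) stop("locus lengths must be positive")
  sweep(cm$counts * 1e9 / as.numeric(len), 2, cm$library_sizes, "/")
}

#' In silico mid-parent expression mix
#'
#' Emulates mixing parental sequencing reads at a 1:1 ratio, at the count
#' level: replicates are paired (by sorted sample order; a warning is issued
#' when replicate counts differ and the excess is dropped), each parent's
#' counts are depth-normalised to the mean parental library size, and the
#' mid-parent count is `round(0.5 * a + 0.5 * b)` of the rescaled counts.
#' Loci absent from one parent count as zero there.
#'
#' @param cm_a,cm_b parental [count_matrix()] objects.
#' @return a [count_matrix()] of virtual mid-parent samples (`mix_1`, ...),
#'   each with the mean parental library size.
#' @export
in_silico_mix <- function(cm_a, cm_b) {
  loci <- sort(union(rownames(cm_a$counts), rownames(cm_b$counts)))
  expand <- function(cm) {
    m <- matrix(0, length(loci), ncol(cm$counts),
                dimnames = list(loci, colnames(cm$counts)))
    m[rownames(cm$counts), ] <- cm$counts
    m
  }
  a <- expand(cm_a)
  b <- expand(cm_b)
  na <- ncol(a); nb <- ncol(b)
  if (na != nb) {
    warning("replicate counts differ (", na, " vs ", nb,
            "); pairing by sorted order and dropping the excess")
  }
  n <- min(na, nb)
  ord_a <- order(colnames(a))[seq_len(n)]
  ord_b <- order(colnames(b))[seq_len(n)]
  la <- cm_a$library_sizes[ord_a]
  lb <- cm_b$library_sizes[ord_b]
  lmix <- (la + lb) / 2
  mix <- sapply(seq_len(n), function(k)
    round(0.5 * a[, ord_a[k]] * lmix[k] / la[k] +
            0.5 * b[, ord_b[k]] * lmix[k] / lb[k]))
  dimnames(mix) <- list(loci, sprintf("mix_%d", seq_len(n)))
  count_matrix(mix, stats::setNames(lmix, colnames(mix)))
}

# Median-of-ratios size factors (relative sequencing depth per sample).
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- rowMeans(lg)
  use <- is.finite(geo)
  if (!any(use)) return(stats::setNames(rep(1, ncol(counts)),
                                        colnames(counts)))
  sf <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - geo[use], na.rm = TRUE)))
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' Differential-expression test between two replicate groups
#'
#' A fully specified stand-in for negative-binomial DE frameworks:
#' replicates are pooled after median-of-ratios library normalisation, the
#' p-value per locus comes from the exact two-sided binomial test of the
#' pooled focal count against the pooled total, with success probability
#' equal to the focal group's normalised depth share, and the fold change is
#' computed from normalised group means with a 0.5 pseudo-count.  The test
#' ignores biological dispersion by design (see the methods vignette for its
#' calibration on null simulations).
#'
#' @param counts_focal,counts_ref count matrices (loci x replicates) for the
#'   focal and reference groups, same loci in the same order.
#' @return data.frame `locus_id`, `p_value`, `log2fc` (focal over
#'   reference); all-zero loci get `p = 1`, `log2fc = 0`.
#' @export
de_test <- function(counts_focal, counts_ref) {
  counts_focal <- as.matrix(counts_focal)
  counts_ref <- as.matrix(counts_ref)
  if (nrow(counts_focal) != nrow(counts_ref))
    stop("groups must share the locus universe")
  if (!is.null(rownames(counts_focal)) && !is.null(rownames(counts_ref))) {
    if (!setequal(rownames(counts_focal), rownames(counts_ref)))
      stop("groups must share the locus universe")
    counts_ref <- counts_ref[rownames(counts_focal), , drop = FALSE]
  }
  all_counts <- cbind(counts_focal, counts_ref)
  sf <- size_factors(all_counts)
  sf_f <- sf[seq_len(ncol(counts_focal))]
  sf_r <- sf[-seq_len(ncol(counts_focal))]
  p0 <- sum(sf_f) / sum(sf)
  pooled_f <- rowSums(counts_focal)
  pooled_r <- rowSums(counts_ref)
  tot <- pooled_f + pooled_r
  p <- vapply(seq_along(tot), function(i) {
    if (tot[i] == 0) return(1)
    stats::binom.test(pooled_f[i], tot[i], p = p0)$p.value
  }, numeric(1))
  mean_f <- rowMeans(sweep(counts_focal, 2, sf_f, "/"))
  mean_r <- rowMeans(sweep(counts_ref, 2, sf_r, "/"))
  lfc <- ifelse(tot == 0, 0, log2((mean_f + 0.5) / (mean_r + 0.5)))
  data.frame(locus_id = rownames(counts_focal), p_value = p, log2fc = lfc,
             stringsAsFactors = FALSE)
}

#' Classify loci into Up / Down / Equal / NotExpressed
#'
#' `Up` iff `p < alpha` and fold change `> fc`; `Down` iff `p < alpha` and
#' fold change `< 1/fc`; `Equal` when expressed but neither; `NotExpressed`
#' otherwise.  A locus is expressed when its RPKM exceeds
#' `expressed_rpkm` in at least one member sample of the contrast.
#'
#' @param de data.frame from [de_test()].
#' @param rpkm_focal,rpkm_ref RPKM matrices (or vectors) for the two groups.
#' @param alpha p-value threshold (default 0.01).
#' @param fc fold-change threshold (default 2).
#' @param expressed_rpkm expression threshold (default 0.5).
#' @return list with `records` (per-locus classes plus the inputs) and
#'   `summary` (`n_up`, `n_down`, `n_de`, `n_expressed`, `percent_de` =
#'   `100 * n_de / n_expressed`, `NA`-flagged when nothing is expressed).
#' @export
classify_de <- function(de, rpkm_focal, rpkm_ref, alpha = 0.01, fc = 2,
                        expressed_rpkm = 0.5) {
  max_f <- if (is.matrix(rpkm_focal)) apply(rpkm_focal, 1, max) else
    rpkm_focal
  max_r <- if (is.matrix(rpkm_ref)) apply(rpkm_ref, 1, max) else rpkm_ref
  expressed <- pmax(max_f[de$locus_id], max_r[de$locus_id]) > expressed_rpkm
  up <- de$p_value < alpha & de$log2fc > log2(fc)
  down <- de$p_value < alpha & de$log2fc < -log2(fc)
  cls <- ifelse(up, "Up", ifelse(down, "Down",
                                 ifelse(expressed, "Equal", "NotExpressed")))
  rec <- cbind(de, data.frame(rpkm_focal = unname(max_f[de$locus_id]),
                              rpkm_ref = unname(max_r[de$locus_id]),
                              expressed = expressed, de_class = cls,
                              stringsAsFactors = FALSE))
  n_expr <- sum(expressed)
  n_de <- sum(up | down)
  pct <- if (n_expr == 0) NA_real_ else 100 * n_de / n_expr
  if (n_expr == 0) warning("no expressed loci; percent DE undefined")
  list(records = rec,
       summary = list(n_up = sum(up), n_down = sum(down), n_de = n_de,
                      n_expressed = n_expr, percent_de = pct))
}

#' Proportion of differentially expressed loci
#'
#' The headline summary statistic `100 * n_de / n_expressed`, as a helper
#' for worked examples on printed count pairs.
#'
#' @param n_de number of differentially expressed loci.
#' @param n_expressed number of expressed loci.
#' @return percentage (0-100); `NA` with a warning when the denominator is 0.
#' @export
percent_de <- function(n_de, n_expressed) {
  if (n_expressed == 0) {
    warning("no expressed loci; percent DE undefined")
    return(NA_real_)
  }
  100 * n_de / n_expressed
}

#' Expression correlation between two samples
#'
#' @param x,y numeric vectors of equal length (>= 3), e.g. RPKM values.
#' @param method `"spearman"` (average ranks for ties) or `"pearson"`.
#' @return correlation coefficient; `NA` with a warning for constant input.
#' @export
expression_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined (constant or insufficient input)")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}
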