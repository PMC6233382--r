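test_that("siRNA filtering applies length and multi-mapping bounds", {
  reads <- data.frame(chrom = "c1", start = 0L, end = 0L, strand = "+",
                      read_id = sprintf("r%03d", 1:100),
                      length = rep(c(19L, 20L, 24L, 25L, 26L), 20),
                      n_mapped_loci = rep(c(1L, 50L, 51L, 2L, 1L), 20),
                      stringsAsFactors = FALSE)
  reads$end <- reads$start + reads$length
  kept <- filter_srna(reads)
  manual <- reads$read_id[reads$length >= 20 & reads$length <= 25 &
                            reads$n_mapped_loci <= 50]
  expect_setequal(kept$read_id, manual)
  expect_false(any(kept$length == 19))            # 19 nt removed
  expect_false(any(kept$n_mapped_loci == 51))     # > 50 loci removed
  expect_true(any(kept$n_mapped_loci == 50))      # boundary kept
  black <- filter_srna(reads, blacklist = manual[1:3])
  expect_false(any(manual[1:3] %in% black$read_id))
})

test_that("weighted methylation is the coverage-weighted estimator", {
  cx <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L), strand = "+",
                   context = "CG", n_meth = c(3L, 0L, 9L),
                   n_total = c(4L, 6L, 10L), stringsAsFactors = FALSE)
  iv <- data.frame(chrom = "c1", start = c(0L, 15L, 500L),
                   end = c(15L, 40L, 600L), strand = ".")
  lv <- weighted_methylation(cx, iv, "CG")
  expect_equal(lv[1], 0.75)
  expect_equal(lv[2], 9 / 16)        # weighted, not mean of ratios
  expect_true(is.na(lv[3]))          # no coverage -> masked
  expect_false(isTRUE(all.equal(lv[2], mean(c(0, 0.9)))))
  zero <- cx
  zero$n_meth <- 0L
  expect_equal(weighted_methylation(zero, iv[1:2, ], "CG"), c(0, 0))

  # 30-cytosine fixture equals the hand sum
  set.seed(19)
  cx2 <- data.frame(chrom = "c1", pos = sort(sample.int(300, 30)) - 1L,
                    strand = "+", context = "CHH",
                    n_meth = rbinom(30, 12, 0.3),
                    n_total = 12L + rpois(30, 3), stringsAsFactors = FALSE)
  iv2 <- data.frame(chrom = "c1", start = 50L, end = 250L, strand = ".")
  inside <- cx2$pos >= 50 & cx2$pos < 250
  expect_equal(weighted_methylation(cx2, iv2, "CHH"),
               sum(cx2$n_meth[inside]) / sum(cx2$n_total[inside]))
  # union of disjoint parts equals count-weighted combination
  iv_parts <- data.frame(chrom = "c1", start = c(50L, 150L),
                         end = c(150L, 250L), strand = ".")
  parts <- weighted_methylation(cx2, iv_parts, "CHH")
  w <- vapply(1:2, function(k) sum(cx2$n_total[cx2$pos >= iv_parts$start[k] &
                                                 cx2$pos < iv_parts$end[k]]),
              numeric(1))
  expect_equal(weighted_methylation(cx2, iv2, "CHH"),
               sum(parts * w) / sum(w))
})

test_that("metaprofiles reproduce geometry on analytic tracks", {
  vals <- rep(1, 1000)
  track <- structure(list(values = list(c1 = vals)),
                     class = "coverage_track")
  feats <- data.frame(chrom = "c1", start = 300L, end = 500L, strand = "+")
  pr <- metaprofile(track, feats, body_bins = 100, flank = 100,
                    flank_bin = 50)
  expect_true(all(abs(pr$value - 1) < 1e-12))     # uniform track -> flat
  # step track 0 | 1 at the body midpoint lands at bin 50 of 100
  step <- c(rep(0, 400), rep(1, 600))
  track2 <- structure(list(values = list(c1 = step)),
                      class = "coverage_track")
  pr2 <- metaprofile(track2, feats, body_bins = 100, flank = 100,
                     flank_bin = 50)
  body <- pr2$value[pr2$segment == "body"]
  expect_true(all(body[1:50] == 0))
  expect_true(all(body[51:100] == 1))
  # minus-strand orientation flips the profile
  featsm <- transform(feats, strand = "-")
  pr3 <- metaprofile(track2, featsm, body_bins = 100, flank = 100,
                     flank_bin = 50)
  expect_equal(pr3$value, rev(pr2$value))
  # flank beyond the chromosome start is masked
  near0 <- data.frame(chrom = "c1", start = 20L, end = 120L, strand = "+")
  pr4 <- metaprofile(track, near0, body_bins = 10, flank = 100,
                     flank_bin = 50)
  expect_true(is.na(pr4$value[1]))
})

test_that("metaprofile binning equals the per-bp averaging oracle", {
  set.seed(37)
  for (rep in 1:10) {
    vals <- runif(600)
    track <- structure(list(values = list(c1 = vals)),
                       class = "coverage_track")
    n <- 10
    start <- sample.int(400, n)
    len <- sample(c(3, 7, 20, 55), n, replace = TRUE)  # incl. < body_bins
    feats <- data.frame(chrom = "c1", start = start, end = start + len,
                        strand = sample(c("+", "-"), n, TRUE))
    pr <- metaprofile(track, feats, body_bins = 10, flank = 100,
                      flank_bin = 20)
    rows <- t(sapply(seq_len(n), function(i)
      bf_metaprofile_row(vals, feats$start[i], feats$end[i],
                         feats$strand[i], 10, 100, 20)))
    want <- colMeans(rows, na.rm = TRUE)
    want[is.nan(want)] <- NA_real_
    expect_equal(pr$value, want, tolerance = 1e-9)
  }
})

test_that("methylation tracks feed metaprofiles with weighted levels", {
  cx <- data.frame(chrom = "c1", pos = c(9L, 19L), strand = "+",
                   context = "CG", n_meth = c(8L, 1L),
                   n_total = c(10L, 10L), stringsAsFactors = FALSE)
  mt <- meth_track(cx, "CG", c(c1 = 100))
  expect_equal(polylnc:::track_window_value(mt, "c1", 0, 100), 9 / 20)
  expect_equal(polylnc:::track_window_value(mt, "c1", 0, 15), 0.8)
  expect_true(is.na(polylnc:::track_window_value(mt, "c1", 30, 60)))
})

test_that("the DMR caller is silent on identical samples and finds plants", {
  set.seed(53)
  pos <- sort(sample.int(4000, 600)) - 1L
  mk <- function(p_vec) data.frame(
    chrom = "c1", pos = pos, strand = "+",
    context = sample(c("CG", "CHG", "CHH"), 600, TRUE),
    n_meth = rbinom(600, 20, p_vec), n_total = 20L,
    stringsAsFactors = FALSE)
  a <- mk(0.5)
  expect_equal(nrow(call_dmrs(a, a)), 0)
  # planted 0.8 -> 0.2 CG drop over [1500, 2000)
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    pa <- mk(0.8)
    pb <- mk(ifelse(pos >= 1500 & pos < 2000, 0.2, 0.8))
    d <- call_dmrs(pa, pb)
    hypo <- d[d$direction == "hypo" & d$start < 2000 & d$end > 1500, ]
    hits <- hits + (nrow(hypo) >= 1)
  }
  expect_gte(hits, 9.5)  # >= 95% of seeds
})

test_that("windows with too few covered cytosines are skipped", {
  cx <- data.frame(chrom = "c1", pos = c(10L, 30L, 50L), strand = "+",
                   context = "CG", n_meth = c(10L, 10L, 10L),
                   n_total = 10L, stringsAsFactors = FALSE)
  cx2 <- cx
  cx2$n_meth <- 0L
  # only 3 covered cytosines per window < min_cyt = 4 -> no calls
  expect_equal(nrow(call_dmrs(cx, cx2, window = 100, step = 50,
                              min_cyt = 4)), 0)
  expect_gte(nrow(call_dmrs(cx, cx2, window = 100, step = 50,
                            min_cyt = 3)), 1)
})

test_that("DMR context composition is a pass-through proportion", {
  dmrs <- data.frame(context = rep(c("CG", "CHG", "CHH"),
                                   c(6366, 2533, 1102)))
  comp <- dmr_context_composition(dmrs)
  # published context split of hybridization DMRs, at printed precision
  expect_lt(max(abs(100 * comp$proportion - c(63.66, 25.33, 11.02))), 0.05)
  expect_equal(sum(comp$proportion), 1)
  all_cg <- dmr_context_composition(data.frame(context = rep("CG", 5)))
  expect_equal(all_cg$proportion, c(1, 0, 0))
})

test_that("DMR-expression association assigns by greatest overlap", {
  dmrs <- data.frame(chrom = "c1", start = c(100L, 5000L),
                     end = c(300L, 5200L), context = c("CHH", "CG"),
                     direction = c("hypo", "hyper"),
                     delta = c(-0.3, 0.2), p = c(1e-4, 1e-4))
  loci <- data.frame(locus_id = c("up1", "dn1"), chrom = "c1",
                     start = c(0L, 4900L), end = c(400L, 5400L))
  rec <- data.frame(locus_id = c("up1", "dn1"), de_class = c("Up", "Down"))
  out <- dmr_expression_association(dmrs, loci, rec, flank = 0)
  expect_equal(nrow(out$assignments), 2)
  up_row <- out$by_class[out$by_class$de_class == "Up" &
                           out$by_class$context == "CHH", ]
  expect_equal(up_row$hypo_proportion, 1)
  # empty association
  far <- data.frame(chrom = "c9", start = 0L, end = 10L, context = "CG",
                    direction = "hypo", delta = -0.2, p = 0.001)
  expect_equal(nrow(dmr_expression_association(far, loci, rec)$assignments),
               0)
})

test_that("methylation-expression correlation behaves at the extremes", {
  fc <- stats::setNames(rnorm(50), paste0("L", 1:50))
  dm <- data.frame(locus_id = names(fc), CG = -0.1 * fc, CHG = -0.05 * fc,
                   CHH = NA_real_)
  r <- suppressWarnings(methylation_expression_correlation(dm, fc))
  expect_equal(unname(r["CG"]), -1)
  expect_equal(unname(r["CHG"]), -1)
  expect_true(is.na(r["CHH"]))
  # independent pairs stay near zero
  set.seed(61)
  null_ok <- 0
  for (i in 1:20) {
    fc2 <- stats::setNames(rnorm(500), paste0("L", 1:500))
    dm2 <- data.frame(locus_id = names(fc2), CG = rnorm(500))
    r2 <- suppressWarnings(methylation_expression_correlation(dm2, fc2))
    null_ok <- null_ok + (abs(r2["CG"]) < 0.15)
  }
  expect_gte(null_ok, 19)
})

test_that("DMR caller type-I error is controlled on null methylomes", {
  set.seed(71)
  frac <- numeric()
  for (s in 1:3) {
    pos <- sort(sample.int(20000, 2500)) - 1L
    mk <- function() data.frame(
      chrom = "c1", pos = pos, strand = "+",
      context = sample(c("CG", "CHG", "CHH"), 2500, TRUE,
                       prob = c(0.4, 0.3, 0.3)),
      n_meth = rbinom(2500, 15, 0.4), n_total = 15L,
      stringsAsFactors = FALSE)
    a <- mk()
    b <- mk()
    d <- call_dmrs(a, b, alpha = 0.01)
    n_windows <- length(seq(0, 19999, by = 50)) * 3
    frac <- c(frac, nrow(d) / n_windows)
  }
  expect_lt(mean(frac), 2 * 0.01)
})
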