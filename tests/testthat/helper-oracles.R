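# Independent brute-force oracles.  These deliberately share no code with
# the implementation: quadratic loops, exhaustive enumeration, textbook
# formulas.

bf_overlaps <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] != subject$chrom[j]) next
    ov <- min(query$end[i], subject$end[j]) -
      max(query$start[i], subject$start[j])
    if (ov >= 1)
      out[[length(out) + 1]] <- data.frame(query = i, subject = j,
                                           overlap_bp = as.integer(ov))
  }
  if (!length(out))
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  do.call(rbind, out)
}

# Exhaustive best chain: enumerate every monotone chain by DFS.
bf_best_chain <- function(anc, max_gap) {
  n <- nrow(anc)
  best <- list(score = -Inf, idx = integer(), orientation = "same")
  extend <- function(idx, sgn) {
    sc <- sum(anc$score[idx])
    if (sc > best$score) {
      best <<- list(score = sc, idx = sort(idx),
                    orientation = if (sgn > 0) "same" else "inverted")
    }
    last <- idx[length(idx)]
    for (j in seq_len(n)) {
      da <- anc$rank_a[j] - anc$rank_a[last]
      db <- sgn * (anc$rank_b[j] - anc$rank_b[last])
      if (da > 0 && da <= max_gap && db > 0 && db <= max_gap)
        extend(c(idx, j), sgn)
    }
  }
  for (sgn in c(1, -1)) for (i in seq_len(n)) extend(i, sgn)
  best
}

bf_chain_blocks <- function(anc, min_anchors, max_gap) {
  # best-first extraction using the exhaustive chain finder
  blocks <- list()
  remaining <- anc
  repeat {
    if (nrow(remaining) == 0) break
    ch <- bf_best_chain(remaining, max_gap)
    if (length(ch$idx) < min_anchors) break
    blocks[[length(blocks) + 1]] <-
      sort(remaining$gene_a[ch$idx])
    remaining <- remaining[-ch$idx, , drop = FALSE]
  }
  blocks
}

bf_fisher2x2 <- function(a, b, c, d) {
  # two-sided Fisher: sum of hypergeometric probabilities <= P(observed)
  m <- a + c
  n <- b + d
  k <- a + b
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

bf_spearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- rk(x)
  ry <- rk(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# per-bp metaprofile oracle for a per-bp value vector track (one chrom)
bf_metaprofile_row <- function(values, start, end, strand, body_bins,
                               flank, flank_bin) {
  L <- length(values)
  win_mean <- function(x0, x1) {
    if (x1 <= 0 || x0 >= L || x1 <= x0) return(NA_real_)
    x0 <- max(x0, 0); x1 <- min(x1, L)
    tot <- 0; w <- 0
    for (i in (floor(x0) + 1):ceiling(x1)) {
      wi <- min(i, x1) - max(i - 1, x0)
      if (wi > 0) { tot <- tot + values[i] * wi; w <- w + wi }
    }
    if (w == 0) NA_real_ else tot / w
  }
  n_flank <- flank %/% flank_bin
  len <- end - start
  up <- sapply(seq_len(n_flank), function(k)
    win_mean(start - flank + (k - 1) * flank_bin,
             start - flank + k * flank_bin))
  body <- sapply(seq_len(body_bins), function(k)
    win_mean(start + len * (k - 1) / body_bins,
             start + len * k / body_bins))
  dn <- sapply(seq_len(n_flank), function(k)
    win_mean(end + (k - 1) * flank_bin, end + k * flank_bin))
  row <- c(up, body, dn)
  if (strand == "-") row <- rev(row)
  row
}

# regex-free independent six-frame ORF scan (longest ORF in codons)
bf_longest_orf <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  longest <- 0
  for (seq in c(s, rc)) for (f in 0:2) {
    chars <- substring(seq, seq(f + 1, nchar(seq) - 2, by = 3),
                       seq(f + 3, nchar(seq), by = 3))
    if (!length(chars)) next
    i <- 1
    while (i <= length(chars)) {
      if (chars[i] == "ATG") {
        j <- i
        while (j <= length(chars) &&
               !(chars[j] %in% c("TAA", "TAG", "TGA"))) j <- j + 1
        longest <- max(longest, j - i)
        i <- j + 1
      } else i <- i + 1
    }
  }
  longest
}

# minimal independent GTF exon parser (exon rows only)
bf_parse_gtf_exons <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[3] != "exon") next
    tid <- sub('.*transcript_id "([^"]+)".*', "\\1", f[9])
    out[[length(out) + 1]] <- data.frame(
      transcript_id = tid, chrom = f[1],
      start = as.integer(f[4]) - 1L, end = as.integer(f[5]),
      strand = f[7], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
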