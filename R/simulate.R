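#' Configuration for the synthetic hybrid/polyploid study design
#'
#' Defaults define the study conditions the generator emulates: two small
#' diploid genomes (A and D) sharing an anchor-gene scaffold, their F1
#' (concatenation of both genomes) and an allotetraploid (relabelled
#' subgenomes); a Gypsy-dominated TE landscape with a minor LINE share;
#' two thirds of lncRNA loci TE-overlapped, with LINE over-represented in
#' the lncRNA-overlapped mix; 80% of syntenic lncRNA loci transcribed in
#' only one genome (SA); about a third of lncRNA loci reprogrammed in the
#' F1 relative to the mid-parent; and per-cytosine binomial methylation
#' with planted demethylation at activated TE-lncRNA loci, anticorrelated
#' with the expression change at strength `meth_expr_rho_target`.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_chroms,chrom_length chromosomes per genome and their length, bp.
#' @param n_pcg,n_lnc protein-coding and lncRNA locus pairs per genome.
#' @param te_density named per-family fraction of the genome covered by
#'   background TEs.
#' @param frac_te_overlapped_lnc fraction of lncRNA loci planted with an
#'   overlapping TE.
#' @param lnc_te_family_mix family proportions among lncRNA-overlapped TEs.
#' @param frac_syntenic fraction of lncRNA loci in syntenic positions
#'   (ST + SA).
#' @param frac_syn_pcg fraction of lncRNA loci whose homologous position in
#'   the other genome is a coding exon.
#' @param frac_sa fraction of syntenic lncRNA loci transcribed in only one
#'   genome.
#' @param frac_f1_reprogrammed fraction of lncRNA loci whose F1 expression
#'   deviates from the mid-parent.
#' @param effect_log2_range range of the absolute log2 deviation of
#'   reprogrammed loci from the mid-parent (minimum 1).
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param read_depth RNA-seq library size per sample.
#' @param lnc_mean_expr,pcg_mean_expr,expr_sdlog log-normal expression
#'   baselines (lncRNAs lower than coding genes).
#' @param sub_rate_lnc,sub_rate_pcg per-base substitution rates between the
#'   A and D copies of homologous lncRNA and coding loci.
#' @param meth_coverage mean per-cytosine bisulfite coverage.
#' @param meth_baseline per-feature-class CG/CHG/CHH methylation levels.
#' @param demeth_effect maximum methylation-level change planted at
#'   reprogrammed lncRNA loci.
#' @param meth_expr_rho_target planted Spearman correlation between the
#'   methylation change and the expression log2 fold change (negative).
#' @param srna_depth number of simulated small-RNA reads.
#' @param srna_weights relative per-bp sampling weights for small-RNA reads
#'   (TE body over flanks, coding-gene flanks over body, background) and the
#'   depletion factors of lncRNA-overlapped TEs and LINEs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2,
                       chrom_length = 200000,
                       n_pcg = 40,
                       n_lnc = 120,
                       te_density = c(Gypsy = 0.14, Copia = 0.05,
                                      LTR_other = 0.02, LINE = 0.012,
                                      SINE = 0.004, DNA = 0.02,
                                      unknown = 0.01),
                       frac_te_overlapped_lnc = 2 / 3,
                       lnc_te_family_mix = c(LINE = 0.40, Gypsy = 0.30,
                                             Copia = 0.12, DNA = 0.08,
                                             LTR_other = 0.05, SINE = 0.03,
                                             unknown = 0.02),
                       frac_syntenic = 0.55,
                       frac_syn_pcg = 0.05,
                       frac_sa = 0.8,
                       frac_f1_reprogrammed = 0.35,
                       effect_log2_range = c(1, 3),
                       nb_dispersion = 0.05,
                       read_depth = 2e5,
                       lnc_mean_expr = 60,
                       pcg_mean_expr = 400,
                       expr_sdlog = 0.8,
                       sub_rate_lnc = 0.12,
                       sub_rate_pcg = 0.03,
                       meth_coverage = 15,
                       meth_baseline = list(
                         background = c(CG = 0.08, CHG = 0.05, CHH = 0.03),
                         pcg_body = c(CG = 0.12, CHG = 0.05, CHH = 0.02),
                         lnc_body = c(CG = 0.18, CHG = 0.14, CHH = 0.09),
                         te = c(CG = 0.85, CHG = 0.65, CHH = 0.15),
                         lnc_te = c(CG = 0.60, CHG = 0.45, CHH = 0.12),
                         lnc_te_line = c(CG = 0.25, CHG = 0.18, CHH = 0.06)),
                       demeth_effect = 0.3,
                       meth_expr_rho_target = -0.6,
                       srna_depth = 3e4,
                       srna_weights = c(te_body = 8, te_flank = 1.5,
                                        pcg_body = 0.8, pcg_flank = 3,
                                        background = 0.3,
                                        lnc_te_depletion = 0.3,
                                        lnc_te_line_depletion = 0.15)) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  issues <- validate_config(cfg)
  if (length(issues)) stop("invalid sim_config: ", issues[1])
  cfg
}

#' Validate a simulation/pipeline configuration
#'
#' @param config a [sim_config()] (or plain list with the same fields).
#' @return character vector of violations; empty when the configuration is
#'   usable.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  fracs <- c("frac_te_overlapped_lnc", "frac_syntenic", "frac_syn_pcg",
             "frac_sa", "frac_f1_reprogrammed")
  for (f in fracs)
    chk(is.numeric(config[[f]]) && config[[f]] >= 0 && config[[f]] <= 1,
        paste0(f, " must lie in [0, 1]"))
  chk(config$frac_syntenic + config$frac_syn_pcg <= 1,
      "frac_syntenic + frac_syn_pcg must not exceed 1")
  chk(sum(config$te_density) < 1, "te_density must sum to < 1")
  chk(all(names(config$te_density) %in% TE_FAMILIES),
      "te_density families must come from the fixed vocabulary")
  chk(config$n_chroms >= 1 && config$chrom_length >= 20000,
      "need n_chroms >= 1 and chrom_length >= 20000")
  chk(config$n_pcg >= 2 * config$n_chroms,
      "need at least 2 coding genes per chromosome")
  chk(config$nb_dispersion >= 0, "nb_dispersion must be >= 0")
  chk(config$read_depth > 0, "read_depth must be positive")
  chk(config$effect_log2_range[1] >= 1,
      "reprogrammed-locus effects must deviate by >= 1 log2 unit")
  chk(config$meth_expr_rho_target >= -1 && config$meth_expr_rho_target <= 1,
      "meth_expr_rho_target must lie in [-1, 1]")
  chk(config$demeth_effect >= 0 && config$demeth_effect <= 0.9,
      "demeth_effect must lie in [0, 0.9]")
  if (!is.null(config$alpha))
    chk(config$alpha > 0 && config$alpha < 1, "alpha must lie in (0, 1)")
  if (!is.null(config$fc)) chk(config$fc > 1, "fc must exceed 1")
  v
}

# Deterministic child seed per generator stream, so adding a data type does
# not perturb the others.
stream_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 17L + stream * 7919L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

te_family_length <- c(Gypsy = 3000, Copia = 2500, LTR_other = 2000,
                      LINE = 1200, SINE = 300, DNA = 800, unknown = 600,
                      other = 600)

# exact integer split of n into parts proportional to p
proportional_counts <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n_mut <- round(rate * length(ch))
  if (n_mut > 0) {
    pos <- sample.int(length(ch), n_mut)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(ch, collapse = "")
}

seq_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  100 * mean(ca[seq_len(n)] == cb[seq_len(n)])
}

# coding sequence with one long clean ORF (ATG + non-stop codons + TAA)
orf_sequence <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  n_codon <- (n - 6) %/% 3
  body <- paste(sample(codons, n_codon, replace = TRUE), collapse = "")
  s <- paste0("ATG", body, "TAA")
  paste0(s, random_seq(max(0, n - nchar(s))))
}

substr_put <- function(s, at, piece) {
  # overwrite s[at .. at+nchar(piece)-1] (1-based)
  paste0(substr(s, 1, at - 1), piece,
         substr(s, at + nchar(piece), nchar(s)))
}

#' Plant a methylation-expression link via a Gaussian copula
#'
#' Given per-locus expression log2 fold changes, draws methylation-level
#' changes whose Spearman correlation with the fold changes equals `rho`
#' (using the bivariate-normal identity `rho_pearson =
#' 2*sin(pi*rho_spearman/6)`), mapped monotonically into
#' `[-max_effect, max_effect]`.
#'
#' @param log2fc numeric vector of planted expression changes.
#' @param rho target Spearman correlation (typically negative:
#'   demethylation accompanies activation).
#' @param max_effect maximum absolute methylation change.
#' @return numeric vector of planted methylation deltas.
#' @export
plant_meth_expr_link <- function(log2fc, rho, max_effect = 0.3) {
  n <- length(log2fc)
  if (n == 0) return(numeric())
  rho_p <- 2 * sin(pi * rho / 6)
  z_fc <- stats::qnorm(rank(log2fc, ties.method = "average") / (n + 1))
  z <- rho_p * z_fc + sqrt(1 - rho_p^2) * stats::rnorm(n)
  max_effect * (2 * stats::pnorm(z) - 1)
}

#' Simulate genomes, annotations, TEs and the truth table
#'
#' Builds two diploid genomes (chromosomes `A1..`, `D1..`) sharing a
#' collinear scaffold of coding anchor genes, with lncRNA loci planted
#' between anchors; the F1 is the union of both chromosome sets and the
#' allotetraploid a relabelled copy (`At..`, `Dt..`).  Homologous loci share
#' sequence up to per-base substitution (`sub_rate_pcg`, `sub_rate_lnc`).
#' Category planting uses deterministic counts, so e.g. `frac_sa = 0.8`
#' yields exactly `round(0.8 * n_syntenic)` SA pairs.
#'
#' @param config a [sim_config()].
#' @return object of class `polylnc_sim`: genomes (character vectors of
#'   chromosome sequences), per-genome annotations ([transcript_set()]),
#'   TE tables, and the `truth` table (one row per lncRNA locus pair, with
#'   planted synteny category, TE family, F1 expression class and
#'   methylation deltas).
#' @export
simulate_genomes <- function(config) {
  cfg <- config
  with_seed(stream_seed(cfg$seed, 1L), {
    n_ch <- cfg$n_chroms
    L <- cfg$chrom_length
    pcg_per_chrom <- proportional_counts(cfg$n_pcg, rep(1, n_ch))
    lnc_per_chrom <- proportional_counts(cfg$n_lnc, rep(1, n_ch))

    # ---- category planting (deterministic counts, random placement) ----
    n_lnc <- cfg$n_lnc
    n_syn_pcg <- round(cfg$frac_syn_pcg * n_lnc)
    n_syn <- round(cfg$frac_syntenic * n_lnc)
    n_sa <- round(cfg$frac_sa * n_syn)
    n_st <- n_syn - n_sa
    n_non <- n_lnc - n_syn - n_syn_pcg
    lnc_len <- 500L
    out_step <- lnc_len + 400L

    # terminal-gap capacity per chromosome; the NON_SYN quota not placeable
    # outside the anchor span falls back to in-span loci without a homolog
    spacing_ch <- as.integer(L) %/% (pcg_per_chrom + 1L)
    term_w <- pmax(0L, spacing_ch - 600L - 1500L - 1000L)
    out_cap <- 2L * (term_w %/% out_step)
    n_out_target <- n_non %/% 2
    out_per_chrom <- pmin(proportional_counts(n_out_target, lnc_per_chrom),
                          out_cap, lnc_per_chrom)
    n_out <- sum(out_per_chrom)
    n_nohom <- n_non - n_out
    inner <- sample(c(rep("ST", n_st), rep("SA", n_sa),
                      rep("SYN_PCG", n_syn_pcg),
                      rep("NON_SYN_NOHOM", n_nohom)))
    chrom_of <- rep(seq_len(n_ch), lnc_per_chrom)
    cat_of <- character(n_lnc)
    ptr <- 1
    for (ch in seq_len(n_ch)) {
      idx <- which(chrom_of == ch)
      k_out <- out_per_chrom[ch]
      if (k_out > 0) cat_of[idx[seq_len(k_out)]] <- "NON_SYN_OUT"
      k_in <- length(idx) - k_out
      if (k_in > 0) {
        cat_of[idx[k_out + seq_len(k_in)]] <- inner[ptr:(ptr + k_in - 1)]
        ptr <- ptr + k_in
      }
    }

    # ---- coordinates (identical layout in A and D) ----
    # alternate inter-anchor gaps carry lncRNAs; the others are left free
    # for background TEs, so multi-kb elements have contiguous room
    pcg <- list()
    lnc <- list()
    for (ch in seq_len(n_ch)) {
      k <- pcg_per_chrom[ch]
      spacing <- spacing_ch[ch]
      centers <- spacing * seq_len(k)
      pcg[[ch]] <- data.frame(
        chrom_idx = ch, pcg_idx = seq_len(k), center = centers,
        start = centers - 600L, end = centers + 600L,
        strand = ifelse(seq_len(k) %% 2 == 1, "+", "-"),
        stringsAsFactors = FALSE)
      idx <- which(chrom_of == ch)
      is_out <- cat_of[idx] == "NON_SYN_OUT"
      n_in <- sum(!is_out)
      gaps <- data.frame(start = centers[-k] + 600L,
                         end = centers[-1] - 600L)
      lnc_gaps <- gaps[seq(1, nrow(gaps), by = 2), , drop = FALSE]
      per_gap <- proportional_counts(n_in, rep(1, nrow(lnc_gaps)))
      starts_in <- unlist(lapply(seq_len(nrow(lnc_gaps)), function(g) {
        q <- per_gap[g]
        if (q == 0) return(integer())
        w <- lnc_gaps$end[g] - lnc_gaps$start[g]
        if (w < (q + 1) * (lnc_len + 300))
          stop("lncRNA density infeasible for chrom_length")
        off <- round(w * seq_len(q) / (q + 1))
        as.integer(lnc_gaps$start[g] + off - lnc_len %/% 2)
      }))
      n_o <- sum(is_out)
      starts_out <- integer()
      if (n_o > 0) {
        n_l <- min(term_w[ch] %/% out_step, ceiling(n_o / 2))
        n_r <- n_o - n_l
        if (n_l > 0)
          starts_out <- as.integer(1500L + out_step * (seq_len(n_l) - 1))
        if (n_r > 0)
          starts_out <- c(starts_out, as.integer(
            centers[k] + 600L + 1000L + out_step * (seq_len(n_r) - 1)))
      }
      starts <- integer(length(idx))
      starts[is_out] <- starts_out
      starts[!is_out] <- starts_in
      lnc[[ch]] <- data.frame(
        pair_id = idx, chrom_idx = ch, start = starts,
        end = starts + lnc_len,
        strand = ifelse(idx %% 2 == 1, "+", "-"),
        category = cat_of[idx], stringsAsFactors = FALSE)
    }
    pcg <- do.call(rbind, pcg)
    lnc <- do.call(rbind, lnc)
    lnc <- lnc[order(lnc$pair_id), , drop = FALSE]

    # which genome(s) transcribe each lncRNA pair
    ann_a <- ann_b <- rep(FALSE, n_lnc)
    for (catg in unique(lnc$category)) {
      idx <- which(lnc$category == catg)
      if (catg == "ST") {
        ann_a[idx] <- ann_b[idx] <- TRUE
      } else {
        # alternate single-genome transcription
        ann_a[idx[seq_along(idx) %% 2 == 1]] <- TRUE
        ann_b[idx[seq_along(idx) %% 2 == 0]] <- TRUE
      }
    }

    # ---- TE planting ----
    n_te_lnc <- round(cfg$frac_te_overlapped_lnc * n_lnc)
    te_idx <- sort(sample.int(n_lnc, n_te_lnc))
    fam_counts <- proportional_counts(n_te_lnc, cfg$lnc_te_family_mix)
    fam_of <- sample(rep(names(cfg$lnc_te_family_mix), fam_counts))
    te_family <- rep("none", n_lnc)
    te_family[te_idx] <- fam_of
    lnc_te <- do.call(rbind, lapply(seq_along(te_idx), function(j) {
      i <- te_idx[j]
      fam <- fam_of[j]
      # TE fragment overlapping the lncRNA exon; capped so it never
      # reaches a neighbouring locus
      len <- min(te_family_length[[fam]], 800L)
      s <- max(0L, lnc$start[i] - 150L)
      data.frame(chrom_idx = lnc$chrom_idx[i], start = s,
                 end = s + as.integer(len), strand = ".",
                 family = fam, te_id = sprintf("lte_%04d", i),
                 on_lnc = TRUE, pair_id = i, stringsAsFactors = FALSE)
    }))
    if (is.null(lnc_te))
      lnc_te <- data.frame(chrom_idx = integer(), start = integer(),
                           end = integer(), strand = character(),
                           family = character(), te_id = character(),
                           on_lnc = logical(), pair_id = integer(),
                           stringsAsFactors = FALSE)

    # background (genome-wide) TEs in the space left free by genes and lncRNAs
    occupied <- rbind(
      data.frame(chrom_idx = pcg$chrom_idx, start = pcg$start - 200L,
                 end = pcg$end + 200L),
      data.frame(chrom_idx = lnc$chrom_idx, start = lnc$start - 200L,
                 end = lnc$end + 200L),
      data.frame(chrom_idx = lnc_te$chrom_idx, start = lnc_te$start - 200L,
                 end = lnc_te$end + 200L))
    bg_te <- list()
    te_counter <- 0L
    for (ch in seq_len(n_ch)) {
      occ <- occupied[occupied$chrom_idx == ch, , drop = FALSE]
      occ <- occ[order(occ$start), , drop = FALSE]
      free <- free_intervals(occ, L)
      fams <- rep(names(cfg$te_density),
                  pmax(0, round(cfg$te_density * L /
                                  te_family_length[names(cfg$te_density)])))
      fams <- sample(fams)
      need <- sum(te_family_length[fams]) + 150 * length(fams)
      if (need > sum(free$end - free$start))
        stop("TE densities infeasible for chrom_length")
      placed <- place_in_free(free, te_family_length[fams])
      if (length(fams)) {
        bg_te[[ch]] <- data.frame(
          chrom_idx = ch, start = placed,
          end = placed + as.integer(te_family_length[fams]), strand = ".",
          family = fams,
          te_id = sprintf("te_%05d", te_counter + seq_along(fams)),
          on_lnc = FALSE, pair_id = NA_integer_, stringsAsFactors = FALSE)
        te_counter <- te_counter + length(fams)
      }
    }
    te <- rbind(do.call(rbind, bg_te), lnc_te)
    te <- te[order(te$chrom_idx, te$start), , drop = FALSE]

    # ---- F1 expression classes and methylation deltas ----
    n_re <- round(cfg$frac_f1_reprogrammed * n_lnc)
    re_idx <- sample.int(n_lnc, n_re)
    f1_class <- rep("Equal", n_lnc)
    f1_class[re_idx[seq_len(n_re %/% 2)]] <- "Up"
    f1_class[re_idx[setdiff(seq_len(n_re), seq_len(n_re %/% 2))]] <- "Down"
    eff <- numeric(n_lnc)
    de <- f1_class != "Equal"
    eff[de] <- stats::runif(sum(de), cfg$effect_log2_range[1],
                            cfg$effect_log2_range[2]) *
      ifelse(f1_class[de] == "Up", 1, -1)
    delta <- numeric(n_lnc)
    delta[de] <- plant_meth_expr_link(eff[de], cfg$meth_expr_rho_target,
                                      cfg$demeth_effect)
    delta[!de] <- pmax(-0.05, pmin(0.05, stats::rnorm(sum(!de), 0, 0.02)))

    truth <- data.frame(
      pair_id = seq_len(n_lnc),
      locus_a = sprintf("A_lnc%04d", seq_len(n_lnc)),
      locus_b = sprintf("D_lnc%04d", seq_len(n_lnc)),
      chrom_idx = lnc$chrom_idx, start = lnc$start, end = lnc$end,
      strand = lnc$strand,
      category = ifelse(startsWith(lnc$category, "NON_SYN"), "NON_SYN",
                        lnc$category),
      placement = lnc$category,
      annotated_a = ann_a, annotated_b = ann_b,
      te_family = te_family,
      f1_class = f1_class, f1_log2_effect = eff,
      delta_cg = delta, delta_chg = 0.8 * delta, delta_chh = 0.5 * delta,
      stringsAsFactors = FALSE)

    # homolog target in the partner genome (same coordinates except SYN_PCG)
    truth$hom_start <- truth$start
    truth$hom_end <- truth$end
    sp <- which(truth$placement == "SYN_PCG")
    for (i in sp) {
      cand <- pcg[pcg$chrom_idx == truth$chrom_idx[i] &
                    pcg$start > truth$end[i], , drop = FALSE]
      if (nrow(cand) == 0)
        cand <- pcg[pcg$chrom_idx == truth$chrom_idx[i], , drop = FALSE]
      # first exon of the nearest downstream anchor gene
      truth$hom_start[i] <- cand$start[1]
      truth$hom_end[i] <- cand$start[1] + 450L
    }
    truth$hom_start[truth$placement %in% c("NON_SYN_NOHOM", "NON_SYN_OUT")] <-
      NA_integer_
    truth$hom_end[is.na(truth$hom_start)] <- NA_integer_

    # ---- sequences ----
    seq_a <- lapply(seq_len(n_ch), function(ch) random_seq(L))
    seq_b <- lapply(seq_len(n_ch), function(ch) random_seq(L))
    for (r in seq_len(nrow(pcg))) {
      cds <- orf_sequence(1000L)
      spl <- if (pcg$strand[r] == "-")
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds))) else cds
      ch <- pcg$chrom_idx[r]
      seq_a[[ch]] <- substr_put(seq_a[[ch]], pcg$start[r] + 1L,
                                paste0(substr(spl, 1, 500),
                                       random_seq(200),
                                       substr(spl, 501, 1000)))
      hom <- mutate_seq(substr(seq_a[[ch]], pcg$start[r] + 1L, pcg$end[r]),
                        cfg$sub_rate_pcg)
      seq_b[[ch]] <- substr_put(seq_b[[ch]], pcg$start[r] + 1L, hom)
    }
    for (i in seq_len(n_lnc)) {
      ch <- truth$chrom_idx[i]
      if (truth$placement[i] == "SYN_PCG") {
        # the lncRNA is a degenerate copy of a coding exon in the partner
        # genome (both copies carry it; only the annotated one transcribes)
        src <- substr(seq_a[[ch]], truth$hom_start[i] + 1L,
                      truth$hom_end[i])
        piece_a <- mutate_seq(paste0(src, random_seq(50)), cfg$sub_rate_lnc)
        piece_b <- mutate_seq(paste0(src, random_seq(50)), cfg$sub_rate_lnc)
        seq_a[[ch]] <- substr_put(seq_a[[ch]], truth$start[i] + 1L,
                                  substr(piece_a, 1, 500))
        seq_b[[ch]] <- substr_put(seq_b[[ch]], truth$start[i] + 1L,
                                  substr(piece_b, 1, 500))
      } else if (truth$placement[i] %in% c("ST", "SA")) {
        hom <- mutate_seq(substr(seq_a[[ch]], truth$start[i] + 1L,
                                 truth$end[i]), cfg$sub_rate_lnc)
        seq_b[[ch]] <- substr_put(seq_b[[ch]], truth$start[i] + 1L, hom)
      }
    }

    chroms_a <- sprintf("A%d", seq_len(n_ch))
    chroms_b <- sprintf("D%d", seq_len(n_ch))
    names(seq_a) <- chroms_a
    names(seq_b) <- chroms_b

    # ---- annotations ----
    pcg_ts <- function(prefix, chroms) {
      ids <- sprintf("%s_pcg%03d", prefix, seq_len(nrow(pcg)))
      tr <- data.frame(transcript_id = paste0(ids, "_t1"), locus_id = ids,
                       chrom = chroms[pcg$chrom_idx], start = pcg$start,
                       end = pcg$end, strand = pcg$strand, biotype = "PCG",
                       stringsAsFactors = FALSE)
      ex <- rbind(
        data.frame(transcript_id = tr$transcript_id, chrom = tr$chrom,
                   start = pcg$start, end = pcg$start + 500L,
                   strand = tr$strand, stringsAsFactors = FALSE),
        data.frame(transcript_id = tr$transcript_id, chrom = tr$chrom,
                   start = pcg$end - 500L, end = pcg$end,
                   strand = tr$strand, stringsAsFactors = FALSE))
      list(tr = tr, ex = ex)
    }
    lnc_ts <- function(prefix, chroms, annotated) {
      keep <- which(annotated)
      ids <- sprintf("%s_lnc%04d", prefix, keep)
      tr <- data.frame(transcript_id = paste0(ids, "_t1"), locus_id = ids,
                       chrom = chroms[truth$chrom_idx[keep]],
                       start = truth$start[keep], end = truth$end[keep],
                       strand = truth$strand[keep],
                       biotype = "lncRNA_candidate", stringsAsFactors = FALSE)
      ex <- data.frame(transcript_id = tr$transcript_id, chrom = tr$chrom,
                       start = tr$start, end = tr$end, strand = tr$strand,
                       stringsAsFactors = FALSE)
      list(tr = tr, ex = ex)
    }
    pa <- pcg_ts("A", chroms_a); la <- lnc_ts("A", chroms_a, ann_a)
    pb <- pcg_ts("D", chroms_b); lb <- lnc_ts("D", chroms_b, ann_b)
    ann_A <- transcript_set(rbind(pa$tr, la$tr), rbind(pa$ex, la$ex))
    ann_D <- transcript_set(rbind(pb$tr, lb$tr), rbind(pb$ex, lb$ex))
    ann_F1 <- transcript_set(rbind(pa$tr, la$tr, pb$tr, lb$tr),
                             rbind(pa$ex, la$ex, pb$ex, lb$ex))

    te_table <- function(chroms) {
      data.frame(chrom = chroms[te$chrom_idx], start = te$start,
                 end = pmin(te$end, L), strand = te$strand,
                 family = te$family, te_id = te$te_id, on_lnc = te$on_lnc,
                 pair_id = te$pair_id, stringsAsFactors = FALSE)
    }
    te_A <- te_table(chroms_a)
    te_D <- te_table(chroms_b)
    te_D$te_id <- sub("^(l?te_)", "\\1D", te_D$te_id)
    te_A$te_id <- sub("^(l?te_)", "\\1A", te_A$te_id)
    te_F1 <- rbind(te_A, te_D)

    structure(list(
      config = cfg,
      chroms = list(A = chroms_a, D = chroms_b),
      chrom_lengths = stats::setNames(rep(L, 2 * n_ch),
                                      c(chroms_a, chroms_b)),
      genomes = list(A = seq_a, D = seq_b),
      annotation = list(A = ann_A, D = ann_D, F1 = ann_F1),
      te = list(A = te_A, D = te_D, F1 = te_F1),
      pcg_layout = pcg,
      truth = truth), class = "polylnc_sim")
  })
}

#' @export
print.polylnc_sim <- function(x, ...) {
  cat("polylnc_sim:", length(x$genomes$A), "+", length(x$genomes$D),
      "chromosomes,", nrow(x$truth), "lncRNA locus pairs,",
      nrow(x$te$F1), "TE features\n")
  invisible(x)
}

free_intervals <- function(occ, L) {
  if (nrow(occ) == 0) return(data.frame(start = 0L, end = L))
  s <- pmax(occ$start, 0L)
  e <- pmin(occ$end, L)
  starts <- c(0L, e)
  ends <- c(s, L)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

# Distribute elements over free intervals, balancing load across chunks
# (largest remaining capacity first) and spacing evenly within each chunk,
# so flanking regions stay as clear of neighbouring TEs as the density
# allows.
place_in_free <- function(free, lens, min_pad = 150) {
  n_chunk <- nrow(free)
  W <- free$end - free$start
  used <- numeric(n_chunk)
  count <- integer(n_chunk)
  member <- vector("list", n_chunk)
  for (j in order(lens, decreasing = TRUE)) {
    remaining <- W - used - (count + 2) * min_pad - lens[j]
    pick <- which.max(remaining)
    if (remaining[pick] < 0)
      stop("TE densities infeasible for chrom_length")
    member[[pick]] <- c(member[[pick]], j)
    used[pick] <- used[pick] + lens[j]
    count[pick] <- count[pick] + 1L
  }
  out <- numeric(length(lens))
  for (fi in seq_len(n_chunk)) {
    take <- sort(member[[fi]])
    if (!length(take)) next
    pad <- (W[fi] - used[fi]) / (length(take) + 1)
    pos <- free$start[fi]
    for (j in take) {
      pos <- pos + pad
      out[j] <- round(pos)
      pos <- pos + lens[j]
    }
  }
  as.integer(out)
}
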