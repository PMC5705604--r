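# TSS-proximal insertion discovery and regulatory statistics: upstream
# GC/CpG/unmethylation window statistics, paired one-sided tests, TE
# classification, and a simple negative-binomial two-group expression
# screen.

#' Find TSSs with a qualifying upstream insertion and their matched partners
#'
#' A TSS qualifies when one strain carries an insertion of size within
#' `size_range` whose nearer breakpoint lies within `max_distance` bp of the
#' TSS; the counterpart strain's (pseudo-)TSS at the orthologous position is
#' the matched no-insertion partner.
#'
#' @param tss data.frame with strain, pair_id, chromosome, pos, strand.
#' @param insertions data.frame of polarized insertions: strain, chromosome,
#'   start, end (carrier coordinates of the inserted segment).
#' @param size_range Inclusive insertion size bounds (bp).
#' @param max_distance Maximum breakpoint-to-TSS distance (bp).
#' @return data.frame: pair_id, chromosome, carrier (strain with the
#'   insertion), carrier_pos, partner, partner_pos, strand, insertion_size,
#'   distance.
#' @export
find_insertion_tss_pairs <- function(tss, insertions,
                                     size_range = c(1000, 10000),
                                     max_distance = 100) {
  strains <- unique(tss$strain)
  if (length(strains) != 2) stop("tss table must cover exactly two strains")
  out <- list()
  for (pid in unique(tss$pair_id)) {
    rows <- tss[tss$pair_id == pid, , drop = FALSE]
    if (nrow(rows) != 2) {
      warning("TSS pair ", pid, " is unpaired; skipped")
      next
    }
    for (si in 1:2) {
      r <- rows[si, ]
      if (is.na(r$pos)) next
      ins <- insertions[insertions$strain == r$strain &
                          insertions$chromosome == r$chromosome, , drop = FALSE]
      if (!nrow(ins)) next
      sz <- ins$end - ins$start + 1
      d <- pmin(abs(ins$start - r$pos), abs(ins$end - r$pos))
      hit <- which(sz >= size_range[1] & sz <= size_range[2] &
                     d <= max_distance)
      if (!length(hit)) next
      h <- hit[which.min(d[hit])]
      partner <- rows[3 - si, ]
      out[[length(out) + 1]] <- data.frame(
        pair_id = pid, chromosome = r$chromosome, carrier = r$strain,
        carrier_pos = r$pos, partner = partner$strain,
        partner_pos = partner$pos, strand = r$strand,
        insertion_size = sz[h], distance = d[h])
      break
    }
  }
  if (!length(out))
    return(data.frame(pair_id = integer(), chromosome = character(),
                      carrier = character(), carrier_pos = integer(),
                      partner = character(), partner_pos = integer(),
                      strand = character(), insertion_size = numeric(),
                      distance = numeric()))
  do.call(rbind, out)
}

#' Upstream-window statistics at a (pseudo-)TSS
#'
#' Over the `window`-bp region upstream (5' side on the TSS strand):
#' GC ratio = (#G + #C) / window length; CpG ratio = #CpG dinucleotides /
#' (window length - 1); unmethylated fraction = unmethylated CpG calls /
#' CpG sites with calls (sites without calls excluded from the denominator).
#' On the minus strand the window covers positions `tss+1 .. tss+window`
#' (its reverse complement has identical GC and CpG counts, which are
#' strand-symmetric).
#'
#' @param chrom_seq Chromosome sequence.
#' @param pos TSS position (1-based).
#' @param strand `"+"` or `"-"`.
#' @param calls Optional methylation calls (data.frame pos, state) on this
#'   chromosome.
#' @param window Window length (bp).
#' @return List: gc_ratio, cpg_ratio, unmethylated_fraction (NA without
#'   calls), n_cpg_called, clipped (TRUE when the window hit a contig edge).
#' @export
window_stats <- function(chrom_seq, pos, strand = "+", calls = NULL,
                         window = 500) {
  w <- upstream_window(pos, strand, window, nchar(chrom_seq))
  if (is.null(w)) stop("window entirely off the contig")
  clipped <- (w[2] - w[1] + 1) < window
  seqw <- substr(chrom_seq, w[1], w[2])
  n <- nchar(seqw)
  v <- strsplit(seqw, "", fixed = TRUE)[[1]]
  gc <- sum(v == "G" | v == "C") / n
  cpg_sites <- cpg_positions(seqw)
  cpg <- length(cpg_sites) / (n - 1)
  unmeth <- NA_real_; ncalled <- 0L
  if (!is.null(calls) && length(cpg_sites)) {
    abs_pos <- cpg_sites + w[1] - 1
    m <- calls[calls$pos %in% abs_pos, , drop = FALSE]
    ncalled <- nrow(m)
    if (ncalled > 0) unmeth <- mean(m$state == "unmethylated")
  }
  list(gc_ratio = gc, cpg_ratio = cpg, unmethylated_fraction = unmeth,
       n_cpg_called = ncalled, clipped = clipped)
}

#' Paired one-sided tests of upstream-parameter increases
#'
#' Wilcoxon signed-rank tests over matched (insertion, no-insertion) window
#' statistics: alternative "greater" for the GC and CpG ratios, "greater"
#' for the unmethylated fraction (i.e. methylation decreases). Zero
#' differences are dropped (the classical convention); with fewer than
#' `min_pairs` informative pairs the test is refused.
#'
#' @param with_ins,without_ins data.frames with columns gc_ratio, cpg_ratio,
#'   unmethylated_fraction (row i of each is a matched pair).
#' @param min_pairs Minimum matched pairs.
#' @return List of p-values: gc, cpg, unmethylated (NA when every difference
#'   is zero), plus `n_used` per parameter.
#' @export
paired_increase_tests <- function(with_ins, without_ins, min_pairs = 6L) {
  if (nrow(with_ins) != nrow(without_ins))
    stop("matched tables differ in length")
  if (nrow(with_ins) < min_pairs)
    stop("fewer than ", min_pairs, " matched pairs")
  one <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    d <- a[keep] - b[keep]
    d <- d[d != 0]
    if (length(d) < min_pairs)
      return(list(p = NA_real_, n = length(d)))
    # exact signed-rank when untied and small, normal approximation otherwise
    p <- suppressWarnings(
      wilcox.test(d, alternative = "greater")$p.value)
    list(p = p, n = length(d))
  }
  gc <- one(with_ins$gc_ratio, without_ins$gc_ratio)
  cpg <- one(with_ins$cpg_ratio, without_ins$cpg_ratio)
  um <- one(with_ins$unmethylated_fraction, without_ins$unmethylated_fraction)
  list(p_values = c(gc = gc$p, cpg = cpg$p, unmethylated = um$p),
       n_used = c(gc = gc$n, cpg = cpg$n, unmethylated = um$n))
}

#' Classify an insertion by transposable-element content
#'
#' The TE family covering the largest fraction of the insertion wins, if
#' that fraction exceeds `min_fraction` (strict); otherwise `"none"`.
#'
#' @param insertion_length Insertion length (bp).
#' @param te_hits data.frame: family, start, end (1-based closed intervals
#'   on the insertion; intervals of one family may overlap).
#' @param min_fraction Strict lower bound on covered fraction.
#' @return Family name or `"none"`.
#' @export
te_classify <- function(insertion_length, te_hits, min_fraction = 0.30) {
  if (is.null(te_hits) || nrow(te_hits) == 0) return("none")
  cov <- vapply(split(te_hits, te_hits$family), function(h) {
    covered <- rep(FALSE, insertion_length)
    for (i in seq_len(nrow(h))) {
      s <- max(1, h$start[i]); e <- min(insertion_length, h$end[i])
      if (s <= e) covered[s:e] <- TRUE
    }
    mean(covered)
  }, numeric(1))
  best <- which.max(cov)
  if (cov[best] > min_fraction) names(cov)[best] else "none"
}

#' Two-group negative-binomial expression screen
#'
#' Median-of-ratios size-factor normalization, per-TSS method-of-moments
#' dispersion (shrunk halfway to the across-TSS median, floored at 0.01),
#' and a Wald-type test of the log fold-change between the two strains (two
#' replicates each). A TSS with zero counts in both counterpart replicates
#' but expression in the carrier is flagged `novel`.
#'
#' @param counts Matrix with 4 columns: strain 1 replicates 1-2, strain 2
#'   replicates 1-2.
#' @param strains Length-2 strain names (columns 1-2 belong to the first).
#' @return data.frame per TSS: log2 fold-change (strain2 / strain1), p
#'   (Wald), direction (`up_in_<strain>` or `none`), novel flag; all-zero
#'   rows give NA.
#' @export
expression_screen <- function(counts, strains = c("strainA", "strainB")) {
  stopifnot(ncol(counts) == 4)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  # median-of-ratios size factors
  logg <- rowMeans(log(counts + 0L))
  use <- is.finite(logg)
  sf <- apply(counts, 2, function(col) {
    r <- log(col[use]) - logg[use]
    exp(median(r[is.finite(r)]))
  })
  if (any(!is.finite(sf) | sf <= 0)) sf[!is.finite(sf) | sf <= 0] <- 1
  norm <- sweep(counts, 2, sf, "/")
  g1 <- norm[, 1:2, drop = FALSE]; g2 <- norm[, 3:4, drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  # method-of-moments dispersion per TSS, pooled across both groups
  v1 <- apply(g1, 1, var); v2 <- apply(g2, 1, var)
  mm <- (m1 + m2) / 2
  disp_raw <- pmax(((v1 + v2) / 2 - mm) / mm^2, 0.01)
  disp_med <- median(disp_raw[mm > 0], na.rm = TRUE)
  disp <- (disp_raw + disp_med) / 2
  eps <- 0.5
  lfc <- log2((m2 + eps) / (m1 + eps))
  # Wald: var(log mu_hat) ~ (1/mu + alpha)/n per group
  se2 <- (1 / (m1 + eps) + disp) / 2 + (1 / (m2 + eps) + disp) / 2
  z <- log((m2 + eps) / (m1 + eps)) / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  allzero <- rowSums(counts) == 0
  p[allzero] <- NA; lfc[allzero] <- NA
  novel <- (rowSums(counts[, 1:2, drop = FALSE]) == 0 & m2 > 0) |
    (rowSums(counts[, 3:4, drop = FALSE]) == 0 & m1 > 0)
  direction <- ifelse(is.na(p) | p >= 1, "none",
                      ifelse(lfc > 0, paste0("up_in_", strains[2]),
                             ifelse(lfc < 0, paste0("up_in_", strains[1]),
                                    "none")))
  data.frame(log2_fold_change = lfc, p = p, direction = direction,
             novel = novel)
}
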