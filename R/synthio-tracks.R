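# Synthetic auxiliary tracks: Hi-C contact tables, CpG methylation calls and
# bisulfite pileups, TSS tag/count tables.

# Expected cis contact mass of a position p on a chromosome of length L under
# exponential decay exp(-a * distance), summed in closed form.
cis_contact_mass <- function(p, L, a) {
  if (a == 0) return(L)
  q <- exp(-a)
  geo <- function(m) if (m <= 0) 0 else q * (1 - q^m) / (1 - q)
  1 + geo(p - 1) + geo(L - p)
}

#' Simulate Hi-C contact counts per contig and chromosome
#'
#' Contact intensity between a contig (at its true position) and a genome
#' position at distance d is `exp(-hic_decay * d)`; positions on other
#' chromosomes are assigned the fixed distance `hic_trans_distance`. Counts
#' are multinomial draws of a Poisson(`hic_depth`) total per contig, so the
#' expected total equals `hic_depth`. As `hic_decay -> Inf` all contacts fall
#' on the contig's own chromosome; at `hic_decay = 0` expected contacts are
#' proportional to chromosome lengths.
#'
#' @param truth A `trio_truth` object (uses its contig map).
#' @param config The matching [trio_config()].
#' @return List: `contacts` (integer matrix, rows contigs, columns
#'   chromosomes), `truth_chromosome` (named vector of true chromosomes).
#' @export
generate_hic_contacts <- function(truth, config) {
  set.seed(substream_seed(config$seed, 2))
  contigs <- truth$contigs
  chroms <- unique(contigs$chromosome)
  lens <- vapply(chroms, function(ch)
    max(contigs$end[contigs$chromosome == ch]), numeric(1))
  a <- config$hic_decay
  m <- matrix(0L, nrow = nrow(contigs), ncol = length(chroms),
              dimnames = list(contigs$contig, chroms))
  trans_w <- exp(-a * config$hic_trans_distance)
  for (i in seq_len(nrow(contigs))) {
    ct <- contigs[i, ]
    p <- (ct$start + ct$end) %/% 2
    w <- lens * trans_w
    w[ct$chromosome] <- cis_contact_mass(p, lens[ct$chromosome], a)
    n <- rpois(1, config$hic_depth)
    if (n > 0) m[i, ] <- as.integer(rmultinom(1, n, w / sum(w)))
  }
  list(contacts = m,
       truth_chromosome = setNames(contigs$chromosome, contigs$contig))
}

#' Simulate a per-position Hi-C contact track for one contig
#'
#' Draws the contig's cis contacts along its true chromosome from the
#' exponential-decay kernel and bins them.
#'
#' @param truth A `trio_truth`.
#' @param config The matching [trio_config()].
#' @param contig Contig id.
#' @param bin Bin width (bp).
#' @param seed_offset Extra stream offset so repeated draws differ.
#' @return List: `counts` (integer vector per bin), `bin_centers`,
#'   `true_position` (contig midpoint on the chromosome).
#' @export
generate_hic_track <- function(truth, config, contig, bin = 1000,
                               seed_offset = 0) {
  set.seed(substream_seed(config$seed, 20 + seed_offset))
  ct <- truth$contigs[truth$contigs$contig == contig, , drop = FALSE]
  if (!nrow(ct)) stop("unknown contig ", contig)
  L <- max(truth$contigs$end[truth$contigs$chromosome == ct$chromosome])
  p <- (ct$start + ct$end) %/% 2
  a <- config$hic_decay
  centers <- seq(bin %/% 2, L, by = bin)
  w <- exp(-a * abs(centers - p))
  n <- rpois(1, config$hic_depth)
  counts <- if (n > 0) as.integer(rmultinom(1, n, w / sum(w))) else
    integer(length(centers))
  list(counts = counts, bin_centers = centers, true_position = p)
}

# CpG positions (position of the C on the + strand) in a sequence window.
cpg_positions <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Simulate CpG methylation calls and a bisulfite pileup for one strain
#'
#' CpGs inside centromeric arrays are methylated except within planted
#' hypomethylated domains. The call track mimics a region-level caller
#' (noise-free states); the pileup simulates zero-truncated
#' Poisson(`meth_coverage_mean`) coverage with per-read error
#' `meth_error_rate`.
#'
#' @param genomes,truth From [generate_trio()].
#' @param config The matching [trio_config()].
#' @param strain Strain name.
#' @param seed_offset Extra stream offset.
#' @return List: `calls` (chromosome, pos, state), `pileup` (chromosome, pos,
#'   meth_count, total_count), `domains` (planted hypo domains in strain
#'   coordinates).
#' @export
generate_methylation <- function(genomes, truth, config, strain = "strainA",
                                 seed_offset = 0) {
  if (config$meth_hypo_domains_per_centromere > 0 &&
      !is.null(truth$hypo_domains)) {
    # planted-domain minimum is enforced at generation time (generate_trio)
  }
  set.seed(substream_seed(config$seed, 3 + seed_offset))
  g <- genomes[[strain]]
  calls <- list(); pile <- list(); doms <- list()
  for (i in seq_len(nrow(truth$centromeres))) {
    cr <- truth$centromeres[i, ]
    chrom <- cr$chromosome
    shift <- if (strain %in% truth$phylogeny$ingroup)
      anc_to_strain(truth, strain, chrom, cr$start) - cr$start else 0L
    s <- cr$start + shift; e <- cr$end + shift
    seqr <- substr(g[[chrom]], s, e)
    pos <- cpg_positions(seqr) + s - 1
    if (!length(pos)) next
    hd <- truth$hypo_domains[truth$hypo_domains$chromosome == chrom, , drop = FALSE]
    state <- rep("methylated", length(pos))
    if (nrow(hd)) {
      hs <- hd$start + shift; he <- hd$end + shift
      for (d in seq_len(nrow(hd)))
        state[pos >= hs[d] & pos <= he[d]] <- "unmethylated"
      doms[[length(doms) + 1]] <- data.frame(chromosome = chrom, start = hs,
                                             end = he)
    }
    calls[[length(calls) + 1]] <- data.frame(chromosome = chrom, pos = pos,
                                             state = state)
    cov <- rpois(length(pos), config$meth_coverage_mean)
    cov[cov == 0] <- 1L  # zero-truncated
    p_meth <- ifelse(state == "methylated", 1 - config$meth_error_rate,
                     config$meth_error_rate)
    meth <- rbinom(length(pos), cov, p_meth)
    pile[[length(pile) + 1]] <- data.frame(chromosome = chrom, pos = pos,
                                           meth_count = meth, total_count = cov)
  }
  list(calls = do.call(rbind, calls), pileup = do.call(rbind, pile),
       domains = if (length(doms)) do.call(rbind, doms) else NULL)
}

#' Simulate TSS tables and per-strain replicate count tables
#'
#' Counts are negative-binomial around a per-pair base mean (log-normal
#' scatter around `tss_base_mean`); insertion-linked TSSs have the carrier
#' strain's mean multiplied by `exp(tss_effect)`. Also emits a CpG
#' methylation call track covering the 500-bp upstream windows: CpGs inside
#' planted (GC/CpG-rich) insertions are unmethylated, background CpGs
#' methylated.
#'
#' @param genomes,truth From [generate_trio()].
#' @param config The matching [trio_config()].
#' @param seed_offset Extra stream offset.
#' @return List: `tss` (per-strain rows: strain, pair_id, chromosome, pos,
#'   strand, linked, carrier, has_insertion), `counts` (matrix TSS pairs x 4:
#'   strainA_1, strainA_2, strainB_1, strainB_2), `calls` (methylation call
#'   track for upstream windows).
#' @export
generate_tss_counts <- function(genomes, truth, config, seed_offset = 0) {
  if (is.null(truth$tss)) stop("truth carries no TSS table")
  set.seed(substream_seed(config$seed, 4 + seed_offset))
  tb <- truth$tss
  strains <- truth$phylogeny$ingroup
  rows <- list(); calls <- list()
  for (st in strains) {
    pos <- vapply(seq_len(nrow(tb)), function(i)
      as.numeric(anc_to_strain(truth, st, tb$chromosome[i], tb$anc_pos[i])),
      numeric(1))
    has_ins <- tb$linked & !is.na(tb$carrier) & tb$carrier == st
    rows[[st]] <- data.frame(strain = st, pair_id = tb$pair_id,
                             chromosome = tb$chromosome, pos = pos,
                             strand = tb$strand, linked = tb$linked,
                             carrier = tb$carrier, has_insertion = has_ins,
                             tag_count = pmax(1L, rpois(nrow(tb), 20)))
    # methylation of upstream windows
    for (i in seq_len(nrow(tb))) {
      g <- genomes[[st]][[tb$chromosome[i]]]
      w <- upstream_window(pos[i], tb$strand[i], 500, nchar(g))
      if (is.null(w)) next
      wseq <- substr(g, w[1], w[2])
      cp <- cpg_positions(wseq)
      if (!length(cp)) next
      cp <- cp + w[1] - 1
      state <- rep("methylated", length(cp))
      if (has_ins[i]) {
        ev <- truth$svs
        ev <- ev[ev$tss_linked & !is.na(ev$tss_id) &
                   ev$tss_id == tb$pair_id[i] & ev$carrier == st, , drop = FALSE]
        if (nrow(ev))
          state[cp >= ev$carrier_start[1] & cp <= ev$carrier_end[1]] <- "unmethylated"
      }
      calls[[length(calls) + 1]] <- data.frame(strain = st,
                                               chromosome = tb$chromosome[i],
                                               pos = cp, state = state)
    }
  }
  base <- exp(rnorm(nrow(tb), log(config$tss_base_mean), 0.4))
  size <- 1 / config$tss_dispersion
  mk <- function(st) {
    mu <- base * ifelse(tb$linked & !is.na(tb$carrier) & tb$carrier == st,
                        exp(tb$effect), 1)
    cbind(rnbinom(nrow(tb), mu = mu, size = size),
          rnbinom(nrow(tb), mu = mu, size = size))
  }
  counts <- cbind(mk(strains[1]), mk(strains[2]))
  colnames(counts) <- c(paste0(strains[1], c("_1", "_2")),
                        paste0(strains[2], c("_1", "_2")))
  rownames(counts) <- paste0("pair", tb$pair_id)
  list(tss = do.call(rbind, rows), counts = counts,
       calls = do.call(rbind, calls))
}

# 500-bp (or w-bp) upstream window of a TSS: 5' of the TSS on its strand.
# Returns c(start, end) in forward coordinates, or NULL if entirely off-end.
upstream_window <- function(pos, strand, w, chrom_len) {
  if (is.na(pos)) return(NULL)
  if (strand == "+") {
    s <- pos - w; e <- pos - 1
  } else {
    s <- pos + 1; e <- pos + w
  }
  if (e < 1 || s > chrom_len) return(NULL)
  c(max(1, s), min(chrom_len, e))
}
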