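# Synthetic trio-genome generator.
#
# Emulates the statistical structure assumed by the downstream analyses: a
# three-strain phylogeny (one outgroup splitting before the two ingroup
# strains), per-chromosome centromeric tandem arrays whose monomers diverge
# at class-specific rates (non-acrocentric faster than acrocentric), rare
# monomer-block exchanges between acrocentric arrays, planted mid-sized
# insertions/deletions on the ingroup branches only, hypermethylated
# centromeres with planted hypomethylated domains of distinct k-mer
# composition, exponential Hi-C contact decay around a contig's true
# position, and TSS count tables with insertion-linked up-regulation.
# Every planted feature is recorded in a ground-truth object so each
# downstream stage can be scored for parameter recovery.

#' Build a validated synthetic-trio configuration
#'
#' Defaults are desk-scale: 6 chromosomes of 1 Mbp with 20-60 kbp centromeric
#' arrays of a 171-bp monomer. Branch lengths follow the split-time ratio of
#' the emulated system (outgroup split at 25, ingroup split at 18 time units):
#' each ingroup branch has weight 1, the internal branch (25-18)/18 and the
#' outgroup branch 25/18. `background_divergence` is the per-ingroup-branch
#' substitution rate outside centromeres (default 0.0123, i.e. ~2.46%
#' pairwise between the two ingroup strains); centromeric arrays substitute
#' at `div_rate_acro` / `div_rate_nonacro` per ingroup branch instead.
#'
#' @param seed Master seed; all module streams derive from it.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param monomer_length Ancestral satellite monomer length (bp).
#' @param array_length_range Min/max centromeric array length (bp).
#' @param acro_fraction Fraction of chromosomes made acrocentric.
#' @param div_rate_acro,div_rate_nonacro Monomer substitutions/site on each
#'   ingroup branch for the two positional classes.
#' @param exchange_rate Expected inter-acrocentric monomer-block swaps per
#'   ingroup genome.
#' @param n_insertions,n_deletions,n_inversions Planted event counts per
#'   ingroup strain.
#' @param sv_size_range Event size range (bp); sizes are drawn log-uniformly.
#' @param hic_decay Exponential contact-decay constant (1/bp).
#' @param hic_trans_distance Effective distance assigned to inter-chromosomal
#'   contacts (bp); controls the trans-contact fraction.
#' @param hic_depth Expected total contacts per contig.
#' @param n_contigs Number of contigs the first ingroup assembly is split into.
#' @param meth_hypo_domains_per_centromere Planted hypomethylated domains per
#'   array.
#' @param meth_domain_length Length of each planted domain (bp).
#' @param min_domain_cpgs Minimum CpGs a planted domain must contain.
#' @param hypo_domain_gc GC content of the re-drawn hypomethylated-domain
#'   sequence (domains acquire a distinct, GC-rich k-mer composition).
#' @param array_heterogeneity Fraction of the class divergence rate that
#'   appears as copy-to-copy noise within an array (concerted evolution
#'   keeps copies nearly homogeneous while the consensus drifts).
#' @param monomer_lineages Monomer sub-lineages (variant blocks) per array;
#'   each becomes one cluster downstream.
#' @param monomer_pair_divergence Monomer divergence between the two members
#'   of a duplicated chromosome pair (chromosomes are paired (1,2), (3,4),
#'   ..., emulating anciently duplicated chromosome pairs with conserved
#'   centromere positions; the duplication long predates the strain split,
#'   so this exceeds the per-branch class rates).
#' @param monomer_lineage_divergence Divergence between sub-lineages of one
#'   chromosome's array.
#' @param monomer_family_divergence Divergence of each pair's monomer from
#'   the shared base monomer (separation between unrelated pairs).
#' @param meth_coverage_mean Mean of the zero-truncated Poisson bisulfite
#'   coverage model.
#' @param meth_error_rate Per-read bisulfite error rate.
#' @param tss_count Number of insertion-linked TSS pairs.
#' @param tss_effect Log fold-change applied to the carrier strain's mean at
#'   insertion-linked TSSs.
#' @param tss_base_mean,tss_dispersion Negative-binomial count model.
#' @param background_divergence Non-centromeric substitutions/site per ingroup
#'   branch.
#' @param centromere_free_chromosomes Number of chromosomes left without an
#'   array (mirrors an unsequenced centromere).
#' @return A validated list of class `trio_config`.
#' @export
trio_config <- function(seed = 1L,
                        n_chromosomes = 6L,
                        chrom_length = 1e6,
                        monomer_length = 171L,
                        array_length_range = c(20000, 60000),
                        acro_fraction = 0.5,
                        div_rate_acro = 0.05,
                        div_rate_nonacro = 0.10,
                        exchange_rate = 1,
                        n_insertions = 20L,
                        n_deletions = 20L,
                        n_inversions = 0L,
                        sv_size_range = c(1000, 50000),
                        hic_decay = 2e-5,
                        hic_trans_distance = 3e5,
                        hic_depth = 2000,
                        n_contigs = 120L,
                        meth_hypo_domains_per_centromere = 2L,
                        meth_domain_length = 3000,
                        min_domain_cpgs = 40L,
                        hypo_domain_gc = 0.66,
                        array_heterogeneity = 0.2,
                        monomer_lineages = 4L,
                        monomer_pair_divergence = 0.08,
                        monomer_lineage_divergence = 0.02,
                        monomer_family_divergence = 0.2,
                        meth_coverage_mean = 5,
                        meth_error_rate = 0.05,
                        tss_count = 50L,
                        tss_effect = 2,
                        tss_base_mean = 100,
                        tss_dispersion = 0.05,
                        background_divergence = 0.0123,
                        centromere_free_chromosomes = 0L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, monomer_length = as.integer(monomer_length),
              array_length_range = array_length_range, acro_fraction = acro_fraction,
              div_rate_acro = div_rate_acro, div_rate_nonacro = div_rate_nonacro,
              exchange_rate = exchange_rate, n_insertions = as.integer(n_insertions),
              n_deletions = as.integer(n_deletions), n_inversions = as.integer(n_inversions),
              sv_size_range = sv_size_range, hic_decay = hic_decay,
              hic_trans_distance = hic_trans_distance, hic_depth = hic_depth,
              n_contigs = as.integer(n_contigs),
              meth_hypo_domains_per_centromere = as.integer(meth_hypo_domains_per_centromere),
              meth_domain_length = meth_domain_length,
              min_domain_cpgs = as.integer(min_domain_cpgs),
              hypo_domain_gc = hypo_domain_gc,
              array_heterogeneity = array_heterogeneity,
              monomer_lineages = as.integer(monomer_lineages),
              monomer_pair_divergence = monomer_pair_divergence,
              monomer_lineage_divergence = monomer_lineage_divergence,
              monomer_family_divergence = monomer_family_divergence,
              meth_coverage_mean = meth_coverage_mean,
              meth_error_rate = meth_error_rate,
              tss_count = as.integer(tss_count), tss_effect = tss_effect,
              tss_base_mean = tss_base_mean, tss_dispersion = tss_dispersion,
              background_divergence = background_divergence,
              centromere_free_chromosomes = as.integer(centromere_free_chromosomes))
  validate_trio_config(cfg)
  class(cfg) <- "trio_config"
  cfg
}

validate_trio_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid trio_config: field '%s' %s", field, why),
                  call. = FALSE)
  }
  chk(cfg$n_chromosomes >= 1, "n_chromosomes", "must be >= 1")
  chk(cfg$chrom_length > 0, "chrom_length", "must be > 0")
  chk(cfg$monomer_length > 0, "monomer_length", "must be > 0")
  chk(length(cfg$array_length_range) == 2 &&
        all(cfg$array_length_range > 0) &&
        cfg$array_length_range[1] <= cfg$array_length_range[2],
      "array_length_range", "must be an increasing positive pair")
  chk(cfg$array_length_range[2] < cfg$chrom_length, "array_length_range",
      "must fit within chrom_length")
  chk(cfg$acro_fraction >= 0 && cfg$acro_fraction <= 1, "acro_fraction",
      "must be in [0, 1]")
  for (f in c("div_rate_acro", "div_rate_nonacro", "background_divergence"))
    chk(cfg[[f]] >= 0 && cfg[[f]] < 0.75, f, "must be in [0, 0.75)")
  chk(cfg$exchange_rate >= 0, "exchange_rate", "must be >= 0")
  chk(all(cfg$sv_size_range > 0) && cfg$sv_size_range[1] <= cfg$sv_size_range[2],
      "sv_size_range", "must be an increasing positive pair")
  chk(cfg$hic_decay >= 0, "hic_decay", "must be >= 0")
  chk(cfg$hic_depth > 0, "hic_depth", "must be > 0")
  chk(cfg$n_contigs >= cfg$n_chromosomes, "n_contigs",
      "must be >= n_chromosomes")
  chk(cfg$meth_domain_length > 0, "meth_domain_length", "must be > 0")
  chk(cfg$min_domain_cpgs >= 1, "min_domain_cpgs", "must be >= 1")
  chk(cfg$hypo_domain_gc > 0 && cfg$hypo_domain_gc < 1, "hypo_domain_gc",
      "must be in (0, 1)")
  chk(cfg$array_heterogeneity >= 0 && cfg$array_heterogeneity <= 1,
      "array_heterogeneity", "must be in [0, 1]")
  chk(cfg$monomer_lineages >= 1, "monomer_lineages", "must be >= 1")
  for (f in c("monomer_pair_divergence", "monomer_lineage_divergence",
              "monomer_family_divergence"))
    chk(cfg[[f]] >= 0 && cfg[[f]] < 0.75, f, "must be in [0, 0.75)")
  chk(cfg$meth_error_rate >= 0 && cfg$meth_error_rate < 0.5, "meth_error_rate",
      "must be in [0, 0.5)")
  chk(cfg$tss_base_mean > 0, "tss_base_mean", "must be > 0")
  chk(cfg$tss_dispersion > 0, "tss_dispersion", "must be > 0")
  invisible(TRUE)
}

# Branch weights relative to one ingroup branch (split times 25 and 18).
branch_weights <- function() {
  list(outgroup = 25 / 18, internal = (25 - 18) / 18, ingroup = 1)
}

#' Plant centromeric tandem arrays into a genome
#'
#' Each chromosome (optionally minus `centromere_free_chromosomes`) receives
#' one tandem array of a chromosome-specific monomer: the per-chromosome
#' monomer is the shared base monomer diverged by 20% (chromosome lineages
#' separate long before the strains do). Acrocentric arrays sit with their
#' midpoint at 5% of the chromosome, non-acrocentric at 50%. Hypomethylated
#' domains are planted inside each array with their sequence re-drawn
#' i.i.d. at `hypo_domain_gc` GC content (a distinct k-mer composition,
#' unique to the chromosome because the draw is random); a planted domain
#' with fewer than `min_domain_cpgs` CpGs is rejected.
#'
#' @param genome Named list of chromosome strings (the ancestor).
#' @param config A [trio_config()].
#' @return List: `genome` (arrays spliced in), `centromeres` (data.frame with
#'   chromosome, start, end, class), `monomers` (per-chromosome array layout),
#'   `hypo_domains` (data.frame of planted domain intervals),
#'   `chrom_monomer` (per-chromosome ancestral monomer sequences).
#' @export
generate_centromere_arrays <- function(genome, config) {
  cfg <- config
  n <- length(genome)
  with_cen <- seq_len(max(0, n - cfg$centromere_free_chromosomes))
  n_acro <- round(length(with_cen) * cfg$acro_fraction)
  base_monomer <- random_dna(cfg$monomer_length)
  # duplicated chromosome pairs (1,2), (3,4), ... share a recent monomer
  # ancestor; with the first half of the chromosomes acrocentric this yields
  # acro-acro, mixed and nonacro-nonacro pairs.
  pair_monomer <- list()
  cen <- list(); mono <- list(); hypo <- list(); chrom_monomer <- list()
  for (ci in with_cen) {
    chrom <- names(genome)[ci]
    L <- nchar(genome[[chrom]])
    class <- if (ci <= n_acro) "acrocentric" else "non-acrocentric"
    alen <- round(runif(1, cfg$array_length_range[1], cfg$array_length_range[2]))
    if (alen > L) stop("centromeric array longer than chromosome ", chrom)
    mid <- if (class == "acrocentric") round(0.05 * L) else round(0.5 * L)
    start <- max(1, mid - alen %/% 2)
    end <- start + alen - 1
    if (end > L) { end <- L; start <- end - alen + 1 }
    pair_id <- (ci + 1) %/% 2
    if (length(pair_monomer) < pair_id || is.null(pair_monomer[[pair_id]]))
      pair_monomer[[pair_id]] <- mutate_sequence(base_monomer,
                                                 cfg$monomer_family_divergence)
    cmono <- mutate_sequence(pair_monomer[[pair_id]],
                             cfg$monomer_pair_divergence)
    lineages <- vapply(seq_len(cfg$monomer_lineages), function(j)
      mutate_sequence(cmono, cfg$monomer_lineage_divergence), "")
    chrom_monomer[[chrom]] <- lineages
    arr <- build_array_from_lineages(lineages, alen, cfg$monomer_length)
    # plant hypomethylated domains with biased composition
    k <- cfg$meth_hypo_domains_per_centromere
    doms <- NULL
    if (k > 0) {
      dl <- cfg$meth_domain_length
      if (k * (dl + 1000) > alen - 2000)
        stop("hypomethylated domains do not fit in the array of ", chrom)
      slot <- (alen - 2000) %/% k
      for (d in seq_len(k)) {
        off <- 1000 + (d - 1) * slot + sample.int(max(1, slot - dl - 500), 1)
        gc <- cfg$hypo_domain_gc
        # domains are satellite too: tandem copies of a domain-specific
        # GC-rich unit (a divergent repeat variant with its own k-mer
        # composition), lightly heterogeneous copy to copy
        dunit <- random_dna(cfg$monomer_length,
                            prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                     (1 - gc) / 2))
        dseq <- substr(paste(rep(dunit, ceiling(dl / cfg$monomer_length)),
                             collapse = ""), 1, dl)
        dseq <- mutate_sequence(dseq, 0.02)
        ncpg <- length(gregexpr("CG", dseq, fixed = TRUE)[[1]])
        if (attr(gregexpr("CG", dseq, fixed = TRUE)[[1]], "match.length")[1] == -1)
          ncpg <- 0
        if (ncpg < cfg$min_domain_cpgs)
          stop(sprintf("planted domain on %s has %d CpGs (< %d required)",
                       chrom, ncpg, cfg$min_domain_cpgs))
        substr(arr, off, off + dl - 1) <- dseq
        doms <- rbind(doms, data.frame(chromosome = chrom,
                                       start = start + off - 1,
                                       end = start + off + dl - 2,
                                       offset = off,
                                       sequence = dseq))
      }
    }
    substr(genome[[chrom]], start, end) <- arr
    cen[[length(cen) + 1]] <- data.frame(chromosome = chrom, start = start,
                                         end = end, class = class)
    mono[[length(mono) + 1]] <- data.frame(chromosome = chrom,
                                           array_start = start,
                                           array_end = end,
                                           monomer_length = cfg$monomer_length,
                                           n_full = alen %/% cfg$monomer_length)
    hypo[[length(hypo) + 1]] <- doms
  }
  list(genome = genome,
       centromeres = do.call(rbind, cen),
       monomers = do.call(rbind, mono),
       hypo_domains = do.call(rbind, hypo),
       chrom_monomer = chrom_monomer)
}

# Tandem array from lineage variants: copies are split into contiguous
# same-size blocks, one per lineage, then truncated to the array length.
build_array_from_lineages <- function(lineages, alen, monomer_length) {
  ncop <- ceiling(alen / monomer_length)
  per <- rep(ncop %/% length(lineages), length(lineages))
  extra <- ncop %% length(lineages)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  arr <- paste(unlist(mapply(function(seq, k) rep(seq, k), lineages, per,
                             SIMPLIFY = FALSE)), collapse = "")
  substr(arr, 1, alen)
}

# Evolve a genome backbone along one branch at the background substitution
# rate. Centromeric arrays are rebuilt at the leaves (concerted evolution:
# the array consensus drifts at the class rate while copies stay nearly
# homogeneous), so whatever this writes inside array intervals is
# overwritten by splice_strain_arrays().
evolve_genome <- function(genome, config, branch) {
  for (chrom in names(genome))
    genome[[chrom]] <- mutate_sequence(genome[[chrom]],
                                       config$background_divergence * branch)
  genome
}

# Rebuild every centromeric array of one leaf genome from the leaf's
# evolved monomer consensus: tandem copies of the consensus, per-site noise
# at array_heterogeneity x class rate x root-to-leaf branch length
# (copy-to-copy heterogeneity left behind by concerted turnover), with the
# leaf's evolved hypomethylated-domain sequences spliced back in.
splice_strain_arrays <- function(genome, cen, consensus, domain_seqs, config,
                                 leaf_branch) {
  for (i in seq_len(nrow(cen$centromeres))) {
    cr <- cen$centromeres[i, ]
    chrom <- cr$chromosome
    alen <- cr$end - cr$start + 1
    rate <- if (cr$class == "acrocentric") config$div_rate_acro else
      config$div_rate_nonacro
    arr <- build_array_from_lineages(consensus[[chrom]], alen,
                                     config$monomer_length)
    arr <- mutate_sequence(arr, config$array_heterogeneity * rate * leaf_branch)
    hd <- cen$hypo_domains
    if (!is.null(hd)) {
      hd <- hd[hd$chromosome == chrom, , drop = FALSE]
      for (d in seq_len(nrow(hd))) {
        dseq <- domain_seqs[[chrom]][d]
        substr(arr, hd$offset[d], hd$offset[d] + nchar(dseq) - 1) <- dseq
      }
    }
    substr(genome[[chrom]], cr$start, cr$end) <- arr
  }
  genome
}

# Mutate every sequence in a named list of character vectors.
mutate_each <- function(seqs, rate) {
  lapply(seqs, function(v) vapply(v, mutate_sequence, "", rate = rate,
                                  USE.NAMES = FALSE))
}

# Apply monomer-block exchanges between acrocentric arrays of one strain.
apply_exchanges <- function(genome, centromeres, config) {
  acro <- centromeres[centromeres$class == "acrocentric", , drop = FALSE]
  n_ex <- if (config$exchange_rate > 0) rpois(1, config$exchange_rate) else 0L
  rec <- NULL
  if (nrow(acro) >= 2 && n_ex > 0) {
    block <- 5 * config$monomer_length
    for (e in seq_len(n_ex)) {
      ij <- sample.int(nrow(acro), 2)
      src <- acro[ij[1], ]; dst <- acro[ij[2], ]
      if (src$end - src$start + 1 <= block || dst$end - dst$start + 1 <= block) next
      so <- sample.int(src$end - src$start + 1 - block, 1)
      do_ <- sample.int(dst$end - dst$start + 1 - block, 1)
      blk <- substr(genome[[src$chromosome]], src$start + so,
                    src$start + so + block - 1)
      substr(genome[[dst$chromosome]], dst$start + do_,
             dst$start + do_ + block - 1) <- blk
      rec <- rbind(rec, data.frame(from = src$chromosome, to = dst$chromosome,
                                   from_start = src$start + so,
                                   to_start = dst$start + do_,
                                   length = block))
    }
  }
  list(genome = genome, exchanges = rec)
}

# Sample non-overlapping event anchor intervals on one chromosome, avoiding
# the centromeric array and the chromosome ends. `spans` are the bp widths
# each event needs on the ancestral coordinate system.
sample_event_positions <- function(L, cen_row, spans, margin = 6000,
                                   edge = 10000, max_tries = 300) {
  occupied <- matrix(numeric(0), ncol = 2)
  if (!is.null(cen_row) && nrow(cen_row))
    occupied <- rbind(occupied, c(cen_row$start - margin, cen_row$end + margin))
  starts <- integer(length(spans))
  for (i in seq_along(spans)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(L - spans[i] - 2 * edge, 1) + edge
      e <- s + spans[i] - 1
      if (nrow(occupied) == 0 ||
          all(e + margin < occupied[, 1] | s - margin > occupied[, 2])) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place all planted events; genome too crowded")
    occupied <- rbind(occupied, c(s, e))
    starts[i] <- s
  }
  starts
}

# Apply a strain's events (sorted by ancestral position) to a chromosome
# string. Returns the new sequence and the events annotated with carrier
# coordinates (1-based; first inserted base for insertions, first base after
# the gap for deletions).
apply_events <- function(seq, events) {
  if (is.null(events) || nrow(events) == 0)
    return(list(seq = seq, events = events))
  events <- events[order(events$anc_pos), , drop = FALSE]
  out <- character(0); cur <- 1; outlen <- 0
  events$carrier_start <- NA_integer_
  events$carrier_end <- NA_integer_
  for (i in seq_len(nrow(events))) {
    p <- events$anc_pos[i]; s <- events$size[i]
    stopifnot(p >= cur)
    pre <- substr(seq, cur, p - 1)
    out <- c(out, pre); outlen <- outlen + nchar(pre)
    if (events$type[i] == "insertion") {
      out <- c(out, events$seq[i])
      events$carrier_start[i] <- outlen + 1
      events$carrier_end[i] <- outlen + s
      outlen <- outlen + s
      cur <- p
    } else if (events$type[i] == "deletion") {
      events$carrier_start[i] <- outlen + 1  # first base after the gap
      events$carrier_end[i] <- outlen + 1
      cur <- p + s
    } else if (events$type[i] == "inversion") {
      seg <- revcomp(substr(seq, p, p + s - 1))
      out <- c(out, seg)
      events$carrier_start[i] <- outlen + 1
      events$carrier_end[i] <- outlen + s
      outlen <- outlen + s
      cur <- p + s
    } else stop("unknown event type ", events$type[i])
  }
  out <- c(out, substr(seq, cur, nchar(seq)))
  list(seq = paste(out, collapse = ""), events = events)
}

#' Map ancestral coordinates to a strain's coordinates
#'
#' Uses the planted-event record to shift positions by the insertions and
#' deletions that the strain carries upstream of them. Positions falling
#' inside a segment the strain deleted map to `NA`.
#'
#' @param truth A `trio_truth` object.
#' @param strain Strain name.
#' @param chromosome Chromosome name.
#' @param pos Vector of ancestral (ingroup-ancestor) positions.
#' @return Integer vector of strain positions (NA where deleted).
#' @export
anc_to_strain <- function(truth, strain, chromosome, pos) {
  ev <- truth$svs
  ev <- ev[!is.na(ev$carrier) & ev$carrier == strain &
             ev$chromosome == chromosome & ev$type != "inversion", , drop = FALSE]
  out <- as.numeric(pos)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      p <- ev$anc_pos[i]; s <- ev$size[i]
      if (ev$type[i] == "insertion") {
        out <- out + ifelse(pos >= p, s, 0)
      } else {
        out[pos >= p & pos <= p + s - 1] <- NA
        out <- out - ifelse(pos >= p + s, s, 0)
      }
    }
  }
  as.integer(out)
}

#' Generate a synthetic trio of genomes with full ground truth
#'
#' The ancestor acquires centromeric arrays, evolves to the outgroup on one
#' branch and to the two ingroup strains after a later split; substitutions
#' are i.i.d. per site at branch-scaled rates; planted SVs (mid-sized
#' insertions, deletions, optional inversions, plus GC/CpG-rich insertions
#' upstream of insertion-linked TSSs) occur only on the ingroup branches.
#'
#' @param config A [trio_config()].
#' @return List with `genomes` (named lists of chromosome strings for
#'   `strainA`, `strainB`, `outgroup`) and `truth` (class `trio_truth`):
#'   centromeres, planted monomer layout, hypomethylated domains, SV events
#'   with true polarity, exchange events, contig map, TSS table and the
#'   configuration.
#' @export
generate_trio <- function(config) {
  validate_trio_config(config)
  cfg <- config
  set.seed(substream_seed(cfg$seed, 1))
  bw <- branch_weights()
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  anc <- setNames(lapply(chroms, function(x) random_dna(cfg$chrom_length)), chroms)
  cen <- generate_centromere_arrays(anc, cfg)
  anc <- cen$genome

  # per-chromosome evolved monomer consensus and domain sequences
  class_rate <- setNames(
    ifelse(cen$centromeres$class == "acrocentric", cfg$div_rate_acro,
           cfg$div_rate_nonacro),
    cen$centromeres$chromosome)
  evolve_consensus <- function(cons, branch) {
    out <- cons
    for (chrom in names(cons))
      out[[chrom]] <- vapply(cons[[chrom]], mutate_sequence, "",
                             rate = class_rate[[chrom]] * branch,
                             USE.NAMES = FALSE)
    out
  }
  dom_anc <- if (!is.null(cen$hypo_domains))
    lapply(split(cen$hypo_domains, cen$hypo_domains$chromosome),
           function(x) x$sequence) else list()
  m_out <- evolve_consensus(cen$chrom_monomer, bw$outgroup)
  m_int <- evolve_consensus(cen$chrom_monomer, bw$internal)
  d_out <- mutate_each(dom_anc, cfg$background_divergence * bw$outgroup)
  d_int <- mutate_each(dom_anc, cfg$background_divergence * bw$internal)
  leaf_branch <- bw$internal + bw$ingroup

  outg <- evolve_genome(anc, cfg, bw$outgroup)
  outg <- splice_strain_arrays(outg, cen, m_out, d_out, cfg, leaf_branch)
  ing_anc <- evolve_genome(anc, cfg, bw$internal)

  strains <- c("strainA", "strainB")
  genomes <- list(outgroup = outg)
  ex_list <- list()
  n_tss <- cfg$tss_count

  for (si in seq_along(strains)) {
    st <- strains[si]
    g <- evolve_genome(ing_anc, cfg, bw$ingroup)
    m_st <- evolve_consensus(m_int, bw$ingroup)
    d_st <- mutate_each(d_int, cfg$background_divergence * bw$ingroup)
    g <- splice_strain_arrays(g, cen, m_st, d_st, cfg, leaf_branch)
    ex <- apply_exchanges(g, cen$centromeres, cfg)
    g <- ex$genome
    if (!is.null(ex$exchanges)) {
      ex$exchanges$strain <- st
      ex_list[[st]] <- ex$exchanges
    }
    genomes[[st]] <- g
  }

  # --- plan SV events per strain, then TSS-linked insertions ---
  sizes_draw <- function(n) {
    if (n == 0) return(numeric(0))
    r <- cfg$sv_size_range
    round(exp(runif(n, log(r[1]), log(r[2]))))
  }
  # Global planning: assign each event a chromosome uniformly, then place.
  plan_strain_events <- function(st) {
    ev <- data.frame(type = c(rep("insertion", cfg$n_insertions),
                              rep("deletion", cfg$n_deletions),
                              rep("inversion", cfg$n_inversions)),
                     stringsAsFactors = FALSE)
    if (nrow(ev) == 0) return(NULL)
    ev$carrier <- st
    ev$size <- sizes_draw(nrow(ev))
    ev$chromosome <- sample(chroms, nrow(ev), replace = TRUE)
    ev$tss_linked <- FALSE
    ev$tss_id <- NA_integer_
    ev$seq <- NA_character_
    ev$anc_pos <- NA_real_
    ins <- ev$type == "insertion"
    gc_prob <- c(0.25, 0.25, 0.25, 0.25)
    ev$seq[ins] <- vapply(ev$size[ins], function(s) random_dna(s, gc_prob), "")
    ev
  }
  events_by_strain <- setNames(lapply(strains, plan_strain_events), strains)

  # TSS-linked insertions: GC/CpG-rich sequence within 100 bp upstream.
  tss_tbl <- NULL
  if (n_tss > 0) {
    gcp <- c(0.17, 0.33, 0.33, 0.17)
    lk <- data.frame(pair_id = seq_len(n_tss),
                     chromosome = sample(chroms, n_tss, replace = TRUE),
                     strand = sample(c("+", "-"), n_tss, replace = TRUE),
                     carrier = sample(strains, n_tss, replace = TRUE),
                     linked = TRUE)
    bg <- data.frame(pair_id = n_tss + seq_len(n_tss),
                     chromosome = sample(chroms, n_tss, replace = TRUE),
                     strand = sample(c("+", "-"), n_tss, replace = TRUE),
                     carrier = NA_character_,
                     linked = FALSE)
    tss_tbl <- rbind(lk, bg)
    tss_tbl$insertion_size <- NA_real_
    tss_tbl$insertion_distance <- NA_real_
    tss_tbl$effect <- ifelse(tss_tbl$linked, cfg$tss_effect, 0)
    lk_idx <- which(tss_tbl$linked)
    tss_tbl$insertion_size[lk_idx] <- round(runif(n_tss, 1000, 10000))
    tss_tbl$insertion_distance[lk_idx] <- sample(10:100, n_tss, replace = TRUE)
    tss_tbl$anc_pos <- NA_real_
    for (i in lk_idx) {
      st <- tss_tbl$carrier[i]
      ins <- data.frame(type = "insertion", carrier = st,
                        size = tss_tbl$insertion_size[i],
                        chromosome = tss_tbl$chromosome[i],
                        tss_linked = TRUE, tss_id = tss_tbl$pair_id[i],
                        seq = random_dna(tss_tbl$insertion_size[i], gcp),
                        anc_pos = NA_real_)
      events_by_strain[[st]] <- rbind(events_by_strain[[st]], ins)
    }
  }

  # Place all anchors per chromosome jointly (across strains and TSSs) so
  # nothing overlaps on the ancestral coordinate system.
  for (chrom in chroms) {
    cen_row <- cen$centromeres[cen$centromeres$chromosome == chrom, , drop = FALSE]
    items <- list()
    for (st in strains) {
      ev <- events_by_strain[[st]]
      if (is.null(ev)) next
      idx <- which(ev$chromosome == chrom & !ev$tss_linked)
      for (j in idx) {
        span <- if (ev$type[j] == "insertion") 1 else ev$size[j]
        items[[length(items) + 1]] <- list(kind = "sv", strain = st, row = j,
                                           span = span)
      }
    }
    if (!is.null(tss_tbl)) {
      for (i in which(tss_tbl$chromosome == chrom)) {
        # a TSS needs its 600-bp neighborhood clean; linked ones carry the
        # insertion anchor too (span 1 on ancestor coordinates)
        items[[length(items) + 1]] <- list(kind = "tss", tss = i, span = 1300)
      }
    }
    if (!length(items)) next
    spans <- vapply(items, function(x) x$span, numeric(1))
    starts <- sample_event_positions(cfg$chrom_length, cen_row, spans)
    for (ii in seq_along(items)) {
      it <- items[[ii]]
      if (it$kind == "sv") {
        events_by_strain[[it$strain]]$anc_pos[it$row] <- starts[ii]
      } else {
        i <- it$tss
        # place the TSS mid-slot; upstream side must stay inside the slot
        tpos <- starts[ii] + 650
        tss_tbl$anc_pos[i] <- tpos
        if (tss_tbl$linked[i]) {
          d <- tss_tbl$insertion_distance[i]
          st <- tss_tbl$carrier[i]
          ev <- events_by_strain[[st]]
          r <- which(ev$tss_linked & !is.na(ev$tss_id) & ev$tss_id == tss_tbl$pair_id[i])
          events_by_strain[[st]]$anc_pos[r] <-
            if (tss_tbl$strand[i] == "+") tpos - d else tpos + d + 1
        }
      }
    }
  }

  # Apply events strain by strain, chromosome by chromosome.
  sv_rows <- list()
  for (st in strains) {
    ev <- events_by_strain[[st]]
    if (is.null(ev) || nrow(ev) == 0) next
    for (chrom in unique(ev$chromosome)) {
      sub <- ev[ev$chromosome == chrom, , drop = FALSE]
      res <- apply_events(genomes[[st]][[chrom]], sub)
      genomes[[st]][[chrom]] <- res$seq
      sv_rows[[paste(st, chrom)]] <- res$events
    }
  }
  svs <- if (length(sv_rows)) do.call(rbind, sv_rows) else
    data.frame(type = character(), carrier = character(), size = numeric(),
               chromosome = character(), tss_linked = logical(),
               tss_id = integer(), seq = character(), anc_pos = numeric(),
               carrier_start = integer(), carrier_end = integer())
  rownames(svs) <- NULL
  svs$id <- seq_len(nrow(svs))
  svs$seq <- NULL

  # Contig map over strainA (the "assembly" strain).
  per_chr <- max(1L, cfg$n_contigs %/% cfg$n_chromosomes)
  contigs <- do.call(rbind, lapply(chroms, function(chrom) {
    L <- nchar(genomes$strainA[[chrom]])
    bounds <- round(seq(1, L + 1, length.out = per_chr + 1))
    data.frame(contig = paste0(chrom, "_ctg", seq_len(per_chr)),
               chromosome = chrom,
               start = bounds[-length(bounds)],
               end = bounds[-1] - 1)
  }))

  # Genetic markers every ~5 contigs' worth of sequence, 1 cM per 30 kbp.
  markers <- do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
    ct <- contigs[i, ]
    mid <- (ct$start + ct$end) %/% 2
    data.frame(marker = paste0("m_", ct$contig),
               chromosome = ct$chromosome,
               cm = mid / 30000,
               contig = ct$contig,
               offset = mid - ct$start + 1)
  }))

  truth <- list(
    phylogeny = list(outgroup = "outgroup", ingroup = strains),
    centromeres = cen$centromeres,
    monomers = cen$monomers,
    chrom_monomer = cen$chrom_monomer,
    hypo_domains = cen$hypo_domains,
    svs = svs,
    exchanges = if (length(ex_list)) do.call(rbind, ex_list) else NULL,
    contigs = contigs,
    markers = markers,
    tss = tss_tbl,
    config = cfg
  )
  class(truth) <- "trio_truth"
  list(genomes = genomes, truth = truth)
}

#' Extract the planted satellite monomers of one strain
#'
#' Monomer intervals follow the planted array layout; because planted SVs
#' never touch centromeric arrays, the layout maps to each strain by a
#' constant per-array offset.
#'
#' @param genomes `genomes` element from [generate_trio()].
#' @param truth Matching `trio_truth`.
#' @param strain One of `"strainA"`, `"strainB"`, `"outgroup"`.
#' @param max_per_chromosome Optional cap on monomers per chromosome
#'   (uniformly spaced subsample).
#' @return data.frame: id, strain, chromosome, start, end, strand, sequence
#'   (1-based closed strain coordinates).
#' @export
truth_monomers <- function(genomes, truth, strain, max_per_chromosome = Inf) {
  g <- genomes[[strain]]
  out <- list()
  for (i in seq_len(nrow(truth$monomers))) {
    m <- truth$monomers[i, ]
    chrom <- m$chromosome
    shift <- if (strain %in% truth$phylogeny$ingroup) {
      s <- anc_to_strain(truth, strain, chrom, m$array_start)
      s - m$array_start
    } else 0L
    n <- m$n_full
    idx <- seq_len(n)
    # skip monomer slots overwritten by planted hypomethylated domains
    hd <- truth$hypo_domains
    if (!is.null(hd)) {
      hd <- hd[hd$chromosome == chrom, , drop = FALSE]
      if (nrow(hd)) {
        ms <- m$array_start + (idx - 1) * m$monomer_length
        me <- ms + m$monomer_length - 1
        keep <- rep(TRUE, length(idx))
        for (d in seq_len(nrow(hd)))
          keep <- keep & (me < hd$start[d] | ms > hd$end[d])
        idx <- idx[keep]
        n <- length(idx)
      }
    }
    if (is.finite(max_per_chromosome) && n > max_per_chromosome)
      idx <- idx[unique(round(seq(1, n, length.out = max_per_chromosome)))]
    starts <- m$array_start + shift + (idx - 1) * m$monomer_length
    ends <- starts + m$monomer_length - 1
    seqs <- substring(g[[chrom]], starts, ends)
    out[[i]] <- data.frame(id = paste0(strain, "_", chrom, "_m", idx),
                           strain = strain, chromosome = chrom,
                           start = starts, end = ends, strand = "+",
                           sequence = seqs)
  }
  do.call(rbind, out)
}
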