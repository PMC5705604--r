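# Parameter-recovery evaluations: each routine generates synthetic data at
# stated conditions, runs the corresponding analysis stage, and scores the
# result against the planted ground truth.

#' Leave-one-out naive-Bayes anchoring and contact-peak placement
#'
#' Generates Hi-C contact vectors for anchored contigs at the configured
#' decay and depth, classifies each contig with a model trained on all the
#' others, and places orphan contigs by their contact peak.
#'
#' @param seed Master seed.
#' @param n_chromosomes,chrom_length,n_contigs Genome/contig shape.
#' @param n_orphans Orphan contigs placed by contact peak.
#' @param window Placement window (bp).
#' @return List: `loo_accuracy`, `placement_rate` (fraction placed within one
#'   window of the true position), `n_contigs`, `n_orphans`.
#' @export
eval_nb_anchoring <- function(seed = 1, n_chromosomes = 6, chrom_length = 1e6,
                              n_contigs = 504, n_orphans = 100,
                              window = 50000) {
  cfg <- trio_config(seed = seed, n_chromosomes = n_chromosomes,
                     chrom_length = chrom_length, n_contigs = n_contigs,
                     n_insertions = 0, n_deletions = 0, tss_count = 0)
  trio <- generate_trio(cfg)
  hic <- generate_hic_contacts(trio$truth, cfg)
  n <- nrow(hic$contacts)
  correct <- logical(n)
  for (i in seq_len(n)) {
    m <- fit_nb(hic$contacts[-i, , drop = FALSE], hic$truth_chromosome[-i])
    correct[i] <- classify_orphan(m, hic$contacts[i, ])$chromosome ==
      hic$truth_chromosome[i]
  }
  ids <- trio$truth$contigs$contig
  placed <- logical(n_orphans)
  for (j in seq_len(n_orphans)) {
    ct <- ids[(j - 1) %% length(ids) + 1]
    tr <- generate_hic_track(trio$truth, cfg, ct, seed_offset = j)
    loc <- locate_orphan(tr$counts, tr$bin_centers, window = window)
    placed[j] <- abs(loc$position - tr$true_position) <= window
  }
  list(loo_accuracy = mean(correct), placement_rate = mean(placed),
       n_contigs = n, n_orphans = n_orphans)
}

#' Recovery and polarization of planted structural variants
#'
#' Generates a trio with planted mid-sized insertions and deletions, calls
#' and polarizes events between the two ingroup strains (satellite arrays
#' masked), matches calls to the planted truth, and repeats with the two
#' ingroup genomes swapped.
#'
#' @param seed Master seed.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_insertions,n_deletions Planted events per ingroup strain.
#' @param sv_size_range Planted size band (bp).
#' @return List: `n_planted`, `recovery_rate`, `polarity_accuracy` (among
#'   recovered events), `swap_consistent` (recovered polarity multiset
#'   unchanged under operand swap), `distances` (outgroup flank distances of
#'   classified events).
#' @export
eval_sv_polarization <- function(seed = 1, n_chromosomes = 6,
                                 chrom_length = 2e6, n_insertions = 50,
                                 n_deletions = 50,
                                 sv_size_range = c(1000, 50000)) {
  cfg <- trio_config(seed = seed, n_chromosomes = n_chromosomes,
                     chrom_length = chrom_length,
                     n_insertions = n_insertions, n_deletions = n_deletions,
                     sv_size_range = sv_size_range, tss_count = 0,
                     n_contigs = n_chromosomes)
  trio <- generate_trio(cfg)
  idx <- seed_index(trio$genomes$outgroup)
  strain_mask <- function(st) {
    m <- trio$truth$centromeres
    for (i in seq_len(nrow(m))) {
      m$start[i] <- anc_to_strain(trio$truth, st, m$chromosome[i], m$start[i])
      m$end[i] <- anc_to_strain(trio$truth, st, m$chromosome[i], m$end[i])
    }
    m
  }
  ab <- polarize_genome_events(trio$genomes$strainA, trio$genomes$strainB,
                               idx, "strainA", "strainB",
                               mask = strain_mask("strainA"))
  ba <- polarize_genome_events(trio$genomes$strainB, trio$genomes$strainA,
                               idx, "strainB", "strainA",
                               mask = strain_mask("strainB"))
  truth <- trio$truth$svs
  truth <- truth[truth$type %in% c("insertion", "deletion"), , drop = FALSE]
  match_one <- function(tr_row, ev) {
    cand <- ev[ev$chromosome == tr_row$chromosome &
                 abs(ev$size - tr_row$size) <= pmax(50, 0.05 * tr_row$size), ,
               drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand[which.min(abs(cand$size - tr_row$size)), , drop = FALSE]
  }
  recovered <- 0; correct <- 0
  for (i in seq_len(nrow(truth))) {
    m <- match_one(truth[i, ], ab)
    if (is.null(m)) next
    recovered <- recovered + 1
    if (!is.na(m$strain) && m$type == truth$type[i] &&
        m$strain == truth$carrier[i]) correct <- correct + 1
  }
  key <- function(e) {
    e <- e[e$type %in% c("insertion", "deletion") & !is.na(e$strain), ]
    sort(paste(e$type, e$strain, e$size))
  }
  list(n_planted = nrow(truth),
       recovery_rate = recovered / nrow(truth),
       polarity_accuracy = if (recovered > 0) correct / recovered else NA_real_,
       swap_consistent = identical(key(ab), key(ba)),
       distances = ab$distance[!is.na(ab$distance)])
}

#' Direction of the acro vs non-acro evolution-rate comparison over seeds
#'
#' For each seed, builds a trio whose non-acrocentric arrays diverge at
#' twice the acrocentric rate (the generator default), clusters a monomer
#' subsample per chromosome, forms best-match associations, and tests
#' whether non-acro/non-acro best-match similarities are lower.
#'
#' @param seed Master seed (per-seed streams derive from it).
#' @param n_seeds Monte-Carlo replicates.
#' @param n_chromosomes,chrom_length,array_length_range Desk-scale shape of
#'   each replicate.
#' @param monomers_per_chromosome Monomer subsample per chromosome.
#' @param alpha Significance threshold.
#' @return List: `fraction_significant` (p < alpha for the NonAcroNonAcro
#'   vs AcroAcro comparison), `median_p`, `n_seeds`.
#' @export
eval_rate_direction <- function(seed = 1, n_seeds = 100, n_chromosomes = 10,
                                chrom_length = 1.5e5,
                                array_length_range = c(18000, 26000),
                                monomers_per_chromosome = 24, alpha = 0.01) {
  ps <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- trio_config(seed = substream_seed(seed, 1000 + s),
                       n_chromosomes = n_chromosomes,
                       chrom_length = chrom_length,
                       array_length_range = array_length_range,
                       n_insertions = 0, n_deletions = 0, tss_count = 0,
                       n_contigs = n_chromosomes)
    trio <- generate_trio(cfg)
    mono <- truth_monomers(trio$genomes, trio$truth, "strainA",
                           max_per_chromosome = monomers_per_chromosome)
    sets <- lapply(split(mono, mono$chromosome), cluster_monomers,
                   threshold = 0.9, min_members_for_representative = 3L)
    classes <- setNames(trio$truth$centromeres$class,
                        trio$truth$centromeres$chromosome)
    rec <- best_match_associations(sets, classes)
    p <- try(compare_similarity_groups(rec)$p_values["vs_AcroAcro"],
             silent = TRUE)
    ps[s] <- if (inherits(p, "try-error") || is.na(p)) 1 else p
  }
  list(fraction_significant = mean(ps < alpha), median_p = median(ps),
       n_seeds = n_seeds)
}

# Shared helper: segment one strain's centromeric methylation track into
# regions carrying sequence, strain and positional class.
segment_strain_regions <- function(genomes, truth, cfg, strain) {
  meth <- generate_methylation(genomes, truth, cfg, strain = strain)
  out <- list()
  for (chrom in unique(meth$calls$chromosome)) {
    segs <- segment_regions(meth$calls[meth$calls$chromosome == chrom, ],
                            min_cpgs = cfg$min_domain_cpgs)
    if (!nrow(segs)) next
    segs$strain <- strain
    segs$sequence <- substring(genomes[[strain]][[chrom]], segs$start,
                               segs$end)
    cls <- truth$centromeres$class[truth$centromeres$chromosome == chrom]
    segs$acro <- cls == "acrocentric"
    out[[chrom]] <- segs
  }
  do.call(rbind, out)
}

#' Recovery of planted hypomethylated domains from noiseless tracks
#'
#' Segments the region-level CpG state track of one strain and checks that
#' every planted domain is recovered as one hypo region whose boundaries lie
#' inside the domain and whose CpG count equals the domain's CpG count.
#'
#' @param seed Master seed.
#' @param n_chromosomes,chrom_length,array_length_range Trio shape.
#' @return List: `n_planted`, `n_recovered_exactly`, `recovery_rate`.
#' @export
eval_domain_recovery <- function(seed = 1, n_chromosomes = 6,
                                 chrom_length = 2.5e5,
                                 array_length_range = c(15000, 25000)) {
  cfg <- trio_config(seed = seed, n_chromosomes = n_chromosomes,
                     chrom_length = chrom_length,
                     array_length_range = array_length_range,
                     n_insertions = 0, n_deletions = 0, tss_count = 0,
                     n_contigs = n_chromosomes)
  trio <- generate_trio(cfg)
  me <- generate_methylation(trio$genomes, trio$truth, cfg, "strainA")
  ok <- 0; total <- 0
  for (chrom in unique(me$calls$chromosome)) {
    calls <- me$calls[me$calls$chromosome == chrom, ]
    segs <- segment_regions(calls, min_cpgs = cfg$min_domain_cpgs)
    segs <- segs[segs$status == "hypo", , drop = FALSE]
    doms <- me$domains[me$domains$chromosome == chrom, , drop = FALSE]
    for (d in seq_len(nrow(doms))) {
      total <- total + 1
      n_dom_cpg <- sum(calls$pos >= doms$start[d] & calls$pos <= doms$end[d] &
                         calls$state == "unmethylated")
      hit <- segs[segs$start >= doms$start[d] & segs$end <= doms$end[d] &
                    segs$n_cpgs == n_dom_cpg, , drop = FALSE]
      if (nrow(hit) == 1) ok <- ok + 1
    }
  }
  list(n_planted = total, n_recovered_exactly = ok,
       recovery_rate = if (total) ok / total else NA_real_)
}

#' Chromosome-first recovery of the methylation-domain phylogeny over seeds
#'
#' For each seed, segments both ingroup strains' methylation tracks,
#' combines each strain's regions per (chromosome, status) into one
#' composite region, builds the spectrum-kernel UPGMA tree over the
#' composites, and checks that every leaf's nearest neighbor (by cophenetic
#' distance) is its cross-strain counterpart — i.e. chromosome segregation
#' and domain differentiation precede strain divergence, the planted
#' history.
#'
#' @param seed Master seed.
#' @param n_seeds Monte-Carlo replicates.
#' @param n_chromosomes,chrom_length,array_length_range Trio shape.
#' @param k Spectrum word length.
#' @return List: `fraction_recovered` (seeds where all leaves pass),
#'   `leaf_rate` (overall fraction of leaves passing), `n_seeds`.
#' @export
eval_phylogeny_recovery <- function(seed = 1, n_seeds = 20, n_chromosomes = 6,
                                    chrom_length = 2.5e5,
                                    array_length_range = c(15000, 25000),
                                    k = 8) {
  pass <- logical(n_seeds); leaf_ok <- 0; leaf_n <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- trio_config(seed = substream_seed(seed, 2000 + s),
                       n_chromosomes = n_chromosomes,
                       chrom_length = chrom_length,
                       array_length_range = array_length_range,
                       n_insertions = 0, n_deletions = 0, tss_count = 0,
                       n_contigs = n_chromosomes)
    trio <- generate_trio(cfg)
    regions <- rbind(
      segment_strain_regions(trio$genomes, trio$truth, cfg, "strainA"),
      segment_strain_regions(trio$genomes, trio$truth, cfg, "strainB"))
    grp <- paste(regions$strain, regions$chromosome, regions$status)
    comp <- do.call(rbind, lapply(split(regions, grp), function(x)
      data.frame(strain = x$strain[1], chromosome = x$chromosome[1],
                 status = x$status[1], acro = x$acro[1],
                 sequence = paste(x$sequence, collapse = ""))))
    ph <- methylation_phylogeny(comp, k = k)
    cop <- as.matrix(cophenetic(ph$tree))
    diag(cop) <- Inf
    nn <- apply(cop, 1, which.min)
    same <- comp$chromosome[nn] == comp$chromosome &
      comp$status[nn] == comp$status
    pass[s] <- all(same)
    leaf_ok <- leaf_ok + sum(same); leaf_n <- leaf_n + length(same)
  }
  list(fraction_recovered = mean(pass), leaf_rate = leaf_ok / leaf_n,
       n_seeds = n_seeds)
}

#' Spectrum-kernel SVM separation of planted domain classes
#'
#' Builds one trio, windows its hypo and hyper region sequences, and runs
#' the five-fold CV spectrum SVM; a null run splits the hyper windows into
#' two arbitrary pseudo-classes.
#'
#' @param seed Master seed.
#' @param n_chromosomes,chrom_length,array_length_range Trio shape.
#' @param k Spectrum word length.
#' @return List: `cv_accuracy`, `null_accuracy`, `n_windows`.
#' @export
eval_svm_separation <- function(seed = 1, n_chromosomes = 6,
                                chrom_length = 2.5e5,
                                array_length_range = c(15000, 25000), k = 8) {
  cfg <- trio_config(seed = seed, n_chromosomes = n_chromosomes,
                     chrom_length = chrom_length,
                     array_length_range = array_length_range,
                     n_insertions = 0, n_deletions = 0, tss_count = 0,
                     n_contigs = n_chromosomes)
  trio <- generate_trio(cfg)
  regions <- segment_strain_regions(trio$genomes, trio$truth, cfg, "strainA")
  hypo <- regions$sequence[regions$status == "hypo"]
  hyper <- regions$sequence[regions$status == "hyper"]
  res <- svm_discriminate(hypo, hyper, k = k, mode = "cv5", seed = seed)
  # null: hyper windows randomly split into two pseudo-classes
  wy <- cut_windows(hyper, 200)$windows
  set.seed(substream_seed(seed, 4000))
  half <- sample(length(wy), length(wy) %/% 2)
  res0 <- svm_discriminate(wy[half], wy[-half], k = k, mode = "cv5",
                           seed = seed)
  list(cv_accuracy = res$accuracy, null_accuracy = res0$accuracy,
       n_windows = res$n_windows)
}

#' Power of the TSS regulatory statistics over seeds
#'
#' For each seed, builds a trio with insertion-linked TSSs, computes the
#' upstream GC/CpG/unmethylation window statistics for the carrier TSSs and
#' their matched no-insertion partners, runs the three paired one-sided
#' tests and the expression screen, and scores the planted effects. A null
#' replicate per seed pairs the background (no-insertion) TSSs of the two
#' strains.
#'
#' @param seed Master seed.
#' @param n_seeds Monte-Carlo replicates.
#' @param n_chromosomes,chrom_length Trio shape.
#' @param tss_count Insertion-linked TSS pairs per replicate.
#' @param alpha Significance threshold.
#' @return List: `fraction_all_significant` (seeds where all three paired
#'   tests have p < alpha), `expression_power` (mean fraction of linked TSSs
#'   detected at p < alpha), `null_fraction_significant` (seeds where any
#'   null paired test reaches p < alpha), `n_seeds`.
#' @export
eval_tss_power <- function(seed = 1, n_seeds = 30, n_chromosomes = 6,
                           chrom_length = 4e5, tss_count = 30, alpha = 0.01) {
  all_sig <- logical(n_seeds); null_sig <- logical(n_seeds)
  expr_pow <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- trio_config(seed = substream_seed(seed, 3000 + s),
                       n_chromosomes = n_chromosomes,
                       chrom_length = chrom_length, tss_count = tss_count,
                       n_insertions = 0, n_deletions = 0,
                       n_contigs = n_chromosomes)
    trio <- generate_trio(cfg)
    tssd <- generate_tss_counts(trio$genomes, trio$truth, cfg)
    sv <- trio$truth$svs[trio$truth$svs$type == "insertion", , drop = FALSE]
    ins <- data.frame(strain = sv$carrier, chromosome = sv$chromosome,
                      start = sv$carrier_start, end = sv$carrier_end)
    pairs <- find_insertion_tss_pairs(tssd$tss, ins)
    ws <- function(strain, chrom, pos, strand) {
      calls <- tssd$calls[tssd$calls$strain == strain &
                            tssd$calls$chromosome == chrom, ]
      as.data.frame(window_stats(trio$genomes[[strain]][[chrom]], pos,
                                 strand, calls))
    }
    w <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      ws(pairs$carrier[i], pairs$chromosome[i], pairs$carrier_pos[i],
         pairs$strand[i])))
    wo <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      ws(pairs$partner[i], pairs$chromosome[i], pairs$partner_pos[i],
         pairs$strand[i])))
    tst <- paired_increase_tests(w, wo)
    all_sig[s] <- all(tst$p_values[c("gc", "cpg", "unmethylated")] < alpha,
                      na.rm = FALSE)
    # null: background TSS pairs, strainA vs strainB windows
    bg <- tssd$tss[!tssd$tss$linked, ]
    bgA <- bg[bg$strain == "strainA", ][1:min(20, sum(bg$strain == "strainA")), ]
    bgB <- bg[bg$strain == "strainB", ]
    bgB <- bgB[match(bgA$pair_id, bgB$pair_id), ]
    wn <- do.call(rbind, lapply(seq_len(nrow(bgA)), function(i)
      ws("strainA", bgA$chromosome[i], bgA$pos[i], bgA$strand[i])))
    won <- do.call(rbind, lapply(seq_len(nrow(bgB)), function(i)
      ws("strainB", bgB$chromosome[i], bgB$pos[i], bgB$strand[i])))
    tn <- paired_increase_tests(wn, won)
    null_sig[s] <- any(tn$p_values[c("gc", "cpg")] < alpha, na.rm = TRUE)
    scr <- expression_screen(tssd$counts)
    linked <- which(trio$truth$tss$linked)
    detected <- !is.na(scr$p[linked]) & scr$p[linked] < alpha
    expr_pow[s] <- mean(detected)
  }
  list(fraction_all_significant = mean(all_sig),
       expression_power = mean(expr_pow),
       null_fraction_significant = mean(null_sig),
       n_seeds = n_seeds)
}
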