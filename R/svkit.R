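# Structural-variant calling from chained whole-genome local alignments,
# mechanism classification by breakpoint-flank homology, and outgroup
# polarization of indels.

#' Reciprocally best matching pairs
#'
#' A pair (a, b) is kept iff b is a's best-scoring match and a is b's; exact
#' score ties disqualify the tied side (dropped with a warning).
#'
#' @param scores data.frame with columns `a`, `b`, `score`.
#' @return data.frame of reciprocal pairs (a, b, score).
#' @export
reciprocal_best_pairs <- function(scores) {
  best_of <- function(keys, other, sc) {
    out <- list()
    for (k in unique(keys)) {
      i <- which(keys == k)
      mx <- max(sc[i])
      top <- i[sc[i] == mx]
      if (length(top) > 1) {
        warning("tied best match for '", k, "'; dropped")
        out[[k]] <- NA_character_
      } else out[[k]] <- other[top]
    }
    out
  }
  ba <- best_of(scores$a, scores$b, scores$score)
  bb <- best_of(scores$b, scores$a, scores$score)
  keep <- vapply(names(ba), function(a) {
    b <- ba[[a]]
    !is.na(b) && !is.na(bb[[b]] %||% NA) && identical(bb[[b]], a)
  }, logical(1))
  pairs <- data.frame(a = names(ba)[keep],
                      b = unlist(ba[keep], use.names = FALSE))
  pairs$score <- scores$score[match(paste(pairs$a, pairs$b),
                                    paste(scores$a, scores$b))]
  rownames(pairs) <- NULL
  pairs
}

#' Chain local alignments by dynamic programming
#'
#' Finds the maximum-total-score colinear subset of local alignments between
#' one sequence pair: query starts strictly increasing, target intervals
#' strictly increasing on the same strand (decreasing for "-"), members
#' non-overlapping on both sequences. Adjacent members pay a gap penalty of
#' `gap_rate * (query gap + target gap)`, capped at the median member score.
#' Strands are chained separately; the higher-scoring strand chain is
#' returned as the best, with both per-strand sub-chains attached.
#'
#' Members that overlap a predecessor by at most `max_overlap` bp on either
#' axis are admitted and trimmed along their diagonal, so the emitted chain
#' is strictly non-overlapping on both sequences and gap sizes stay exact.
#'
#' @param alignments data.frame with qstart, qend, tstart, tend, strand,
#'   score.
#' @param gap_rate Gap penalty per bp of gap.
#' @param max_overlap Largest per-axis overlap absorbed by trimming.
#' @return List of class `alignment_chain`: `chain` (members in chain
#'   order), `score`, `strand`, `sub_chains` (list by strand).
#' @export
chain_alignments <- function(alignments, gap_rate = 0.01, max_overlap = 1000) {
  if (is.null(nrow(alignments)) || nrow(alignments) == 0)
    stop("need at least one alignment")
  cap <- median(alignments$score)
  overlap_of <- function(al, j, i, strand) {
    # bp the successor i must be trimmed by to clear predecessor j
    oq <- al$qend[j] - al$qstart[i] + 1
    ot <- if (strand == "+") al$tend[j] - al$tstart[i] + 1
    else al$tend[i] - al$tstart[j] + 1
    max(0, oq, ot)
  }
  chain_strand <- function(al, strand) {
    al <- al[al$strand == strand, , drop = FALSE]
    if (!nrow(al)) return(NULL)
    al <- al[order(al$qstart, al$tstart), , drop = FALSE]
    n <- nrow(al)
    dp <- al$score
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1)) {
        d <- overlap_of(al, j, i, strand)
        if (d > max_overlap) next
        if (al$qstart[i] + d > al$qend[i]) next  # trim would consume member
        if (al$qend[j] >= al$qend[i]) next
        if (strand == "+") {
          if (al$tend[j] >= al$tend[i]) next
          gt <- al$tstart[i] + d - al$tend[j] - 1
        } else {
          if (al$tstart[j] <= al$tstart[i]) next
          gt <- al$tstart[j] - (al$tend[i] - d) - 1
        }
        gq <- al$qstart[i] + d - al$qend[j] - 1
        pen <- min(gap_rate * (gq + gt), cap) + d
        cand <- dp[j] + al$score[i] - pen
        if (cand > dp[i]) { dp[i] <- cand; prev[i] <- j }
      }
    }
    end <- which.max(dp)
    path <- integer(0); i <- end
    while (i != 0) { path <- c(i, path); i <- prev[i] }
    ch <- al[path, , drop = FALSE]
    # trim members along their diagonals so the chain is non-overlapping
    if (nrow(ch) >= 2) for (i in 2:nrow(ch)) {
      d <- overlap_of(ch, i - 1, i, strand)
      if (d > 0) {
        ch$qstart[i] <- ch$qstart[i] + d
        if (strand == "+") ch$tstart[i] <- ch$tstart[i] + d
        else ch$tend[i] <- ch$tend[i] - d
        if ("length" %in% names(ch)) ch$length[i] <- ch$length[i] - d
        if ("matches" %in% names(ch))
          ch$matches[i] <- max(0, ch$matches[i] - d)
      }
    }
    list(chain = ch, score = dp[end], strand = strand)
  }
  subs <- Filter(Negate(is.null),
                 list(`+` = chain_strand(alignments, "+"),
                      `-` = chain_strand(alignments, "-")))
  best <- subs[[which.max(vapply(subs, function(x) x$score, numeric(1)))]]
  structure(list(chain = best$chain, score = best$score, strand = best$strand,
                 sub_chains = subs),
            class = "alignment_chain")
}

#' Call structural-variant candidates from chain gaps
#'
#' For each adjacent pair of chain members the query gap g_q and target gap
#' g_t are computed; `|g_q - g_t|` in `[min_size, Inf)` yields an indel
#' candidate carried by the gap-richer genome (size class `mid` up to
#' `max_mid_size`, `large` beyond). A minus-strand sub-chain falling inside
#' both gaps of a plus-strand pair is called an inversion. When sequences
#' are supplied, a query gap whose sequence has a high-identity second copy
#' near the target gap is reclassified as a duplication.
#'
#' @param chain An `alignment_chain` (plus strand primary).
#' @param min_size Minimum `|g_q - g_t|` to call (bp).
#' @param max_mid_size Upper bound of the mid size class (bp).
#' @param query_seq,target_seq Optional sequences for the duplication check.
#' @return data.frame of unpolarized events: gap index, carrier
#'   (`query`/`target`), type (`indel`/`inversion`/`duplication`), size,
#'   size_class, q_gap_start, q_gap_end, t_gap_start, t_gap_end.
#' @export
call_svs <- function(chain, min_size = 1000, max_mid_size = 50000,
                     query_seq = NULL, target_seq = NULL) {
  ch <- chain$chain
  if (nrow(ch) >= 2) {
    bad <- any(ch$qstart[-1] <= ch$qend[-nrow(ch)]) ||
      any(ch$tstart[-1] <= ch$tend[-nrow(ch)])
    if (chain$strand == "+" && bad)
      stop("overlapping chain members: colinearity invariant breached")
  }
  minus <- chain$sub_chains[["-"]]
  out <- list()
  if (nrow(ch) >= 2) for (i in seq_len(nrow(ch) - 1)) {
    gq <- ch$qstart[i + 1] - ch$qend[i] - 1
    gt <- ch$tstart[i + 1] - ch$tend[i] - 1
    diff <- gq - gt
    qgs <- ch$qend[i] + 1; qge <- ch$qstart[i + 1] - 1
    tgs <- ch$tend[i] + 1; tge <- ch$tstart[i + 1] - 1
    type <- NULL
    if (!is.null(minus) && gq >= min_size && gt >= min_size &&
        abs(diff) < min_size) {
      mc <- minus$chain
      inside <- mc$qstart >= qgs & mc$qend <= qge &
        mc$tstart >= tgs & mc$tend <= tge
      if (any(inside)) {
        type <- "inversion"
        out[[length(out) + 1]] <- data.frame(
          gap = i, carrier = NA_character_, type = type, size = gq,
          size_class = if (gq <= max_mid_size) "mid" else "large",
          q_gap_start = qgs, q_gap_end = qge,
          t_gap_start = tgs, t_gap_end = tge)
        next
      }
    }
    if (abs(diff) >= min_size) {
      carrier <- if (diff > 0) "query" else "target"
      size <- abs(diff)
      type <- "indel"
      if (diff > 0 && !is.null(query_seq) && !is.null(target_seq) &&
          size <= max_mid_size && gq <= max_mid_size) {
        gap_seq <- substr(query_seq, qgs, qge)
        wlo <- max(1, tgs - 2 * size); whi <- min(nchar(target_seq), tge + 2 * size)
        win <- substr(target_seq, wlo, whi)
        al <- genome_local_alignments(gap_seq, win, min_len = 200,
                                      both_strands = FALSE)
        if (nrow(al) && max(al$matches) >= 0.8 * size) type <- "duplication"
      }
      out[[length(out) + 1]] <- data.frame(
        gap = i, carrier = carrier, type = type, size = size,
        size_class = if (size <= max_mid_size) "mid" else "large",
        q_gap_start = qgs, q_gap_end = qge,
        t_gap_start = tgs, t_gap_end = tge)
    }
  }
  if (!length(out))
    return(data.frame(gap = integer(), carrier = character(),
                      type = character(), size = numeric(),
                      size_class = character(), q_gap_start = integer(),
                      q_gap_end = integer(), t_gap_start = integer(),
                      t_gap_end = integer()))
  do.call(rbind, out)
}

#' Classify an indel's mechanism from its breakpoint flanks
#'
#' NAHR iff the two breakpoint flanks share a local alignment of at least
#' `min_len` bp at `min_identity` or better; otherwise NHEJ. Truncated
#' flanks (event at a contig edge) yield `"unclassified"`.
#'
#' @param left_flank,right_flank Flank sequences at the two breakpoints.
#' @param flank Expected flank length; shorter inputs are unclassified.
#' @param min_len,min_identity NAHR homology thresholds.
#' @return `"NAHR"`, `"NHEJ"` or `"unclassified"`.
#' @export
classify_mechanism <- function(left_flank, right_flank, flank = 500,
                               min_len = 50, min_identity = 0.8) {
  if (is.na(left_flank) || is.na(right_flank) ||
      nchar(left_flank) < flank || nchar(right_flank) < flank)
    return("unclassified")
  al <- cpp_sw_best(toupper(left_flank), toupper(right_flank))
  if (al$length >= min_len && al$matches / al$length >= min_identity)
    "NAHR" else "NHEJ"
}

#' Build a reusable seed index over a genome
#' @param genome Named list of chromosome strings.
#' @param k,max_occ Index parameters (see [genome_local_alignments()]).
#' @return Opaque index object for [polarize_with_outgroup()].
#' @export
seed_index <- function(genome, k = 15, max_occ = 20) {
  seqs <- unlist(genome)
  cpp_index_build(setNames(as.character(seqs), names(seqs)),
                  as.integer(k), as.integer(max_occ))
}

# Best block of a probe against an index; NULL if nothing maps well enough.
index_best_block <- function(index, probe, min_frac = 0.2, min_len = 100,
                             min_ident = 0.75) {
  al <- as.data.frame(cpp_index_blocks(index, toupper(probe), 400L,
                                       as.integer(min_len), min_ident))
  if (nrow(al)) al$strand <- "+"
  rc <- as.data.frame(cpp_index_blocks(index, revcomp(probe), 400L,
                                       as.integer(min_len), min_ident))
  if (nrow(rc)) { rc$strand <- "-"; al <- if (nrow(al)) rbind(al, rc) else rc }
  if (!nrow(al)) return(NULL)
  b <- al[which.max(al$matches), , drop = FALSE]
  if (b$matches < min_frac * nchar(probe)) return(NULL)
  b
}

#' Polarize an indel with an outgroup genome
#'
#' The two `flank`-bp regions upstream and downstream of the gap position in
#' the strain lacking the segment are mapped to the outgroup; the distance
#' between the facing ends of the two mapped blocks classifies the event:
#' near zero (below `max(500, 0.25 * size)`) the segment is absent from the
#' outgroup, so it was an insertion into the carrier; a distance within
#' `[0.5, 2] x size` matches an outgroup homolog, so it was a deletion from
#' the non-carrier. Anything else, unalignable flanks, or flanks mapping to
#' different chromosomes, is unclassified.
#'
#' @param gap_pos Position of the gap in the non-carrier strain (1-based,
#'   first base after the gap).
#' @param noncarrier_seq The non-carrier chromosome sequence.
#' @param outgroup_index A [seed_index()] over the outgroup genome.
#' @param size Event size (bp).
#' @param flank Flank length (bp).
#' @return List: `polarity` (`insertion`/`deletion`/`unclassified`),
#'   `distance` (bp on the outgroup, NA if unclassified early), `reason`.
#' @export
polarize_with_outgroup <- function(gap_pos, noncarrier_seq, outgroup_index,
                                   size, flank = 2500) {
  L <- nchar(noncarrier_seq)
  if (gap_pos - flank < 1 || gap_pos + flank - 1 > L)
    return(list(polarity = "unclassified", distance = NA_real_,
                reason = "flank outside sequence"))
  up <- substr(noncarrier_seq, gap_pos - flank, gap_pos - 1)
  down <- substr(noncarrier_seq, gap_pos, gap_pos + flank - 1)
  bu <- index_best_block(outgroup_index, up)
  bd <- index_best_block(outgroup_index, down)
  if (is.null(bu) || is.null(bd))
    return(list(polarity = "unclassified", distance = NA_real_,
                reason = "flank unalignable"))
  if (bu$target != bd$target)
    return(list(polarity = "unclassified", distance = NA_real_,
                reason = "flanks map to different chromosomes"))
  if (bu$strand != bd$strand)
    return(list(polarity = "unclassified", distance = NA_real_,
                reason = "flanks map to opposite strands"))
  d <- if (bu$strand == "+") bd$tstart - bu$tend - 1 else bu$tstart - bd$tend - 1
  polarity <- if (d < max(500, 0.25 * size)) "insertion"
  else if (d >= 0.5 * size && d <= 2 * size) "deletion"
  else "unclassified"
  list(polarity = polarity, distance = d,
       reason = if (polarity == "unclassified") "distance in neither band" else "")
}

#' Compare two ingroup chromosomes and call unpolarized events
#'
#' Convenience driver: aligns the pair with the built-in seed aligner,
#' chains, and calls SVs.
#'
#' @param qseq,tseq Chromosome sequences of the two ingroup strains.
#' @param ... Passed to [genome_local_alignments()].
#' @param min_size,max_mid_size See [call_svs()].
#' @return List: `events` (from [call_svs()]), `chain`, `alignments`.
#' @export
compare_chromosome_pair <- function(qseq, tseq, min_size = 1000,
                                    max_mid_size = 50000, ...) {
  al <- genome_local_alignments(qseq, tseq, ...)
  if (!nrow(al))
    return(list(events = call_svs(structure(list(
      chain = al, score = 0, strand = "+", sub_chains = list()),
      class = "alignment_chain")), chain = NULL, alignments = al))
  ch <- chain_alignments(al)
  list(events = call_svs(ch, min_size = min_size,
                         max_mid_size = max_mid_size,
                         query_seq = qseq, target_seq = tseq),
       chain = ch, alignments = al)
}

#' Call and polarize all mid-sized indels between two ingroup genomes
#'
#' Runs [compare_chromosome_pair()] on same-named chromosomes, then
#' polarizes every indel with the outgroup. The reported `strain` is the
#' strain the event happened to: the sequence-carrying strain for
#' insertions, the sequence-lacking strain for deletions.
#'
#' @param genome_q,genome_t Named chromosome lists of the two ingroup
#'   strains.
#' @param outgroup Named chromosome list of the outgroup (or a prebuilt
#'   [seed_index()]).
#' @param strain_q,strain_t Strain names for reporting.
#' @param flank Polarization flank (bp).
#' @param min_size,max_mid_size Size band for indel calls.
#' @param mask Optional data.frame (chromosome, start, end) of satellite or
#'   other repeat regions, in query-strain coordinates; calls whose query
#'   gap overlaps a masked interval (padded by `mask_pad`) are dropped, as
#'   tandem-repeat phase shifts mimic indels.
#' @param mask_pad Padding around masked intervals (bp).
#' @return data.frame of polarized events: chromosome, type, strain, size,
#'   size_class, positions, outgroup flank distance.
#' @export
polarize_genome_events <- function(genome_q, genome_t, outgroup,
                                   strain_q = "strainA", strain_t = "strainB",
                                   flank = 2500, min_size = 1000,
                                   max_mid_size = 50000, mask = NULL,
                                   mask_pad = 5000) {
  idx <- if (is.list(outgroup)) seed_index(outgroup) else outgroup
  out <- list()
  for (chrom in intersect(names(genome_q), names(genome_t))) {
    cmp <- compare_chromosome_pair(genome_q[[chrom]], genome_t[[chrom]],
                                   min_size = min_size,
                                   max_mid_size = max_mid_size)
    ev <- cmp$events
    if (!is.null(mask) && nrow(ev)) {
      mk <- mask[mask$chromosome == chrom, , drop = FALSE]
      if (nrow(mk)) {
        drop <- rep(FALSE, nrow(ev))
        for (m in seq_len(nrow(mk)))
          drop <- drop | (ev$q_gap_start <= mk$end[m] + mask_pad &
                            ev$q_gap_end >= mk$start[m] - mask_pad)
        ev <- ev[!drop, , drop = FALSE]
      }
    }
    if (!nrow(ev)) next
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$type != "indel") {
        out[[length(out) + 1]] <- data.frame(
          chromosome = chrom, type = e$type, strain = NA_character_,
          size = e$size, size_class = e$size_class,
          q_gap_start = e$q_gap_start, t_gap_start = e$t_gap_start,
          distance = NA_real_)
        next
      }
      if (e$carrier == "query") {
        carrier_strain <- strain_q; other_strain <- strain_t
        gap_pos <- e$t_gap_start
        nseq <- genome_t[[chrom]]
      } else {
        carrier_strain <- strain_t; other_strain <- strain_q
        gap_pos <- e$q_gap_start
        nseq <- genome_q[[chrom]]
      }
      pol <- polarize_with_outgroup(gap_pos, nseq, idx, e$size, flank = flank)
      type <- pol$polarity
      strain <- if (type == "insertion") carrier_strain
      else if (type == "deletion") other_strain
      else NA_character_
      out[[length(out) + 1]] <- data.frame(
        chromosome = chrom, type = type, strain = strain, size = e$size,
        size_class = e$size_class, q_gap_start = e$q_gap_start,
        t_gap_start = e$t_gap_start, distance = pol$distance)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(), type = character(),
                      strain = character(), size = numeric(),
                      size_class = character(), q_gap_start = integer(),
                      t_gap_start = integer(), distance = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-strain insertion/deletion balance summary
#'
#' @param events Polarized events (from [polarize_genome_events()]).
#' @return List: `table` (strain, type, n, total_bp), `ratio`
#'   (insertions : deletions over both strains; NA when no deletions or no
#'   events).
#' @export
indel_balance_summary <- function(events) {
  ev <- events[events$type %in% c("insertion", "deletion") &
                 !is.na(events$strain), , drop = FALSE]
  if (!nrow(ev))
    return(list(table = data.frame(strain = character(), type = character(),
                                   n = integer(), total_bp = numeric()),
                ratio = NA_real_))
  tab <- aggregate(cbind(n = rep(1, nrow(ev)), total_bp = ev$size),
                   by = list(strain = ev$strain, type = ev$type), FUN = sum)
  n_ins <- sum(ev$type == "insertion")
  n_del <- sum(ev$type == "deletion")
  list(table = tab[order(tab$strain, tab$type), ],
       ratio = if (n_del > 0) n_ins / n_del else NA_real_)
}
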