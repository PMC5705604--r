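# Chromosome-map construction from genetic markers, clone-end linking,
# naive-Bayes Hi-C chromosome assignment and contact-peak placement of
# orphan contigs.

#' Order contigs along chromosomes by genetic markers
#'
#' Contigs whose markers all come from one chromosome are placed in order of
#' the median genetic position (cM) of their markers; a contig carrying
#' markers from exactly two chromosomes is split at the midpoint between the
#' two marker blocks and each part placed; contigs without markers are
#' reported as orphans. Contigs tied at the same cM are ordered by contig id
#' and flagged unoriented; contigs with at least two distinct marker
#' positions are oriented by the sign of the cM-versus-offset trend.
#'
#' @param markers data.frame: marker, chromosome, cm, contig, offset.
#' @param contigs data.frame: contig, length.
#' @return List: `map` (data.frame chromosome, position (rank), contig,
#'   orientation (+/-/`unoriented`), source), `misassembled` (split report),
#'   `orphans` (character vector).
#' @export
order_contigs_by_markers <- function(markers, contigs) {
  unknown <- setdiff(markers$contig, contigs$contig)
  if (length(unknown))
    stop("markers reference unknown contig(s): ",
         paste(head(unknown, 3), collapse = ", "))
  mis <- list(); rows <- list()
  for (ct in unique(markers$contig)) {
    mk <- markers[markers$contig == ct, , drop = FALSE]
    chroms <- unique(mk$chromosome)
    if (length(chroms) == 1) {
      rows[[length(rows) + 1]] <- place_row(ct, mk)
    } else if (length(chroms) == 2) {
      mk <- mk[order(mk$offset), , drop = FALSE]
      # innermost discordant markers: last of the first block, first of the second
      first_chrom <- mk$chromosome[1]
      brk <- which(mk$chromosome != first_chrom)[1]
      split_at <- (mk$offset[brk - 1] + mk$offset[brk]) %/% 2
      len <- contigs$length[match(ct, contigs$contig)]
      mis[[length(mis) + 1]] <- data.frame(contig = ct, split_at = split_at,
                                           chrom_a = first_chrom,
                                           chrom_b = mk$chromosome[brk])
      a <- mk[seq_len(brk - 1), , drop = FALSE]
      b <- mk[brk:nrow(mk), , drop = FALSE]
      b$offset <- b$offset - split_at
      rows[[length(rows) + 1]] <- place_row(paste0(ct, ".1"), a)
      rows[[length(rows) + 1]] <- place_row(paste0(ct, ".2"), b)
    } else {
      stop("contig ", ct, " carries markers from more than two chromosomes")
    }
  }
  placed <- do.call(rbind, rows)
  placed <- placed[order(placed$chromosome, placed$cm, placed$contig), ,
                   drop = FALSE]
  placed$position <- stats::ave(seq_len(nrow(placed)), placed$chromosome,
                                FUN = seq_along)
  # flag cM ties as unoriented
  for (ch in unique(placed$chromosome)) {
    idx <- which(placed$chromosome == ch)
    dup <- placed$cm[idx] %in% placed$cm[idx][duplicated(placed$cm[idx])]
    placed$orientation[idx][dup] <- "unoriented"
  }
  map <- placed[, c("chromosome", "position", "contig", "orientation")]
  map$source <- "marker"
  list(map = map,
       misassembled = if (length(mis)) do.call(rbind, mis) else NULL,
       orphans = setdiff(contigs$contig, unique(markers$contig)))
}

place_row <- function(ct, mk) {
  orient <- "unoriented"
  if (length(unique(mk$cm)) >= 2) {
    tr <- sign(stats::cor(mk$cm, mk$offset))
    if (!is.na(tr) && tr != 0) orient <- if (tr > 0) "+" else "-"
  }
  data.frame(chromosome = mk$chromosome[1], cm = median(mk$cm), contig = ct,
             orientation = orient)
}

#' Link contigs into a map by clone-end pairs
#'
#' Contig pairs connected by at least two qualifying clone-end pairs (both
#' reads within the clone type's distance bound of a contig end: BAC 150
#' kbp, fosmid 50 kbp) are joined adjacently; an unplaced partner is
#' inserted next to its placed partner with source "clone". A contig whose
#' end links to two different partners leaves the map unchanged and is
#' reported as a conflict.
#'
#' @param map Map data.frame from [order_contigs_by_markers()].
#' @param end_pairs data.frame: contig1, pos1, contig2, pos2 (1-based read
#'   positions on each contig).
#' @param clone_type `"BAC"` or `"fosmid"`.
#' @param contigs data.frame: contig, length.
#' @return List: `map` (augmented), `joined` (data.frame of joins),
#'   `conflicts` (character).
#' @export
link_by_clone_ends <- function(map, end_pairs, clone_type, contigs) {
  bound <- switch(clone_type, BAC = 150000, fosmid = 50000,
                  stop("unknown clone type '", clone_type, "'"))
  len <- setNames(contigs$length, contigs$contig)
  near_end <- function(ct, pos) pos <= bound | pos > len[ct] - bound
  ok <- near_end(end_pairs$contig1, end_pairs$pos1) &
    near_end(end_pairs$contig2, end_pairs$pos2) &
    end_pairs$contig1 != end_pairs$contig2
  ep <- end_pairs[ok, , drop = FALSE]
  if (!nrow(ep)) return(list(map = map, joined = NULL, conflicts = character(0)))
  key <- paste(pmin(ep$contig1, ep$contig2), pmax(ep$contig1, ep$contig2))
  tab <- table(key)
  links <- names(tab)[tab >= 2]
  joined <- list(); conflicts <- character(0)
  partners <- strsplit(links, " ", fixed = TRUE)
  seen <- table(unlist(partners))
  bad <- names(seen)[seen > 1]
  for (p in partners) {
    if (any(p %in% bad)) {
      conflicts <- c(conflicts, paste(p, collapse = "-"))
      next
    }
    placed <- p %in% map$contig
    if (sum(placed) != 1) next  # both placed or both orphans: nothing to insert
    anchor <- p[placed]; orphan <- p[!placed]
    i <- which(map$contig == anchor)
    row <- map[i, , drop = FALSE]
    row$contig <- orphan
    row$position <- row$position + 0.5
    row$orientation <- "unoriented"
    row$source <- "clone"
    map <- rbind(map, row)
    joined[[length(joined) + 1]] <- data.frame(anchor = anchor, added = orphan,
                                               clone_type = clone_type)
  }
  map <- map[order(map$chromosome, map$position), , drop = FALSE]
  map$position <- stats::ave(seq_len(nrow(map)), map$chromosome, FUN = seq_along)
  list(map = map,
       joined = if (length(joined)) do.call(rbind, joined) else NULL,
       conflicts = conflicts)
}

#' Fit the naive-Bayes Hi-C chromosome classifier
#'
#' Priors are proportional to the number of training contigs per chromosome.
#' The conditional model for the contact count with chromosome i given the
#' true chromosome c is Poisson with rate (contig total contacts) x
#' profile(i | c), where the profile is the pseudocount-smoothed mean
#' contact composition of class c's training contigs (optionally
#' length-normalized before averaging).
#'
#' @param contacts Integer matrix (rows contigs, columns chromosomes).
#' @param chromosomes True chromosome per training contig.
#' @param lengths Optional contig lengths for length normalization.
#' @param pseudocount Smoothing added to profile numerators.
#' @return Object of class `nb_model`: `prior`, `profile` (rows chromosomes
#'   = classes, columns contact chromosomes), `levels`.
#' @export
fit_nb <- function(contacts, chromosomes, lengths = NULL, pseudocount = 1) {
  stopifnot(nrow(contacts) == length(chromosomes))
  lev <- colnames(contacts)
  if (is.null(lev)) stop("contacts needs chromosome column names")
  missing <- setdiff(lev, unique(chromosomes))
  if (length(missing))
    stop("no training contig for chromosome ", missing[1])
  w <- contacts
  if (!is.null(lengths)) w <- w / lengths
  profile <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (c in lev) {
    rows <- w[chromosomes == c, , drop = FALSE]
    v <- colSums(rows) + pseudocount
    profile[c, ] <- v / sum(v)
  }
  prior <- as.numeric(table(factor(chromosomes, levels = lev))) /
    length(chromosomes)
  names(prior) <- lev
  structure(list(prior = prior, profile = profile, levels = lev,
                 pseudocount = pseudocount), class = "nb_model")
}

#' Posterior chromosome assignment of an orphan contig
#'
#' Log-domain accumulation of the prior and the per-chromosome Poisson
#' conditional likelihoods of the observed contact counts; the normalizer Z
#' makes posteriors sum to 1. An all-zero vector returns the prior.
#'
#' @param model An `nb_model`.
#' @param v Contact count vector (length = number of chromosomes).
#' @return List: `posterior` (named, sums to 1), `chromosome` (argmax).
#' @export
classify_orphan <- function(model, v) {
  if (length(v) != length(model$levels))
    stop("contact vector length does not match the model")
  if (any(v < 0)) stop("negative contact counts")
  total <- sum(v)
  logpost <- log(model$prior)
  if (total > 0) {
    for (c in model$levels) {
      lam <- total * model$profile[c, ]
      logpost[c] <- logpost[c] + sum(stats::dpois(v, lam, log = TRUE))
    }
  }
  logpost <- logpost - max(logpost)
  post <- exp(logpost) / sum(exp(logpost))
  list(posterior = post, chromosome = model$levels[which.max(post)])
}

#' Locate an orphan contig by its contact peak
#'
#' Sliding-window mean contact frequency along the assigned chromosome; the
#' contig is slated for insertion adjacent to the argmax window center.
#' Ties are broken leftmost; a flat track additionally raises a
#' low-confidence warning.
#'
#' @param counts Per-bin contact counts along the chromosome.
#' @param bin_centers Genomic centers of the bins (bp).
#' @param window Averaging window (bp).
#' @return List: `position` (bp of best window center), `window_mean`.
#' @export
locate_orphan <- function(counts, bin_centers, window = 50000) {
  if (!length(counts)) stop("empty contact track")
  stopifnot(length(counts) == length(bin_centers))
  half <- window / 2
  wm <- vapply(seq_along(bin_centers), function(i) {
    sel <- abs(bin_centers - bin_centers[i]) <= half
    mean(counts[sel])
  }, numeric(1))
  best <- which.max(wm)  # which.max takes the leftmost maximum
  if (max(wm) == min(wm))
    warning("flat contact track: placement is low-confidence")
  list(position = bin_centers[best], window_mean = wm[best])
}

#' Export a chromosome map as sequences with gaps between neighbors
#'
#' Concatenates each chromosome's placed contigs in map order (reverse
#' complementing "-" contigs) with a run of `gap` N characters between
#' neighbors; unoriented contigs are exported forward.
#'
#' @param map Map data.frame (chromosome, position, contig, orientation).
#' @param contig_seqs Named character vector/list of contig sequences.
#' @param gap Gap length between neighboring contigs (bp).
#' @return Named list of chromosome sequences.
#' @export
export_chromosome_sequences <- function(map, contig_seqs, gap = 1000) {
  out <- list()
  for (ch in unique(map$chromosome)) {
    rows <- map[map$chromosome == ch, , drop = FALSE]
    rows <- rows[order(rows$position), , drop = FALSE]
    seqs <- vapply(seq_len(nrow(rows)), function(i) {
      s <- contig_seqs[[rows$contig[i]]]
      if (identical(rows$orientation[i], "-")) revcomp(s) else s
    }, "")
    out[[ch]] <- paste(seqs, collapse = strrep("N", gap))
  }
  out
}

#' Transfer orientation from the best-matching contig of another strain
#'
#' The orientation is copied from the strand of the best-scoring cross-
#' strain alignment; below `score_floor`, or on an exact score tie between
#' conflicting strands, the contig stays unoriented (with a warning for the
#' tie).
#'
#' @param contig_seq Unoriented contig sequence.
#' @param counterparts Named character vector of candidate contig sequences
#'   from the other strain.
#' @param counterpart_orientation Named orientation (+/-) of each candidate
#'   in its own map.
#' @param score_floor Minimum alignment score (matched bases).
#' @param ... Passed to [genome_local_alignments()].
#' @return `"+"`, `"-"` or `"unoriented"`.
#' @export
orient_by_best_match <- function(contig_seq, counterparts,
                                 counterpart_orientation, score_floor = 200,
                                 ...) {
  best <- NULL
  for (nm in names(counterparts)) {
    al <- genome_local_alignments(contig_seq, counterparts[[nm]], ...)
    if (!nrow(al)) next
    al <- al[which.max(al$matches), , drop = FALSE]
    strand <- al$strand
    eff <- if (counterpart_orientation[[nm]] == "-") {
      if (strand == "+") "-" else "+"
    } else strand
    cand <- data.frame(matches = al$matches, orientation = eff)
    if (is.null(best) || cand$matches > best$matches) best <- cand
    else if (cand$matches == best$matches &&
             cand$orientation != best$orientation) {
      warning("conflicting equal-score orientations; contig left unoriented")
      best$orientation <- "unoriented"
    }
  }
  if (is.null(best) || best$matches < score_floor) return("unoriented")
  best$orientation
}
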