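# Centromeric satellite monomer analysis: greedy identity clustering,
# best-match association across chromosomes, evolution-rate comparison
# between positional classes, representative scoring, satellite genomic
# fraction, telomere detection and the Ward family tree.

#' Greedy identity clustering of satellite monomers
#'
#' Monomers (from one chromosome of one strain) are processed longest-first;
#' each joins the first existing cluster whose current representative has
#' [monomer_similarity()] at or above `threshold`, otherwise it founds a new
#' cluster. The representative of a cluster is its longest member and is only
#' reported for clusters with more than `min_members_for_representative`
#' members (default 10: clusters of exactly 10 get none).
#'
#' @param monomers data.frame with columns `id` and `sequence` (extra columns
#'   kept).
#' @param threshold Similarity threshold in (0, 1].
#' @param min_members_for_representative Representative reported only when
#'   cluster size exceeds this.
#' @return List of class `monomer_clusters`: `clusters` (data.frame cluster,
#'   size, representative — NA when too small), `assignment` (data.frame id,
#'   cluster), `monomers` (input).
#' @export
cluster_monomers <- function(monomers, threshold = 0.9,
                             min_members_for_representative = 10L) {
  if (!all(c("id", "sequence") %in% names(monomers)))
    stop("monomers needs 'id' and 'sequence' columns")
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  ord <- order(-nchar(monomers$sequence))  # longest first; ties by input order
  reps <- character(0)      # representative-so-far (longest member) sequences
  rep_id <- character(0)
  members <- list()
  cl_of <- integer(nrow(monomers))
  for (i in ord) {
    seq <- monomers$sequence[i]
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (monomer_similarity(seq, reps[k]) >= threshold) {
        members[[k]] <- c(members[[k]], i)
        cl_of[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, seq)  # first (longest) member is the representative
      rep_id <- c(rep_id, monomers$id[i])
      members[[length(members) + 1]] <- i
      cl_of[i] <- length(reps)
    }
  }
  sizes <- lengths(members)
  clusters <- data.frame(cluster = seq_along(members), size = sizes,
                         representative = ifelse(
                           sizes > min_members_for_representative, rep_id, NA))
  structure(list(clusters = clusters,
                 assignment = data.frame(id = monomers$id, cluster = cl_of),
                 monomers = monomers),
            class = "monomer_clusters")
}

# Representative sequence lookup for a monomer_clusters object.
representative_sequences <- function(mc) {
  cl <- mc$clusters[!is.na(mc$clusters$representative), , drop = FALSE]
  if (!nrow(cl)) return(NULL)
  data.frame(cluster = cl$cluster,
             id = cl$representative,
             sequence = mc$monomers$sequence[match(cl$representative,
                                                   mc$monomers$id)])
}

#' Best-match association of monomer clusters across chromosomes
#'
#' For every cluster with a representative, finds the cluster on a different
#' chromosome whose representative has the highest [monomer_similarity()],
#' and categorizes the pair by the positional classes of the two chromosomes
#' (`AcroAcro`, `AcroNonAcro`, `NonAcroNonAcro`). Ties are broken by the
#' lowest cluster label; clusters with no cross-chromosome candidate are
#' skipped with a warning.
#'
#' @param cluster_sets Named list (by chromosome) of `monomer_clusters`.
#' @param classes Named character vector: positional class
#'   (`"acrocentric"`/`"non-acrocentric"`) per chromosome.
#' @return data.frame of similarity records: cluster_a, cluster_b (labels
#'   `<chromosome>#<cluster>`), similarity, distance, category.
#' @export
best_match_associations <- function(cluster_sets, classes) {
  reps <- list()
  for (chrom in names(cluster_sets)) {
    r <- representative_sequences(cluster_sets[[chrom]])
    if (is.null(r)) next
    r$chromosome <- chrom
    reps[[chrom]] <- r
  }
  if (length(reps) < 2)
    stop("need representatives on at least two chromosomes")
  reps <- do.call(rbind, reps)
  reps$label <- paste0(reps$chromosome, "#", reps$cluster)
  reps <- reps[order(reps$label), , drop = FALSE]
  n <- nrow(reps)
  sim <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (reps$chromosome[i] == reps$chromosome[j]) next
    s <- monomer_similarity(reps$sequence[i], reps$sequence[j])
    sim[i, j] <- s; sim[j, i] <- s
  }
  out <- list()
  for (i in seq_len(n)) {
    cand <- which(!is.na(sim[i, ]))
    if (!length(cand)) {
      warning("cluster ", reps$label[i], " has no cross-chromosome candidate; skipped")
      next
    }
    j <- cand[which.max(sim[i, cand])]  # ties: lowest label (rows sorted)
    ca <- classes[[reps$chromosome[i]]]
    cb <- classes[[reps$chromosome[j]]]
    acro <- c(ca, cb) == "acrocentric"
    cat <- if (all(acro)) "AcroAcro" else if (!any(acro)) "NonAcroNonAcro" else "AcroNonAcro"
    out[[length(out) + 1]] <- data.frame(cluster_a = reps$label[i],
                                         cluster_b = reps$label[j],
                                         similarity = sim[i, j],
                                         distance = 1 - sim[i, j],
                                         category = cat)
  }
  do.call(rbind, out)
}

#' Compare best-match similarity distributions between positional classes
#'
#' One-sided Wilcoxon rank-sum tests of the `NonAcroNonAcro` group against
#' each of the other categories, alternative "less" (the non-acrocentric
#' group evolving faster shows lower similarities).
#'
#' With 12 or fewer records in a comparison the one-sided p-value is
#' computed exactly by enumerating all rank assignments (valid under ties);
#' larger comparisons use the normal approximation.
#'
#' @param records data.frame from [best_match_associations()].
#' @return List: `p_values` (named: vs_AcroAcro, vs_AcroNonAcro), `medians`
#'   (per category), `n` (per category), `summary` (box-plot-ready stats).
#' @export
compare_similarity_groups <- function(records) {
  split_sim <- split(records$similarity, records$category)
  for (g in names(split_sim))
    if (length(split_sim[[g]]) < 2)
      stop("group ", g, " has fewer than 2 records")
  target <- split_sim[["NonAcroNonAcro"]]
  if (is.null(target)) stop("group NonAcroNonAcro has fewer than 2 records")
  pv <- c(vs_AcroAcro = NA_real_, vs_AcroNonAcro = NA_real_)
  if (!is.null(split_sim[["AcroAcro"]]))
    pv["vs_AcroAcro"] <- rank_sum_less_p(target, split_sim[["AcroAcro"]])
  if (!is.null(split_sim[["AcroNonAcro"]]))
    pv["vs_AcroNonAcro"] <- rank_sum_less_p(target, split_sim[["AcroNonAcro"]])
  list(p_values = pv,
       medians = vapply(split_sim, median, numeric(1)),
       n = vapply(split_sim, length, numeric(1)),
       summary = do.call(rbind, lapply(names(split_sim), function(g)
         data.frame(category = g, t(quantile(split_sim[[g]],
                                             c(0, 0.25, 0.5, 0.75, 1)))))))
}

# One-sided (x stochastically smaller) rank-sum p-value: exact permutation
# enumeration for small samples, normal approximation otherwise.
rank_sum_less_p <- function(x, y, exact_max = 12L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 + n2 <= exact_max) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n1)])
    combs <- utils::combn(n1 + n2, n1)
    w_all <- apply(combs, 2, function(idx) sum(r[idx]))
    mean(w_all <= w_obs)
  } else {
    wilcox.test(x, y, alternative = "less", exact = FALSE)$p.value
  }
}

#' Representative score of a monomer against a set of repeat regions
#'
#' Sum over local-alignment hits of identity x alignment length / monomer
#' length; hits below the identity floor are discarded. The monomer
#' maximizing this score is the natural class representative.
#'
#' @param monomer Monomer sequence.
#' @param regions Character vector of region sequences.
#' @param identity_floor Hits below this identity are ignored.
#' @param min_score Minimum local alignment score per hit.
#' @return Non-negative score (0 when nothing hits).
#' @export
representative_score <- function(monomer, regions, identity_floor = 0.7,
                                 min_score = 30) {
  if (!nzchar(monomer)) stop("empty monomer")
  if (!length(regions)) stop("no regions supplied")
  total <- 0
  for (r in regions) {
    h <- local_hits(monomer, r, min_score = min_score)
    if (!nrow(h)) next
    h <- h[h$identity >= identity_floor, , drop = FALSE]
    if (nrow(h))
      total <- total + sum(h$identity * h$length) / nchar(monomer)
  }
  total
}

#' Satellite fraction of a read set
#'
#' Reads are filtered (length strictly greater than `min_length`, mean QV
#' strictly greater than `min_qv`); the fraction is satellite-masked bases
#' (local-alignment hits of the monomer) over total bases of surviving reads.
#'
#' @param reads data.frame with columns `sequence` and `qv` (mean per-read
#'   quality value).
#' @param monomer Satellite monomer sequence.
#' @param min_length Length filter (bp, exclusive).
#' @param min_qv QV filter (exclusive).
#' @param min_score,identity_floor Hit filters, as in
#'   [representative_score()].
#' @return Fraction in `[0, 1]`.
#' @export
satellite_fraction <- function(reads, monomer, min_length = 1000, min_qv = 10,
                               min_score = 60, identity_floor = 0.7) {
  keep <- nchar(reads$sequence) > min_length & reads$qv > min_qv
  if (!any(keep)) stop("no reads pass filters")
  reads <- reads[keep, , drop = FALSE]
  masked <- 0; total <- 0
  for (i in seq_len(nrow(reads))) {
    sq <- reads$sequence[i]
    total <- total + nchar(sq)
    h <- local_hits(monomer, sq, min_score = min_score)
    if (nrow(h)) {
      h <- h[h$identity >= identity_floor, , drop = FALSE]
      if (nrow(h)) masked <- masked + sum(h$tend - h$tstart + 1)
    }
  }
  masked / total
}

#' Find telomeric repeat arrays
#'
#' Maximal tandem arrays of the vertebrate telomeric unit TTAGGG (and its
#' reverse complement CCCTAA) with at least `min_copies` copies.
#'
#' @param sequence Character string.
#' @param min_copies Minimum unit copies.
#' @return data.frame: start, end (1-based closed), strand, copies.
#' @export
find_telomeric_repeats <- function(sequence, min_copies = 3L) {
  scan_unit <- function(unit, strand) {
    pat <- paste0("(?:", unit, "){", min_copies, ",}")
    m <- gregexpr(pat, sequence)[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    data.frame(start = as.integer(m), end = as.integer(m) + len - 1,
               strand = strand, copies = len %/% nchar(unit))
  }
  out <- rbind(scan_unit("TTAGGG", "+"), scan_unit("CCCTAA", "-"))
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), copies = integer())
  out[order(out$start), , drop = FALSE]
}

#' Classify a centromere as acrocentric or non-acrocentric
#'
#' Acrocentric iff the region midpoint lies within `fraction` of the
#' chromosome length from the nearer end (closed boundary: exactly at the
#' cutoff is acrocentric).
#'
#' @param start,end Region interval (1-based closed).
#' @param chromosome_length Chromosome length (bp).
#' @param fraction Cutoff fraction of length from the nearer end.
#' @return `"acrocentric"` or `"non-acrocentric"`.
#' @export
classify_centromere_position <- function(start, end, chromosome_length,
                                         fraction = 0.15) {
  if (start < 1 || end > chromosome_length || start > end)
    stop("region outside chromosome")
  mid <- (start + end) / 2
  d <- min(mid, chromosome_length - mid + 1)
  if (d <= fraction * chromosome_length) "acrocentric" else "non-acrocentric"
}

#' Ward family tree of representative monomers
#'
#' Agglomerative clustering with the ward.D2 convention (distances squared
#' inside the Lance-Williams update) on pairwise distance 1 - similarity.
#'
#' @param representatives data.frame with `id` and `sequence`.
#' @return List: `tree` (hclust), `dist` (the distance matrix).
#' @export
family_tree <- function(representatives) {
  n <- nrow(representatives)
  if (is.null(n) || n < 2) stop("need at least 2 representatives")
  d <- matrix(0, n, n, dimnames = list(representatives$id, representatives$id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- monomer_similarity(representatives$sequence[i],
                            representatives$sequence[j])
    d[i, j] <- 1 - s; d[j, i] <- 1 - s
  }
  hc <- hclust(as.dist(d), method = "ward.D2")
  list(tree = hc, dist = d)
}

#' Cut a family tree into k groups
#' @param tree Result of [family_tree()] (or an hclust).
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_family_tree <- function(tree, k) {
  hc <- if (inherits(tree, "hclust")) tree else tree$tree
  cutree(hc, k = k)
}

#' Decompose a repeat region into monomer occurrences
#'
#' Greedy non-overlapping tiling of the region by local-alignment hits of a
#' representative monomer, best score first.
#'
#' @param region Region sequence.
#' @param representative Monomer sequence used as the probe.
#' @param min_score,identity_floor Hit filters.
#' @return data.frame: start, end (1-based closed within the region),
#'   identity, sequence.
#' @export
decompose_monomers <- function(region, representative, min_score = 60,
                               identity_floor = 0.7) {
  h <- local_hits(representative, region, min_score = min_score)
  h <- h[h$identity >= identity_floor, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(start = integer(), end = integer(), identity = numeric(),
                      sequence = character()))
  data.frame(start = h$tstart, end = h$tend, identity = h$identity,
             sequence = substring(region, h$tstart, h$tend))
}
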