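# CpG-state calling and filtering, hyper/hypo region segmentation,
# cross-technology concordance and average methylation ratios.

#' Length of a 1-based fully-closed genomic interval
#'
#' The coordinate convention used throughout for methylation regions and
#' monomer intervals: both endpoints are included, so the length is
#' `end - start + 1`.
#'
#' @param start,end Interval endpoints (1-based, closed).
#' @return Integer length.
#' @export
region_length <- function(start, end) {
  stopifnot(all(end >= start))
  as.integer(end - start + 1)
}

#' Call CpG states from a bisulfite pileup by strict majority
#'
#' A site is methylated iff strictly more than half of its reads support
#' methylation; ties and minorities are unmethylated. Sites with zero
#' coverage yield no call.
#'
#' @param pileup data.frame: chromosome, pos, meth_count, total_count.
#' @return data.frame: chromosome, pos, state, meth_count, total_count
#'   (zero-coverage rows dropped).
#' @export
call_cpg <- function(pileup) {
  stopifnot(all(pileup$meth_count >= 0), all(pileup$meth_count <= pileup$total_count))
  keep <- pileup$total_count >= 1
  p <- pileup[keep, , drop = FALSE]
  p$state <- ifelse(p$meth_count > p$total_count / 2, "methylated", "unmethylated")
  p[, c("chromosome", "pos", "state", "meth_count", "total_count")]
}

#' Filter bisulfite calls to the trusted coverage band
#'
#' Keeps calls with total coverage between `min_cov` and `max_cov`
#' inclusive (defaults 2 and 9); abnormally high coverage tends to flag
#' collapsed repeat copies.
#'
#' @param calls data.frame with `total_count`.
#' @param min_cov,max_cov Inclusive coverage bounds.
#' @return Filtered data.frame; the number of dropped sites is attached as
#'   attribute `dropped`.
#' @export
filter_for_concordance <- function(calls, min_cov = 2L, max_cov = 9L) {
  keep <- calls$total_count >= min_cov & calls$total_count <= max_cov
  out <- calls[keep, , drop = FALSE]
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Segment a CpG state track into hyper/hypomethylated regions
#'
#' Maximal runs of one state, tolerating up to `max_interruptions`
#' opposite-state calls per run; runs with fewer than `min_cpgs` same-state
#' calls are discarded. Output regions are non-overlapping and sorted.
#'
#' @param calls data.frame: chromosome, pos, state — one chromosome, sorted
#'   by position.
#' @param min_cpgs Minimum CpGs per reported region.
#' @param max_interruptions Opposite-state calls tolerated inside a run.
#' @return data.frame: chromosome, start, end, status (`hyper`/`hypo`),
#'   n_cpgs.
#' @export
segment_regions <- function(calls, min_cpgs = 40L, max_interruptions = 2L) {
  if (nrow(calls) == 0)
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), status = character(), n_cpgs = integer()))
  if (length(unique(calls$chromosome)) > 1)
    stop("segment_regions works on one chromosome at a time")
  if (is.unsorted(calls$pos)) stop("calls must be sorted by position")
  st <- calls$state
  pos <- calls$pos
  n <- length(st)
  out <- list()
  i <- 1
  while (i <= n) {
    state <- st[i]
    used <- 0      # interrupting opposite calls absorbed into this run
    j <- i
    k <- i + 1
    while (k <= n) {
      if (st[k] == state) {
        j <- k
        k <- k + 1
      } else {
        r <- 0
        while (k + r <= n && st[k + r] != state) r <- r + 1
        if (used + r <= max_interruptions && k + r <= n) {
          used <- used + r
          k <- k + r
        } else break
      }
    }
    n_same <- (j - i + 1) - used
    if (n_same >= min_cpgs)
      out[[length(out) + 1]] <- data.frame(
        chromosome = calls$chromosome[1], start = pos[i], end = pos[j],
        status = if (state == "methylated") "hyper" else "hypo",
        n_cpgs = n_same)
    i <- j + 1
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), status = character(), n_cpgs = integer())
  res
}

#' Concordance of region-level calls with per-CpG bisulfite calls
#'
#' Over filtered bisulfite CpGs falling inside hypo (hyper) regions, the
#' fraction called unmethylated (methylated).
#'
#' @param regions data.frame from [segment_regions()] (chromosome, start,
#'   end, status).
#' @param bis_calls Filtered bisulfite calls (chromosome, pos, state).
#' @return List: `pct_unmeth_agree`, `pct_meth_agree` (percent), `n_hypo`,
#'   `n_hyper` (denominators).
#' @export
concordance <- function(regions, bis_calls) {
  in_region <- function(status) {
    r <- regions[regions$status == status, , drop = FALSE]
    if (!nrow(r)) return(logical(nrow(bis_calls)))
    hit <- rep(FALSE, nrow(bis_calls))
    for (i in seq_len(nrow(r)))
      hit <- hit | (bis_calls$chromosome == r$chromosome[i] &
                      bis_calls$pos >= r$start[i] & bis_calls$pos <= r$end[i])
    hit
  }
  hypo <- bis_calls[in_region("hypo"), , drop = FALSE]
  hyper <- bis_calls[in_region("hyper"), , drop = FALSE]
  if (nrow(hypo) + nrow(hyper) == 0)
    stop("no filtered bisulfite CpGs fall inside any region")
  list(pct_unmeth_agree = if (nrow(hypo)) 100 * mean(hypo$state == "unmethylated") else NA_real_,
       pct_meth_agree = if (nrow(hyper)) 100 * mean(hyper$state == "methylated") else NA_real_,
       n_hypo = nrow(hypo), n_hyper = nrow(hyper))
}

#' Average methylation ratio from methylated/unmethylated cytosine counts
#'
#' @param methylated,unmethylated Total counts over the aligned monomer set.
#' @return Percentage methylated / (methylated + unmethylated).
#' @export
average_methylation_ratio <- function(methylated, unmethylated) {
  if (methylated + unmethylated == 0) stop("zero denominator")
  100 * methylated / (methylated + unmethylated)
}
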