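# k-spectrum kernel machinery: normalized k-mer frequency vectors, the
# distance D(A,B) = sqrt(2 - 2 K(A,B)), UPGMA clustering and the
# methylation-domain phylogeny.

#' Euclidean-normalized k-mer spectrum of a sequence
#'
#' Counts over the 4^k k-mer space (held sparsely), Euclidean-normalized;
#' windows containing non-ACGT letters are skipped.
#'
#' @param sequence Character string.
#' @param k Word length (default 8).
#' @return Object of class `kmer_spectrum`: list with `k`, `index` (1-based
#'   positions in the 4^k space), `value` (normalized frequencies).
#' @export
kmer_spectrum <- function(sequence, k = 8L) {
  cnt <- cpp_kmer_counts(toupper(sequence), as.integer(k))[[1]]
  if (!length(cnt$index)) stop("no valid k-mer in sequence")
  v <- as.numeric(cnt$count)
  v <- v / sqrt(sum(v^2))
  ord <- order(cnt$index)
  structure(list(k = as.integer(k), index = cnt$index[ord], value = v[ord]),
            class = "kmer_spectrum")
}

#' Spectrum-kernel inner product of two spectra
#' @param a,b `kmer_spectrum` objects with equal `k`.
#' @return K(A, B) in `[0, 1]`.
#' @export
spectrum_kernel <- function(a, b) {
  if (a$k != b$k) stop("spectra have different k")
  i <- match(a$index, b$index)
  hit <- !is.na(i)
  if (!any(hit)) return(0)
  sum(a$value[hit] * b$value[i[hit]])
}

#' Spectrum distance D(A, B) = sqrt(2 - 2 K(A, B))
#'
#' Equals the Euclidean distance between the unit-norm spectra; lies in
#' `[0, sqrt(2)]` and is 0 iff the spectra coincide.
#'
#' @param a,b `kmer_spectrum` objects with equal `k`.
#' @return Non-negative distance.
#' @export
spectrum_distance <- function(a, b) {
  K <- spectrum_kernel(a, b)
  d2 <- max(0, 2 - 2 * K)
  if (d2 < 1e-14) d2 <- 0  # identical spectra up to rounding
  sqrt(d2)
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Standard unweighted average-linkage agglomeration. Merge heights follow
#' the half-average-distance convention (the height of a merge is half the
#' average inter-cluster distance), so leaf-to-root heights are equal
#' (ultrametric output). Ties are broken by the smallest label pair.
#'
#' @param d Symmetric non-negative matrix with zero diagonal (labels in
#'   dimnames) or a `dist`.
#' @return An `hclust` object (heights on the half-distance convention;
#'   attribute `height_convention` = "half-average-distance").
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-12) stop("asymmetric distance matrix")
  labels <- rownames(d) %||% as.character(seq_len(n))
  active <- seq_len(n)
  sizes <- rep(1, n)
  id <- -seq_len(n)             # hclust convention: negatives are leaves
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      v <- D[active[i], active[j]]
      if (v < bd - 1e-15) { bd <- v; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    ai <- active[i]; aj <- active[j]
    v <- c(id[ai], id[aj])
    merge[step, ] <- v[order(v >= 0, abs(v))]  # hclust row convention
    height[step] <- bd / 2
    # unweighted average update
    for (kk in active) {
      if (kk == ai || kk == aj) next
      D[ai, kk] <- D[kk, ai] <-
        (sizes[ai] * D[ai, kk] + sizes[aj] * D[aj, kk]) / (sizes[ai] + sizes[aj])
    }
    sizes[ai] <- sizes[ai] + sizes[aj]
    id[ai] <- step
    active <- active[active != aj]
  }
  hc <- list(merge = merge, height = height, order = seq_len(n),
             labels = labels, method = "upgma",
             call = match.call(), dist.method = "supplied")
  class(hc) <- "hclust"
  # a plottable leaf order: use the merge structure
  hc$order <- order_from_merge(merge, n)
  attr(hc, "height_convention") <- "half-average-distance"
  hc
}

# Derive a valid leaf ordering from an hclust merge matrix.
order_from_merge <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' Phylogeny of methylation domains by spectrum-kernel distance
#'
#' Composition of [kmer_spectrum()], [spectrum_distance()] and [upgma()].
#' Leaf labels carry strain, chromosome and status, with acrocentric repeats
#' flagged by a trailing "a".
#'
#' @param regions data.frame with columns strain, chromosome, status,
#'   sequence and optionally acro (logical).
#' @param k Spectrum word length.
#' @return List: `tree` (hclust), `dist` (labelled distance matrix),
#'   `newick` (Newick string).
#' @export
methylation_phylogeny <- function(regions, k = 8L) {
  n <- nrow(regions)
  if (is.null(n) || n < 2) stop("need at least 2 regions")
  ac <- if ("acro" %in% names(regions)) regions$acro %in% TRUE else rep(FALSE, n)
  labels <- paste0(regions$strain, "_", regions$chromosome, "_", regions$status,
                   ifelse(ac, "_a", ""))
  labels <- make.unique(labels, sep = "#")
  specs <- lapply(regions$sequence, kmer_spectrum, k = k)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- spectrum_distance(specs[[i]], specs[[j]])
    d[i, j] <- v; d[j, i] <- v
  }
  tree <- upgma(d)
  list(tree = tree, dist = d, newick = as_newick(tree))
}
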