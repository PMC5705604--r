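# Sequence utilities and alignment wrappers around the compiled core.

#' Generate a random DNA sequence
#'
#' Bases are drawn i.i.d. from the supplied probabilities (uniform by default).
#'
#' @param n Sequence length in bp.
#' @param prob Probabilities for A, C, G, T.
#' @return A single character string.
#' @export
random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(n >= 1, length(prob) == 4)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

#' Mutate a sequence under i.i.d. per-site uniform replacement
#'
#' Each site is substituted independently with probability `rate`; the new
#' base is drawn uniformly from the three alternatives (a Jukes-Cantor-like
#' replacement process with no indels).
#'
#' @param seq Character string (ACGT alphabet).
#' @param rate Per-site substitution probability in `[0, 0.75)`.
#' @return Mutated character string.
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(is.character(seq), length(seq) == 1, rate >= 0, rate < 0.75)
  if (rate == 0 || nchar(seq) == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3,
                  dimnames = list(NULL, c("A","C","G","T")))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- alt[cbind(pick, match(v[hit], colnames(alt)))]
  }
  paste(v, collapse = "")
}

#' Reverse-complement a DNA string
#' @param seq Character string.
#' @return Reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Global alignment similarity between two monomer sequences
#'
#' Computes a Needleman-Wunsch global alignment (match +1, mismatch -1,
#' gap -1, end gaps penalized) and returns
#' (number of matched bases) / (length of the shorter sequence).
#' `N` never counts as a match. Matches are counted on one optimal traceback
#' chosen deterministically (prefer diagonal, then up, then left) after
#' putting the operands in canonical (lexicographic) order, so the value is
#' exactly symmetric and lies in `[0, 1]`.
#'
#' @param a,b DNA sequences as character strings.
#' @return Similarity in `[0, 1]`.
#' @export
monomer_similarity <- function(a, b) {
  if (!nzchar(a)) stop("monomer_similarity: operand 'a' is empty")
  if (!nzchar(b)) stop("monomer_similarity: operand 'b' is empty")
  a <- toupper(a); b <- toupper(b)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- cpp_nw_align(a, b)
  aln$matches / min(nchar(a), nchar(b))
}

#' Non-overlapping local alignment hits of a query in a region
#'
#' Greedy Smith-Waterman tiling: the best local hit is recorded, its target
#' interval is masked, and the search repeats until no hit reaches
#' `min_score`. Identity is matched bases over alignment columns.
#'
#' @param query Query sequence (character string).
#' @param region Target region sequence.
#' @param min_score Minimum local alignment score to keep a hit.
#' @param max_hits Safety cap on the number of hits.
#' @return data.frame with columns qstart, qend, tstart, tend, score,
#'   matches, length, identity (coordinates 1-based, closed).
#' @export
local_hits <- function(query, region, min_score = 30, max_hits = 10000) {
  h <- cpp_sw_hits(toupper(query), toupper(region), as.integer(min_score),
                   as.integer(max_hits))
  h$identity <- ifelse(h$length > 0, h$matches / h$length, 0)
  h[order(h$tstart), , drop = FALSE]
}

#' Ungapped local alignments between two long sequences
#'
#' Seed-and-merge aligner for substitution-diverged sequence pairs: exact
#' k-mer seeds are merged along diagonals into ungapped blocks. Both strands
#' are searched; minus-strand blocks report target coordinates on the forward
#' strand with `strand == "-"`.
#'
#' @param query,target Character strings.
#' @param k Seed length.
#' @param max_gap Maximum seed spacing merged into one block (bp).
#' @param max_occ Seeds occurring more often than this in the target are
#'   ignored (suppresses satellite arrays).
#' @param min_len Minimum block length (bp).
#' @param min_ident Minimum block identity.
#' @param both_strands Also search the reverse complement of the target.
#' @return data.frame of blocks: qstart, qend, tstart, tend, strand, length,
#'   matches, identity, score (score = 2*matches - length, the +1/-1 ungapped
#'   score).
#' @export
genome_local_alignments <- function(query, target, k = 15, max_gap = 400,
                                    max_occ = 20, min_len = 100,
                                    min_ident = 0.75, both_strands = TRUE) {
  fw <- cpp_seed_blocks(toupper(query), toupper(target), as.integer(k),
                        as.integer(max_gap), as.integer(max_occ),
                        as.integer(min_len), min_ident)
  fw <- as.data.frame(fw)
  if (nrow(fw)) fw$strand <- "+"
  out <- fw
  if (both_strands) {
    tl <- nchar(target)
    rv <- cpp_seed_blocks(toupper(query), revcomp(target), as.integer(k),
                          as.integer(max_gap), as.integer(max_occ),
                          as.integer(min_len), min_ident)
    rv <- as.data.frame(rv)
    if (nrow(rv)) {
      ts <- tl - rv$tend + 1
      te <- tl - rv$tstart + 1
      rv$tstart <- ts
      rv$tend <- te
      rv$strand <- "-"
      out <- rbind(fw, rv)
    }
  }
  if (!nrow(out)) {
    return(data.frame(qstart = integer(), qend = integer(), tstart = integer(),
                      tend = integer(), strand = character(), length = integer(),
                      matches = integer(), identity = numeric(),
                      score = numeric()))
  }
  out$score <- 2 * out$matches - out$length
  out[order(out$qstart), c("qstart", "qend", "tstart", "tend", "strand",
                           "length", "matches", "identity", "score")]
}

#' Best mapping position of a probe sequence on a set of chromosomes
#'
#' Convenience wrapper used for flank mapping and orientation transfer: the
#' probe is aligned against every chromosome and the block with the most
#' matched bases wins.
#'
#' @param probe Character string.
#' @param chromosomes Named character vector of chromosome sequences.
#' @param min_frac Minimum fraction of the probe that must be covered by the
#'   best block for a mapping to be reported.
#' @param ... Passed to [genome_local_alignments()].
#' @return One-row data.frame (chromosome, qstart, qend, tstart, tend, strand,
#'   matches, identity) or NULL if nothing maps.
#' @export
map_probe <- function(probe, chromosomes, min_frac = 0.25, ...) {
  best <- NULL
  for (chrom in names(chromosomes)) {
    al <- genome_local_alignments(probe, chromosomes[[chrom]], ...)
    if (!nrow(al)) next
    al <- al[which.max(al$matches), , drop = FALSE]
    if (is.null(best) || al$matches > best$matches) {
      best <- cbind(chromosome = chrom, al)
    }
  }
  if (is.null(best)) return(NULL)
  if (best$matches < min_frac * nchar(probe)) return(NULL)
  best
}
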