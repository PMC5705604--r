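# File-format interfaces: FASTA via Biostrings, BED (0-based half-open),
# plain TSV tables, Newick trees via ape.

#' Write a trio of genomes as FASTA
#'
#' One file per strain, one record per chromosome, IDs `<strain>_chr<N>`.
#'
#' @param genomes `genomes` element from [generate_trio()].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_trio_fasta <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (st in names(genomes)) {
    x <- Biostrings::DNAStringSet(unlist(genomes[[st]]))
    names(x) <- paste0(st, "_", names(genomes[[st]]))
    p <- file.path(dir, paste0(st, ".fasta"))
    Biostrings::writeXStringSet(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a genome FASTA into a named list of chromosome strings
#' @param path FASTA file.
#' @return Named list of character strings.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.list(as.character(x)), names(x))
}

#' Write 1-based closed intervals as BED (0-based half-open)
#'
#' @param df data.frame with columns chromosome, start, end and optionally
#'   name (class labels), score, strand.
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chromosome, start = df$start - 1, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read BED into 1-based closed intervals
#' @param path BED file.
#' @return data.frame with chromosome, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(x)[seq_len(min(6, ncol(x)))] <-
    c("chromosome", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(x)))]
  x$start <- x$start + 1
  x
}

#' Write a data.frame as a TSV with header
#' @param df data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path Input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Export a dendrogram (hclust) as a Newick string
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param hc An `hclust` object.
#' @return Newick string.
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
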