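# Spectrum-kernel SVM discrimination of hypo- vs hypermethylated domain
# sequence composition.

# Sparse row-normalized spectrum matrix for a set of sequences.
spectra_matrix <- function(seqs, k) {
  cl <- cpp_kmer_counts(toupper(seqs), as.integer(k))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in seq_along(cl)) {
    idx <- cl[[s]]$index
    if (!length(idx)) stop("sequence ", s, " has no valid k-mer")
    v <- as.numeric(cl[[s]]$count)
    v <- v / sqrt(sum(v^2))
    ii <- c(ii, rep.int(s, length(idx)))
    jj <- c(jj, idx)
    xx <- c(xx, v)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(cl), 4^k))
}

# Cut sequences into non-overlapping windows; tails shorter than the window
# are dropped.
cut_windows <- function(seqs, window = 200L, chrom = NULL) {
  out <- character(0); src <- integer(0)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    nw <- L %/% window
    if (nw == 0) next
    starts <- (seq_len(nw) - 1) * window + 1
    out <- c(out, substring(seqs[i], starts, starts + window - 1))
    src <- c(src, rep.int(i, nw))
  }
  list(windows = out, source = src)
}

#' Spectrum-kernel SVM discrimination of methylation domain classes
#'
#' Sequences of the two classes are divided into 200-bp non-overlapping
#' windows (shorter tails dropped) and classified by a support-vector
#' machine with the k-spectrum kernel (precomputed kernel matrix, C = 1).
#' Mode `"cv5"` runs a stratified five-fold cross-validation and reports the
#' mean accuracy; mode `"loco"` (leave-one-chromosome-out) trains on all but
#' one chromosome and tests on the held-out one, per chromosome.
#'
#' @param hypo_seqs,hyper_seqs Character vectors of domain sequences.
#' @param k Spectrum word length.
#' @param mode `"cv5"` or `"loco"`.
#' @param window Window length (bp).
#' @param C SVM cost parameter.
#' @param seed Fold-assignment seed.
#' @param hypo_chrom,hyper_chrom Chromosome of each sequence (required for
#'   `"loco"`).
#' @return List: `accuracy` (mean), `per_fold` (named vector), `n_windows`
#'   (per class), `mode`, `seed`.
#' @export
svm_discriminate <- function(hypo_seqs, hyper_seqs, k = 8L,
                             mode = c("cv5", "loco"), window = 200L, C = 1,
                             seed = 1L, hypo_chrom = NULL, hyper_chrom = NULL) {
  mode <- match.arg(mode)
  wh <- cut_windows(hypo_seqs, window)
  wy <- cut_windows(hyper_seqs, window)
  if (!length(wh$windows) || !length(wy$windows))
    stop("a class has no window of length ", window)
  X <- spectra_matrix(c(wh$windows, wy$windows), k)
  y <- factor(c(rep("hypo", length(wh$windows)),
                rep("hyper", length(wy$windows))))
  K <- as.matrix(Matrix::tcrossprod(X))
  fit_predict <- function(train, test) {
    Ktr <- K[train, train, drop = FALSE]
    m <- kernlab::ksvm(kernlab::as.kernelMatrix(Ktr), y[train], C = C,
                       type = "C-svc")
    sv <- kernlab::SVindex(m)
    Kte <- K[test, train[sv], drop = FALSE]
    pred <- kernlab::predict(m, kernlab::as.kernelMatrix(Kte))
    mean(pred == y[test])
  }
  if (mode == "cv5") {
    if (min(table(y)) < 5)
      stop("each class needs at least 5 windows for five-fold CV")
    set.seed(seed)
    folds <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(1:5, length(idx)))
    }
    acc <- vapply(1:5, function(f)
      fit_predict(which(folds != f), which(folds == f)), numeric(1))
    names(acc) <- paste0("fold", 1:5)
  } else {
    if (is.null(hypo_chrom) || is.null(hyper_chrom))
      stop("loco mode needs hypo_chrom and hyper_chrom")
    chrom <- c(hypo_chrom[wh$source], hyper_chrom[wy$source])
    chroms <- unique(chrom)
    if (length(chroms) < 2) stop("loco mode needs at least 2 chromosomes")
    acc <- vapply(chroms, function(ch)
      fit_predict(which(chrom != ch), which(chrom == ch)), numeric(1))
    names(acc) <- chroms
  }
  list(accuracy = mean(acc), per_fold = acc,
       n_windows = c(hypo = length(wh$windows), hyper = length(wy$windows)),
       mode = mode, seed = seed)
}
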