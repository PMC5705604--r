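# CpG calling, coverage filtering, segmentation, concordance, spectra,
# UPGMA and the methylation-domain phylogeny.

test_that("strict-majority calling handles ties and unit coverage", {
  p <- data.frame(chromosome = "c", pos = 1:3,
                  meth_count = c(3, 2, 1), total_count = c(4, 4, 1))
  calls <- call_cpg(p)
  expect_equal(calls$state, c("methylated", "unmethylated", "methylated"))
  expect_equal(nrow(call_cpg(data.frame(chromosome = "c", pos = 1,
                                        meth_count = 0, total_count = 0))), 0)
})

test_that("coverage filter bounds are inclusive at 2 and 9", {
  p <- data.frame(chromosome = "c", pos = 1:4, meth_count = 0,
                  total_count = c(1, 2, 9, 10))
  kept <- filter_for_concordance(call_cpg(p))
  expect_equal(kept$total_count, c(2, 9))
  expect_equal(attr(kept, "dropped"), 2)
})

test_that("segmentation enforces the 40-CpG minimum", {
  mk <- function(n, state) data.frame(chromosome = "c",
                                      pos = seq_len(n) * 10, state = state)
  expect_equal(nrow(segment_regions(mk(40, "unmethylated"))), 1)
  expect_equal(segment_regions(mk(40, "unmethylated"))$status, "hypo")
  expect_equal(nrow(segment_regions(mk(39, "unmethylated"))), 0)
})

test_that("segmentation tolerates bounded interruptions", {
  st <- c(rep("unmethylated", 50), "methylated", rep("unmethylated", 50))
  calls <- data.frame(chromosome = "c", pos = seq_along(st) * 10, state = st)
  seg <- segment_regions(calls, max_interruptions = 2)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_cpgs, 100)
  expect_equal(c(seg$start, seg$end), c(10, 1010))
  # three consecutive interruptions break the run
  st2 <- c(rep("unmethylated", 50), rep("methylated", 3),
           rep("unmethylated", 50))
  seg2 <- segment_regions(data.frame(chromosome = "c",
                                     pos = seq_along(st2) * 10, state = st2),
                          max_interruptions = 2)
  expect_equal(seg2$n_cpgs, c(50, 50))
  expect_error(segment_regions(calls[c(2, 1), ]), "sorted")
})

test_that("segmented regions never overlap and satisfy the minimum", {
  set.seed(51)
  for (i in 1:20) {
    # blocky state tracks with occasional single-call flips
    blocks <- sample(10:120, 12, TRUE)
    st <- unlist(mapply(rep, rep(c("methylated", "unmethylated"), 6), blocks))
    flip <- runif(length(st)) < 0.02
    st[flip] <- ifelse(st[flip] == "methylated", "unmethylated", "methylated")
    seg <- segment_regions(data.frame(chromosome = "c",
                                      pos = cumsum(sample(5:50, length(st), TRUE)),
                                      state = st))
    expect_true(all(seg$n_cpgs >= 40))
    if (nrow(seg) >= 2)
      expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
  }
})

test_that("concordance is exact on noiseless tracks and tracks planted error", {
  set.seed(52)
  pos <- sort(sample(1e5, 2000))
  truth_state <- ifelse(pos < 5e4, "unmethylated", "methylated")
  regions <- data.frame(chromosome = "c", start = c(1, 5e4 + 1),
                        end = c(5e4, 1e5), status = c("hypo", "hyper"))
  bis <- data.frame(chromosome = "c", pos = pos, state = truth_state)
  cc <- concordance(regions, bis)
  expect_equal(cc$pct_unmeth_agree, 100)
  expect_equal(cc$pct_meth_agree, 100)
  flip <- runif(length(pos)) < 0.1
  noisy <- ifelse(flip, ifelse(truth_state == "methylated", "unmethylated",
                               "methylated"), truth_state)
  cc2 <- concordance(regions, data.frame(chromosome = "c", pos = pos,
                                         state = noisy))
  expect_equal(cc2$pct_unmeth_agree, 90, tolerance = 0.05)
  expect_equal(cc2$pct_meth_agree, 90, tolerance = 0.05)
  expect_error(concordance(regions, data.frame(chromosome = "other", pos = 1,
                                               state = "methylated")),
               "no filtered")
})

test_that("average methylation ratio is the arithmetic of its counts", {
  expect_equal(average_methylation_ratio(1, 1), 50)
  expect_equal(average_methylation_ratio(19103, 7356),
               100 * 19103 / (19103 + 7356))  # 72.2, from the printed counts
  expect_equal(average_methylation_ratio(0, 10), 0)
  expect_error(average_methylation_ratio(0, 0), "denominator")
})

test_that("k-mer spectra are unit-norm with brute-force counts", {
  s <- kmer_spectrum("AAAAAAAAAA", k = 8)
  expect_equal(length(s$index), 1)
  expect_equal(s$value, 1)
  s2 <- kmer_spectrum("ACGTACGTACGT", k = 2)
  # brute-force 2-mer counting
  cnt <- table(substring("ACGTACGTACGT", 1:11, 2:12))
  v <- as.numeric(cnt) / sqrt(sum(as.numeric(cnt)^2))
  expect_equal(sort(s2$value), sort(v))
  expect_equal(sum(s2$value^2), 1, tolerance = 1e-12)
  expect_error(kmer_spectrum("ACG", k = 8), "no valid k-mer")
  # non-ACGT windows are skipped
  s3 <- kmer_spectrum("AANAA", k = 2)
  expect_equal(length(s3$index), 1)  # only AA windows survive
})

test_that("spectrum distance follows the unit-norm kernel identity", {
  a <- kmer_spectrum("ACGTACGTACGTACGT", k = 4)
  expect_equal(spectrum_distance(a, a), 0)
  b <- kmer_spectrum(strrep("A", 20), k = 4)
  c_ <- kmer_spectrum(strrep("C", 20), k = 4)
  expect_equal(spectrum_distance(b, c_), sqrt(2))
  expect_error(spectrum_distance(a, kmer_spectrum("ACGTACGT", k = 3)),
               "different k")
  set.seed(53)
  for (i in 1:25) {
    x <- kmer_spectrum(rand_seq(200), k = 8)
    y <- kmer_spectrum(rand_seq(200), k = 8)
    # dense Euclidean distance as the oracle
    ix <- union(x$index, y$index)
    xv <- setNames(rep(0, length(ix)), ix); xv[as.character(x$index)] <- x$value
    yv <- setNames(rep(0, length(ix)), ix); yv[as.character(y$index)] <- y$value
    expect_equal(spectrum_distance(x, y), sqrt(sum((xv - yv)^2)),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA reproduces the average-linkage oracle and is ultrametric", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc <- upgma(d)
  expect_equal(hc$height, 0.2)
  set.seed(54)
  for (i in 1:50) {
    m <- matrix(runif(16, 0.1, 1), 4, 4)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:4], letters[1:4])
    hc <- upgma(m)
    o <- oracle_upgma_heights(m)
    expect_equal(hc$merge, o$merge)
    expect_equal(hc$height, o$height, tolerance = 1e-12)
    expect_true(ape::is.ultrametric(ape::as.phylo(hc), tol = 1e-9))
  }
  # duplicate points merge first at height zero
  d4 <- matrix(0.5, 3, 3); diag(d4) <- 0; d4[1, 2] <- d4[2, 1] <- 0
  dimnames(d4) <- list(c("x", "y", "z"), c("x", "y", "z"))
  hc4 <- upgma(d4)
  expect_equal(hc4$height[1], 0)
  expect_equal(sort(hc4$merge[1, ]), c(-2, -1))
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
})

test_that("verbatim-copied regions cluster by chromosome before strain", {
  set.seed(55)
  seqs <- replicate(3, rand_seq(800))
  regions <- data.frame(
    strain = rep(c("strainA", "strainB"), each = 3),
    chromosome = rep(paste0("chr", 1:3), 2),
    status = "hypo",
    sequence = rep(seqs, 2))
  ph <- methylation_phylogeny(regions, k = 8)
  cop <- as.matrix(cophenetic(ph$tree))
  labs <- ph$tree$labels
  for (ch in paste0("chr", 1:3)) {
    same <- grep(ch, labs)
    expect_equal(cop[same[1], same[2]], 0)
  }
  expect_error(methylation_phylogeny(regions[1, , drop = FALSE]), "at least 2")
})

test_that("spectrum SVM separates planted composition and not null data", {
  set.seed(56)
  hypo <- replicate(8, random_dna(1000, prob = c(0.17, 0.33, 0.33, 0.17)))
  hyper <- replicate(8, strrep(mutate_sequence(rand_seq(171), 0.05), 6))
  res <- svm_discriminate(hypo, hyper, k = 8, mode = "cv5", seed = 1)
  expect_gte(res$accuracy, 0.9)
  # null: both classes from the same source
  all_null <- replicate(16, rand_seq(1000))
  res0 <- svm_discriminate(all_null[1:8], all_null[9:16], k = 8, mode = "cv5",
                           seed = 1)
  expect_gte(res0$accuracy, 0.25)
  expect_lte(res0$accuracy, 0.75)
  expect_error(svm_discriminate(rand_seq(199), hyper, k = 8), "window")
})

test_that("leave-one-chromosome-out SVM reports per-chromosome accuracy", {
  set.seed(57)
  hypo <- replicate(6, random_dna(800, prob = c(0.17, 0.33, 0.33, 0.17)))
  hyper <- replicate(6, rand_seq(800))
  res <- svm_discriminate(hypo, hyper, k = 6, mode = "loco",
                          hypo_chrom = rep(paste0("chr", 1:3), 2),
                          hyper_chrom = rep(paste0("chr", 1:3), 2))
  expect_equal(sort(names(res$per_fold)), paste0("chr", 1:3))
  expect_gte(res$accuracy, 0.8)
})

test_that("region length follows 1-based closed arithmetic", {
  expect_equal(region_length(10434969, 10459620), 24652L)
  expect_equal(region_length(5, 5), 1L)
})
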