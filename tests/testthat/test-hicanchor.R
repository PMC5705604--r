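# Marker-based contig ordering, clone-end linking, naive-Bayes Hi-C
# classification and contact-peak placement.

test_that("contigs are ordered by median marker cM", {
  markers <- data.frame(marker = paste0("m", 1:3), chromosome = "chr1",
                        cm = c(20, 0, 10),
                        contig = c("c3", "c1", "c2"),
                        offset = c(100, 100, 100))
  contigs <- data.frame(contig = paste0("c", 1:3), length = 10000)
  res <- order_contigs_by_markers(markers, contigs)
  expect_equal(res$map$contig, c("c1", "c2", "c3"))
  expect_equal(res$map$position, 1:3)
  expect_error(order_contigs_by_markers(
    data.frame(marker = "x", chromosome = "chr1", cm = 1, contig = "nope",
               offset = 1), contigs), "unknown contig")
})

test_that("a two-chromosome contig is split at the marker-block midpoint", {
  markers <- data.frame(marker = paste0("m", 1:4),
                        chromosome = c("chr1", "chr1", "chr2", "chr2"),
                        cm = c(1, 2, 5, 6),
                        contig = "c1",
                        offset = c(1000, 2000, 8000, 9000))
  contigs <- data.frame(contig = "c1", length = 10000)
  res <- order_contigs_by_markers(markers, contigs)
  expect_equal(res$misassembled$split_at, 5000)
  expect_setequal(res$map$contig, c("c1.1", "c1.2"))
  expect_setequal(res$map$chromosome, c("chr1", "chr2"))
})

test_that("cM ties order by contig id and stay unoriented", {
  markers <- data.frame(marker = paste0("m", 1:2), chromosome = "chr1",
                        cm = c(3, 3), contig = c("cB", "cA"),
                        offset = c(10, 10))
  contigs <- data.frame(contig = c("cA", "cB", "cZ"), length = 1000)
  res <- order_contigs_by_markers(markers, contigs)
  expect_equal(res$map$contig, c("cA", "cB"))
  expect_true(all(res$map$orientation == "unoriented"))
  expect_equal(res$orphans, "cZ")
})

test_that("clone-end linking honors type bounds and the two-pair rule", {
  map <- data.frame(chromosome = "chr1", position = 1, contig = "anchor",
                    orientation = "+", source = "marker")
  contigs <- data.frame(contig = c("anchor", "orphan"),
                        length = c(200000, 80000))
  ep2 <- data.frame(contig1 = "anchor", pos1 = c(195000, 192000),
                    contig2 = "orphan", pos2 = c(10000, 12000))
  res <- link_by_clone_ends(map, ep2, "fosmid", contigs)
  expect_equal(res$joined$added, "orphan")
  expect_true("orphan" %in% res$map$contig)
  # a pair 60 kb from the end does not qualify for fosmids
  ep_far <- data.frame(contig1 = "anchor", pos1 = c(100000, 100001),
                       contig2 = "orphan", pos2 = c(10000, 10001))
  res2 <- link_by_clone_ends(map, ep_far, "fosmid", contigs)
  expect_null(res2$joined)
  # but it does for BACs (150 kb bound)
  res3 <- link_by_clone_ends(map, ep_far, "BAC", contigs)
  expect_equal(res3$joined$added, "orphan")
  # a single qualifying pair is not enough
  res4 <- link_by_clone_ends(map, ep2[1, ], "fosmid", contigs)
  expect_null(res4$joined)
  expect_error(link_by_clone_ends(map, ep2, "cosmid", contigs), "clone type")
})

test_that("naive-Bayes priors follow training contig counts", {
  set.seed(61)
  chroms <- paste0("chr", 1:3)
  mk <- function(ch, n) t(vapply(seq_len(n), function(i) {
    mu <- c(chr1 = 5, chr2 = 5, chr3 = 5); mu[ch] <- 200
    rpois(3, mu)
  }, numeric(3)))
  X <- rbind(mk("chr1", 10), mk("chr2", 20), mk("chr3", 10))
  colnames(X) <- chroms
  y <- rep(chroms, c(10, 20, 10))
  m <- fit_nb(X, y)
  expect_equal(unname(m$prior["chr2"] / m$prior["chr1"]), 2)
  expect_equal(sum(m$prior), 1)
  expect_error(fit_nb(X[1:10, ], y[1:10]), "chr2")
})

test_that("posteriors normalize, follow likelihood dominance, and default to the prior", {
  set.seed(62)
  chroms <- paste0("chr", 1:3)
  X <- matrix(rpois(90, 10), 30, 3, dimnames = list(NULL, chroms))
  for (i in 1:30) X[i, (i - 1) %% 3 + 1] <- 300
  y <- chroms[(0:29) %% 3 + 1]
  m <- fit_nb(X, y)
  r <- classify_orphan(m, c(10, 10, 400))
  expect_equal(r$chromosome, "chr3")
  expect_equal(sum(r$posterior), 1, tolerance = 1e-12)
  r0 <- classify_orphan(m, c(0, 0, 0))
  expect_equal(unname(r0$posterior), unname(m$prior), tolerance = 1e-12)
  expect_error(classify_orphan(m, c(-1, 0, 0)), "negative")
  expect_error(classify_orphan(m, c(1, 2)), "length")
})

test_that("class profiles converge toward generator rates with sample size", {
  set.seed(63)
  chroms <- paste0("chr", 1:3)
  rates <- list(chr1 = c(0.8, 0.15, 0.05), chr2 = c(0.1, 0.8, 0.1),
                chr3 = c(0.05, 0.15, 0.8))
  draw <- function(n) {
    X <- do.call(rbind, lapply(chroms, function(ch)
      t(vapply(seq_len(n), function(i) rpois(3, 500 * rates[[ch]]),
               numeric(3)))))
    colnames(X) <- chroms
    list(X = X, y = rep(chroms, each = n))
  }
  d50 <- draw(50); d500 <- draw(500)
  m50 <- fit_nb(d50$X, d50$y)
  m500 <- fit_nb(d500$X, d500$y)
  err50 <- max(abs(m50$profile["chr1", ] - rates$chr1))
  err500 <- max(abs(m500$profile["chr1", ] - rates$chr1))
  expect_lt(err500, err50 + 0.005)
  expect_lt(err500, 0.01)
})

test_that("contact-peak placement finds spikes and flags flat tracks", {
  counts <- rep(0, 100); counts[40] <- 50
  r <- locate_orphan(counts, seq(500, by = 1000, length.out = 100),
                     window = 5000)
  # every window containing the spike ties; the leftmost wins, so the
  # placement is within half a window of the spike
  expect_lte(abs(r$position - 39500), 2500)
  expect_warning(locate_orphan(rep(1, 50), seq(500, by = 1000, length.out = 50)),
                 "flat")
  expect_error(locate_orphan(integer(0), numeric(0)), "empty")
})

test_that("map export joins contigs with N gaps and honors orientation", {
  map <- data.frame(chromosome = "chr1", position = 1:2,
                    contig = c("c1", "c2"), orientation = c("+", "-"),
                    source = "marker")
  seqs <- list(c1 = "ACGTACGT", c2 = "AAAACCCC")
  ex <- export_chromosome_sequences(map, seqs, gap = 5)
  expect_equal(ex$chr1, paste0("ACGTACGT", strrep("N", 5), "GGGGTTTT"))
})

test_that("orientation transfers from the best cross-strain match", {
  set.seed(64)
  contig <- rand_seq(3000)
  counter <- revcomp(contig)
  o <- orient_by_best_match(contig, list(c1 = counter),
                            c(c1 = "+"), min_len = 500)
  expect_equal(o, "-")
  # counterpart itself flagged "-" in its map flips the call back
  o2 <- orient_by_best_match(contig, list(c1 = counter),
                             c(c1 = "-"), min_len = 500)
  expect_equal(o2, "+")
  o3 <- orient_by_best_match(contig, list(c1 = rand_seq(3000)),
                             c(c1 = "+"), min_len = 500)
  expect_equal(o3, "unoriented")
})
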