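# Reciprocal-best pairing, chain DP with its brute-force oracle, SV calling
# from chain gaps, mechanism classification and outgroup polarization.

test_that("reciprocal best pairing keeps mutual bests and drops ties", {
  sc <- data.frame(a = c("a1", "a1", "a2", "a2"),
                   b = c("b1", "b2", "b1", "b2"),
                   score = c(10, 2, 3, 9))
  p <- reciprocal_best_pairs(sc)
  expect_equal(nrow(p), 2)
  expect_setequal(paste(p$a, p$b), c("a1 b1", "a2 b2"))
  # non-reciprocal: a1 -> b1 but b1 -> a2
  sc2 <- data.frame(a = c("a1", "a2"), b = c("b1", "b1"), score = c(5, 8))
  p2 <- reciprocal_best_pairs(sc2)
  expect_false("a1" %in% p2$a)
  expect_warning(reciprocal_best_pairs(
    data.frame(a = c("a1", "a1"), b = c("b1", "b2"), score = c(5, 5))),
    "tied")
})

test_that("chain DP equals the exhaustive subset oracle", {
  al1 <- data.frame(qstart = 1, qend = 100, tstart = 1, tend = 100,
                    strand = "+", score = 50)
  ch <- chain_alignments(al1)
  expect_equal(nrow(ch$chain), 1)
  expect_equal(ch$score, 50)
  # two crossing alignments: the higher-score one wins alone
  cross <- data.frame(qstart = c(1, 200), qend = c(100, 300),
                      tstart = c(500, 1), tend = c(600, 100),
                      strand = "+", score = c(30, 80))
  ch2 <- chain_alignments(cross)
  expect_equal(nrow(ch2$chain), 1)
  expect_equal(ch2$chain$score, 80)
  set.seed(71)
  for (i in 1:50) {
    al <- rand_chain_instance(sample(3:8, 1))
    ch <- chain_alignments(al)
    expect_equal(ch$score, oracle_best_chain_score(al), tolerance = 1e-9)
  }
})

test_that("chaining absorbs small block overlaps by trimming", {
  al <- data.frame(qstart = c(1, 99), qend = c(100, 200),
                   tstart = c(1, 99), tend = c(100, 200),
                   strand = "+", score = c(100, 100))
  ch <- chain_alignments(al)
  expect_equal(nrow(ch$chain), 2)
  expect_true(ch$chain$qstart[2] > ch$chain$qend[1])
  expect_true(ch$chain$tstart[2] > ch$chain$tend[1])
})

test_that("SV candidates come from asymmetric chain gaps only", {
  mk_chain <- function(gq, gt) {
    al <- data.frame(qstart = c(1, 1001 + gq), qend = c(1000, 2000 + gq),
                     tstart = c(1, 1001 + gt), tend = c(1000, 2000 + gt),
                     strand = "+", score = c(5000, 5000))
    chain_alignments(al)
  }
  ev <- call_svs(mk_chain(5000, 0))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$carrier, "query")
  expect_equal(ev$size, 5000)
  expect_equal(ev$size_class, "mid")
  expect_equal(nrow(call_svs(mk_chain(900, 0))), 0)
  big <- call_svs(mk_chain(60000, 0))
  expect_equal(big$size_class, "large")
  sym <- call_svs(mk_chain(3000, 3000))
  expect_equal(nrow(sym), 0)
})

test_that("planted inversions are called from strand-flipped sub-chains", {
  cfg <- tiny_config(seed = 72, n_insertions = 0, n_deletions = 0,
                     n_inversions = 1, tss_count = 0,
                     sv_size_range = c(8000, 12000))
  trio <- generate_trio(cfg)
  inv <- trio$truth$svs[trio$truth$svs$type == "inversion", ]
  found <- 0
  for (chrom in unique(inv$chromosome)) {
    cmp <- compare_chromosome_pair(trio$genomes$strainA[[chrom]],
                                   trio$genomes$strainB[[chrom]])
    found <- found + sum(cmp$events$type == "inversion")
  }
  expect_gte(found, 1)
})

test_that("mechanism classification keys on flank homology", {
  set.seed(73)
  repeatseq <- rand_seq(500)
  expect_equal(classify_mechanism(repeatseq, repeatseq), "NAHR")
  expect_equal(classify_mechanism(rand_seq(500), rand_seq(500)), "NHEJ")
  expect_equal(classify_mechanism(rand_seq(100), rand_seq(500)),
               "unclassified")
  # shared 60-bp cassette inside otherwise random flanks
  cassette <- rand_seq(60)
  l <- paste0(rand_seq(200), cassette, rand_seq(240))
  r <- paste0(rand_seq(300), cassette, rand_seq(140))
  expect_equal(classify_mechanism(l, r), "NAHR")
})

test_that("outgroup polarization separates insertions from deletions", {
  set.seed(74)
  anc <- rand_seq(30000)
  seg <- rand_seq(5000)
  # insertion into the carrier: outgroup lacks the segment
  noncarrier <- anc
  outg <- list(chrO = mutate_sequence(anc, 0.02))
  idx <- seed_index(outg)
  r <- polarize_with_outgroup(15000, noncarrier, idx, 5000)
  expect_equal(r$polarity, "insertion")
  expect_lt(abs(r$distance), 500)
  # deletion from the non-carrier: outgroup carries a homolog of the segment
  anc2 <- paste0(substr(anc, 1, 15000), seg, substr(anc, 15001, 30000))
  outg2 <- list(chrO = mutate_sequence(anc2, 0.02))
  r2 <- polarize_with_outgroup(15001, anc, seed_index(outg2), 5000)
  expect_equal(r2$polarity, "deletion")
  expect_equal(r2$distance, 5000, tolerance = 0.1)
  # unalignable flank
  r3 <- polarize_with_outgroup(15000, rand_seq(30000), idx, 5000)
  expect_equal(r3$polarity, "unclassified")
  # flank outside the sequence
  r4 <- polarize_with_outgroup(100, noncarrier, idx, 5000)
  expect_equal(r4$polarity, "unclassified")
})

test_that("self-comparison of a genome yields no events", {
  cfg <- tiny_config(seed = 75, n_insertions = 2, n_deletions = 2,
                     tss_count = 0)
  trio <- cached_trio("t75", cfg)
  for (chrom in names(trio$genomes$strainA)[1:2]) {
    cmp <- compare_chromosome_pair(trio$genomes$strainA[[chrom]],
                                   trio$genomes$strainA[[chrom]])
    expect_equal(nrow(cmp$events), 0)
  }
})

test_that("polarity is invariant under swapping the ingroup genomes", {
  cfg <- tiny_config(seed = 76, n_insertions = 3, n_deletions = 3,
                     tss_count = 0)
  trio <- cached_trio("t76", cfg)
  idx <- seed_index(trio$genomes$outgroup)
  strain_mask <- function(st) {
    m <- trio$truth$centromeres
    for (i in seq_len(nrow(m))) {
      m$start[i] <- anc_to_strain(trio$truth, st, m$chromosome[i], m$start[i])
      m$end[i] <- anc_to_strain(trio$truth, st, m$chromosome[i], m$end[i])
    }
    m
  }
  ab <- polarize_genome_events(trio$genomes$strainA, trio$genomes$strainB,
                               idx, "strainA", "strainB",
                               mask = strain_mask("strainA"))
  ba <- polarize_genome_events(trio$genomes$strainB, trio$genomes$strainA,
                               idx, "strainB", "strainA",
                               mask = strain_mask("strainB"))
  key <- function(e) {
    e <- e[e$type %in% c("insertion", "deletion"), ]
    sort(paste(e$type, e$strain, e$size))
  }
  expect_equal(key(ab), key(ba))
})

test_that("indel balance summarizes counts, lengths and the ratio", {
  ev <- data.frame(chromosome = "chr1",
                   type = c("insertion", "insertion", "deletion"),
                   strain = c("strainA", "strainB", "strainA"),
                   size = c(2000, 3000, 1500),
                   size_class = "mid", q_gap_start = 1, t_gap_start = 1,
                   distance = 0)
  s <- indel_balance_summary(ev)
  expect_equal(s$ratio, 2)
  expect_equal(sum(s$table$total_bp), 6500)
  empty <- indel_balance_summary(ev[0, ])
  expect_true(is.na(empty$ratio))
})
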