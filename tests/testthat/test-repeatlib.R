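# Monomer clustering, best-match association, rate comparison,
# representative scoring, satellite fraction, telomeres, positional
# classification and the Ward family tree.

test_that("identical monomers form one cluster with a representative", {
  mono <- data.frame(id = paste0("m", 1:20),
                     sequence = rep(strrep("ACGT", 40), 20))
  mc <- cluster_monomers(mono, threshold = 0.9)
  expect_equal(nrow(mc$clusters), 1)
  expect_equal(mc$clusters$size, 20)
  expect_false(is.na(mc$clusters$representative))
})

test_that("two distant families give exactly two clusters", {
  set.seed(31)
  fx <- rand_seq(160); fy <- rand_seq(160)
  # verify the families are mutually below threshold by exhaustive pairwise
  # similarity before asserting the clustering
  xs <- replicate(11, mutate_sequence(fx, 0.02))
  ys <- replicate(11, mutate_sequence(fy, 0.02))
  cross <- outer(seq_along(xs), seq_along(ys),
                 Vectorize(function(i, j) monomer_similarity(xs[i], ys[j])))
  expect_true(all(cross < 0.9))
  mc <- cluster_monomers(data.frame(id = paste0("m", 1:22),
                                    sequence = c(xs, ys)), threshold = 0.9)
  expect_equal(nrow(mc$clusters), 2)
  expect_equal(sort(mc$clusters$size), c(11, 11))
})

test_that("a cluster of exactly 10 members gets no representative", {
  mono <- data.frame(id = paste0("m", 1:10),
                     sequence = rep(strrep("ACGT", 40), 10))
  mc <- cluster_monomers(mono, threshold = 0.9)
  expect_equal(mc$clusters$size, 10)
  expect_true(is.na(mc$clusters$representative))
})

test_that("clustering partitions the input", {
  set.seed(32)
  mono <- data.frame(id = paste0("m", 1:30),
                     sequence = replicate(30, mutate_sequence(rand_seq(150), 0.1)))
  mc <- cluster_monomers(mono, threshold = 0.85)
  expect_setequal(mc$assignment$id, mono$id)
  expect_equal(sum(mc$clusters$size), 30)
  expect_true(all(table(mc$assignment$id) == 1))
})

make_cluster_set <- function(seqs) {
  # one >10-member cluster per provided sequence
  mono <- data.frame(id = paste0(seq_along(seqs), "_", "m",
                                 rep(1:11, each = length(seqs))),
                     sequence = rep(seqs, times = 11))
  cluster_monomers(mono, threshold = 0.9)
}

test_that("two single-cluster chromosomes are mutually best matches", {
  set.seed(33)
  s <- rand_seq(150)
  sets <- list(chrA = make_cluster_set(mutate_sequence(s, 0.02)),
               chrB = make_cluster_set(mutate_sequence(s, 0.02)))
  rec <- best_match_associations(sets, c(chrA = "acrocentric",
                                         chrB = "acrocentric"))
  expect_equal(nrow(rec), 2)
  expect_equal(rec$category, c("AcroAcro", "AcroAcro"))
  expect_equal(rec$similarity[1], rec$similarity[2])
  expect_equal(rec$distance, 1 - rec$similarity)
})

test_that("best-match graph equals the exhaustive argmax", {
  set.seed(34)
  base <- rand_seq(150)
  seqs <- c(chr1 = mutate_sequence(base, 0.05),
            chr2 = mutate_sequence(base, 0.25),
            chr3 = mutate_sequence(base, 0.45))
  sets <- lapply(seqs, make_cluster_set)
  classes <- c(chr1 = "acrocentric", chr2 = "acrocentric",
               chr3 = "non-acrocentric")
  rec <- best_match_associations(sets, classes)
  # brute-force pairwise similarity over representatives
  sim <- outer(names(seqs), names(seqs), Vectorize(function(i, j)
    if (i == j) NA_real_ else monomer_similarity(seqs[[i]], seqs[[j]])))
  dimnames(sim) <- list(names(seqs), names(seqs))
  for (i in seq_len(nrow(rec))) {
    a <- sub("#.*", "", rec$cluster_a[i])
    b <- sub("#.*", "", rec$cluster_b[i])
    expect_equal(b, names(which.max(sim[a, ])))
    expect_equal(rec$similarity[i], max(sim[a, ], na.rm = TRUE))
  }
  expect_equal(rec$category[rec$cluster_a == "chr1#1"], "AcroAcro")
})

test_that("group comparison p-value equals exact rank enumeration", {
  rec <- data.frame(cluster_a = letters[1:6], cluster_b = LETTERS[1:6],
                    similarity = c(0.5, 0.5, 0.5, 0.9, 0.9, 0.9),
                    distance = NA,
                    category = rep(c("NonAcroNonAcro", "AcroAcro"), each = 3))
  res <- compare_similarity_groups(rec)
  # independent enumeration over all choose(6, 3) = 20 rank assignments:
  # the observed rank sum (1.5+1.5+... = 6 with average ranks) is the unique
  # minimum achieved by 1 of 20 assignments... enumerate explicitly
  r <- rank(rec$similarity)
  w_obs <- sum(r[rec$category == "NonAcroNonAcro"])
  w_all <- apply(utils::combn(6, 3), 2, function(ix) sum(r[ix]))
  expect_equal(unname(res$p_values["vs_AcroAcro"]), mean(w_all <= w_obs))
  expect_error(compare_similarity_groups(rec[c(1, 4, 5), ]), "NonAcroNonAcro")
})

test_that("null group comparison is rarely significant", {
  set.seed(35)
  hits <- 0
  for (i in 1:40) {
    sim <- runif(24, 0.6, 0.9)
    rec <- data.frame(cluster_a = seq_len(24), cluster_b = seq_len(24),
                      similarity = sim, distance = 1 - sim,
                      category = rep(c("NonAcroNonAcro", "AcroAcro",
                                       "AcroNonAcro"), each = 8))
    p <- compare_similarity_groups(rec)$p_values["vs_AcroAcro"]
    if (p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 8)  # ~5% nominal, generous bound
})

test_that("representative score follows identity x length / query length", {
  set.seed(36)
  mono <- rand_seq(200)
  region1 <- paste0(rand_seq(100), mono, rand_seq(100))
  expect_equal(representative_score(mono, region1), 1.0)
  expect_equal(representative_score(mono, c(region1, region1)), 2.0)
  # one hit: 100 bp at 90% identity over a 200 bp monomer -> 0.45
  hit <- substr(mono, 1, 100)
  v <- strsplit(hit, "")[[1]]
  flip <- function(x) c(A = "C", C = "A", G = "T", T = "G")[[x]]
  for (p in seq(5, 95, by = 10)) v[p] <- flip(v[p])
  region2 <- paste0(rand_seq(120), paste(v, collapse = ""), rand_seq(120))
  expect_equal(representative_score(mono, region2, identity_floor = 0.7),
               0.45, tolerance = 0.01)
  expect_equal(representative_score(mono, "TTTTTTTTTT"), 0)
})

test_that("representative score is invariant to region order", {
  set.seed(37)
  mono <- rand_seq(150)
  regions <- replicate(3, paste0(rand_seq(50), mutate_sequence(mono, 0.1),
                                 rand_seq(50)))
  expect_equal(representative_score(mono, regions),
               representative_score(mono, rev(regions)))
})

test_that("satellite fraction applies strict read filters", {
  set.seed(38)
  mono <- rand_seq(171)
  pure <- strrep(mono, 10)
  reads <- data.frame(sequence = c(pure, pure), qv = c(20, 20))
  expect_equal(satellite_fraction(reads, mono), 1.0)
  # length exactly 1000 and low QV are both excluded
  r1000 <- substr(pure, 1, 1000)
  reads2 <- data.frame(sequence = c(r1000, pure, pure),
                       qv = c(20, 9, 20))
  expect_equal(satellite_fraction(reads2, mono), 1.0)
  expect_error(satellite_fraction(data.frame(sequence = r1000, qv = 20), mono),
               "no reads pass")
})

test_that("satellite fraction recovers a planted composition", {
  set.seed(39)
  mono <- rand_seq(171)
  reads <- data.frame(
    sequence = replicate(6, paste0(strrep(mono, 3), rand_seq(1197))),
    qv = 20)
  f <- satellite_fraction(reads, mono)
  expect_gt(f, 0.25); expect_lt(f, 0.35)
})

test_that("telomeric repeat arrays are found on both strands", {
  s <- paste0(strrep("TTAGGG", 10), rand_seq(100))
  tel <- find_telomeric_repeats(s)
  expect_equal(nrow(tel), 1)
  expect_equal(c(tel$start, tel$end), c(1, 60))
  expect_equal(tel$strand, "+")
  expect_equal(nrow(find_telomeric_repeats(rand_seq(50))), 0)
  s2 <- paste0(rand_seq(40), strrep("CCCTAA", 5), rand_seq(40))
  tel2 <- find_telomeric_repeats(s2)
  expect_equal(tel2$strand, "-")
  expect_equal(tel2$start, 41)
})

test_that("centromere positional classification uses a closed boundary", {
  expect_equal(classify_centromere_position(9000, 11000, 1e6), "acrocentric")
  expect_equal(classify_centromere_position(499000, 501000, 1e6),
               "non-acrocentric")
  # midpoint exactly at 15% of length
  expect_equal(classify_centromere_position(150000, 150000, 1e6),
               "acrocentric")
  expect_equal(classify_centromere_position(150001, 150001, 1e6),
               "non-acrocentric")
  expect_error(classify_centromere_position(10, 2e6, 1e6), "outside")
})

test_that("family tree matches naive Ward agglomeration", {
  set.seed(40)
  base <- rand_seq(150)
  base2 <- mutate_sequence(base, 0.4)
  reps <- data.frame(id = paste0("r", 1:4),
                     sequence = c(mutate_sequence(base, 0.02),
                                  mutate_sequence(base, 0.02),
                                  mutate_sequence(base2, 0.02),
                                  mutate_sequence(base2, 0.02)))
  ft <- family_tree(reps)
  grp <- cut_family_tree(ft, 2)
  expect_equal(grp[["r1"]], grp[["r2"]])
  expect_equal(grp[["r3"]], grp[["r4"]])
  expect_true(grp[["r1"]] != grp[["r3"]])
  # 3-leaf exact check against the Lance-Williams oracle
  reps3 <- reps[1:3, ]
  ft3 <- family_tree(reps3)
  o <- oracle_ward(ft3$dist)
  expect_equal(ft3$tree$merge, o$merge)
  expect_equal(ft3$tree$height, o$height, tolerance = 1e-12)
  # two items merge at their distance
  ft2 <- family_tree(reps[c(1, 3), ])
  expect_equal(ft2$tree$height, ft2$dist[1, 2])
  expect_error(family_tree(reps[1, , drop = FALSE]), "at least 2")
})

test_that("monomer decomposition tiles a small array", {
  set.seed(41)
  mono <- rand_seq(171)
  arr <- strrep(mono, 8)
  dec <- decompose_monomers(arr, mono)
  expect_equal(nrow(dec), 8)
  expect_true(all(dec$identity == 1))
  expect_equal(sum(dec$end - dec$start + 1), nchar(arr))
})
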