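# Synthetic trio generator: configuration contracts, limit behavior,
# bookkeeping conservation, track generators.

test_that("invalid configurations are rejected with the field named", {
  expect_error(trio_config(chrom_length = -1), "chrom_length")
  expect_error(trio_config(div_rate_acro = 0.9), "div_rate_acro")
  expect_error(trio_config(array_length_range = c(2e6, 3e6),
                           chrom_length = 1e6), "array_length_range")
  expect_error(trio_config(acro_fraction = 1.4), "acro_fraction")
  expect_error(trio_config(hic_depth = 0), "hic_depth")
})

test_that("zero rates reproduce the ancestor in all three strains", {
  cfg <- tiny_config(seed = 21, div_rate_acro = 0, div_rate_nonacro = 0,
                     background_divergence = 0, n_insertions = 0,
                     n_deletions = 0, tss_count = 0, exchange_rate = 0)
  trio <- generate_trio(cfg)
  expect_identical(trio$genomes$strainA, trio$genomes$strainB)
  expect_identical(trio$genomes$strainA, trio$genomes$outgroup)
})

test_that("identical seeds give byte-identical FASTA outputs", {
  cfg <- tiny_config(seed = 22)
  d1 <- file.path(tempdir(), "trio1"); d2 <- file.path(tempdir(), "trio2")
  write_trio_fasta(generate_trio(cfg)$genomes, d1)
  write_trio_fasta(generate_trio(cfg)$genomes, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e8),
                     readBin(file.path(d2, f), "raw", 1e8))
  }
})

test_that("planted SV bookkeeping is conserved and centromeres stay clear", {
  cfg <- tiny_config(seed = 23, n_insertions = 5, n_deletions = 5,
                     tss_count = 0)
  trio <- generate_trio(cfg)
  sv <- trio$truth$svs
  expect_equal(nrow(sv), 20)  # 5 + 5 per ingroup strain
  expect_equal(sum(sv$type == "insertion"), 10)
  expect_equal(sum(sv$type == "deletion"), 10)
  cen <- trio$truth$centromeres
  for (i in seq_len(nrow(sv))) {
    cr <- cen[cen$chromosome == sv$chromosome[i], ]
    hi <- sv$anc_pos[i] + ifelse(sv$type[i] == "deletion", sv$size[i] - 1, 0)
    expect_true(hi < cr$start || sv$anc_pos[i] > cr$end)
  }
})

test_that("array layout arithmetic gives floor(length/monomer) full copies", {
  cfg <- tiny_config(seed = 24, array_length_range = c(20000, 20000),
                     monomer_length = 171)
  trio <- generate_trio(cfg)
  expect_true(all(trio$truth$monomers$n_full == 20000 %/% 171))  # 116
})

test_that("extreme Hi-C decay concentrates contacts on the true chromosome", {
  cfg <- tiny_config(seed = 25, hic_decay = 1)  # decay length 1 bp
  trio <- generate_trio(cfg)
  hic <- generate_hic_contacts(trio$truth, cfg)
  own <- vapply(seq_len(nrow(hic$contacts)), function(i)
    hic$contacts[i, hic$truth_chromosome[i]] / max(1, sum(hic$contacts[i, ])),
    numeric(1))
  expect_true(all(own > 0.999))
})

test_that("zero Hi-C decay spreads contacts proportionally to chromosome length", {
  cfg <- tiny_config(seed = 26, hic_decay = 0, hic_depth = 50000)
  trio <- generate_trio(cfg)
  hic <- generate_hic_contacts(trio$truth, cfg)
  share <- colSums(hic$contacts) / sum(hic$contacts)
  ct <- trio$truth$contigs
  lens <- tapply(ct$end, ct$chromosome, max)[colnames(hic$contacts)]
  expect_true(all(abs(share - lens / sum(lens)) < 0.02))
})

test_that("noiseless methylation calls equal the planted states", {
  cfg <- tiny_config(seed = 27, meth_error_rate = 0)
  trio <- cached_trio("t27", cfg)
  me <- generate_methylation(trio$genomes, trio$truth, cfg, "strainA")
  called <- call_cpg(me$pileup)
  expect_identical(called$state, me$calls$state)
})

test_that("constant coverage 1 leaves nothing for the concordance filter", {
  cfg <- tiny_config(seed = 27, meth_error_rate = 0)
  trio <- cached_trio("t27", cfg)
  me <- generate_methylation(trio$genomes, trio$truth, cfg, "strainA")
  p <- me$pileup
  p$total_count <- 1L
  p$meth_count <- pmin(p$meth_count, 1L)
  kept <- filter_for_concordance(call_cpg(p))
  expect_equal(nrow(kept), 0)
  expect_equal(attr(kept, "dropped"), nrow(p))
})

test_that("TSS counts are integers, deterministic in truth, variable in noise", {
  cfg <- tiny_config(seed = 28)
  trio <- cached_trio("t28", cfg)
  a <- generate_tss_counts(trio$genomes, trio$truth, cfg, seed_offset = 0)
  b <- generate_tss_counts(trio$genomes, trio$truth, cfg, seed_offset = 100)
  expect_true(all(a$counts == floor(a$counts)))
  expect_false(identical(a$counts, b$counts))
  expect_identical(a$tss$pos, b$tss$pos)  # planted truth identical
})

test_that("planted hypomethylated domains must be able to hold 40 CpGs", {
  expect_error(
    generate_trio(tiny_config(seed = 29, meth_domain_length = 120,
                              min_domain_cpgs = 40)),
    "CpG")
})

test_that("ancestral coordinates map through planted events correctly", {
  cfg <- tiny_config(seed = 30, n_insertions = 3, n_deletions = 3,
                     tss_count = 0)
  trio <- generate_trio(cfg)
  sv <- trio$truth$svs
  ins <- sv[sv$type == "insertion", ][1, ]
  # a position 1 kb left of the insertion anchor is unshifted by that event
  p <- anc_to_strain(trio$truth, ins$carrier, ins$chromosome,
                     ins$anc_pos - 1000)
  probe <- substr(trio$genomes[[ins$carrier]][[ins$chromosome]], p, p + 49)
  # the same ancestral context exists in the outgroup near that position
  expect_equal(nchar(probe), 50)
  del <- sv[sv$type == "deletion", ][1, ]
  expect_true(is.na(anc_to_strain(trio$truth, del$carrier, del$chromosome,
                                  del$anc_pos + 1)))
})
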