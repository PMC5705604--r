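# cenevol

Comparative analysis of a trio of related genome assemblies — two ingroup
strains and an outgroup — focused on the questions that long-read trio
studies of fish genomes raised: how centromeric satellites evolve, how CpG
methylation domains inside centromeres diversify, how unplaced contigs can
be anchored with Hi-C contacts, which mid-sized structural variants are
insertions versus deletions, and what upstream insertions do to
transcription. A synthetic trio-genome generator plants every feature class
with recorded ground truth, so each analysis stage is scored for parameter
recovery instead of being trusted on faith.

The package is aimed at comparative genomicists who want these analyses as
tested, seedable R functions rather than one-off scripts.

## What it computes

* **Centromeric monomer evolution.** Monomer similarity is
  `(matched bases) / (length of the shorter monomer)` on a global alignment
  (match +1, mismatch −1, gap −1). Monomers are clustered greedily at 0.90
  similarity per chromosome; each cluster with more than 10 members gets a
  representative (its longest member), each cluster is associated with its
  best-matching cluster on another chromosome, and the best-match pairs are
  grouped Acro–Acro / Acro–nonAcro / nonAcro–nonAcro by centromere position.
  A one-sided Wilcoxon rank-sum test (exact by enumeration for small
  groups) asks whether nonAcro–nonAcro similarities are lower, i.e. whether
  non-acrocentric centromeres evolve faster.
* **Methylation domains.** Strict-majority CpG calls, the 2–9 coverage
  concordance filter, run-length segmentation into hyper/hypomethylated
  regions of at least 40 CpGs, spectrum-kernel distances
  `D(A,B) = sqrt(2 − 2K(A,B))` between unit-norm 8-mer frequency vectors,
  UPGMA trees of the domains, and a spectrum-kernel SVM (200-bp windows,
  five-fold CV or leave-one-chromosome-out) separating the two domain
  classes.
* **Hi-C anchoring.** A naive-Bayes classifier
  `p(c | a_1..a_C) = p(c) prod_i p(a_i | c) / Z` with priors proportional to
  training contig counts and Poisson contact-count conditionals, plus
  contact-peak placement of orphan contigs, marker-based map construction
  with misassembly splitting, and BAC/fosmid clone-end linking (150/50-kbp
  end bounds, at least two pairs).
* **Structural variants.** Reciprocal-best pairing, colinear chaining of
  local alignments by dynamic programming, indel/inversion/duplication
  calls from chain gaps (mid class 1–50 kbp), NHEJ/NAHR classification by
  breakpoint-flank homology, and polarization of each indel by mapping the
  2,500-bp flanks of the gap in the sequence-lacking strain onto the
  outgroup: flanks that abut mean an insertion into the carrier, a gap
  matching the event size means a deletion.
* **TSS regulatory statistics.** TSSs with 1–10-kbp insertions within
  100 bp, GC ratio / CpG ratio / unmethylated-CpG fraction over 500-bp
  upstream windows against matched pseudo-TSS controls, one-sided Wilcoxon
  signed-rank tests, a strict >30% transposable-element classification
  rule, and a simple negative-binomial two-group expression screen.

## Worked example

```r
library(cenevol)
cfg <- trio_config(seed = 42, n_chromosomes = 6, chrom_length = 3e5,
                   array_length_range = c(15000, 25000),
                   n_insertions = 3, n_deletions = 3, tss_count = 10,
                   n_contigs = 60)
report <- run_trio_pipeline(cfg)
print(report)
```

```
Synthetic trio pipeline report (seed 42)
  monomer similarity medians:
      AcroAcro    AcroNonAcro NonAcroNonAcro
        0.7368         0.7251         0.7193
  rank-sum p (NonAcroNonAcro lower):  0.00116 0.19724
  methylation regions:  60
  hypo/hyper SVM 5-fold accuracy:  1
  Hi-C naive-Bayes self-classification accuracy: 1 (60 contigs)
  polarized SV events: 22; ins:del ratio 2.67
  insertion-linked TSS pairs:  10
  paired one-sided p (gc/cpg/unmethylated):  0.000977 / 0.002945 / 0.000977
```

Reading the report: the non-acrocentric best-match similarities are the
lowest of the three groups and significantly lower than the acro–acro group
(p ≈ 1e-3) — the planted 2× divergence-rate difference, recovered. All 60
contigs re-classify to their true chromosomes from Hi-C contacts alone. The
22 polarized events are the planted insertions and deletions (insertions
dominate because the insertion-linked TSS events add to the planted 3+3
per strain), and all three upstream-window statistics shift significantly
at the insertion-carrying TSSs.

Individual stages are exposed directly: `generate_trio()`,
`cluster_monomers()`, `best_match_associations()`,
`compare_similarity_groups()`, `segment_regions()`,
`methylation_phylogeny()`, `svm_discriminate()`, `fit_nb()` /
`classify_orphan()` / `locate_orphan()`, `chain_alignments()` /
`call_svs()` / `polarize_with_outgroup()`, `window_stats()` /
`paired_increase_tests()` / `expression_screen()`. See the vignette in
`vignettes/cenevol-methods.Rmd` for the models, conventions and parameter
rationale.

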