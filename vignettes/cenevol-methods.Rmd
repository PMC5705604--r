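---
title: "Models and methods behind cenevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cenevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cenevol` re-implements, as a tested and reusable pipeline, the bespoke
computations of a trio-genome comparative study: clustering of centromeric
satellite monomers and comparison of their evolutionary rates between
acrocentric and non-acrocentric chromosomes; spectrum-kernel distances and
UPGMA phylogeny of hyper-/hypomethylated centromeric domains plus a
spectrum-kernel SVM that discriminates the two domain classes; naive-Bayes
Hi-C anchoring of orphan contigs with contact-peak placement; a
chained-alignment structural-variant (SV) caller with outgroup polarization
of insertions versus deletions; and regulatory statistics around
transcription start sites (TSSs) that carry mid-sized upstream insertions.
Every stage can be exercised on synthetic trio genomes whose planted ground
truth the package records, so each stage is scored for parameter recovery
rather than eyeballed.

The real study's headline numbers (genome-wide SNP rates, absolute TSS
tallies, the exact Fig-2b p-values) depend on the real assemblies and
sequencing data and are not reproducible at desk scale; what the package
guarantees instead is that every algorithmic component is correct against
independent oracles and that every planted effect is recovered in the
correct direction and magnitude class.

# The synthetic trio generator

`generate_trio()` builds an ancestor genome and evolves it along a
three-taxon tree: the outgroup splits first, the two ingroup strains later.
Branch lengths follow the emulated split times (outgroup at 25, ingroup at
18 time units): each ingroup branch has weight 1, the internal branch
(25-18)/18 ≈ 0.389 and the outgroup branch 25/18 ≈ 1.389. Substitutions are
i.i.d. per site with uniform replacement (a Jukes–Cantor-like process, no
small indels): the downstream similarity measure is alignment-based and
tolerant, so modelling the substitution spectrum would add parameters
without changing any conclusion.

Key structural choices, each a generator default that can be overridden:

* **Desk scale.** 6 chromosomes of 1 Mbp (not 24 × 30 Mbp), centromeric
  arrays of 20–60 kbp, a 171-bp ancestral monomer (the typical vertebrate
  satellite scale; the emulated species' monomer length is not published).
* **Background divergence.** 1.23% substitutions/site per ingroup branch,
  i.e. ~2.46% between the two ingroup strains — the revised SNP-rate scale
  of the emulated strain pair.
* **Concerted evolution of arrays.** Within an array, monomer copies are
  nearly homogeneous while the array consensus drifts at the class rate
  (`div_rate_acro` = 0.05, `div_rate_nonacro` = 0.10 per ingroup branch:
  non-acrocentric centromeres evolve faster, the phenomenon the comparison
  stage must detect). A fraction `array_heterogeneity` (0.2) of the class
  rate appears as copy-to-copy noise, which is what concerted turnover
  leaves behind. Each array carries `monomer_lineages` (4) variant
  sub-lineages, the structure that makes within-chromosome clustering
  non-trivial.
* **Duplicated chromosome pairs.** Chromosomes are paired (1,2), (3,4), …;
  pair members share a monomer ancestor at `monomer_pair_divergence`
  (0.08) while unrelated pairs differ by `monomer_family_divergence`
  (0.2). This emulates anciently duplicated chromosome pairs whose
  centromere positions are conserved; because the duplication long predates
  the strain split, the pair divergence exceeds the per-branch class rates.
  With the first half of the chromosomes acrocentric, the pairs provide
  acro–acro, mixed and nonacro–nonacro best-match comparisons — the three
  categories of the rate comparison.
* **Exchanges.** `exchange_rate` (1 per ingroup genome) Poisson-distributed
  5-monomer block copies between acrocentric arrays, the mechanism
  hypothesized to slow apparent acrocentric divergence.
* **Hypomethylated domains.** Each array carries 2 planted domains of 3 kbp
  built from a domain-specific GC-rich repeat unit (unit GC content
  `hypo_domain_gc` = 0.66, 2% copy-to-copy noise): hypomethylated
  sub-regions are still satellite, but a divergent variant with its own
  k-mer composition. Domains are planted in the ancestor and inherited by
  all strains, diverging at the background rate (unique sequence mutates at
  the point-mutation rate; the elevated class rates model repeat turnover,
  not point mutation). A requested domain that cannot contain 40 CpGs is
  rejected, mirroring the downstream minimum.
* **Structural variants.** Per ingroup strain, `n_insertions` novel-sequence
  insertions and `n_deletions` deletions with log-uniform sizes in
  `sv_size_range` (1–50 kbp, the heavy-tailed shape of real mid-sized SV
  size spectra), placed jointly so that no two events fall within 6 kbp of
  each other or within 10 kbp of an array; deletions never touch arrays.
  Insertions upstream of TSSs are GC/CpG-rich (base probabilities
  0.17/0.33/0.33/0.17) and sit within 100 bp of the TSS.
* **Hi-C contacts.** Contact intensity at genomic distance d is
  `exp(-hic_decay * d)` with `hic_decay` = 2e-5 (50-kbp decay length);
  positions on other chromosomes are assigned the fixed distance
  `hic_trans_distance` = 300 kbp, which yields a realistic ~10% trans
  fraction at the default decay, degenerates to proportional-to-length at
  decay 0 and to all-cis as decay → ∞. Counts are multinomial draws of a
  Poisson(`hic_depth` = 2000) total per contig.
* **Bisulfite pileups.** Coverage is zero-truncated Poisson(5) — chosen to
  exercise both sides of the 2–9 coverage filter — with per-read error 5%.
* **TSS counts.** Negative-binomial (dispersion 0.05) around a log-normal
  per-pair base mean of 100; insertion-linked TSSs have the carrier mean
  multiplied by `exp(tss_effect)` with `tss_effect` = 2.

All randomness derives from one master seed through per-module streams, so
identical configurations give byte-identical FASTA/BED/TSV outputs.

**What the generator does not emulate:** read-level noise (no FASTQ, no
SMRT kinetics), recombination and population structure, higher-order repeat
structure, small indels, segmental duplication families beyond the planted
events, and mappability artifacts. Tests passing on these genomes therefore
demonstrate algorithmic correctness and statistical power under the planted
model, not performance on real sequencing data.

# Monomer similarity and clustering

Monomer similarity is (number of matched bases) / (length of the shorter
monomer) on a global Needleman–Wunsch alignment with match +1, mismatch −1,
gap −1 and no end-gap forgiveness; `N` never counts as a match. Because
distinct optimal tracebacks can carry different match counts, matches are
counted on one traceback chosen deterministically (prefer diagonal, then
up, then left) after putting the operands in canonical lexicographic order;
this makes the similarity exactly symmetric.

Clustering is greedy at a similarity threshold of 0.90 (the published
pipeline's clustering radius is not stated): monomers are processed
longest-first, each joining the first cluster whose representative-so-far
(its longest member) is within the threshold, or founding a new cluster.
Representatives are reported only for clusters with more than 10 members.
Each cluster is associated with the best-matching cluster on a different
chromosome; pairs are categorized AcroAcro / AcroNonAcro / NonAcroNonAcro
by the positional classes of the two chromosomes, with the acrocentric
class assigned when the region midpoint lies within 15% of the chromosome
length from the nearer end (closed boundary; the real classification is by
karyotype, so the rule is configurable). The one-sided rank-sum test of
"NonAcroNonAcro is lower" is computed exactly by rank enumeration when the
comparison holds ≤ 12 records (valid under ties) and by the normal
approximation otherwise.

Local-alignment utilities (representative scoring, satellite masking,
monomer decomposition, flank homology) use Smith–Waterman with match +1,
mismatch −2, gap −2: the global scheme (+1/−1/−1) lies in the linear phase
for 4-letter alphabets, where "local" alignments extend indefinitely, so
local scans need the stricter penalties. The representative score is the
sum over hits of identity × alignment length / query length with an
identity floor of 0.7.

# Methylation domains

Bisulfite CpG calls use the strict-majority rule (ties are unmethylated);
cross-technology concordance is computed over calls with coverage 2–9
inclusive. Region segmentation is a run-length rule: maximal runs of one
state tolerating at most 2 opposite-state calls per run, with runs below 40
CpGs discarded. This is a declared substitute for the kinetic region
caller used in the original study — the downstream analyses consume
regions, not kinetics — and on noiseless tracks it recovers every planted
domain boundary to within one CpG.

Spectra are Euclidean-normalized k-mer frequency vectors (k = 8; windows
containing non-ACGT letters are skipped), computed on the stored strand
only (the kernel formula is strand-silent). The domain distance is
D(A,B) = sqrt(2 − 2K(A,B)) where K is the spectrum kernel, i.e. exactly the
Euclidean distance between unit-norm spectra — an identity the tests hold
to 1e−12. UPGMA is implemented directly with the half-average-distance
height convention (heights are half the merged average distance, so the
output is ultrametric; some implementations report the full distance, a
factor-2 difference flagged in the object) and smallest-label tie-breaks;
`hclust(..., "average")` serves as its independent oracle in the tests.
The Ward family tree of monomer representatives uses `hclust`'s ward.D2.

The SVM stage cuts domain sequences into 200-bp non-overlapping windows
(shorter tails dropped) and trains `kernlab::ksvm` on the precomputed
spectrum kernel with C = 1 (no value is published; the kernel is scale-free
so C = 1 is the natural default). Five-fold CV is stratified with a seeded
fold assignment; leave-one-chromosome-out mode holds out every window of
one chromosome.

The phylogeny-recovery evaluation combines each strain's regions per
(chromosome, status) into one composite leaf before building the tree:
single short boundary regions carry noisy spectra, and the planted claim —
chromosome segregation and domain differentiation precede strain
divergence — is a statement about the domains, not about segmentation
fragments. Recovery means every leaf's nearest cophenetic neighbor is its
cross-strain counterpart.

# Hi-C anchoring

The chromosome classifier is naive Bayes with priors proportional to the
number of training contigs per chromosome and, per chromosome, a
pseudocount-smoothed mean contact-composition profile (length-normalized
before averaging, to remove contig-length bias). The conditional
distribution of each contact count is Poisson with mean (contig total) ×
(profile proportion), accumulated in the log domain; the published
formulation fixes only the posterior form, not the conditional family, and
Poisson handles varying sequencing depth while giving the same argmax as a
multinomial. Orphan contigs are then placed at the argmax of a sliding
mean contact window (desk-scale window 50 kbp standing in for the 1-Mbp
window of the full-scale data; both are accepted), leftmost on ties.
Marker-based map construction orders contigs by median marker cM, splits a
contig carrying markers of two chromosomes at the midpoint between the
innermost discordant markers, and leaves single-marker or tied contigs
unoriented; clone-end linking requires at least two qualifying end pairs
within 150 kbp (BAC) or 50 kbp (fosmid) of a contig end.

# Structural variants

Whole-genome alignment at desk scale uses a built-in seed-and-merge
aligner: exact 15-mer seeds (seeds occurring more than 20 times in the
target are ignored, which silences satellite arrays) merged along
diagonals into ungapped blocks with at least 100 bp and 75% identity.
Externally produced local alignments in the same tabular form are equally
accepted. Blocks are chained by dynamic programming per strand with a gap
penalty of 0.01 × (query gap + target gap), capped at the median member
score; members overlapping a predecessor by up to 1 kbp on either axis are
admitted and trimmed along their diagonal, so emitted chains are strictly
colinear and gap sizes stay exact. Adjacent-pair gaps with
|g_q − g_t| ≥ 1 kbp become indel candidates (mid class up to 50 kbp); a
minus-strand sub-chain inside both gaps of a plus pair is an inversion; a
query gap with a high-identity second copy near the target gap is a
duplication. Mechanism labels use breakpoint-flank homology: NAHR iff the
two flanks share a local alignment of ≥ 50 bp at ≥ 80% identity (the
published criteria are unprinted; these are declared thresholds).

Polarization maps the two 2,500-bp flanks of the gap position in the
sequence-lacking strain onto the outgroup and measures the facing-end gap
between the two mapped blocks. Distances below max(500 bp, 0.25 × size)
mean the outgroup also lacks the segment — an insertion into the carrier;
distances within [0.5, 2] × size match an outgroup homolog — a deletion
from the non-carrier; anything else (or unalignable flanks, or flanks on
different chromosomes or strands) is unclassified. The published procedure
separated an empirical bimodal distance histogram by eye; the bands above
formalize that split and the recovered distance histogram is indeed
bimodal. Calls whose query gap overlaps an annotated satellite interval
(padded 5 kbp) can be masked out: tandem-repeat phase shifts mimic indels
of exact monomer multiples.

# TSS statistics

A TSS qualifies when one strain carries a 1–10-kbp insertion whose nearer
breakpoint is within 100 bp of the TSS and the orthologous region of the
other strain carries none; the partner's pseudo-TSS position anchors the
matched control window. Window statistics over the 500-bp upstream region
(5′ side; on the minus strand positions tss+1 … tss+500, whose reverse
complement has identical GC and CpG counts) are: GC ratio = (#G + #C) /
length; CpG ratio = #CpG dinucleotides / (length − 1) (the plain
dinucleotide ratio, not observed/expected — flagged in the output);
unmethylated fraction = unmethylated calls / called CpG sites. Increases
are tested with the one-sided Wilcoxon signed-rank test (exact for small
untied samples, normal approximation otherwise), zero differences dropped
per the classical convention, refusing fewer than 6 informative pairs. TE
classification takes the family covering the largest fraction of the
insertion if that fraction strictly exceeds 30%.

The expression screen is a deliberately simple two-group negative-binomial
test standing in for a full shrinkage-based differential pipeline:
median-of-ratios size factors, per-TSS method-of-moments dispersion shrunk
halfway to the across-TSS median and floored at 0.01, and a Wald z on the
log ratio of group means (two replicates each). With two replicates the
tail is mildly anticonservative relative to the nominal level; the planted
four-fold effects it must detect are far from that regime. A TSS with zero
counts in both counterpart replicates but expression in the carrier is
flagged novel.

# Evaluation problem sizes

The packaged evaluations run at sizes chosen to finish comfortably on one
CPU while keeping every statistical margin wide: spectrum identity on 100
random 200-bp pairs; UPGMA/Ward oracles on 50 random 4×4 matrices; chain
DP against brute force on 200 instances of ≤ 10 alignments; naive-Bayes
leave-one-out on 504 anchored contigs over 6 chromosomes plus 100 orphan
placements; SV polarization of 50 + 50 planted events per strain on 6 × 2
Mbp genomes; rate-direction power over 100 seeds of 10 × 150 kbp trios
with 18–26 kbp arrays and 24 monomers sampled per chromosome; domain
recovery and 20-seed phylogeny recovery on 6 × 250 kbp trios; TSS power
over 30 seeds of 6 × 400 kbp trios with 30 insertion-linked TSS pairs.
The per-branch divergence rates, effect sizes, coverage models and
filters are identical to the full-scale defaults throughout.

# Known limitations

* The seed-and-merge aligner assumes substitution-dominated background
  divergence; genomes with dense small indels would fragment its blocks
  (real data would come with externally computed local alignments).
* Monomer decomposition by greedy local-hit tiling is adequate for
  synthetic arrays but is not a RepeatMasker replacement.
* The expression screen does not shrink fold-changes and is not a
  substitute for a full differential-expression analysis.
* Positional centromere classification is a geometric stand-in for
  karyotype-based classification.
* The rank-sum and signed-rank exact enumerations switch to normal
  approximations beyond small sample sizes.
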