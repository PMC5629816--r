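---
title: "Methods: assembly metrics, two-genome divergence, and gene-loss screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly metrics, two-genome divergence, and gene-loss screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlgenome)
library(dplyr)
```

owlgenome packages the bespoke computations that sit between standard
bioinformatics tools in a draft-genome study of nocturnal birds: summarising
a scaffolded assembly, estimating genome-wide differentiation between two
diploid individuals of closely related species, screening candidate gene
loci for inactivating mutations, inferring whole-gene deletion from
flanking-gene synteny, and mapping microsatellite primer pairs in silico.
Every analysis has a paired, seeded simulator with exact ground truth, so
the whole pipeline is testable at desk scale without any sequence download.

## Assembly continuity and composition

A scaffold joins contigs with runs of `N` that stand for unsequenced gaps,
so contig-level statistics depend on a convention: how many consecutive N's
constitute a gap? `split_scaffolds()` exposes that convention directly. The
conservative choice `n_run_min = 1` breaks at every N and is the right
yardstick for comparing draft assemblies pessimistically; `n_run_min = 25`
(the default, and the hard-coded behaviour of the widely used Assemblathon
statistics script) treats only runs of 25 or more N's as gaps and is the
convention for final reporting. Continuity improves monotonically with the
threshold — allowing longer N blocks before breaking can only merge
contigs, never split them — and the test suite asserts that contig N50 is
non-decreasing in `n_run_min` on random assemblies.

`summarize_assembly()` computes Nx/Lx at the configured levels (Nx is the
length at which descending-sorted sequences first accumulate x% of the
total; Lx the count needed to get there), strict "> T nt" length-class
counts, %GC over non-N bases, %N over all bases, and internal-gap
statistics. Conventions worth stating because the definitions genuinely
vary between tools:

* `filter_min_length()` removes records *strictly* shorter than the cutoff
  (1,000 nt in the motivating study), and `shortest` is computed after the
  filter.
* The median of an even count is the mean of the two central values.
* Ambiguity codes other than N (R, Y, ...) count as non-GC, non-N bases, so
  %GC + %AT + %other never exceeds 100.
* The %N denominator is the total assembly length including the N's.
* A scaffold with no internal gap at the chosen threshold is a single
  *unscaffolded* contig; the "% of assembly in scaffolded contigs" is the
  contig mass of multi-contig scaffolds over the total assembly length.
* Leading and trailing N runs produce no empty contigs and are not counted
  as internal gaps.

Genome-scale published values (a 1.26-Gnt assembly with scaffold N50 of
~3.98 Mnt) cannot be recomputed at desk scale; instead `simulate_assembly()`
generates assemblies whose exact metrics are known from the generating
parameters — scaffold lengths, planted N runs, composition bookkeeping kept
while drawing bases — and the suite requires `summarize_assembly()` to
reproduce that ground truth exactly, alongside the split/rejoin
reconstruction invariant (contigs plus removed gaps concatenate back to the
scaffold).

## Diversity and Hudson's fixation index from two genomes

With one diploid individual per species genotyped jointly against one
reference assembly, per-site pairwise differences decompose cleanly
(`site_diffs()`):

* within species: an individual contributes 1 iff heterozygous;
* between species: the fraction of unequal allele pairs among the 2 × 2
  cross-individual comparisons, so a fixed difference scores 1 and a
  heterozygote against a homozygote scores 1/2. Comparisons are categorical
  over the full allele list, so multiallelic sites need no special casing.

Summing over sites and dividing by a callable length L gives the
within-species diversities $H_w^A$, $H_w^B$ and the between-species
diversity $H_b$, and

$$F_{ST} = 1 - \frac{(H_w^A + H_w^B)/2}{H_b},$$

Hudson's estimator with an unweighted mean of the two within-species
values. On the published component values ($2.008\times10^{-4}$,
$2.352\times10^{-3}$, $7.042\times10^{-3}$) this reproduces the published
0.819:

```{r fst}
hudson_fst(2.008e-4, 2.352e-3, 7.042e-3)
```

Site filters (`filter_sites()`) mirror the source study: indel sites are
dropped; then sites where either individual's genotype quality falls below
`gq_min`; then sites where the *reference individual* (the one whose
assembly the reads were mapped to) is homozygous non-reference; then sites
whose combined depth exceeds the mean plus `coverage_k` standard
deviations. Decisions the source text leaves open, exposed here as explicit
parameters rather than buried constants:

* **GQ cutoff.** "Low genotyping quality" is unquantified; the default
  `gq_min = 20` is common GATK practice. Change it and the filter changes —
  it is a parameter, not a reproduction of a published constant.
* **Coverage rule.** Whether depth was per-sample or combined is not
  stated; this implementation sums DP over the two individuals, computes
  mean and SD over *all* pre-filter sites, and freezes the threshold before
  removing anything, which makes the filter idempotent and testable.
* **Callable length.** A variant-only VCF carries no invariant-site count,
  so the per-nt denominator L is supplied by the caller (e.g. the non-N
  length of the reference assembly).
* **Reference-hom-alt exclusion.** Excluding those sites biases $H_b$
  downward (they are real divergence); the filter applies the rule as the
  study states it and documents rather than corrects the bias.
* Sites with a missing genotype in either individual are excluded by the
  reader from all sums and tallied; with one genotype absent neither the
  within- nor the between-species comparison is defined, so exclusion is
  the conservative reading.

`simulate_variant_sites()` draws each of L sites independently into one of:
heterozygous-in-A, heterozygous-in-B, fixed difference, four
filter-violating decoy classes, or invariant. Because heterozygous sites
contribute 1/2 to the between component, the fixed-difference rate hitting
a target $H_b$ is `div = hb - (het_a + het_b)/2`
(`calibrate_divergence_rates()`). Sites are independent — no linkage, no
mutation model — which suffices because the estimator is site-additive;
what passing recovery tests show is that the filters and the arithmetic are
right, not that the simulator resembles real linked genomes. The acceptance
suite runs the full filter → diversity → F_ST pipeline at L = 10^6 over 20
seeds and requires the mean recovered F_ST to lie within 3 Monte-Carlo
standard errors of 0.819.

## Inactivating-mutation screening

`screen_gene()` compares a candidate locus against a functional reference
ortholog. A global affine-gap alignment (either supplied, or computed by
`align_pair()`) is projected through the reference gene model
(`coding_alignment()`), and four detectors run on the columns:

* **Start-codon loss** — any non-ATG first codon is called; no
  alternative-start whitelist is credited (the motivating study treats ACA
  as a start-codon mutation).
* **Premature stops** — codon boundaries come from the *reference* CDS
  coordinates ("reference-projected frame"), so stops downstream of a query
  frameshift are still reported. The study catalogues stops and frameshifts
  independently (one pseudogene carries both), which this convention
  matches; how the authors resolved frame downstream of multiple
  frameshifts is not stated, and reference projection is this package's
  explicit choice. The terminal reference codon is excluded.
* **Coding indels** — each maximal gap run fully inside one exon is a
  frameshift if its length is not a multiple of 3, in-frame otherwise.
  Adjacent insertion/deletion pairs are reported separately, never netted.
  In-frame indels are reported but excluded from `n_inactivating`.
* **Splice sites** — canonical GT donor / AG acceptor only; a gap run
  spanning an exon–intron boundary becomes a single `splice_boundary_indel`
  (regardless of length mod 3) and suppresses the engulfed donor/acceptor
  call. Functional non-canonical sites (e.g. GC donors) will be over-called;
  this is a documented limitation.

The shipped mutation plans encode, exon by exon, the published per-gene
catalogs for the rod-like cone opsin (Rh2), pinopsin (OpnP), mammal-like
melanopsin (Opn4m) and carotenoid ketolase (CYP2J19) orthologs of the two
owl families. Only mutations the study enumerates explicitly are planted;
qualitative statements (e.g. counts of missense changes) are not encoded as
inactivation truth. Fixtures come with their construction-time alignment
and expected calls, so detectors are tested both against the true alignment
and through the de-novo alignment path:

```{r screen}
fx <- make_locus_fixture("opn4m_tyto", seed = 42)
screen_gene(fx$model, fx$ref, fx$query)
```

Whether the shared 4-nt melanopsin deletion "counts" biologically is a
judgment the study itself leaves nuanced (the gene appears to remain
functional); the screen reports it as a frameshift and leaves
interpretation to the caller.

`infer_gene_deletion()` implements the synteny argument for genes with no
probe hit at all: if the two flanking genes map to one scaffold and the
intervening sequence is real sequence rather than an N gap, the gene was
deleted rather than merely unassembled. "Not composed of missing data" has
no published cutoff; the default tolerates an intergenic N fraction up to
0.2. Flanks on different scaffolds yield `indeterminate_split` (the
published situation for the ultraviolet-sensitive opsin SWS1), an
N-dominated gap `indeterminate_gap`, and a probe hit short-circuits to
`gene_present`.

`export_codon_alignment()` prepares multi-species codon alignments for
downstream selection analyses: any codon column containing a stop in *any*
sequence is removed for all sequences, and (by default) so is any column
containing a gap — the operational stand-in for "codon positions with
questionable homology", which has no published operational definition.
Fitting dN/dS models is out of scope; the cleaned PHYLIP/FASTA output is
the hand-off point.

## In-silico microsatellite mapping

`pair_primer_hits()` forms a locus when the best hits (longest alignment,
then fewest mismatches, then lowest scaffold id) of a forward/reverse
primer pair share a scaffold within `max_span` (default 10,000 nt, generous
relative to typical microsatellite products). The inferred PCR product
(`product_length()`) spans the outermost mapped coordinates, after
extending each primer's outer (5'-distal) end by its unaligned remainder
`primer_length - aln_length` — a PCR primer anneals full-length even when
the alignment reported is partial. That outer-end-only extension rule was
reverse-engineered from the three partially aligned published rows and
reproduces all 15 published product lengths exactly; it is an inference,
not a stated convention. Inter-locus distances use the printed 5' mapping
coordinates inclusively (`|a - b| + 1`), because only that convention
reproduces both published distances (12,172 nt and 717,153 nt).

## Problem sizes and numerical choices

The test and acceptance workloads were sized to what the methods need, not
more: parameter-recovery runs use L = 10^6 sites over 20 seeds (Monte-Carlo
SE on F_ST of roughly 0.001), property tests run hundreds of random loci
and assemblies, and statistical calibration pools 120 seeds at L = 2,000
against 99% binomial bounds. Alignment scoring defaults (match 1, mismatch
−2, gap open −5, gap extend −1, with a gap of length k costing
`open + (k−1)·extend`) favour contiguous gaps over scattered mismatches,
which is what recovering planted indel runs requires; ties inside
homopolymers can shift a gap by a base, so fixtures keep planted events
clear of feature boundaries. Degenerate inputs fail loudly rather than
silently: empty assemblies, empty depth vectors, zero callable length,
$H_b = 0$ (undefined F_ST), and alignment of an empty sequence are all
errors with directed messages.

## What the simulators do and do not show

The generators emulate the *structure* the analyses consume — scaffolds
with planted gaps, variant tables with known per-category counts and
decoys, clean multi-exon genes with planted lesions, primer landing sites
with known spans. They do not emulate linkage disequilibrium, alignment or
genotyping error beyond the planted decoy classes, repetitive sequence, GC
heterogeneity, or assembly artefacts. Green tests therefore certify the
correctness of the computations under their stated conventions, not the
robustness of variant calling or alignment on real owl genomes — those
stages are upstream of this package by design.
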