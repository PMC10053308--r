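---
title: "Screening for defense systems organized around diversity-generating retroelements"
author: "dgrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for defense systems organized around diversity-generating retroelements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgrscan)
```

## The biological question

Diversity-generating retroelements (DGRs) are prokaryotic genetic elements
that hypermutate a short variable repeat (VR) inside a target gene by
error-prone reverse transcription of a template repeat (TR), carried out by
a dedicated reverse transcriptase (RT). Because this machinery can generate
enormous protein sequence diversity ahead of any selective challenge, DGRs
are attractive candidates for the core of anti-phage defense systems that
work by preemptive diversification — the prokaryotic analogue of an
antibody repertoire. Known defense systems cluster in genomic "immunity
islands", so an unknown DGR-based defense system should betray itself by
co-localizing, again and again across many genomes and metagenomic contigs,
with protein families (Pfams) already catalogued near known defense
systems ("immune Pfams").

`dgrscan` turns that reasoning into a reproducible pipeline over annotated
contigs: score every Pfam family for co-localization with DGR components,
keep Pfam compositions anchored by an immune Pfam with enough support,
then subject each candidate composition to three orthogonal plausibility
checks — conservation of gene order and strand, codon-usage discordance
with the host replicon (a horizontal-transfer signature), and coherence of
residence (cellular vs viral), RT clade and taxon distributions.

## Data model

All coordinates inside the package are 0-based half-open; GFF3 input and
output (1-based inclusive) is converted only at the file boundary, which
keeps interval arithmetic free of off-by-one drift across modules. A
`DgrDataset` holds contig metadata (length, topology, residence, taxon),
gene features, Pfam hits, and the DGR component table (RT gene, TR
interval, VR intervals with their host genes, RT clade 1–6). Circular
contigs are first-class: a feature may wrap the origin (stored with
`start < length`, `end > length`) and all window and region arithmetic is
modular on them.

Pfam accessions are compared with their version suffix stripped
(`PF05635.13` and `PF05635` are the same family); proteins that contain a
VR are deliberately segregated from their non-VR peers of the same family
(cluster keys `PFxxxxx` vs `PFxxxxx:VR`), because a hypermutated
VR-containing protein and an ordinary family member are different
functional entities.

## The co-localization (Icity) score

For each DGR system two bait classes are used: the RT gene and each VR
host gene. A neighborhood is the bait gene span extended by `D = 10000` bp
on both sides; a gene is a member if it overlaps the window by at least
one base pair. The score of a cluster is

\[
\mathrm{Icity} = \frac{w'}{w},
\]

where \(w\) is the summed weight of all genes carrying the cluster and
\(w'\) the summed weight of those members falling inside at least one
neighborhood. The weights dereplicate overrepresented loci: neighborhoods
are fingerprinted by their ordered cluster content, and each gene whose
home neighborhood belongs to a group of \(k\) identical fingerprints
contributes \(1/k\). Genes outside every neighborhood weigh 1. This is a
deterministic, documented stand-in for the statistical corrections of
guilt-by-association protocols; it is pluggable behind
`redundancyWeights()` if a different scheme is wanted.

Scoring is repeated over seeded random contig subsamples (default
fraction 0.8), each run scoring RT baits and VR baits separately and
taking the per-cluster maximum. Runs continue until comparing two
consecutive runs reveals no new cluster above the 0.7 threshold — i.e. the
latest run adds nothing to the cumulative set of above-threshold
clusters — with a floor of 2 runs and a hard cap of 25 (cap hits warn).
With `subsampleFraction = 1` every run is identical and the protocol
collapses to exactly 2 deterministic runs, which is what the exact unit
tests use. Per-cluster results are the per-run scores and their mean;
selection is either strict (`all_runs`: above 0.7 in every run; a run
where the cluster was absent from the subsample counts as failure) or
lenient (`any_run`). The inequality is strict — a score of exactly 0.7
never qualifies.

The source of run-to-run stochasticity in the multi-run protocol is
contig subsampling. This choice is reproducible (each run's seed is
`seed + run`), tunable, and can be switched off entirely, which makes the
convergence semantics testable.

## Compositions and arrangement conservation

A composition is the set of strictly selected cluster keys found in a DGR
locus's neighborhoods; loci without at least one immune Pfam
(version-agnostic catalog match) are dropped. Compositions kept for
downstream analysis must occur in **more than 20** loci, among which at
least **4 distinct contigs** are longer than 20 kbp. "Occurrences" count
DGR loci, so a contig with two DGR systems contributes two; the
long-contig count is over distinct contigs. Short contigs truncate
neighborhoods, so compositions that are subsets of larger ones are
expected and are reported via the composition-by-Pfam membership matrix.

A functional gene system should show a conserved gene order. \(n\) genes
admit \(n!\) orders and \(2^n\) strand choices, but reading the whole
locus from the other end is the same arrangement, so the count of
distinct arrangements is

\[
2^{\,n-1}\, n! \qquad (4 \text{ for } n=2,\; 24 \text{ for } n=3).
\]

`canonicalSignature()` implements exactly that quotient: the signature is
the ordered list of (cluster key, strand) along the contig, and the
canonical form is the lexicographic minimum of the signature and its
reversal with strands flipped. Reverse-complementing a contig therefore
leaves canonical forms unchanged (a tested invariant), and exhaustive
enumeration for \(n \le 4\) yields exactly \(2^{n-1} n!\) distinct forms.
Loci on circular contigs are linearized by cutting at the largest
inter-gene gap before reading; duplicated families at one locus stay in
the signature in positional order even though the composition key is a
set. The conservation statistic per composition is the modal canonical
signature's fraction of loci (ties broken lexicographically).

## Codon-usage-bias screen

Recently transferred modules have not yet ameliorated to the host's codon
usage. For each locus the putative system span (RT gene, TR and VR host
genes combined) extended by ±10 kbp is compared against a control region
of identical length on the most distant part of the sequence: on circular
contigs the control midpoint is offset by half the contig length, giving
equal gaps of \((L - 2R)/2\) on both arcs; on linear contigs the control
is placed as far in-bounds as possible. Pairs separated by less than
20 kbp are omitted (with the reason logged), as are systems larger than
half the contig.

Within each region, every ORF longer than 360 nt gets Wright's effective
number of codons,

\[
N_c = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} + \frac{5}{\bar F_4} +
\frac{3}{\bar F_6},
\]

where \(\bar F_k\) is the mean codon homozygosity
\(\hat F = (n\sum p_i^2 - 1)/(n-1)\) over synonymous families of
degeneracy \(k\) with at least two observed codons. The three six-fold
families (Leu, Ser, Arg) form their own class, which makes the uniform
61-codon limit exactly 61; single-codon usage gives exactly 20. Values
are capped to [20, 61]. Numerical details: families with \(\hat F \le 0\)
(possible at tiny counts, e.g. two observations split over two codons)
are excluded as uninformative since they would otherwise produce an
unbounded term; a missing 3-fold class (no Ile) is imputed as the mean of
the 2- and 4-fold class means, and any other missing class as the mean of
the available classes; stop codons are excluded and codons containing
ambiguity characters are dropped.

The two per-ORF \(N_c\) samples are compared with a two-sided two-sample
Kolmogorov–Smirnov test at \(\alpha = 0.05\), with no multiple-testing
correction. The p-value is the `stats::ks.test` default: exact for small
tie-free samples, asymptotic otherwise. The exact p matters here — at the
10–20 ORFs a ±10 kbp region typically contains, the purely asymptotic
p-value is visibly conservative (measured type-I error near 0.015 instead
of 0.05), while the exact version keeps the screen calibrated (measured
0.03–0.05 under the simulation null). Loci with fewer than 3 usable ORFs
on either side are marked untestable and excluded from the reported
per-composition proportion of significant loci.

## Profiles

Residence profiles report cellular/viral counts per composition and the
minority fraction \(\min(c, v)/(c + v)\); a strongly skewed fraction
marks a composition as predominantly cellular or viral. Clade profiles
report the six RT-clade counts, the modal clade fraction over known
labels, and whether the composition is single-clade. Taxon labels are
opaque strings; the clade-by-taxon matrix row-normalizes clade
proportions per taxon. Unknown labels are always excluded from
denominators and reported separately, so missing metadata cannot bias a
proportion silently. Gene maps are emitted as deterministic SVG: genes as
strand-oriented arrows, RT in white, same-family genes sharing a color,
VR-containing genes flagged. Cross-family coloring by amino-acid identity
(≥30%) would require protein sequences, which the data model does not
demand, so family identity is the grouping key.

## The synthetic-data generator

`simulateDataset()` is first-class, tested code — it defines the study
conditions under which the pipeline's statistical behavior is verified.
Each contig carries one planted DGR cassette (immune, accessory, RT and
VR-target genes, canonically in that order on the forward strand, plus a
TR interval next to the RT and a VR inside the target gene, written as a
TR copy with adenine-position substitutions). Defaults encode the contig
population the method is meant for:

* **Lengths**: log-normal with mode 3 kbp, truncated to 3–20 kbp, mixed
  with a `fractionLong = 0.5` uniform component on 20–200 kbp — i.e.
  about half of all contigs are longer than 20 kbp, with the short-contig
  mode at 3 kbp. Contigs too short for their sampled cassette are
  resampled.
* **Topology**: circular with probability 0.5, exercising all modular
  arithmetic.
* **Co-localization**: the immune gene is placed inside the cassette with
  probability `pImmuneColocalization` (default 0.9) and otherwise beyond
  the 10 kbp window on *both* arcs (which on circular contigs requires
  clearance on the wrap side too), so the planted rate is exactly the
  realized rate.
* **Decoys**: Poisson genes at `backgroundPfamRate = 0.2` per kbp, drawn
  from 20 decoy families and placed uniformly in free space with no
  positional association to the cassette. The default is below real
  prokaryotic gene density (~1 gene/kbp) because only Pfam-annotated
  decoys are emitted and a substantial fraction of metagenomic proteins
  has no Pfam hit.
* **Gene lengths**: 300–2400 nt, multiples of 3, so some ORFs pass and
  some fail the 360 nt codon-bias filter.
* **Codon usage**: gene sequences are sampled codon-by-codon
  (`sampleCodons()`); genes inside the island — the cassette span
  ±10 kbp, matching the scale of a transferred module — use a usage table
  skewed by `codonShiftDelta` (mass \(1/k + \delta(1-1/k)\) on one codon
  per family), all others the uniform table. \(\delta = 0\) is an exact
  null; \(\delta = 1\) forces \(N_c = 20\).
* **Arrangement**: the cassette keeps its canonical order with
  probability `arrangementConservation` (default 0.95), otherwise order
  and strands are scrambled uniformly.
* **Labels**: residence viral with probability 0.3, clade from a fixed
  6-vector of weights, and taxon equal to the clade's preferred taxon
  with probability `taxonCladeBias` (default 0.8), which makes the
  clade-by-taxon association recoverable.

Calibration and power experiments for the codon-bias screen (in the test
suite and the acceptance script) use `fractionLong = 1` and
`backgroundPfamRate = 0.8`: the 20 kbp gap rule needs contigs of roughly
90 kbp or more before a region pair is even valid, and a near-realistic
gene density gives each region enough ORFs (~10–20) for the exact KS
p-value to be meaningful. Statistical tests in the suite run at fixed
seeds with 3-standard-error bands; simulation sizes (200 contigs for
recovery and calibration, 500 loci for arrangement recovery, 8–30 contigs
for exact-oracle and smoke tests) were chosen as the smallest sizes at
which the binomial bands are informative.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no phylogenetic correlation between contigs
(real datasets contain near-clonal genomes; the fingerprint weights exist
precisely for that, but the simulation exercises them only through
incidentally identical neighborhoods), no genuine retrohoming dynamics
(VR hypermutation is a static annotation), no Pfam annotation noise or
chimeric gene calls, no GC-content or amino-acid composition structure
(background codon usage is uniform), and a single planted composition
rather than a mixture of overlapping systems.

## Determinism and degenerate inputs

Every stochastic step derives from one seed: the generator from
`DgrSimConfig@seed`, each Icity run from `seed + run`. `runAll()` with a
fixed config reproduces every output file byte-identically (a tested
acceptance property); the manifest deliberately contains no timestamps.
Degenerate inputs have defined behavior: empty GFF3 yields contigs
without features; a cluster with no members is an error; a subsample
without DGR systems is redrawn with a warning; loci whose key set lacks
an immune Pfam are dropped; all-unknown residence yields `NA` minority
fractions; undersized KS samples are untestable rather than silently
significant.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipelineConfig(
  simConfig = dgrSimConfig(nContigs = 25, seed = 101),
  outDir = "dgr_demo", minOccurrences = 10, minLong = 3, seed = 5)
res <- runAll(cfg)
compositionSummary(res$kept)
res$arrangements$modal
res$bias$perComposition
```

## Known limitations

The redundancy weighting dereplicates only *identical* neighborhood
fingerprints; near-identical loci from closely related genomes are not
merged, so scores on redundant real datasets will be more optimistic than
on the simulation. Strict selection requires presence in every subsample
run, which penalizes genuinely rare associated families. The codon-bias
screen inherits the known weaknesses of \(N_c\) on short ORFs and of
codon-usage HGT signals generally (compositional drift has many causes).
RT clades are input metadata, not inferred phylogeny. None of these
affect the pipeline's contracts; they bound its interpretation.
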