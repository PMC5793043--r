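---
title: "Detecting hypermutator lineages from near-identical genomes"
author: "mutatorscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hypermutator lineages from near-identical genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutatorscan)
```

## The problem

A bacterial strain distributed across culture collections for decades is,
genetically, a natural evolution experiment. If the strain carries a
*mutator* phenotype — a heritably elevated mutation rate, typically from
loss of methyl-directed mismatch repair (MMR: *mutL*, *mutS*, *mutH*,
*dam*, *uvrD*) or of oxidized-guanine sanitation (*mutT*) — isolates of
the *same* strain can accumulate hundreds of differences, enough to fool
standard typing thresholds into declaring them different strains.

`mutatorscan` implements the comparative-genomics workflow for this
situation end to end: variant detection between near-identical assembled
genomes, mutational-spectrum and mutator-signature analysis, an
expected-versus-observed Ka/Ks statistic, cgMLST-style allele-distance
phylogeography, antimutator-gene screening, and convergence analysis of
antibiotic-resistant "squatter" colonies (colonies growing inside an
inhibition zone — a classical mutator hallmark). A forward
genome-evolution simulator with exact ground truth ties everything
together and is what the test suite and the acceptance script run on.

## Data model

* `AnnotatedGenome` — one chromosome/contig (`Biostrings`-validated DNA)
  plus CDS features in a `GRanges`. All coordinates are 1-based
  inclusive; BED's 0-based half-open convention appears only at export.
* `VariantSet` — position-sorted normalized variants of one isolate
  versus one reference. Indels use the VCF anchor-base representation
  and are **left-aligned and parsimony-trimmed**
  (`normalizeVariants()`), so a +1 C insertion anywhere inside a C tract
  has exactly one canonical record. This is what makes per-isolate sets
  comparable by `(pos, ref, alt)` keys. Protein-level naming instead
  follows the HGVS 3' rule (right-shifting within repeats) — the
  conversion happens at annotation time, not in the variant records.
* `MutatorRegime`, `SpectrumProfile`, `CgScheme`, `KaKsResult` — see
  below.

## Variant calling between assembled genomes

`callVariantsCollinear()` compares two near-identical (divergence well
below 1%), rearrangement-free assemblies: unique shared 21-mers anchor a
colinear chain (longest increasing subsequence, leftmost on ties);
segments between anchors are resolved by optimal global alignment
(match 1, mismatch −2, gap open −4, gap extend −1) and normalized.
Anchor failure — too few anchors, a chain covering under half of the
anchors or under half of the reference — raises an explicit
"non-collinear" error rather than silently truncating the call set.
Segments that decompose as prefix + single event + suffix are resolved
directly; the affine-gap aligner only runs on genuinely complex
segments. Sites whose alleles would contain ambiguity codes are masked
from the output.

This replaces a read-mapping pipeline: there are no reads, so the
read-level coverage/quality filter (`filterVariants()`) acts on VCF
metadata when present — keep iff relative coverage **> 0.5** and
absolute coverage **> 10** (both strict) and Phred quality **≥ 23**
(inclusive) — and passes variants with missing metadata, with a
warning, so that assembly-derived calls are not silently discarded.

## The simulator (and what it does and does not emulate)

`generateAncestor()` packs ORF-valid CDS (ATG start, single terminal
stop) on both strands of a GC-controlled random chromosome.
`evolveGenome()` introduces exactly `n` mutations: a substitution class
is drawn from the regime's six-class weights and a site with the
matching base pair is then drawn uniformly, so the realized spectrum is
multinomial in the weights; indels are ±1 bp homopolymer slippage with
probability `indelHomopolymerBias`, otherwise 1–6 bp events with length
1 dominant. `simulateCollectionHistory()` chains edges over a transfer
plan, drawing all mutations in root coordinates so variant sets are
nested along every root-to-leaf path (no back-mutation) and the number
of mutations grows with transfer depth — the phylogeographic signal the
clustering recovers.

Design choices worth stating explicitly:

* **Mutation counts, not rates.** Storage time and passage numbers are
  not modeled; an edge is "n mutations", full stop.
* **Minimum event spacing (25 bp, homopolymer runs blocked whole).**
  Distinct sites alone do not guarantee that the normalized
  representation of each event is unique — two adjacent indels can have
  equivalent but differently factored records. Spacing makes the exact
  round trip (`call(apply(truth)) == truth`, recall = precision = 1) a
  well-defined property rather than a representation accident.
* **Preset regimes.** The paperless numbers here are the package's own:
  `MMR` (transitions 0.42/0.42, indel fraction 0.5, homopolymer bias
  0.8), `MutT` (A:T>C:G 0.50, indel fraction 0.1), `oxidative`
  (G:C>T:A 0.50), `wildtype` (uniform, indel fraction 0.1). They encode
  the qualitative biology — MMR loss elevates indels and transitions,
  MutT loss elevates A:T>C:G transversions, oxidative stress elevates
  G:C>T:A — with effect sizes strong enough to be unambiguous at a few
  hundred events.
* **What is not simulated:** recombination, horizontal transfer,
  plasmid dynamics (plasmid content enters as fixture gene blocks),
  selection during evolution (selection enters only through
  `simulateSelectionSnps()` for Ka/Ks calibration), multi-hit sites,
  and sequencing error. Passing tests therefore demonstrate method
  correctness on clean collinear assemblies, not robustness to
  assembly artifacts or repeat-rich real genomes.

The "odyssey" preset plan (`odysseyPlan()`) wires six isolates along a
collection-transfer chain with per-edge counts 4/11/94/341/126 —
cumulative root-to-leaf totals of 4/11/105/446/572 allele-scale
differences — with MMR regimes on the early edges and MutT regimes
later, emulating sequential inactivation of the two repair systems.
The default pipeline genome is 120 kb with 100 genes: large enough for
spacing and cgMLST targets, small enough that the full analysis runs in
minutes on one CPU (sizes are stated in `runConfig()` and are the
package's choice).

## Spectra and signatures

`computeSpectrum()` collapses each SNP with its reverse complement into
six classes (two transitions `A:T>G:C`, `G:C>A:T`; four transversions);
MNPs are split into component SNPs first; indels of any length count
once (`indelSnpRatio()` is undefined for an indel-only set, reported as
`NA`). `inferMutatorSignatures()` applies explicit cutoffs — MMR:
indel/SNP ratio ≥ 0.2 *and* transition fraction ≥ 0.4; MutT-like:
A:T>C:G fraction ≥ 0.15; oxidative: G:C>T:A fraction ≥ 0.15 — each
backed by a one-sided binomial test against a configurable null
spectrum (uniform by default). The default evidence level is
α = 0.001: at the working scale of ~500 events an unbiased spectrum
essentially never reaches both the fraction cutoff and that evidence
level (the fraction would need to exceed the null by >3 SD), while the
presets exceed their cutoffs by many SD; below 30 events the verdict is
"insufficient data" rather than a flag. `hotspotScan()` bins variant
positions into 10-kb windows and tests uniformity by chi-square
goodness of fit, pooling adjacent windows until every expectation is at
least 1; one variant gives p = 1 by convention.

## Ka/Ks by site enumeration

`expectedEffectWeights()` enumerates every coding site and its three
alternatives; the transition gets weight `ts`, each transversion
`(1−ts)/2`, with `ts` estimated from all of the isolate's observed SNPs
(coding and intergenic). Weights accumulate into missense (Ka) and
synonymous (Ks) expectations; nonsense and stop-loss alternatives are
excluded from both sums, terminal stop codons from the enumeration,
observed nonsense SNPs from the observed counts. The statistic is
`(Ka_obs/Ks_obs) / (Ka_exp/Ks_exp)`: 1 under neutrality. An isolate
with no synonymous SNPs (e.g. indel-only) yields an explicit
"undefined" result rather than a number. The two-class ts/tv weighting
is the primary mode; a six-class spectrum weighting is available behind
`sixClass = TRUE` for sensitivity analysis. Overlapping CDS contribute
once per frame; the initiator codon is included; translation uses the
standard bacterial table (stop codons TAA/TAG/TGA; no non-standard
codes).

Calibration is by construction: `simulateSelectionSnps()` draws sites
uniformly and alternatives with the same 1-ts : 2-tv allocation the
expectation uses, so neutral replicates average 1.0 and rejecting half
of the missense draws halves the ratio.

## cgMLST, distances and trees

`buildScheme()` keeps every reference CDS except targets under 120 bp,
targets containing ambiguity codes, and paralogous pairs (≥ 90%
identical over ≥ 50% of the shorter — both dropped); SeqSphere-style
"standard parameters" are opaque, so these are declared defaults, all
configurable. `callAlleleProfiles()` extracts each target's complete
CDS from the query (via the genome-wide collinear call for single
contigs, exact flank matching for contig sets); identical sequences
share an allele id assigned in order of first observation, reference =
1; absent or border-truncated targets are MISSING. `allelicDistance()`
counts differing alleles over mutually typed targets (pairwise deletion;
raw counts, never rescaled — whether MISSING-versus-present should count
as a difference is genuinely open, and pairwise deletion is the declared
choice). `upgmaTree()` and `averageLinkageManhattan()` delegate to
`stats::hclust` (average linkage) after lexicographic label ordering so
merge ties resolve deterministically; the test suite checks both against
an independent naive agglomeration oracle. `exportSnpAlignment()` writes
the concatenated segregating SNP columns (reference included, missing
calls filled with the reference base) as FASTA/PHYLIP for external
maximum-likelihood inference — tree inference itself is out of scope.

## Screening and squatter convergence

`screenGenePanel()` reports every change in a role-tagged gene panel
(MMR, oxidized-guanine repair, SPANC-balance, efflux and porin-regulator
genes by default), named at the protein level (`R190C`, `L68_A69del`,
frameshifts). Panel genes are matched by `gene_id`; orthology search
beyond exact ids is out of scope. `squatterSpecificVariants()` is the
resistance filter: normalized squatter-minus-parent set difference,
keeping only CDS-overlapping indels and missense/nonsense SNPs.
`convergenceGenes()` counts isolates hit per gene; the default
threshold n−1 of n generalizes an "all or nearly all" rule, and gene
grouping (e.g. treating a sensor/regulator pair as one locus) is left
to user-supplied panels rather than guessed.

## Numerical and edge-case conventions

* Left-alignment loop re-anchors on the right only at position 1.
* A variant overlapping two CDS yields one consequence row per CDS;
  calls truncated by the sequence end carry a `border` flag.
* `set_specific` gene presence = local alignment at ≥ 80% identity over
  ≥ 80% of the gene, anchored by a shared unique 21-mer (no shared
  21-mer ⇒ absent; at the threshold identity a shared 21-mer is
  expected with overwhelming probability for gene-length sequences).
* All randomness flows from one top-level seed through fixed
  per-stage derived streams; identical inputs and seed give
  byte-identical outputs.

## Problem sizes used in validation

The suite validates on: 50 kb / 40-gene genomes with 200 mutations for
exact-recovery round trips (50 seeds); 150 kb genomes at ~1000 SNPs for
spectrum recovery; 20 seeds at 500 events for signature calls; 30 kb /
28-gene genomes with 1000-SNP replicates for Ka/Ks calibration; 60 kb /
80-gene genomes for the transfer-chain phylogeography (≥ 20 mutations
per edge, 20 seeds); brute-force enumeration cross-checks on genomes
≤ 10 kb; and 100 random matrices of ≤ 6 taxa for the clustering
oracles. These sizes were chosen as the smallest at which each property
is statistically unambiguous.

## Known limitations

* The caller requires collinearity; rearranged genomes error out by
  design and structural variation is not called.
* Allelic distances saturate: a target counts once no matter how many
  mutations hit it, so on heavily mutated lineages cgMLST distances
  compress and UPGMA's merge margins shrink. Topology recovery from
  allelic distances therefore needs a root-light transfer geometry
  (early edges clearly shorter than later ones, as in a real
  collection history); the SNP/indel presence/absence Manhattan route
  is exactly additive and is the more reliable of the two at high
  divergence.
* cgMLST allele calling assumes the query is the same strain
  (near-identity); it is not a general ortholog finder.
* Signature thresholds are tuned for hundreds of events; weak mutators
  at low divergence will return no flags rather than a borderline call.
* The Ka/Ks expectation conditions on the observed ts fraction; with
  very few SNPs that estimate is noisy and the ratio inherits the
  noise.
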