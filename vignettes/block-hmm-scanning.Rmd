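---
title: "Finding Dscam-family genes and hypervariable exon arrays with conserved-block profile HMMs"
author: "dscamtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding Dscam-family genes and hypervariable exon arrays with conserved-block profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscamtools)
```

## The problem

*Dscam* genes are hard to find with BLAST-style reciprocal searches: their
coding sequence is scattered over many short exons separated by large
introns, and the hypervariable form (*Dscam-hv*) additionally carries
tandem arrays of dozens of mutually exclusively spliced exon variants.
An ordinary local alignment cannot bridge the introns, and a single
full-length model would have to cross exon boundaries that move between
species.

`dscamtools` implements the detection strategy that works around this:

1. From a protein alignment of known family members, extract short,
   highly conserved **blocks** that cross no annotated exon boundary
   (`extractBlocks()`).
2. Build one **profile HMM** per block (`buildProfile()`), calibrate its
   score null distribution (`calibrate()`).
3. **Six-frame translate** genome scaffolds, split at stop codons, and
   score every stop-free segment against every block
   (`scanGenome()`).
4. Call a scaffold a **gene candidate** when at least *k* of the *n*
   blocks hit it *in the genomic order matching the block order*
   (`callCandidates()`; 6 of 10 at E ≤ 0.001 by default).
5. Chain the block hits into a gene model and stitch the matched
   peptides (`chainGeneModel()`).
6. Between constant-exon anchors of a candidate, scan intronic DNA in
   all six frames for **hypervariable exon variants**, flagging copies
   on the opposite strand as candidate inversions
   (`scanExonVariants()`).

Because a block never spans an exon boundary, each block lies inside one
exon, and an intron interrupting the gene cannot interrupt a block
match; the *order* of the block hits on the scaffold then carries the
architectural signal that single-hit methods lack.

## The profile HMM

Each block is modelled Plan7-style: per-column match states with 20-way
emission distributions, insert states emitting background, delete
states, and per-column transition groups (`M→{M,I,D}`, `I→{M,I}`,
`D→{M,D}`). Columns with gap fraction < 0.5 become match states.
Emissions use background-proportional pseudocounts,

$$e_j(a) = \frac{c_j(a) + \alpha\,bg(a)}{n_j + \alpha},$$

with $\alpha = 1$ by default and the Robinson–Robinson background
(`robinsonBackground()`; a uniform background is available). Training
sets are small (a handful of sequences), so sequences are weighted
uniformly.

Scoring is local log-odds in bits by Viterbi dynamic programming:
uniform entry $1/L$ into any match state, free exit from any match
state, unknown residues (`X`) emitting at background. A forward variant
(`forwardScore()`) sums over paths and always dominates the Viterbi
score. The stop symbol is never scored: scanning operates on stop-free
segments only, which also guarantees that every reported hit translates
cleanly.

## Calibration and E-values

`calibrate()` scores `nSamples` i.i.d. background sequences of length
`sampleLen` and fits a Gumbel by maximum likelihood:

$$P(S > s) = 1 - \exp(-e^{-\lambda (s - \mu)}), \qquad
E = D \times P(S > s),$$

with $D$ the number of translated segments in the search. Defaults are
`nSamples = 5000` (the sample size classic HMM calibration used) and
`sampleLen = 100`. E-values are per-search; they will not numerically
match values from other engines whose database conventions differ, so
all thresholds (0.001 for block matches, 0.01 for the longer
hypervariable-gene models, 0.001 for exon variants) are configuration,
not constants.

**Approximation quality.** The Gumbel is the correct asymptotic family
for optimal local alignment scores, but for short blocks
(20–30 match states) its fit to the *bulk* of the null distribution is
imperfect: across our block models the best achievable two-parameter
fit leaves a Kolmogorov–Smirnov distance of roughly 0.06–0.12 to fresh
null scores, and maximum-likelihood fits sit at the upper end of that
range. We verified that the deviation is intrinsic — minimum-distance
fits, longer null sequences, multihit score accumulation and a fully
probabilistic local model with flanking states all leave a comparable
bulk misfit — which is consistent with standard practice in the field,
where extreme-value calibration is fitted to (and trusted in) the tail.
The *tail* is what matters here: binomial checks of the fraction of
fresh null scores below p-values 0.1 and 0.01 pass, and every decision
the pipeline makes uses tail E-values many orders of magnitude below
these. The package therefore keeps the spec-simple full-sample ML
Gumbel and documents the bulk approximation rather than hiding it; the
test suite asserts tail calibration sharply and bulk uniformity at the
preset KS bound 0.15.

## The ordered k-of-n rule

Hits are retained per (scaffold, HMM) — the best two by default — and a
candidate requires at least `kMin` blocks whose hits are strictly
collinear with block order (nt midpoints increasing with block index on
`+`, decreasing on `-`). Midpoints avoid ambiguity from unequal hit
lengths. The collinear subset is found as a heaviest strictly
increasing subsequence (count first, summed bit score as tie-break) and
is verified in the test suite against exhaustive enumeration on
thousands of random instances. Candidates are called per strand;
cross-strand mixing is disallowed (inversions are monitored at the exon
level instead, where all six frames are scanned). Hits from different
frames on the same strand may combine, since exons need not share
frame.

`chainGeneModel()` resolves alternatives with a chain DP maximising
total bit score minus a gap penalty (0.001 bits/nt by default — small
enough that intron-scale gaps never outweigh a real hit), subject to
block order and non-overlap, and stitches the matched peptides in block
order.

## What the synthetic data emulate — and what they do not

The synthetic module generates the study conditions the detector
assumes:

* `randomGenome()` — i.i.d. nucleotide scaffolds at a chosen GC; the
  negative control is 1,000 scaffolds × 30,000 nt (the original
  negative control was 55,000 × 30,000; the generator reaches that
  scale by configuration, the desk-scale default keeps the run in
  minutes).
* `syntheticFamily()` — a 600-residue ancestor split into 10 exons of
  60 aa, with 5 family members at 15% per-site divergence. This gives
  conserved blocks of realistic information content while remaining
  desk-scale; real Dscam-like training sets were 7 sequences over a
  much longer alignment.
* `plantGene()` — uniform synonymous codon reverse-translation,
  introns with `GT`…`AG` ends and an in-frame stop within the first
  9 nt (formalising why block HMM matches terminate at exon
  boundaries), per-nt substitution noise. Mutation draws are coupled
  across rates under a fixed seed, so recovery sweeps are nested by
  construction.
* `plantExonArray()` — tandem arrays of a 150-nt base exon at 10%
  per-nt divergence with 60-nt spacers, in the printed cluster sizes
  12/48/33; cluster HMMs train on 3 representatives
  (`syntheticExonFamily()`), mirroring the
  one-representative-per-clade rule.

Real genomes differ in ways these fixtures deliberately omit: repeats,
assembly gaps, composition bias and codon usage (a hook for a codon
bias table exists in the generator design), paralogous families, and
splice-site structure beyond the `GT`/`AG` dinucleotides. Passing the
synthetic benchmark therefore demonstrates that the machinery is
correct and calibrated under its own assumptions — not that sensitivity
on diverged real genomes matches the original study, which used
full-genome assemblies and a different HMM engine.

## Numerical and design choices

* Ties in block extraction break to the leftmost, then longest window;
  the conservation score is mean majority-residue identity with gaps
  scoring zero. The original ten regions were chosen manually; this is
  a deterministic, reproducible formalisation.
* Representative selection cuts the tree at `treeHeight - height` from
  the root and returns each cluster's patristic medoid (lexicographic
  on ties); tree building itself stays external.
* The k-of-n rule is evaluated per scaffold per strand (the original
  text does not say whether strands were pooled; this is configurable
  via `sameStrand`).
* `hv_k_min` defaults to 11, reading "more than 10" strictly;
  the exon-variant cutoff defaults to 0.001 (the main-text value; a
  supplementary figure legend says 0.0001 — both reachable via
  configuration).
* Overlapping exon-variant hits are resolved greedily by ascending
  E-value, discarding a hit that overlaps a kept one by more than 50%
  of the shorter interval; how the original study merged overlaps (if
  ever needed) is unstated.
* Degenerate inputs: empty sequences score `-Inf` with an empty
  interval; all-gap training columns abort the build; zero-variance
  calibration scores abort calibration; `N`-containing codons translate
  to `X`, which scores 0 bits everywhere (so all-`N` scaffolds can
  never reach a positive threshold).
* Problem sizes in the test suite: the negative control scans
  1,000 × 30,000 nt with all 10 block HMMs; the cut-off sweep uses 50
  scaffolds plus one planted gene; oracle equivalence runs 1,000 random
  instances of up to 12 hits; calibration soundness uses 1,000 fresh
  nulls; the array benchmark plants 12/48/33 variants at divergences
  {0, 0.1, 0.2, 0.3}.

## Known limitations

* Single-hit local scoring per segment (multiple hits per segment are
  recovered by rescanning the flanks of accepted hits); no
  biased-composition correction; no splice-site refinement of exon
  hit boundaries — hit intervals are alignment intervals, not spliced
  exons.
* Gumbel E-values are extrapolations far into the tail; they are used
  as ranked thresholds, as in the original analysis, not as literal
  expected counts.
* The pipeline emits phylogeny-ready FASTA/codon alignments
  (`backTranslate()`) but tree inference and ortholog naming are out of
  scope.
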