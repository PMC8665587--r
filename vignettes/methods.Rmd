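---
title: "Methods: measuring the divergence of duplicated gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the divergence of duplicated gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dupdiverge` implements the analyses used to characterize large, rapidly
evolving duplicated gene families — the motivating case being the nematode
F-box family, whose copy number ranges from tens to over a thousand genes
across *Caenorhabditis* species. Six questions are addressed: how much of a
family arose by tandem duplication; how copy number changed along the
species phylogeny; by which structural mechanisms paralog siblings diverged;
whether short tandem repeats drive intron elongation; what selective
pressure acts on paralog pairs; and whether paralogs diverged in
stage-specific expression. Every stage also has a simulator that generates
its inputs with planted ground truth, so the whole pipeline is scored
end-to-end without any external data.

## Tandem duplication from gene order

Two family members on the same chromosome are linked when no more than
`max_gap` genes (default 20, counted in the complete gene catalog, not just
family members) lie between them; clusters are the connected components
under transitive chaining, so arrays larger than two arise from successive
links even when their ends are farther apart than the gap rule. Chaining is
the natural reading of an intergenic-distance criterion — without it no
cluster could exceed two members — but a `chain = FALSE` mode imposes the
gap rule on every member pair (a diameter bound) for sensitivity analysis.
Members of size-one components are "single" genes; the tandem percentage is
`100 * n_tandem / family_size`, rounded to the nearest integer. Density
tracks count family genes per 1-Mb window by gene start, including the
final partial window. Treating contigs as chromosomes can only break links,
so fragmented assemblies underestimate tandem counts; this monotonicity is
asserted in the tests.

## Duplication–loss reconciliation

Gene trees are reconciled against the species tree by LCA (last-common-
ancestor) mapping: each gene-tree node maps to the species-tree LCA of its
descendant leaves' species; an internal node is a duplication exactly when
it maps to the same species node as one of its children, otherwise a
speciation. Losses on a gene-tree edge `(u, v)` are the species nodes
"passed through": with `d` the species-tree path length from `map(u)` to
`map(v)`, an edge contributes `d - 1` losses below a speciation and `d`
below a duplication (the off-path sibling of every traversed node gains one
loss). Under unit costs the LCA mapping attains the minimum
duplications + losses, which the test suite verifies against an exhaustive
search over all valid mappings — every topology with up to four leaves on a
three-species tree (1305 cases), plus random five- and six-leaf gene trees;
the exhaustive window was kept at four leaves because the case count and
the brute-force search both grow super-exponentially beyond it, while the
random layer covers the larger sizes.

Aggregation records, per species branch, the duplications mapped to the
branch's child node and the losses attributed to it, plus one "origin" gain
per family on the branch entering the species LCA of its observed species —
so a family absent from a clade contributes no phantom losses above its
root. Ancestral copy numbers follow top-down from
`count(child) = count(parent) + gains - losses`, which makes the
bookkeeping identity checkable at the extant leaves. Parsimony is exact
when no losses occurred (asserted on simulated forests with zero loss
rate) and otherwise a lower bound on the true event counts, since a
duplication whose copies all died leaves no trace.

## Structural divergence of sibling pairs

Each exon of one sibling is aligned against the full genomic span of the
other by Smith–Waterman local alignment with affine gaps (match +2,
mismatch −3, gap open −5, gap extend −2 per base, so a length-L gap costs
`5 + 2L`). Alignments shorter than 30 bp or below 60% identity mean "no
counterpart" — thresholds mirroring the dot-plot stringency below. An
accepted alignment is assigned to target exons (reciprocal overlap of at
least half the shorter feature), to a target intron (contained within ±10
bp), or to nothing. Five mechanism rules are applied in fixed priority
order:

1. **Exon split** — one exon corresponds to two adjacent exons of the
   sibling. Detected from either direction: the alignment may bridge the
   novel intron with one long gap, or the two sibling exons each map into
   disjoint parts of the one exon.
2. **Exonization / pseudoexonization** — an exon's homolog lies inside the
   sibling's intron.
3. **Exon/intron gain/loss** — an exon with no counterpart at all.
4. **Boundary alteration** — a one-to-one matched exon pair whose annotated
   lengths differ by at least 3 bp while flanking introns stay within the
   elongation factor. Annotated lengths are used rather than alignment
   end-trimming because local alignment shaves mismatched ends, which would
   fake small offsets on heavily mutated exons.
5. **Intron elongation** — an intron whose flanking exons both match
   one-to-one (the operational definition of intron homology) with length
   ratio `max/min > 2`. The ratio is direction-symmetric because without an
   outgroup the polarity (elongation vs contraction) is unknowable; all
   event polarities are reported as `UNKNOWN` for the same reason.

The priority order (split > exonization > gain/loss > boundary >
elongation) makes the "primary mechanism" deterministic when events
co-occur — an exonized or deleted exon, for example, necessarily also
perturbs the flanking intron lengths, and the more specific signal should
win; all events are still reported, so per-pair tallies can be read either
as primary-only or as any-occurrence counts. Features explained by a
higher-priority event are excluded from the lower-priority rules.

The pair simulator plants exactly one event per pair on a 5-exon gene
(exons 100–300 bp, introns 80–200 bp) and applies 5% per-site point
mutations. Gain/loss plants whole-exon gains or losses: an intron gain is
structurally identical to an exon split (and an intron loss its mirror), so
those events are deliberately left to the split rule. Planted-mechanism
recovery is ≥ 90% over 250 pairs and mutation-only pairs stay quiet in
≥ 95/100 — both asserted.

## Dot-matrix repeat detection

The self dot matrix compares every pair of 30-bp windows at stride 1 and
records pairs agreeing at `ceil(0.6 × 30) = 18` or more positions
(forward-strand direct repeats only). At these settings the per-pair hit
probability on random DNA is the binomial tail
`P(X ≥ 18), X ~ Bin(30, 0.25) ≈ 5e-5`, so a random kilobase yields ~20
isolated matches and short chance runs are common; calling therefore
requires collinear runs of at least 10 adjacent window starts (a true
tandem array of `c` copies of a `u`-bp unit produces runs of roughly
`(c-1)u - 30` windows at offset `u`, far above the cutoff, while chance
runs of 10 require a ≥ 40 bp stretch at 60% identity). A region is called
when at least two runs sit at near-multiples (±2 bp) of a common unit —
the modal spacing of the run offsets, which is also the unit-length
estimate; the span is taken from the fundamental-offset runs only, since
higher multiples and coincidental near-multiple runs can only inflate it.
Planted units of 30/50/80 bp are recovered within ±2 bp with ≥ 90% span
overlap, and at most 1 in 100 random kilobase sequences produces any call.

## Selection: NG86 dN/dS with Jukes–Cantor correction

Synonymous sites per codon are counted position-wise as the fraction of
single-base alternatives that preserve the amino acid, excluding
alternatives that create stop codons from the denominator (so every sense
codon contributes exactly 3 sites). Differences between codons are averaged
over all orderings of the differing positions, excluding pathways through
stop codons (renormalizing over the rest; if every pathway passes through a
stop, all are used and the codon is flagged). Sites are averaged over the
two sequences; `pS = Sd/S` and `pN = Nd/N` receive the Jukes–Cantor
correction `d = -(3/4) ln(1 - 4p/3)`, undefined at `p ≥ 3/4` (saturation,
flagged). `ω = dN/dS` is reported as undefined — not 0, not infinity — when
`dS = 0`, and such windows are excluded from selection classes. Codons
containing gaps or ambiguous bases are dropped pairwise.

Sliding windows span 45 codons with a 9-codon step (window counts follow
`floor((L - 45)/9) + 1`); windows are classified positive above ω = 1.5 and
purifying below 0.67. The window unit is codons, not base pairs: a 45-codon
window matches the scale of protein structural domains, which is the
stated motivation for the window size, whereas 15 codons would not.
Terminal summaries group windows lying entirely within the first 50 codons
(the span of the family-defining N-terminal domain) as N-terminal and
entirely within the last 50 as C-terminal; a single whole-sequence window
belongs to both. The whole estimator is checked to 1e-9 against an
independent brute-force oracle (mutant enumeration, pathway permutation,
closed-form correction) on 200 random pairs.

The codon-pair simulator evolves a random stop-free sequence by proposed
single-base changes: stops rejected, synonymous changes always accepted,
nonsynonymous accepted with probability `min(1, ω)`. This
acceptance-rejection scheme is simpler than a full codon-substitution
matrix and makes the realized ω measurable exactly from the recorded
substitutions; recovery is scored against that realized value (mean
estimated ω within ±0.15 at 500 codons, asserted at ω = 0.2 and 0.5 over
100 pairs each with 300 proposal attempts — enough substitutions for a
stable estimate while staying far from saturation).

## Expression divergence

Expression matrices (FPKM-like, genes × developmental stages) are
log-transformed (`log2(x + 1)`) and standardized per gene to z-scores
across stages. Genes with zero variance, or with less than a 2-fold range
across stages (`min_range = 1` on the log2 scale), receive an all-zero
profile and a flag: standardizing a no-signal profile only amplifies
measurement noise to unit variance and would scatter such genes randomly
across pattern clusters. Patterns are grouped by Euclidean k-means on the
z-profiles (k = 8, best of 20 seeded restarts, deterministic given the
seed). A gene is stage-specific when exactly one stage reaches z ≥ 1.5 —
an explicit operationalization of calling out the deviant stage from a
gene's mean. A paralog pair is expression-divergent when the Pearson
correlation of z-profiles falls below 0.5 **or** both genes are
stage-specific with different peak stages; both sub-criteria are reported
separately so a stricter or looser reading can be reconstructed, and pairs
involving a flat profile are decided on peaks alone and flagged. The
simulator plants one-peak-per-stage archetypes (peak 2^8, baseline 2^2 on
the FPKM scale) plus a flat-low archetype, with Gaussian log-scale noise
(sd 0.2 for the scored runs); clustering recovers planted archetypes at
ARI ≥ 0.9 and pair flags at ≥ 90%, asserted.

## Numerical and interface conventions

* Coordinates are 1-based inclusive throughout, matching GFF3 on disk and
  the conventions of the R genomics stack; exon/intron arithmetic is
  asserted to conserve gene-span length.
* The longest-CDS isoform represents each gene, ties broken by smallest
  transcript id; records with overlapping exons are dropped with a warning.
* Newick polytomies are resolved deterministically (left-to-right
  caterpillar) and the resolution is recorded on the returned object.
* Minus-strand genes store exons in genomic order; spliced sequences are
  reverse-complemented on extraction.
* Every simulator is a pure function of its seed (asserted), and the
  pipeline driver writes a manifest with input digests so identical inputs
  and seed reproduce byte-identical outputs (asserted).
* Scales used by the scored runs: 250 structural pairs (50 per mechanism),
  200 random NG86 pairs of up to 60 codons, 100 ω-recovery pairs per level,
  200 random tandem catalogs, 100 random kilobases for dot-plot
  specificity, 400-gene expression matrices. These sizes give stable
  pass/fail margins for the asserted thresholds.

## What the simulations do and do not show

The generators reproduce the *structure* of real data — gene order with
planted arrays, one planted structural event per pair, known substitution
types, known birth–death events, known expression archetypes — but not its
full texture: nucleotide composition is uniform, codon usage unbiased,
exons experience no indels, expression noise is homoscedastic Gaussian on
the log scale, and annotation error is absent. Passing the planted-truth
checks therefore demonstrates that each method recovers what it is designed
to recover under its stated assumptions; it does not certify performance on
real annotations, where isoform ambiguity, assembly fragmentation, and
alignment artifacts add error modes the simulators deliberately omit.
Known limitations: reconciliation assumes binary rooted trees and unit
costs (no transfer events, no rearrangement of weakly supported nodes);
structural polarity requires an outgroup the pipeline does not consume;
dot-plot detection is forward-strand only; and the expression divergence
rule is an explicit interpretation of an under-specified published
procedure, exposed through its two sub-criteria.
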