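# dupdiverge

Analysis toolkit for the evolution of large duplicated gene families — the
motivating case being the nematode F-box family, whose copy number spans
tens to over a thousand genes per species. Given gene annotations, gene
trees, coding sequences and expression matrices, the package answers six
questions about a family:

1. **Tandem duplication** — how many family members sit in tandem arrays?
   Two members are linked when at most 20 genes of the full gene order lie
   between them; clusters are transitive closures of those links.
2. **Copy-number history** — duplication–loss maximum-parsimony
   reconciliation of gene trees against the species tree (LCA mapping),
   aggregated into per-branch gains/losses and ancestral family sizes.
3. **Structural divergence** — a five-mechanism classifier for paralog
   sibling pairs based on Smith–Waterman alignment of each exon against the
   sibling's genomic span: exon split, exonization/pseudoexonization,
   exon/intron gain/loss, exon–intron boundary alteration, and intron
   elongation (homologous intron length ratio > 2).
4. **Repeat-driven intron growth** — self dot-matrix analysis (window 30,
   minimum identity 60%) with tandem-repeat calling from collinear
   off-diagonal runs at near-multiples of a common unit.
5. **Selection pressure** — Nei–Gojobori (1986) dN/dS with the
   Jukes–Cantor correction `d = -(3/4) ln(1 - 4p/3)`, whole-gene and in
   45-codon sliding windows (step 9), classified positive at ω > 1.5 and
   purifying at ω < 0.67.
6. **Expression divergence** — z-score stage profiles, k-means pattern
   clustering (k = 8), stage-specificity calls, and divergence calls for
   paralog pairs (profile correlation < 0.5 or mismatched specific peaks).

Every stage has a matching simulator (`sim_*`) that generates its inputs
with planted ground truth, so the whole pipeline runs and is scored
end-to-end with no external downloads.

## Worked example

```r
library(dupdiverge)

## NG86 dN/dS: nine Phe codons, one synonymous third-position change
pairwise_dnds(strrep("TTT", 9), paste0("TTC", strrep("TTT", 8)))
#> <dnds_result> 9 codons  S=3.00 N=24.00  Sd=1.00 Nd=0.00  dS=0.4408 dN=0.0000  omega=0.000
```

One synonymous difference over 3 synonymous sites gives `pS = 1/3`, which
the Jukes–Cantor correction inflates to `dS = 0.4408`; with no
nonsynonymous differences, `dN = 0`.

```r
## a paralog pair whose second intron grew from 64 bp to ~900 bp
pr <- sim_paralog_pair("INTRON_ELONGATION", intron_len = c(64L, 64L),
                       elongation_factor = 14, seed = 64)
dv <- classify_pair(build_correspondence(pr$A, pr$B), pr$A, pr$B)
dv
#> <divergence_events> primary: INTRON_ELONGATION (1 event(s))
#>           mechanism feature_A feature_B
#> 1 INTRON_ELONGATION   intron2   intron2
dv$events$detail
#> [1] "homologous intron lengths 64 vs 914 (ratio 14.28)"

## the inserted ~50 bp tandem repeats are visible in a self dot matrix
rp <- sim_repeat_sequence(unit_len = 50, n_copies = 6, flank_len = 500,
                          mutation_rate = 0.02, seed = 5)
call_repeats(self_dot_matrix(rp$seq))
#>   start end unit_length n_runs mean_offset
#> 1   484 813          50      5         150
```

The planted repeat (6 × 50 bp at positions 501–800) is recovered with the
exact unit length and a span that covers the array.

## Analysis workflow

The `analysis/` scripts run the whole study on a simulated dataset with
planted truth, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R        # dataset + ground_truth.json
Rscript analysis/02_tandem_and_density.R   # tandem arrays, 1-Mb density
Rscript analysis/03_reconcile_families.R   # per-branch gains/losses
Rscript analysis/04_structural_divergence.R
Rscript analysis/05_dotplot_repeats.R
Rscript analysis/06_selection_scan.R
Rscript analysis/07_expression_divergence.R
```

`run_all()` performs the same stages programmatically on any dataset
directory and writes a reproducibility manifest (input digests, seed, row
counts); identical inputs and seed give byte-identical outputs.

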