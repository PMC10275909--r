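# wcsea — Weighted Concept Signature Enrichment Analysis

Pathway-enrichment analysis for weighted (WCSEA) and unweighted (CSEA)
gene lists, built to stay stable under the high noise and dropout rates
of single-cell RNA-seq. It is aimed at anyone who has a differential
expression result — a signed statistic per gene, or a plain list of
regulated genes — and wants pathway rankings that do not reshuffle when
a fraction of the expressed genes goes missing.

## The method in brief

Rather than testing each pathway directly against the measured gene
list, the package first characterizes the list by its **molecular
concept signature**: every concept *i* (a knowledge-derived gene set —
ontology term, pathway, interaction neighborhood, domain family) gets a
weight

- CSEA: ω<sub>i</sub> = |T ∩ C<sub>i</sub>| / √(|T||C<sub>i</sub>|)
  (Ochiai similarity with the target list T),
- WCSEA: ω<sub>i</sub> = max(0, NES<sub>i</sub>) from a weighted
  Kolmogorov–Smirnov (WKS) test of the concept in the weight-ranked
  list, with NES = ES / mean(same-sign ES<sub>random</sub>).

Each gene *x* is then scored by the redundancy-penalized cumulative
signature (the **uniConSig score**)

    uniConSig(x) = Σᵢ ωᵢ/εᵢ / sqrt(Σᵢ 1/εᵢ),   εᵢ = Σⱼ O(Cᵢ, Cⱼ)

where ε cumulates the Ochiai similarity of concept *i* with the other
concepts containing *x* (self term included, so ε ≥ 1), discounting
redundant knowledge. Pathways are finally tested by the WKS running sum
on the uniConSig-sorted genome, with permutation NES, p-values and BH
q-values. Downstream modules disambiguate pathway crosstalk
(deletion–retest of overlapping pathways), compute CSEA-based
pathway–pathway association matrices with network export, and benchmark
rank stability under simulated expression dropouts.

## Worked example

Everything below is synthetic and self-contained: the fixture generator
plants pathway `P01` (a +3 mean shift on its genes over N(0,1) noise)
and builds signature concepts around it.

```r
library(wcsea)

fx  <- generate_fixture(seed = 42)   # 1000 genes, 60 concepts, 30 pathways
tab <- run_wcsea(fx$weighted, fx$compendium, fx$pathways,
                 n_perm = 1000, seed = 7)
print(tab, n = 5)
#> pathway_table (wcsea, up): 30 pathways tested, 0 skipped
#>  rank pathway     es   nes  p_value q_value n_overlap
#>     1     P01 0.9948 2.791 0.000999 0.02997        36
#>     2     P03 0.4974 1.340 0.053000 0.73000        25
#>     3     P27 0.4890 1.304 0.073000 0.73000        23
#>     4     P14 0.4369 1.218 0.116883 0.78273        33
#>     5     P18 0.4347 1.188 0.152847 0.78273        29
#> ... and 25 more rows
summary(tab, q_cutoffs = c(0.05, 0.25))
#> WCSEA enrichment, direction up; seed 7, 1000 permutations
#>   q <= 0.05  : 1 pathways
#>   q <= 0.25  : 1 pathways
```

The planted pathway is recovered at rank 1: its ES ≈ 0.99 says its
genes sit essentially at the top of the uniConSig ranking, NES ≈ 2.8
normalizes that against random same-size gene sets, and it is the only
pathway significant at FDR 0.05 — the 29 unplanted pathways behave as
nulls. From here, `disambiguate(tab, ...)` prunes pathways that are not
independently enriched, `associate(...)` + `export_network(...)` build
the pathway association heatmap/network, and
`dropout_benchmark(fx, ...)` reruns everything under 20%/50% gene
dropout and reports rank variations. `plot(tab)` draws the classic
running-sum enrichment curve.

A command-line front-end with the same functionality is installed as
`exec/wcsea` (subcommands `run`, `disambiguate`, `associate`,
`fixture`, `benchmark`; try `--help`).

For real data, supply your own concept compendium and pathway
collection as GMT files (`read_gmt()`) and your DE statistic as a
two-column TSV (`read_weighted_list()`); analyze up- and down-regulated
directions in separate runs. See the vignette in `vignettes/` for the
model, parameter meanings and design choices.

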