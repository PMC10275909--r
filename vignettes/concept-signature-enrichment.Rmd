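---
title: "Concept-signature pathway enrichment: model, parameters and design choices"
author: "wcsea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-signature pathway enrichment: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcsea)
```

## The problem

Pathway enrichment on single-cell RNA-seq differential-expression output
is fragile: dropouts and amplification noise mean that the measured DE
statistic of any individual gene is unreliable, so methods that test a
pathway directly against the measured gene list (over-representation
tests, GSEA-style running sums) can reshuffle their pathway rankings
badly when a fraction of the expressed genes goes missing.

Concept signature enrichment analysis (CSEA), and its weighted variant
WCSEA, take an indirect route. Instead of asking "are this pathway's
genes high in the DE list?", they first ask "which *molecular concepts*
— knowledge-derived gene sets from ontologies, pathway databases,
interaction neighborhoods, protein domain families — characterize the
DE list?", and then score **every** gene in the genome by how strongly
its concept memberships match that signature. Pathway enrichment is
finally tested on this genome-wide, signature-sorted ranking. Because a
concept's enrichment is estimated from many genes at once, the
signature — and hence the pathway ranking — is buffered against the
loss or corruption of individual measurements.

## The model

### Concept weights

Given a molecular-concept compendium, each concept $i$ receives a
weight $\omega_i \ge 0$ measuring its enrichment in the input:

* **CSEA** (unweighted target list $T$): the Ochiai (cosine) set
  similarity
  $\omega_i = |T \cap C_i| / \sqrt{|T|\,|C_i|}$.
  Ochiai rather than Jaccard because a small concept fully contained in
  a large one still scores $\sqrt{|A|/|B|}$ instead of the vanishing
  $|A|/|B|$.
* **WCSEA** (weighted list, e.g. a signed DE statistic per gene): a
  weighted Kolmogorov–Smirnov (WKS) running-sum test of the concept
  against the weight-ranked list; $\omega_i = \max(0, \mathrm{NES}_i)$.
  Depleted concepts (negative NES) are floored to zero rather than kept
  with absolute value: a concept anti-correlated with up-regulation is
  not evidence of functional relatedness to the up-regulated program.
  Up- and down-regulation are analyzed in separate runs; the down run
  negates the weights before ranking.

### Redundancy penalization and the uniConSig score

Knowledge bases are redundant — the same pathway appears under several
names, neighborhoods overlap, ontology terms nest. For a gene $x$ with
concept set $S_x$ (restricted to concepts with $\omega > 0$), each
concept $i \in S_x$ gets a penalization factor

$$\varepsilon_i = \sum_{j \in S_x} O_{ij},$$

the cumulated Ochiai similarity of concept $i$ with the other concepts
of the same gene, **including the self term** $O_{ii} = 1$, so
$\varepsilon_i \ge 1$ and a lone concept is not penalized at all. The
effective weight is $EW_i = \omega_i/\varepsilon_i$, the effective
concept number is the harmonic-style sum
$ECN = \sum_i 1/\varepsilon_i$, and the gene's score is

$$\mathrm{uniConSig}(x) = \frac{\sum_i \omega_i/\varepsilon_i}
                               {\sqrt{\sum_i 1/\varepsilon_i}}.$$

The square root damps the influence of sheer concept count, so the
score behaves like a redundancy-adjusted average of the concept
weights. Scores are min–max normalized to $[0,1]$ across the genome.

Two deliberate refinements:

* **Zero-weight concepts are excluded** from both sums. A non-enriched
  concept should neither add signal nor dilute $ECN$; this also makes
  the single-concept closed form exact
  ($\mathrm{uniConSig} = \omega$ for a gene in one concept).
* **Exact duplicate gene sets are collapsed** to one representative per
  gene before $\varepsilon$ is computed. The $\varepsilon$ scheme is
  motivated as being equivalent to removing duplicated concepts, and
  for an isolated group of $m$ identical concepts it is
  ($\varepsilon = m$ each, so the group contributes exactly what one
  copy would). But when a duplicated concept also partially overlaps a
  *third* concept of the same gene, keeping the copies shifts every
  $\varepsilon$ and the equivalence breaks (a two-concept worked
  example moves the score by over 1%). Collapsing exact duplicates
  makes the removing-duplicates equivalence an identity, which is the
  behavior the partial-overlap penalization is designed to approximate;
  partial overlaps are still handled entirely by $\varepsilon$. The
  standalone `penalization_factors()` keeps duplicates visible, so the
  textbook values ($\varepsilon = [2, 2]$ for a gene in two identical
  concepts) remain inspectable.

### Pathway testing on the signature-sorted genome

The enrichment universe is the concept universe plus any input genes;
genes with no positive-weight concept sit at score 0 and pad the tail
— functional relevance, not measurement, determines rank. Each pathway
is then tested by the WKS running sum on this ranking: hits step up
proportionally to $|w|^{p}$ (exponent $p = 1$ by default, $p = 0$ gives
the classic rank-only K-S), misses step down by $1/(N - N_{hit})$, ES is
the signed extremum. NES divides ES by the mean of same-sign ES values
from random gene subsets of equal size ("sign-matched" normalization,
the standard GSEA convention; the alternative of normalizing against
the pooled null is not well defined when the two tails have different
scales). The permutation p-value uses add-one smoothing
$(k+1)/(n+1)$, so it is never exactly zero; q-values are
Benjamini–Hochberg by default.

The null model permutes **gene subsets**, the only option available to
a tool that consumes gene-level lists rather than expression matrices.
Nulls are stratified by overlap size, shared across equally-sized sets,
and generated in sorted-size order under one seed — identical gene sets
therefore receive identical NES, and results are invariant to the order
of concepts or pathways in their files.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `min_size`, `max_size` (GMT) | 5, 2500 | concepts below 5 genes make Ochiai unstable; bounds are explicit and user-configurable because knowledge bases differ |
| `exponent` | 1 | GSEA-style weighting; 0 for rank-only |
| `n_perm` | 1000 | permutation resolution; the smallest attainable p is $\approx 1/(n_{perm}+1)$ |
| `seed` | none (required) | every stochastic entry point takes an explicit seed; there is no hidden RNG state |
| `min_concept_overlap` | 3 | concepts overlapping the weighted list in fewer genes are skipped during concept weighting |
| `min_pathway_overlap` | 5 | smaller overlaps give degenerate running sums |
| `alpha`, `method` (disambiguation) | 0.01, Bonferroni | conservative default for declaring a pathway *independently* enriched |
| dropout `fraction` | 0.2 / 0.5 | the two regimes benchmarked |

## Crosstalk disambiguation

Overlapping pathways inherit each other's enrichment. For every ordered
pair (stronger $A$, weaker $B$) among the top-$k$ (default 30) pathways
whose sets overlap appreciably (Ochiai $\ge 0.05$ or $\ge 3$ shared
genes), the remainder $B \setminus A$ is re-tested on the same ranked
genome. Implementation is two-pass: all triggered pairs are tested
first and their p-values adjusted as one batch (Bonferroni by default),
then removals are applied greedily in rank order — a removed pathway is
excluded from later pairings, and a weaker pathway can never remove a
stronger one. A remainder smaller than `min_overlap` (nested or
identical sets) is removed as *degenerate*: it cannot be independently
enriched. The two-pass design keeps the procedure deterministic and
idempotent; testing the symmetric remainder $A \setminus B$ (which
could dethrone the stronger pathway) is deliberately not done, keeping
the rank order authoritative.

## Pathway association

The functional association of pathways $i, j$ is the NES of $j$ under a
CSEA run that uses $i$'s genes as the target list — two pathways
sharing concept signatures associate even with little direct gene
overlap. The directed matrix is symmetrized by the arithmetic mean
(max available), and the diagonal is set to the row maximum purely as a
display convention for heatmaps. One shared seed drives all $K$
directed runs, which makes the matrix exactly equivariant under
relabeling of the pathway order. NES (not p) is kept as the score to
preserve magnitude for edge weights in the network export.

## The synthetic fixture generator

`generate_fixture()` emulates what a DE pipeline hands to this package,
at sizes chosen to be realistic for a focused analysis while keeping
the full test suite fast:

* background weights $\mathcal N(0, 1)$ — a signed z-like DE statistic;
* planted pathways receive an additive $+3$ mean shift — the effect
  size of a clearly regulated pathway in a well-powered comparison;
* per planted pathway, 8 *signature concepts* drawn 70% from the
  pathway's genes and 30% from the background — the concept redundancy
  that creates the method's buffer zone — plus unrelated random
  concepts (concept sizes 10–60, pathway sizes 20–40, 1000 genes, 60
  concepts, 30 pathways by default).

Regeneration under a fixed seed is byte-identical. What the generator
does **not** emulate: the heavy-tailed, zero-inflated shape of real DE
statistics, correlated (co-expressed) background genes, and a
knowledge base that is orders of magnitude larger and more nested than
60 synthetic concepts. Passing tests therefore demonstrate the
machinery and its qualitative robustness claims, not performance on any
real dataset; analyses of real scRNA-seq comparisons require a real
concept compendium and pathway collection in GMT format.

## Benchmark protocol

Dropouts are simulated by deleting exactly $\mathrm{round}(f \cdot N)$
genes from the weighted list uniformly at random — deletion rather than
weight-zeroing, since a dropped-out gene never reaches the DE output.
Each method is re-run on the perturbed list with the **same enrichment
seed** as its unperturbed run, so rank variation (original rank minus
perturbed rank; a pathway that disappears is assigned rank
$K_{new}+1$) isolates the dropout effect, and a zero-fraction
perturbation gives exactly zero variation. Five replicates per fraction
at 20% and 50% are the default grid; the plain WKS run on the raw
weighted list serves as the GSEA-like baseline. The shipped acceptance
checks use a 600-gene, 15-pathway fixture for this protocol and the
default 1000-gene fixture elsewhere; these sizes are stated here
because they define the conditions under which the package's
qualitative stability claim (WCSEA's planted-pathway rank variation no
worse than the baseline's) is reproduced.

## Numerical and degenerate-input conventions

* Ranking ties (equal weights or equal scores) are broken by gene id;
  an all-equal weighted list triggers a warning and falls back to the
  id ordering, deterministically.
* A running-sum extremum tie between the positive and negative side is
  resolved toward the earlier list position, matching a literal walk of
  the list.
* If a null contains no same-sign samples, NES is reported as 0 with
  p = 1 and a warning rather than NA, so downstream tables stay
  rectangular.
* All-hit gene sets score ES = 1 by convention; empty intersections are
  an error, not a silent zero.
* Degenerate normalization (all raw scores equal) maps every normalized
  score to 0 with a warning.
* Target genes are not excluded from their own scoring; the inputs to
  `uniconsig_scores()` are explicit, so a leave-one-out protocol can be
  assembled by the caller if desired.

## Known limitations

* Gene identifiers are opaque, case-sensitive strings; no symbol
  mapping is attempted. Lists and GMT files must be pre-harmonized.
* The permutation null is gene-subset based; sample-label permutation
  would require the expression matrix, which this package deliberately
  does not consume.
* Disambiguation is a greedy deletion–retest scheme, not a joint model
  of pathway overlap; with heavily chained overlaps the outcome depends
  on the (deterministic) processing order.
* Association matrices cost $K$ full CSEA runs; for large $K$ reduce
  `n_perm` or restrict to the disambiguated top pathways.
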