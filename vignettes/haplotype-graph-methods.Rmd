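---
title: "Haplotype graphs for autotetraploid genomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype graphs for autotetraploid genomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplograph)
options(haplograph.quiet = TRUE)
```

## The problem

Autotetraploid crops such as cultivated potato carry four divergent
chromosome copies (haplotypes). Sequence diversity between haplotypes is
extremely high (on the order of one variant per 50--60 bp), yet the number of
*distinct* haplotypes segregating in a breeding pool is small: in any given
genomic region most cultivars carry copies of a handful of founder
haplotypes. `haplograph` exploits this structure. Given a panel of phased
haplotype assemblies, it builds a **haplotype graph** whose nodes are
clusters of near-identical 100-kb haplotype blocks; a new cultivar can then
be genotyped against the graph with cheap short reads alone, by counting
node-specific k-mers and estimating how many of the query's four haplotypes
carry each node.

## Graph construction

The reference is tiled into non-overlapping windows (`make_windows`, 100 kb
by default; the last window of a chromosome may be shorter). Within each
window every haplotype is reduced to its SNP profile — its allele vector over
the window's variant positions — and haplotypes are clustered
(`cluster_window`) whenever their profile distance is below 10% of the
compared SNPs. Two choices here were genuinely open:

* **Distance denominator.** Missing calls are common in alignment-derived
  genotype tables. We count differences and compared sites over positions
  where *both* profiles are non-missing, which avoids penalizing alignment
  gaps; the alternative (the window's total SNP count) is available via
  `denominator = "window"`.
* **Linkage.** The merge relation "fewer than 10 differences per 100 SNPs"
  is not transitive. We use single linkage, the most literal reading of
  "clustered together if": any pair below threshold joins their clusters.
  The boundary is strict — a pair at exactly 10% stays apart.

Windows with zero variant positions carry no evidence to separate
haplotypes; instead of emitting 40 singleton nodes, all haplotypes collapse
into a single node flagged *indistinguishable* (`cluster_empty_window`).
Nodes in adjacent windows are connected by an edge whenever at least one
haplotype passes from one to the other (`build_edges`); the edge records the
supporting haplotypes. Each node's representative sequence comes from its
lexicographically smallest member, which is deterministic and harmless
because members are near-identical by construction.

### Marker k-mers

A canonical k-mer (the lexicographic minimum of the k-mer and its reverse
complement; k = 51 by default) is a **marker** of a node if it occurs in the
windowed sequence of every member, lies inside the optional synteny mask,
and occurs in *no other node's* windowed sequences anywhere in the graph
(`extract_markers`). Uniqueness is enforced graph-wide rather than only
within the window: that is the strictest reading of "unique to that node"
and guarantees that a read k-mer maps to at most one node. k-mers containing
non-ACGT letters are skipped. Because the graph can contain millions of
candidate k-mers, the set operations run in compiled code over 2-bit-packed
k-mers (k up to 63); `max_per_node` caps each node's marker set at the
lexicographically smallest candidates, which keeps downstream count tables
small without introducing randomness.

The synteny requirement is expressed as an optional BED mask because
whole-genome alignment is outside this package's scope; with no mask, every
position is eligible.

## Copy-number genotyping

For a query genome we observe, for every marker of every node, the count of
that k-mer in the query's short reads. Counts of a node's markers are
modelled as conditionally independent draws from a five-component Gaussian
mixture indexed by copy number $c \in \{0,1,2,3,4\}$:

$$x \mid c \sim \mathcal N(\mu_c,\ \alpha\,\max(\mu_c, 1)), \qquad
  \mu_0 = \varepsilon,\quad \mu_c = c\lambda \ (c \ge 1).$$

* $\lambda$ — haploid k-mer depth (counts per marker per haplotype copy).
  Tying the component means to multiples of one $\lambda$ halves the
  parameter count and removes label switching; the five classes *are* copy
  numbers by construction.
* $\varepsilon$ — the zero-copy mean, a small positive value absorbing
  sequencing-error k-mers; re-estimated but capped below $\lambda/4$.
* $\alpha$ — a variance scale giving Poisson-like mean–variance scaling with
  overdispersion; the floor of 1 in the variance keeps the zero-copy
  component proper.

`em_copy_numbers` alternates an E-step (per-node posteriors over $c$,
computed in log space from per-node sufficient statistics) with an M-step
(weighted least-squares update of $\lambda$, posterior-weighted updates of
$\varepsilon$, $\alpha$ and the class weights). Iteration stops when the
maximum absolute change over $(\lambda, \varepsilon, \alpha, w)$ falls below
0.001, or after 100 iterations. Counts above $8\lambda$ are winsorized
before each E-step to guard against repeat-derived k-mers that slip through
marker filtering.

Initialization matters: the count histogram of a tetraploid query is
multimodal with peaks near $\lambda, 2\lambda, 3\lambda, 4\lambda$.
`init_mixture` smooths the histogram (kernel density, bandwidth at least 1)
and starts $\lambda$ at the *lowest prominent mode* — any mode at least a
quarter the height of the tallest — because higher modes are the
multi-copy images of the same depth; starting at a higher mode can trap the
EM in a local optimum where copy classes shift by one. Counts below 6 are
excluded from mode finding when enough signal remains, since they belong to
the error component.

Nodes without markers are flagged *uninformative* and excluded from
fitting. `window_consistency_report` checks the tetraploid expectation that
copies in each window sum to 4 and flags deviations.

## Pseudo-contig stitching

Nodes with non-zero copies are connected into **pseudo-contigs**
(`stitch`): within each window a node with copy $c$ occupies $c$ lanes, and
a lane extends across a window boundary only when an edge leads to exactly
one supported successor with free capacity. Ambiguity — two supported
successors — terminates the pseudo-contig rather than guessing; this trades
N50 for precision of the contiguity claims, which we consider the right
default for a genotyping tool. Unconsumed capacity seeds new pseudo-contigs,
so every supported lane–window instance belongs to exactly one
pseudo-contig. Lanes are interchangeable; their indices are stable but
arbitrary. When lanes compete for limited successor capacity, they are
served in creation order, which keeps the output deterministic.

`score_assembly` evaluates a pseudo-assembly against truth node-copy
instances: recall and precision over instances (per-node overlap is
`min(predicted, truth)`), N50 over pseudo-contig sequence lengths, and
coverage as total pseudo-contig length over four times the reference length
(the tetraploid genome). With a pericentromere mask all four metrics are
recomputed after dropping masked windows, splitting contig paths at the
removed windows.

## Population statistics

`window_diversity` computes, per window (10 kb is the conventional scale),
the segregating-site count, nucleotide diversity
$\pi = \sum_s 2 p_s (1-p_s)\, n_s/(n_s-1) / L$ (the unbiased mean pairwise
difference per bp, pairwise-complete over missing calls), and Watterson's
$\theta_w = S / (a_{n-1} L)$. An effective window length can be supplied
where part of a window is unalignable. `count_haplotype_blocks` reuses the
single-linkage machinery with an *absolute* threshold (fewer than 10
differences per 10-kb window) to count distinct haplotypes;
`sharing_matrix` turns per-window partitions into pairwise sharing
fractions.

`ld_decay` computes $r^2 = D^2/(p(1-p)q(1-q))$ for a seeded,
distance-stratified sample of site pairs and fits the Hill–Weir
drift–recombination expectation
$$E[r^2](C) = \frac{10+C}{(2+C)(11+C)}\left[1 +
  \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right],\quad C = \rho d,$$
by least squares over $\log\rho$. The half-decay distance is where the
fitted curve reaches half its value at $d = 0$. The expectation formula is a
concretization we chose — it is the standard finite-sample drift expectation
— and `fit_ld_curve` is isolated so an alternative can be swapped in.

## Pan-genome growth and gene families

`growth_points` measures pan-genome size as the cardinality of the union of
per-haplotype content-token sets (k-mers or segment identifiers; graph
alignment itself is out of scope, so the growth machinery is agnostic to the
token source). `fit_saturation` fits $y = a_1 x/(x+a_2) + a_3$ by BFGS from
multiple starts; the asymptotic pan-genome size is $a_1 + a_3$ and
`genomes_for_fraction` inverts the curve in closed form,
$x(q) = a_2 g/(a_1 - g)$ with $g = q(a_1+a_3) - a_3$.

`family_categories` partitions gene families by sharing: core (all n),
softcore ($\lceil 0.925\,n\rceil$ to $n-1$; 37--39 of 40), dispensable
(2 up to the softcore bound), private (exactly 1). `pan_core_curves` draws
up to 2,000 random subsets per sample size — enumerating all subsets
exactly when there are no more than that, which also makes small fixtures
exactly checkable. `tetraploid_family_null` compares a focal genome's four
haplotypes against random four-haplotype draws; the default p-value is
lower-tailed because the scientific question is whether real tetraploids
carry *fewer* families than random combinations.

## Depth triage

`classify_contig` classifies assembly contigs by mean depth relative to the
per-haplotype depth d into haplotig/diplotig/triplotig/tetraplotig/replotig.
Band notation in assembly pipelines is often written with integer endpoints
("[1.5d + 1, 2.5d]"), which is ambiguous for non-integer depths and can
leave boundary depths doubly assigned; we use continuous half-open bands,
left-exclusive above the haplotig band: $[0, 1.5d]$, $(1.5d, 2.5d]$,
$(2.5d, 3.5d]$, $(3.5d, 4.5d]$, $(4.5d, \infty)$. This is unambiguous and
monotone in depth. d is a user input; `estimate_haploid_depth` offers a
crude length-weighted median fallback.

## The simulator, and what passing tests do and do not show

`simulate_pangenome` generates the structure the method assumes: a random
reference; a founder pool mutated from it at per-site rate $r$ solving
$2r(1-r) = \pi_\text{target}$ (mutations flip to a fixed transition
alternative, keeping every site biallelic — the clustering operates on SNP
profiles, and indel/SV simulation is deliberately out of scope); and output
haplotypes that are per-window mosaics over a window-specific founder
subset, with lineage persistence controlled by a switch probability.
Defaults mirror the tetraploid-potato setting: 40 output haplotypes,
target $\pi$ = 0.018, about 9 founders per window. `simulate_query` builds
member, recombinant, or partially novel tetraploid queries with recorded
truth; `simulate_kmer_counts` draws marker counts from a negative binomial
(mean $c\lambda$) — deliberately heavier-tailed than the Gaussian inference
model, so the EM is never tested against its own generative assumptions —
plus low-count noise at a configurable fraction of absent markers.

The simulator does *not* emulate structural variation, repeat families,
alignment error, GC bias, or assembly gaps. Consequently, passing the
desk-scale reconstruction test (recall and precision at least 0.95 on a
member query of a 10-founder, 5-Mb pan-genome at 30x) demonstrates the
correctness of the graph/EM/stitching machinery under the stated model, not
the field performance on real potato data, where marker loss in repetitive
pericentromeres and incomplete pan-genomes dominate the error budget.

## Numerical choices and problem sizes

All coordinates are 0-based half-open except VCF positions; conversions
happen only at the VCF boundary. Posteriors are computed in log space;
ties in the copy argmax resolve to the smaller copy. Every stochastic
routine takes an explicit seed and restores the caller's RNG state. The test
suite exercises the full pipeline at a 5-Mb, 10-founder, 40-haplotype scale
(about a minute of CPU) and the EM at 2,000 nodes x 20 markers; unit tests
run on sub-100-kb fixtures with brute-force oracles for k-mer inventories,
pairwise diversity and N50.

## Known limitations

* Clustering quality degrades when true haplotype divergence approaches the
  10% threshold; the simulator's founders are well separated, as in the
  motivating crop.
* The EM shares one $\lambda$ across the whole genome; chromosome-specific
  depth biases would need a stratified fit.
* Stitching never joins across a window in which a haplotype has no
  supported node, so a single dropped window splits a pseudo-contig; no gap
  filling is attempted.
* `growth_points` measures token-set unions, not graph-alignment novel
  sequence; absolute pan-genome sizes depend on the token choice, though
  saturation behaviour does not.
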