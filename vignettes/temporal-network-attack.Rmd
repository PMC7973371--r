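---
title: "Methods: temporal grouping, subnetwork extraction, and combinatorial attack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal grouping, subnetwork extraction, and combinatorial attack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the parameter choices, and
the numerical decisions behind each stage of the `myonet` pipeline, along
with the scope of the synthetic data generator and the known limitations of
the methods.

## 1. Differential expression model

Counts for gene $g$ in sample $j$ are modeled as negative binomial,
$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g)$ with
$\mathrm{Var}(K) = \mu + \phi \mu^2$, the standard overdispersed model for
RNA-seq counts. For each timepoint, disease and control samples are
compared by a Wald test on the log2 fold change of normalized means.

Components and the reasons behind them:

- **Size factors** (`size_factors()`): median-of-ratios against the
  geometric-mean reference gene, computed over genes with all-positive
  counts; this is robust to a minority of strongly differential genes,
  unlike total-count scaling. If no gene is positive in all samples, library
  totals are used as a fallback.
- **Dispersion** (`test_differential()`, `prior_df = 6`): per-gene
  method-of-moments estimates $\hat\phi = (\mathrm{var} - \mu)/\mu^2$ pooled
  across the two groups, then shrunk toward the mean dispersion trend with
  a prior weight of 6 pseudo-replicates. With n = 4 per group the raw
  estimates are noisy; shrinkage stabilizes the test without tracking any
  external implementation. The floor `1e-8` prevents degenerate
  Poisson-limit standard errors.
- **Wald statistic**: `log2fc / se`, with
  $se(\log_2 FC) = \sqrt{(1/\mu_d + \phi)/n_d + (1/\mu_c + \phi)/n_c} / \ln 2$,
  the delta-method standard error of a log ratio of NB means. Two-sided
  normal p-values.
- **Pseudo-count**: 0.5 is added to a group's fitted mean only when that
  mean is zero, so fold changes stay finite without biasing the typical
  gene.
- **Calls**: induced iff FDR < `alpha` (default 0.01) and
  `log2fc >= lfc_min` (default 1, i.e., two-fold); repressed symmetrically.
  Benjamini–Hochberg adjustment is applied per timepoint.
- **Low-count filter** (`filter_low_counts()`): genes are kept when at
  least `min_samples` samples (default: the size of the smallest
  experimental group) have at least `min_count = 10` reads, so a gene
  expressed in only one condition still passes.

## 2. Temporal grouping

Each gene's per-timepoint calls form a three-letter pattern over the coded
timepoints (`i` induced, `r` repressed, `n` not significant). The default
rules (`group_rules()`) are:

| pattern | group | reading |
|---|---|---|
| iii | EPi | early-onset, persistent, induced |
| nii | MPi | mid-onset, persistent, induced |
| nrr | MPr | mid-onset, persistent, repressed |
| nin | MTi | mid-onset, transient, induced |
| nrn | MTr | mid-onset, transient, repressed |
| nni | LTi | late-onset, induced |
| nnr | LTr | late-onset, repressed |

Genes with pattern `nnn` are excluded from the output; any other pattern is
reported as `unclassified` rather than silently dropped, so the grouping is
a partition of all genes with at least one call. The rules vector is a
plain named character vector and can be replaced wholesale.

## 3. Enrichment

One-sided hypergeometric (Fisher's exact) test per (group, gene set) pair:
`phyper(k - 1, m, N - m, g, lower.tail = FALSE)`. Odds ratios come from the
2×2 table with a Haldane–Anscombe 0.5 correction only when a cell is zero,
and 95% confidence intervals from the Woolf log-OR variance. BH adjustment
is applied within each gene-set category by default (`adjust_scope =
"category"`), since categories (e.g., pathway vs ontology collections) are
typically interpreted separately; `"global"` pools all tests.

## 4. Gene scores and subnetwork extraction

Per-gene significance is aggregated over timepoints with Fisher's combined
probability method on the per-timepoint FDRs:
$X^2 = -2 \sum_t \ln q_{gt} \sim \chi^2_{2T}$, and the score is
$s_g = -\log_{10}$ of the upper-tail probability. Genes absent from a
table contribute $q = 1$; values are clamped to $[10^{-300}, 1]$ before
logging, bounding scores at 300 and avoiding `-Inf`.

The module search maximizes net weight $\sum_{v \in M} (s_v - \theta)$ over
connected subgraphs $M$ — a maximum-weight connected subgraph /
prize-collecting Steiner tree problem, which is NP-hard, so a deterministic
heuristic is used:

1. Nodes with $s_v \ge \theta$ are terminals; crossing a non-terminal costs
   $\max(\theta - s_v, 0)$. Edge weights are the mean of their endpoint
   costs, so path costs count interior nodes once.
2. Kou–Markowsky–Berman: metric closure over terminals, minimum spanning
   tree of the closure, expansion of each tree edge to its shortest path.
3. Candidate modules: the leaf-pruned path union; its strong pruning
   (the exact dynamic program for the best subtree of a tree,
   $f(v) = w_v + \sum_{c} \max(0, f(c))$); strong prunings of a BFS
   spanning tree and of a cost-weighted minimum spanning tree of the whole
   component; and the best single terminal.
4. The best candidate (net weight, then size, then lexicographically
   smallest node set) is polished by a hill climb that adds positive-weight
   neighbors and removes the most negative non-articulation node until a
   fixed point; every step strictly increases net weight, so it terminates.

On tree-shaped networks step 3 is exact, because the optimum's leaves are
terminals and hence contained in the Steiner tree. The threshold $\theta$
is scanned over the observed score values from high to low; the first
module whose size falls in `size_range` (default 30–60 nodes) is returned.
Because modules only grow as $\theta$ decreases, the scan stops early once
the size exceeds the upper bound; if no threshold lands in the range the
nearest achievable size is returned and flagged (`size_in_range = FALSE`).
All ties — equal path costs, equal net weights, equal candidate sizes — are
broken lexicographically on gene symbols, making the output bit-reproducible.

## 5. Attackness and combinatorial attack

Attackness of a removed node set $S$ in a network of $N$ nodes with
post-removal giant component $G$ is reported under two documented
conventions:

- **count-removed** (default): $(N - G)/N$ — removed nodes count as
  disconnected. This is monotone under set inclusion, which makes ranked
  combination search well-behaved.
- **remaining-only**: $(N - |S| - G)/N$ — only surviving nodes count.

`combinatorial_attack()` enumerates **all** $\binom{|C|}{k}$ candidate
combinations exhaustively rather than greedily: the semantics of the result
("the best k-set") are defined by the exhaustive optimum, and at the
intended problem sizes (modules of ~50 nodes, $k \le 5$,
$\binom{50}{5} \approx 2.1\times10^6$) full enumeration is feasible on one
CPU. A guard (`max_combinations = 1e7`) rejects accidental combinatorial
explosions, and `k` is capped at 5. Ties are ordered lexicographically on
the sorted node sets. The giant-component computation is a purpose-built
integer BFS with early exit; the test suite checks it against an
independent igraph implementation.

`constrained_attack()` is the same search restricted to druggable
candidates, optionally conditioned on a fixed `base_set` (e.g., targets of
a therapy already in use).

## 6. Drug repurposing

`filter_drug_table()` keeps rows that are non-withdrawn, have a known
mechanism of action, belong to drugs targeting at most
`max_targets_per_drug = 5` distinct genes (a configurable definition of
"non-promiscuous"; 5 is a conservative, documented default), and carry the
maximum clinical phase per (gene, indication). Phase classes: approved =
phase 4; phased = phases 2–3. The default homology map is case-folded
symbol identity (adequate for symbol-matched gene families); an explicit
two-column map overrides it, and ambiguous mappings are dropped with a
warning.

## 7. Synthetic data generator: scope and intent

`simulate_counts()` draws NB counts with log-uniform baseline means
(20–2000), a common dispersion (default 0.1), and log-uniform library-size
factors (0.7–1.3). Planted genes receive a multiplicative
$2^{\pm \text{effect\_log2fc}}$ effect in the disease group at exactly the
timepoints their temporal group prescribes. `simulate_network_and_pathways()`
builds overlapping pathways (random spanning tree plus extra edges each) and
grows a connected planted module; `simulate_drug_table()` plants a withdrawn
row and a duplicate (gene, indication) pair so the downstream filter is
always exercised; `simulate_study()` ties all of these to one gene universe.
All stages derive independent substream seeds from the single user seed, so
enlarging one stage does not reshuffle another.

The generator is a **validation instrument, not a biological simulator**:
effects are homogeneous within a group, dispersion is shared across genes,
samples are independent, and the network model is not scale-free. It is
designed so that recovery of planted truth is well-defined, not so that the
data mimic any particular tissue.

## 8. Limitations

- The subnetwork search is a heuristic; outside tree-shaped networks it
  carries no optimality guarantee (the tests compare it to an exhaustive
  oracle only on small graphs).
- The DE test assumes a common dispersion per gene across conditions and
  uses a normal approximation to the Wald statistic; very small counts with
  few replicates will be conservative-to-miscalibrated at the tails.
- Fisher's combination assumes independence across timepoints; repeated
  measures on the same animals would violate this.
- Attackness treats node removal as complete and simultaneous; partial
  inhibition or network rewiring is out of scope.
- The homology default is symbol identity; true orthology inference must be
  supplied as an explicit map.
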