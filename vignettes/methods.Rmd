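---
title: "Methods: inferring miRNA sponge co-regulation of PPIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring miRNA sponge co-regulation of PPIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical model, its
tunable parameters, the synthetic data it validates against, and the
design decisions taken where more than one reasonable reading existed.

## The model

### Sponge-pair inference

The competing-endogenous-RNA mechanism predicts that two transcripts
sequestering the same miRNA pool are (a) regulated by overlapping miRNA
sets, (b) regulated in a *similar pattern* by those shared miRNAs, and
(c) positively co-expressed, because a rise in one frees miRNAs and
de-represses the other. `infer_sponge_network()` operationalizes this as
four conditions on every candidate ceRNA pair:

1. **Disease membership.** Both ceRNAs must be in the supplied disease
   list. This is a scoping filter, not a statistical one; passing the
   full ceRNA universe disables it and yields generalized sponge pairs.
2. **Significant sharing.** The pair must share at least
   `min_shared_mirnas` (default 3) validated regulators among the `M`
   miRNAs measured in the dataset, and the upper-tail hypergeometric
   p-value of that overlap must fall below `hypergeom_alpha` (0.01).
   The test conditions on the regulator-set sizes `N` and `K` of the two
   ceRNAs and asks whether an overlap of `x` could arise by chance.
3. **Similar regulation pattern.** Over the shared miRNAs only, the
   signed correlation vectors enter a cosine score (conservative: signs
   must agree) and the absolute-value vectors enter a collaboration
   score (liberal: only magnitudes matter). The collaboration score's
   denominator is the square root of the *plain sum* of absolute
   correlations — not a Euclidean norm. Because `a² ≤ a` for `a ∈ [0,1]`,
   Cauchy–Schwarz gives `Col ≤ 1`, and uniformly strong regulation
   (all `AC = 1`) attains it; weak uniform regulation (all `AC = c`)
   yields `Col = c`, so the score scales with regulation *strength*,
   which the cosine deliberately ignores. Their mean, `Sim`, must reach
   `sim_threshold` (0.5).
4. **Positive co-expression.** The pair's Pearson correlation must be
   positive with a two-sided t-test p-value below `corr_alpha` (0.01).

Correlation p-values use the exact t transform on `n − 2` degrees of
freedom. No multiple-testing correction is applied across candidate
pairs: the cutoffs are fixed per-pair thresholds of the procedure, and
tightening any of them can only shrink the accepted edge set (a
monotonicity the test suite checks). Signs of miRNA–ceRNA correlations
are not filtered before scoring; repression makes them predominantly
negative, but the scores consume them as-is.

### Candidate semantics

A pair becomes a *candidate* (a row of the audit table) as soon as it
passes the shared-miRNA count gate; the disease flag, the significance,
pattern and correlation flags are all recorded per candidate, and
acceptance requires all four. Keeping failed candidates visible makes
the disease filter auditable and lets users re-score with a different
disease list without recomputing. Pairs with an undefined cosine or
collaboration score (an all-zero correlation vector, possible only with
degenerate input) are retained with a rejection note rather than
dropped.

### Motif enumeration

The integrated network types its nodes: `lncRNA` (declared via
`lncrna_ids`), `mRNA_protein` (sponge endpoints that are not lncRNAs),
`protein` (remaining PPI / lncRNA-target endpoints). A symbol declared
lncRNA but found inside the PPI layer is an error, not a silent
reassignment.

A sponge reaches the protein layer through *link* edges: lncRNA sponges
via lncRNA–target edges, mRNA sponges via their own PPIs — an mRNA and
its protein are one node. This is the only reading that keeps both motif
types at exactly 4 distinct nodes for every mix of sponge kinds:

* **Type A** `sponge(s1,s2), link(s1,p1), link(s2,p2), ppi(p1,p2)` —
  the sponges touch the two different parties of one PPI.
* **Type B** `sponge(s1,s2), link(s1,p), link(s2,p), ppi(p,q)` — the
  sponges share one protein that itself has a PPI partner; each distinct
  partner `q` is a distinct match.

Match identity is the edge realization: swapping the two
(sponge, protein) arms of a type-A match relabels the same realization
and is counted once, but when a sponge pair maps onto one PPI in both
orientations through *different* link edges, those are two matches. The
enumerator is edge-driven (per sponge edge, intersect link
neighbourhoods with PPI edges); the test suite holds it equal to an
independent brute force over all 4-node subsets on random typed
networks. The merged co-regulation network is the union of match edges,
so every edge in it supports at least one motif.

### Network analytics, clustering, module scoring

*Degrees* count all incident typed edges (a sponge edge and a PPI edge
between the same mRNA pair both count). *Characteristic path length*
averages shortest paths over reachable unordered pairs only, excluding
cross-component pairs with a logged count — a finite summary even on
multi-component networks. *Scale-freeness* is assessed by ordinary
least squares of log10 frequency on log10 degree over the raw
(unbinned) empirical spectrum, skipping zero frequencies; R² of that
line is reported. Frequency (not complementary CDF) fitting was chosen
as the convention consistent with reporting a single R² per spectrum;
no maximum-likelihood exponent estimation is attempted. A flat spectrum
is returned as slope 0 / R² 0 with a `constant` flag rather than an
error. *Hubs* are the top `ceiling(hub_fraction × n)` nodes by degree,
ties broken lexicographically so selection is deterministic.

*Markov clustering* runs on the simple unweighted graph (edge types
ignored), with self-loops of weight 1, column normalization, expansion
2, inflation 2, pruning at 1e-5, convergence tolerance 1e-6, and a cap
of 100 iterations (a warning, and the final state's clusters, on
non-convergence). These are MCL's canonical defaults; all are exposed.
Clusters are read off via attractors (positive diagonal), attractors
exchanging flow form systems, and nodes join the lowest-indexed system
they flow into — every node lands in exactly one cluster, and clusters
always refine connected components. Modules are clusters of size at
least `min_module_size = 4`, the size of one motif; smaller clusters are
dropped with a logged count and survivors are numbered in decreasing
size order.

*Module scoring* trains an RBF-kernel SVM (cost 1, kernel width
1/feature-count — the reference implementation's defaults, pinned
explicitly so results reproduce across ecosystems) on the module's
expression-measured genes; protein-only members have no features and
are excluded. Folds are stratified by class and seeded; features are
standardized with training-fold statistics only, so no test information
leaks. ACC is the pooled out-of-fold correct fraction. AUC uses the
rank (Mann–Whitney) formulation on the pooled out-of-fold decision
values — pooling one ROC rather than averaging per-fold AUCs was chosen
for stability at the ~144-sample scale this method targets; the suite
verifies the rank formulation equals trapezoidal ROC integration
exactly. OPI = (AUC + ACC)/2 ranks modules; a *signature* needs both
ACC and AUC strictly above `signature_cutoff = 0.9`. The `Sim`
threshold, by contrast, is inclusive (`≥ 0.5`): it is described as a
moderate set-point rather than a strict significance bound, and the
boundary case belongs inside.

*Over-representation* of a module in user gene sets reuses the same
upper-tail hypergeometric (universe = network genes unless supplied),
with Benjamini–Hochberg adjustment across the tested sets and an
adjusted-p cutoff of 0.01.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `min_shared_mirnas` | 3 | candidate gate on shared validated regulators |
| `hypergeom_alpha` | 0.01 | sharing-significance cutoff (strict `<`) |
| `sim_threshold` | 0.5 | regulation-pattern similarity (inclusive `≥`) |
| `corr_alpha` | 0.01 | co-expression p cutoff (strict `<`, with `r > 0`) |
| `hub_fraction` | 0.10 | top-degree fraction selected as hubs (ceiling) |
| `mcl_inflation` / `mcl_expansion` | 2 / 2 | MCL granularity / walk length |
| `min_module_size` | 4 | one motif's node count |
| `cv_folds` | 10 | stratified CV folds for module scoring |
| `signature_cutoff` | 0.9 | both ACC and AUC must exceed it |
| `enrichment_alpha` | 0.01 | BH-adjusted ORA cutoff |

All thresholds are strict or inclusive exactly as documented above;
borderline values therefore behave deterministically.

## The synthetic generator

`simulate_sponge_data()` emulates the statistical structure the
inference assumes, with planted ground truth recorded exactly as
generated. miRNA expression is i.i.d. standard normal. Each planted
pair (A, B) owns a dedicated block of `shared_per_pair = 4` miRNAs
(blocks of distinct pairs are disjoint, keeping truth unambiguous), and

```
expr_A = −reg_strength · Σ_k mir_k + N(0, noise_sd²)
expr_B = −reg_strength · Σ_k mir_k + N(0, noise_sd²)
```

The negative sign mirrors miRNA repression — the canonical ceRNA
mechanism — and makes both partners positively co-expressed while the
scores only see the correlation values. Background ceRNAs get at most 2
random regulator edges (below the candidate gate) and independent
expression. The disease list contains all planted sponges plus 30
background decoys. The protein layer wires every planted pair into one
type-A and one type-B motif plus 60 random background PPIs. Tumor
columns of each differential gene set (blocks of 3 consecutive planted
pairs; one set by default) are shifted by `+delta`.

Defaults are 100 miRNAs, 30 lncRNAs, 120 mRNAs, 72 + 72 samples,
20 planted pairs, `reg_strength = 1`, `noise_sd = 0.3`, `delta = 2`.
The miRNA count is set to 100 because 20 disjoint regulator blocks of 4
need at least 80 miRNAs, and a round 100 keeps realistic headroom of
unused miRNAs (real miRNome panels measure several hundred). The
sample counts mirror a typical matched tumor/normal cohort. `delta = 2`
is roughly one within-gene standard deviation for planted genes — a
visible but not trivial class separation.

What the generator does **not** emulate: count-distribution skew and
heteroscedastic noise of real RNA-seq, correlated miRNA co-expression,
hub-dominated scale-free topology of curated PPI databases, regulator
overlap *between* sponge pairs, and annotation errors in target
databases. Passing recovery tests on this generator therefore
demonstrates correctness of the statistical machinery under its own
assumptions, not performance on TCGA-scale data, where thresholds
interact with far heavier candidate multiplicity.

## Numerical and degenerate-input choices

* Duplicate expression rows are averaged at read time; missing values
  are rejected, never imputed (no imputation rule is part of the
  method). Gene symbols are case-sensitive and never remapped.
* Undirected edges are stored with endpoints in lexicographic order;
  all set arithmetic uses that canonical form. Self-loops are dropped
  with a logged count.
* `r = ±1` returns p = 0 directly, avoiding the singular t transform.
* `shared_mirna_pvalue` delegates to the exact hypergeometric tail
  (`x = 0` returns 1 by the empty-sum convention); the test suite pins
  it to an enumeration oracle to 1e-12 over the full `M ≤ 15` lattice.
* Power-law fits require ≥ 3 distinct positive-frequency points;
  degree 0 cannot enter a log-log fit and raises an error.
* MCL is deterministic: no randomness enters anywhere in the pipeline
  except expression simulation and CV fold assignment, both seeded.
  Columns that prune to zero mass are re-anchored with a self-loop.
* An empty PPI layer (or empty sponge network) flows through cleanly:
  zero motifs, an empty co-regulation network, no topology block.

## Problem sizes used in the test suite

Unit tests run on hand-built fixtures of 3–20 nodes plus simulated
bundles of 4–8 planted pairs; the brute-force motif oracle covers 100
random typed networks of up to 30 nodes (the largest size at which
exhaustive 4-subset checking stays immediate); recovery is averaged
over 10 generator seeds at the full default scale (20 pairs, 144
samples); the permutation null uses 100 label permutations. These sizes
were chosen so the whole suite exercises every code path at full
statistical strength while remaining a sub-minute run on a laptop.

## Known limitations

* The method is threshold-parametric: the accepted edge set depends on
  the four cutoffs, and only monotonicity (never an error bound) is
  guaranteed as they move.
* Sponge species are limited to lncRNAs and mRNAs; pseudogenes and
  circRNAs would need their own expression and target layers.
* The motif vocabulary is fixed to the two 4-node patterns; there is no
  general subgraph-isomorphism engine.
* Expression input is taken as analysis-ready (normalized/log-scale);
  no transformation is applied before correlation.
* Module "prognostication" is tumor/normal classification, not survival
  modelling.
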