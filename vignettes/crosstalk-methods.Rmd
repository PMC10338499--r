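---
title: "Methods: ligand-receptor integration and rank-based crosstalk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-receptor integration and rank-based crosstalk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrtalk)
```

## Scope

Tumor cells and immune cells in the microenvironment communicate largely
through ligand-receptor (LR) binding. `lrtalk` provides the computational
layer for studying that crosstalk from transcriptomic data: (i) harmonizing
LR pair tables from heterogeneous source resources into one catalog with
evidence labels and functional groups, (ii) scoring candidate gene pairs on
bulk expression cohorts with a rank-based interaction-strength statistic and
permutation p-values, and (iii) integrating per-method cell-cell
communication predictions into a consensus and quantifying, per method, how
strongly the consensus concentrates at the top of that method's own ranking.
Manual literature curation, the upstream single-cell inference algorithms
themselves, and any database/server layer are out of scope: the package
consumes their exported tables.

## Catalog integration

Each source resource contributes a table of directed (ligand, receptor)
gene pairs. Pairs are keyed by `(ligand, receptor, species)`; direction
matters because the ligand and receptor roles are not interchangeable, so
`(A, B)` and `(B, A)` are distinct. Merging takes the union of pairs,
accumulates source provenance, and assigns the evidence subclass:
`manually_curated` if at least one contributing source flags experimental
or literature support for the pair, `predicted` otherwise. The merge is
idempotent, commutative and associative, which the tests verify on random
catalogs.

Gene identity is canonically an Ensembl gene ID. Symbol-to-ID mapping is a
user-supplied table (`id_map`), never fetched at runtime; genes missing
from the map keep their symbol and carry an `id_flag` so downstream users
can audit provenance. Rows with empty gene fields cannot participate in the
pair key and are dropped with a count in the load report — this is the one
place we diverge from "retain everything", because a keyless row has no
identity to retain.

### Functional groups

Pairs are classified into ten functional groups (notch signaling, antigen
binding, neuropeptide, hormone, growth factor, interferon, interleukin,
tumor necrosis factor, chemokine, cytokine) by intersecting the group
annotations of the ligand and the receptor: a pair belongs to a group only
when *both* genes are annotated to it. Annotations derive from GO term
groupings (e.g. from MSigDB) and are supplied as a two-column TSV or GMT
file; curating the GO term lists themselves is the user's task. Pairs
matching no group fall into `"other"`.

A pair can legitimately match several groups (interleukins are cytokines).
Nothing forces a unique label, so the design choice here is a configurable
priority order, defaulting to the order the groups are listed above; the
first match becomes `primary_group` and all matches are retained in
`all_groups`. This is deterministic, auditable, and loses no information.
Multi-subunit receptor complexes are flattened to gene pairs; we do not
model complexes.

### Intersection statistics

`intersection_stats()` reports, for every non-empty subset of sources, the
number of pairs present in exactly that subset (the semantics of an UpSet
plot), plus per-source totals and the shared-by-all count. Exclusive counts
partition the merged catalog, so they must sum to its size — a property the
tests check against brute-force subset enumeration over all 127 subsets of
seven random catalogs.

## The interaction-strength statistic

Bulk cohorts are FPKM gene-by-sample matrices. Preprocessing follows the
standard recipe: genes whose expression is zero in **more than** 30% of
samples are excluded (a gene at exactly 30% is retained — the inequality is
strict), and values are `log2(FPKM + 0.05)` normalized for storage and
reporting. Cohorts with fewer than six samples are refused by default
(`min_samples`), mirroring the usual admission threshold for bulk datasets
(single-cell datasets are conventionally admitted above 500 cells; that
threshold lives in `run_config()` for callers that filter their own
inputs).

Within each sample, genes are ranked in descending order of expression and
positions are mapped to a 0–10 scale:

$$r = 10\,\frac{G - \mathrm{pos} + 1}{G},$$

with `pos = 1` for the highest-expressed of the `G` retained genes, so the
top gene scores 10 and the bottom `10/G`. Ties take the average position,
so equal expression always gives equal rank scores. The per-sample
interaction strength of a gene pair is

$$\mathrm{IS} = (r_1 + r_2)\,\bigl(10 - |r_1 - r_2|\bigr),$$

which rewards pairs that are jointly *and similarly* highly expressed: the
first factor grows with joint expression, the second shrinks with rank
discordance. IS is symmetric, bounded in `[0, 200]`, equals `20r` on the
diagonal `r_1 = r_2 = r`, and attains 200 only at `r_1 = r_2 = 10`. The
0–10 scale is a design choice: the `10` in the second factor is only
coherent if ranks live on that scale, and mapping the *highest* expression
to 10 makes both factors non-negative and makes IS reward strong joint
expression, which is the statistic's intent. Note that two *distinct*
genes can never both score exactly 10 in one sample (tied top genes average
to position 1.5), so the two-gene per-sample maximum is
$(10 + 10\frac{G-1}{G})(10 - \frac{10}{G})$, approaching 200 as `G` grows.
Because IS depends only on within-sample ranks, it is invariant to any
strictly increasing transform of a sample's expression vector; scoring FPKM
or log-normalized values gives identical results.

### Permutation significance

The dataset-level statistic is the arithmetic mean of IS across samples.
Its null distribution is built from `n_perm` (default 1000) random gene
pairs — two distinct genes drawn uniformly from the retained universe, the
observed pair excluded — scored and aggregated identically. Sample labels
are never permuted: the statistic lives on each sample's rank structure,
and destroying it would test the wrong null. The p-value is upper-tailed
with add-one correction,

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{n_\text{perm} + 1},$$

so `p` is never zero and the strongest possible result at 1000 permutations
is `1/1001`. The upper tail is what "is the real interaction strength
larger than random?" means; a lower-tail variant is available via
`alternative = "less"`. A seed is mandatory — permutation results without
one are not reproducible — and all draws come from a single RNG stream, with
pairs processed in input order, so a run is exactly replayable. The draw
scheme is documented in `score_pairs()` precisely so that an independent
scalar reimplementation can replay it; the test suite does exactly that and
checks p-values to equality.

Significance defaults to `alpha = 0.05`; the `"small-cohort"` profile of
`run_config()` relaxes it to 0.1, the conventional allowance for cohorts
near the six-sample admission floor.

## Consensus integration and evaluation

Per-method prediction tables are keyed by (ligand, receptor, sender cell,
receiver cell). Method-native communication scores are incomparable across
methods, so each record first receives its *within-method percentile rank*
(1 = that method's strongest call), and only percentiles enter cross-method
arithmetic. How the original multi-algorithm integration was formed is not
specified anywhere we could follow, so the package makes the simplest
defensible choice and exposes it: a communication enters the consensus when
at least `min_support` methods (default 2) predict it, and its
`consensus_rank` is the mean of the supporting methods' percentiles. Output
ordering is fully deterministic (support, then consensus rank, then
lexicographic key), making results invariant to input file order. The
evaluation metrics below are agnostic to the integration rule.

### Enrichment score

To ask whether the consensus concentrates at the top of an individual
method's ranking, we use the classic weighted Kolmogorov–Smirnov running
sum: walking down the method's list (score-descending, lexicographic key as
tie-break), hits increment the sum by $|s|^w$ normalized over in-set
scores ($w = 1$ by default; $w = 0$ gives the unweighted KS statistic) and
misses decrement by $1/(N - N_h)$. The enrichment score (ES) is the
running-sum value at its extremum of largest magnitude; it lies in
`[-1, 1]`, equals 1 when the set is the whole list, and is negative for
bottom-concentrated sets. Significance is by set-membership permutation
(random same-size key sets; there are no sample labels to permute here),
upper tail for positive ES, lower for negative, add-one corrected. The
implementation is cross-checked in the tests against an established GSEA
implementation (`fgsea::calcGseaStat`) and against hand-enumerated running
sums. Normalized enrichment scores across set sizes are not needed for this
single-set use case and are not provided.

### Top-fraction occupancy

The second, blunter metric: with `k = ceil(fraction × N)`, the occupancy is
the fraction of consensus keys (among those present in the list) that fall
in the list's top `k`. At `fraction = 0.5` this answers "does more than
half of the consensus sit in the method's top half?" — the qualitative
benchmark the consensus should clear against every contributing method.

## Synthetic data

All statistical structure the methods assume can be generated in code, so
the whole pipeline is testable without downloads.

* `make_expression()` draws log-normal FPKM backgrounds (meanlog 1,
  sdlog 1 — a standard stand-in for bulk abundance distributions), with
  optional per-entry zero inflation to exercise the zero-fraction filter.
  Planted pairs are forced *above a quantile* of their sample's background
  (default: above the 0.9 quantile in 90% of samples) rather than shifted
  additively, because the statistic is rank-based and only quantiles
  matter. Planted genes are exempt from zero inflation so planting survives
  filtering.
* `make_lr_catalogs()` builds source catalogs whose exclusive intersection
  structure exactly matches a prescribed subset-count specification.
* `make_predictions()` builds per-method tables as a shared planted core
  scored from U(4, 10) plus method-specific noise from U(0, 6) — deliberately
  overlapping, so the core dominates each ranking without being perfectly
  separated; disjoint ranges reproduce the perfectly separated regime.

Everything is deterministic under a fixed seed. What the generators do
*not* emulate: realistic single-cell counts and dropout, cell-type
mixtures, correlated gene modules, batch structure, or heavy-tailed
method-score distributions. Passing tests therefore demonstrate
correctness of the algorithms and calibration under the stated null — not
performance on real tumor cohorts.

## Numerical choices and problem sizes

* Ties: average-position fractional ranks everywhere; all orderings use
  stable radix sorts with lexicographic final tie-breaks.
* Degenerate inputs are errors, not silent results: single-gene matrices,
  empty reference sets, empty set-list intersections, all-genes-filtered
  matrices, missing seeds.
* The test suite exercises calibration with 1,000 null pairs at 200
  permutations on a 200-gene × 20-sample matrix, and recovery with 20
  planted pairs under the same geometry — sizes chosen so the full suite
  runs in well under a minute while leaving the binomial envelope on the
  calibration check tight (99% envelope half-width ≈ 0.018 at n = 1000).
* `evaluate_consensus()` offsets the seed per method (`seed + i`) so
  method-level permutations are independent but reproducible.

## Limitations

The interaction-strength statistic sees only marginal rank profiles: it
cannot distinguish co-expression within the same cells from coincidental
joint abundance across a bulk mixture, and it has no notion of sender and
receiver cell types on bulk data — cell-type attribution comes only from
the curated tables or the single-cell predictions it is paired with. The
permutation null holds expression fixed and randomizes pair identity, so
p-values measure "stronger than a random gene pair in this cohort", not a
causal claim about signaling. Consensus support counting treats methods as
exchangeable votes and ignores that some algorithms share reference
databases and are therefore correlated.
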