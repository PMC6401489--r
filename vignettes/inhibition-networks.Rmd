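---
title: "Analysing multi-condition microbial inhibition networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing multi-condition microbial inhibition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibnet)
```

## The data and the model

Pairwise antagonism screens test every strain in a collection for its
ability to inhibit the growth of every other strain, typically by scoring
the presence or absence of a zone of inhibition on an agar plate, and
repeat the screen on several media because antibiosis is strongly
condition-dependent. The raw result is a binary *inhibition tensor*:
producers in rows, receivers in columns, one 0/1 slice per medium. The
diagonal is meaningless (a strain is never scored against itself) and is
required to be zero; a nonzero diagonal raises an error rather than being
silently dropped.

All community-level statistics are computed on the **union network**: a
directed graph with an edge producer → receiver whenever inhibition was
detected under *at least one* condition, each edge annotated with its
*support set* — the exact subset of conditions in which it was seen. The
number of conditions is not fixed at three; every statistic generalises to
any number of conditions of at least one.

```{r fixture}
tensor <- paper_scale_fixture(seed = 1)
network <- union_network(tensor)
network
```

## Statistics

**Connectance** is the fraction of all possible directed interactions that
are realised, `C = |edges| / S^2` for `S` strains. The denominator
deliberately includes the diagonal: that is the convention under which a
105-edge, 21-strain screen yields `105/441 = 0.238`, printed as 0.24
(with the off-diagonal denominator it would print 0.25).

**Sender–receiver asymmetry** `Q` contrasts the structure on the producer
and receiver sides. We use a degree-variance definition: with `V_out` the
population variance (divide by `n`) of per-strain distinct-target
out-degrees and `V_in` the analogue for in-degrees,

```
Q = (V_in - V_out) / (V_in + V_out)
```

so `Q` lies in [−1, 1], is exactly antisymmetric under graph
transposition, is negative when producer identity carries more of the
structure ("producer determined"), and is undefined (returned as `NA`
with a warning) on edgeless networks or when both degree sequences are
constant. Published work on antagonism matrices uses an asymmetry
statistic with this sign convention but the exact published formula is
not always reproduced alongside it; the definition above is therefore
documented explicitly, fixed as the default, and kept behind a
`definition` argument so alternatives can be added without changing the
interface. Population rather than sample variance is used; the ratio is
scale-free either way, but one convention must be fixed for
reproducibility.

**Hierarchy scores** implement a reward/penalty scheme: each strain earns
+1 per distinct strain it inhibits, −1 per distinct strain that inhibits
it, and a further −1 per *reciprocal* partner (a strain it both inhibits
and is inhibited by). Scoring operates on the union network, so an edge
found in all media still contributes a single point. Reading the
reciprocal penalty as additional to the in/out points makes reciprocal
pairs score below neutral, which is consistent with largely-reciprocal
strains appearing at middle and low ranks. Because rewards and
in-penalties cancel pairwise across the network, the scores sum to minus
twice the number of reciprocal pairs — an identity asserted in the test
suite on every computed network.

```{r hierarchy}
hier <- assign_levels(hierarchy_scores(network))
head(hier$table[order(-hier$table$score), ], 6)
top_k_producer_share(network, hier, k = 4)[c("edge_count", "percent")]
```

Level labels (high/medium/low) are presentational. The default scheme
splits the ranked score list into tertiles, with tied scores always
sharing the *higher* level (so equal scores never land in different
levels, and an all-tied network is entirely "high"); explicit numeric
thresholds are accepted instead. Top-`k` producer ranking breaks score
ties deterministically by reward and then strain ID, so reports are
reproducible; nothing in the data guarantees the real screen used the
same tie-break, which is why the concentration statistic is reported with
its exact edge count alongside the percentage.

**Conservation** partitions union edges by their exact support subset
(the Venn partition over `2^k − 1` cells — disjointness and exhaustiveness
are asserted on every run), tabulates the support-size histogram, and
reports "conserved in at least *s* conditions" counts with percentages
relative to the union edge count, rounded to the nearest integer
(`71/105 = 67.6 → 68%`). A reciprocal pair is classed `single-medium`
when both of its directed edges have singleton support and `multi-medium`
otherwise. "Nonhierarchical" edges are operationalised as directed edges
whose reverse also exists; broader cyclic definitions are out of scope.

```{r conservation}
conservation_summary(tensor)$conserved_at_least
nonhierarchical_fraction(network)[c("edge_count", "percent")]
```

## Permutation null models

Three null families, all preserving strain count and edge count and never
placing self-loops:

* `erdos` — edges placed uniformly over off-diagonal ordered pairs;
* `out-preserving` — each producer keeps its out-degree, targets
  resampled;
* `both-margins` — both degree sequences preserved exactly by
  checkerboard (2×2 submatrix) swaps starting from the observed matrix,
  with a burn-in of 10 accepted swaps per edge (configurable; at the
  21-strain scale the chain mixes long before that).

Empirical p-values use the standard add-one form
`p = (1 + #{null ≥ observed}) / (1 + n_perm)`, which is never zero, and
are bit-for-bit reproducible given `(seed, family, n_perm)`. Null draws
on which a statistic is undefined are excluded and counted in the result.

Choose the family to match the question. The `both-margins` family
preserves every strain's in- *and* out-degree, and therefore preserves
each strain's reward and in-penalty; the hierarchy score ranking (up to
reciprocity shifts) and the top-`k` producer share are nearly invariant
under it, so a concentration test under that family has essentially no
power by construction and reports p ≈ 1. Producer concentration should be
tested against the `erdos` (or `out-preserving`) null; `both-margins` is
the right family for statistics that are *not* functions of the margins,
such as reciprocity.

For calibration we verify that when the observed network is itself a draw
from the null family, the p-values are uniform. The acceptance suite runs
this check with the asymmetry statistic `Q`, which is effectively
continuous; for a discrete count statistic such as the reciprocal-pair
count the add-one p-value is super-uniform (conservative) and
lattice-valued, so a two-sided Kolmogorov–Smirnov test against U(0,1) can
reject for reasons unrelated to correctness — that statistic is instead
checked for conservative coverage.

## The synthetic-data generator

The generator emulates a multi-medium antagonism screen as a *noisy
tournament* over a latent total order of producers — the simplest
generative process consistent with a layered inhibition hierarchy:

1. a latent rank is drawn uniformly (rank 1 = top producer);
2. each unordered strain pair becomes connected with probability
   `p_pair`, solved in closed form so the *expected union edge count*
   equals `target_connectance × n²` after accounting for reciprocity and
   detection: `E[edges] = N_pairs · p_pair · (1 + r) · q_det` with
   `q_det = 1 − ∏(1 − detection_probs)`; an unreachable target raises an
   error stating the maximum achievable connectance;
3. a connected pair is reciprocal with probability `r`
   (`reciprocity_rate`), otherwise carries one edge oriented down-rank
   with probability `(1 + h)/2` (`hierarchy_strength` h = 1: always
   rank-consistent; h = 0: a coin flip);
4. every true edge is detected in each condition independently with that
   condition's `detection_probs`; an edge detected nowhere is absent.

Defaults (`n = 21`, three conditions, `target_connectance = 0.24`,
`h = 0.9`, `r = 0.03`, detection 0.8 per condition) emulate the scale of
a 21-strain, three-medium screen with ~105 union edges, a strong producer
hierarchy and rare reciprocity. Detection noise is independent across
conditions, so condition-specific biology (an interaction that only
exists on one medium, as opposed to one that merely escapes detection) is
representable only through unequal detection probabilities — correlated
condition effects are a known limitation. At `h = 1` the construction
guarantees every edge *direction* matches the latent rank; it does not
guarantee the hierarchy-score ordering is violation-free (a high-ranked
strain with several higher-ranked inhibitors can score below a
low-ranked strain with many targets), so rank recovery is validated
statistically: the mean Spearman correlation between score and negated
rank exceeds 0.9 at `h = 1` and increases monotonically in `h`.

`paper_scale_fixture()` is the deterministic companion used for
desk-scale validation: rather than rejection-sampling the generator until
the printed totals of the real screen happen to hold, it constructs them
directly — a top tier of four producers emitting 16 + 15 + 14 + 13 = 58
edges, a middle tier of 41 further rank-consistent edges, and three
reciprocal pairs spanning six otherwise low-scoring strains (one pair
detected only under a single medium), with a fixed support pool of
27 triple-, 44 double- and 34 single-condition edges. That pins 105 union
edges, connectance 0.238, 71 edges (68%) conserved at ≥2 conditions, a
58-edge (55%) top-4 share, and a 6% nonhierarchical fraction exactly, for
every seed; the seed only permutes which strain label plays which latent
role and how support subsets are assigned to non-reciprocal edges.
Passing tests on generator output therefore demonstrate internal
consistency of the statistics at realistic scale — they do not validate
the biology of any particular real screen, whose raw matrix may not be
publicly machine-readable.

## Pipeline, formats, reproducibility

`run_pipeline()` wires validation → union network → statistics →
hierarchy → conservation → optional null tests, and writes a versioned
JSON report (full-precision values; rounded companions carry a
`_rounded` suffix), per-strain TSVs, and Cytoscape-readable SIF
(`producer inhibits receiver`) and GraphML (node attributes `score`,
`level`, `phylum`; edge attribute `support_count`) files. Wide input is
one square delimited table per condition (first row/column strain IDs,
rows producers); long input is a sparse
`producer receiver condition value` table where unlisted cells mean "no
inhibition observed" and are counted in a single message. The canonical
strain order is the first file's order and is enforced everywhere;
mismatched strain sets, non-binary cells, conflicting duplicate rows and
nonzero diagonals all fail loudly with the offending cell named. Every
random step (generator, nulls) takes an explicit integer seed, and
rerunning any stage alone reproduces its value in the full report.

Problem sizes used by the validation suite — exhaustive hierarchy-scoring
enumeration on up to 4 strains plus 4,000 sampled 5-strain edge sets,
1,000 random tensors for the score and asymmetry identities, 100
generator seeds for rank recovery, and 200 replicates of 199 permutations
for null calibration — were chosen as the smallest sets that exercise
every code path while keeping the full suite runnable in well under half
an hour on a single CPU.

## Limitations

* Inhibition is binary presence/absence; zone diameters, lags and
  quantitative strengths are out of scope, as is any image analysis.
* "Nonhierarchical" means reciprocated edges only; longer cycles are not
  counted.
* The degree-variance `Q` is one documented member of a family of
  asymmetry statistics; values are comparable within this package, not
  necessarily across publications.
* The generator's conditions are exchangeable given their detection
  probabilities; it cannot produce interactions whose very existence is
  condition-specific.
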