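---
title: "Composition-vector phylogenetics with proper correlation distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-vector phylogenetics with proper correlation distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlphylo)
```

## The problem

Whole genomes of distant organisms cannot be multiply aligned, so classical
distance methods do not apply directly. Alignment-free methods instead
summarize each genome by the frequencies of all length-`K` substrings
("K-strings") over its alphabet — 4 nucleotides or 20 amino acids, giving
`N = 4^K` or `20^K` possible string types — and compare genomes through
these length-`N` composition vectors. dlphylo implements the
dynamical-language variant of this idea: raw K-string frequencies are
dominated by short-range compositional structure (codon usage, GC content)
that carries little phylogenetic signal, so each genome's expected
background is predicted from its own shorter strings and subtracted before
genomes are compared.

## The model

For one genome, let `p(w)` be the observed frequency of K-string `w`,
counted by sliding a window one position at a time through every sequence;
for a genome given as `m` genes the counts and windows are pooled,
`p = (Σ_j n_j) / (Σ_j (L_j − K + 1))`. A K-string `s1…sK` can be built by
appending `sK` to `s1…s(K−1)` or prepending `s1` to `s2…sK`, which motivates
the background prediction from the (K−1)-string and single-letter
frequencies:

```
q(s1…sK) = [ p(s1…s(K−1)) p(sK) + p(s1) p(s2…sK) ] / 2
```

The denoised component is `X(w) = p(w)/q(w) − 1` where `q(w) > 0` and `0`
where `q(w) = 0`. Two genomes are compared by the uncentered (cosine)
sample correlation over all `N` components,
`C(X, Y) = Σ X_i Y_i / sqrt(Σ X_i² Σ Y_i²)`, which equals the cosine of the
angle between the two vectors and is invariant to rescaling — so the
unit-vector normalization that defines the metrics below never needs to be
materialized.

Three distances are derived from `C`:

* **pseudo-distance** `D_r = (1 − C)/2` — the legacy quantity. It is *not*
  a proper metric: it vanishes for any two proportional vectors and can
  violate the triangle inequality (both failures are demonstrated in the
  test suite by randomized search).
* **chord distance** `D = sqrt(2(1 − C))` — the Euclidean length of the
  chord between the two unit vectors (the Cavalli-Sforza chord distance); a
  proper metric, range `[0, 2]`, normalized form `D/2`.
* **piecewise distance** `D = 0` if `C = 1`, else `1 − C/ρ` with `ρ ≥ 3`;
  a proper metric with a jump at `C = 1`. The bound `ρ ≥ 3` is exactly what
  makes `D(x,y) + D(y,z) − D(x,z) = [ρ + C(x,y) + C(y,z) − C(x,z)]/ρ ≥ 0`,
  since each correlation lies in `[−1, 1]`. Normalized form `D/2`.

A symmetric pairwise matrix under one of these metrics is handed to
neighbor joining (Saitou & Nei), which is exact on additive matrices; the
tree is reported unrooted with a trifurcation at the last join.

## Parameters that matter

* **`K`** (string length, unitless). The key tuning knob. Short `K` mixes
  signal with compositional background; large `K` makes `p` sparse and
  noisy. The built-in diagnostic is the mean of `X` over all `N` strings
  (`mean_x_profile()`, `kselect` subcommand): once the background model
  predicts the observed frequencies well, the mean approaches zero, and the
  smallest such `K` is a good choice. In practice that is around 6–7 for
  protein sequences and 11–12 for whole DNA; the CLI defaults are `K = 6`
  (protein) and `K = 11` (DNA).
* **`rho`** (piecewise only, default 3). Any value `≥ 3` is valid; NJ
  topology is provably unchanged by it, because `1 − C/ρ` is an affine,
  increasing transform of `1 − C` and neighbor joining's selection
  criterion is invariant under positive affine maps of the input distances.
  The knob is exposed so that this insensitivity can be replicated
  empirically (the acceptance checks do so for ρ ∈ {3, 4, 6, 8, 10}).
* **`normalized`** (default off). Divides chord/piecewise by 2 to land in
  `[0, 1]`. A global rescaling, hence also topology-neutral; raw distances
  are the default since nothing in the pipeline requires the unit range.

## Numerical choices

* Correlations are clipped to `[−1, 1]` before any distance; the `C = 1`
  branch of the piecewise distance is taken when the clipped `C` is within
  `1e-12` of 1, so identical vectors land on the zero branch despite
  floating point.
* Composition vectors are stored sparsely with an explicit partition of the
  index set: `S` (`p > 0`, so `X = p/q − 1 > −1`), `Z` (`q > 0`, `p = 0`,
  so `X = −1`) and implicit zeros (`q = 0`). Dot products over all `N`
  components are evaluated exactly from the partition
  (`Σ_{S∩S} xy − Σ_{S∩Z} x − Σ_{Z∩S} y + |Z∩Z|`), so protein `K = 6`
  (`N = 6.4e7`) never requires a dense vector. String indices are held as
  doubles (exact below `2^53`).
* No pseudocounts anywhere: zeros are meaningful and drive the partition.
  The mean-`X` diagnostic averages over all `N` strings, structural zeros
  included (an `only q > 0` variant would change the denominator, not the
  qualitative approach to zero; we fix the all-`N` convention).
* Frequencies divide by the number of *valid* windows — windows free of
  ambiguity characters — rather than the nominal `L − K + 1`, which keeps
  `Σp = 1` in the presence of Ns. Ambiguous characters are kept in place
  and windows overlapping them skipped; deleting them would manufacture
  junction K-strings that never occur in the genome. Windows never span
  two sequences (genes or replicons).
* `K = 1` composition vectors are rejected rather than special-cased: the
  background model needs a (K−1)-string.
* A genome whose denoised vector is identically zero (e.g. a single-letter
  genome, where the model fits perfectly) has no defined correlation; this
  is an error, not a silent convention.
* NJ can produce negative branch lengths on non-additive input; they are
  kept by default, with `clamp_negative` setting them to zero and moving
  the deficit to a sibling branch so path lengths around the node are
  preserved.
* Newick output orders children lexicographically by the smallest leaf
  label in each subtree, so identical topologies serialize byte-identically
  regardless of join order. Two-taxon trees are written `(A:d,B:0.0);`.

## The synthetic-data generator

Real multi-genome datasets are large downloads; the generator stands in for
them so the whole pipeline is testable offline. It emulates neutral
sequence divergence only: an i.i.d. uniform root sequence of given length
is evolved down a known tree under the exact Jukes–Cantor site process — on
a branch of length `b` expected substitutions/site a site differs with
probability `(1 − 1/size)(1 − exp(−b·size/(size−1)))`, substituted sites
drawing uniformly among the other letters. This composes exactly along
paths, so the expected differing fraction at path length `t` is the JC
closed form (`(3/4)(1 − e^{−4t/3})` for DNA), which the tests verify at
`L = 1e5`. Each branch has its own deterministic random stream derived
from the global seed and the leaf set below the branch, so one seed fixes
the whole dataset and subtree regeneration is stable under tree edits.

The default benchmark (`balanced_tree()` + `evolve_genomes()`, also the
`simulate` subcommand) uses an 8-leaf balanced topology, branch lengths
uniform in 0.05–0.15 substitutions/site, and 50 kb genomes at `K = 6`:
moderate, unsaturated divergence at a scale where composition signal is
strong — a desk-scale regime a simulation study would consider realistic.
What passing these tests shows is that counting, denoising, the distances
and NJ interact correctly and recover known topologies under neutral
substitution; what it does not show is robustness to the features of real
genomes the generator omits — indels, rearrangement, horizontal transfer,
rate heterogeneity, compositional bias — nor anything about which `K` or
metric is biologically preferable for a given clade.

## Design choices where the design was open

* Whether the original analyses averaged `X` over all `N` strings or only
  strings with `q > 0` for the K-selection plot is not documented; we take
  all `N` (that is what "over all K-strings" means literally).
* Whether trees should be built from raw or normalized distances is
  likewise open; we default to raw and expose `normalized` — for NJ the
  choice is provably immaterial to topology.
* Ambiguity handling (skip-window vs delete) is our choice, as above.
* Neighbor joining is delegated to ape's reference implementation behind
  `neighbor_joining()`; it is deterministic for a given input matrix, which
  is the property the pipeline's byte-stable outputs rely on.
* In evolution simulation, the exact exponential substitution probability
  is used rather than a per-branch Bernoulli approximation, so closed-form
  divergence checks are valid at any branch length.

## Problem sizes used in the checks

Unit and property tests run at small `L` (hundreds to a few thousand) with
brute-force oracles at `K ≤ 4`; the metric-axiom fuzz uses 10^4 random
unit-vector triples in dimensions 10–1000; NJ exactness uses 1000 random
additive matrices with 4–12 leaves; the end-to-end benchmark uses 40 seeds
of the 8-leaf / 50 kb / `K = 6` configuration. These sizes give the
statistical assertions comfortable margins while keeping the whole suite
around a minute.

## Known limitations

* Whole-genome DNA at `K = 11–12` (`N ≈ 4.2e6–1.7e7`) is supported by the
  sparse representation, but counting is pure R; genomes of tens of
  megabases will take minutes, not seconds.
* Only the dynamical-language background is implemented; alternative
  denoising models (e.g. the (K−2)-order Markov background of CVTree) are
  out of scope.
* No bootstrap support values, and no BioNJ/FastME variants.
* The pseudo-distance is provided for comparison and legacy replication
  only; it should not be fed to methods that assume a metric.
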