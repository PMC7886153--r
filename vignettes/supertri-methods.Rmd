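---
title: "Methods: windowed signal, SuperTRI support, and calibration priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed signal, SuperTRI support, and calibration priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, derivations and design decisions
behind `mitophylo`. All code chunks are illustrative and are not
evaluated when the package is built; every quantitative claim made here
is checked by the test suite or by `scripts/acceptance.R`.

## 1. Circular half-overlapping windows

A mitogenome is circular, so a windowing scheme over an alignment of
`L` columns should cover the origin as evenly as any other position.
`make_windows(L, k)` produces `2k` windows from `k` primary blocks:

* The primary block length is `base = L %/% k`; any remainder `L %% k`
  is absorbed by the last primary block, so primary blocks tile
  `1..L` exactly.
* Secondary windows repeat the primary blocks shifted by
  `offset = (base - 1) %/% 2`, half a block to the right. The last
  secondary window runs past column `L` and wraps to the start,
  which is recorded as a second interval (`start2`, `end2`).

Two invariants follow and are enforced by property tests over random
`(L, k)`: every column is covered by exactly two windows, and window
lengths differ only where the remainder lands. For `L = 14892`,
`k = 5` this yields ten windows, the first spanning columns 1–2978,
the second starting at 1489, and the tenth starting at 13401 and
wrapping through column 1488.

```{r}
ws <- make_windows(14892, 5)
ws$windows
```

## 2. Per-window trees and the stand-in for posterior support

Within each window the package computes uncorrected p-distances with
pairwise deletion of gaps and ambiguity codes, builds a neighbor-joining
tree (`ape::nj`, with negative branches clamped to zero), and draws a
nonparametric bootstrap sample of trees (`bootstrap_trees`, seeded and
RNG-state preserving). Bipartition frequencies across that sample play
the role that split posterior probabilities play in a Bayesian
analysis; the package deliberately keeps this inference step simple and
fast so that the aggregation machinery — the part this package is
about — can be tested end to end in seconds. Tree samples produced by
external samplers can be substituted via `read_trees` and the
`tree_source` configuration entry.

## 3. SuperTRI: weighted MRP and supertree bootstrap

Each window's bipartition list becomes a block of binary characters:
one character per split, taxa in the split's canonical smaller side
coded `1`, the rest `0`, and the split's bootstrap frequency used as
the character weight (`build_mrp`). The supertree criterion is weighted
Fitch parsimony; `mrp_supertree` offers exhaustive enumeration,
branch-and-bound (both exact, used up to ~9 taxa) and seeded
NNI hill-climbing with restarts for larger problems. Correctness of the
scoring and of the exact searches is established in the tests against
an independent parsimony implementation (`phangorn`) and brute-force
enumeration of all unrooted topologies.

Supertree bootstrap percentages (SBP) resample MRP characters with
replacement; a split scores a replicate only if it appears in the
strict consensus of *all* optimal trees for that replicate, so ties
count for nobody. On a four-taxon matrix with three characters for one
split and one for a conflicting split, the optimum contains the
majority split exactly when it receives at least three of the four
resampled characters, giving an exact expectation of
`100 * P(Binomial(4, 3/4) >= 3) = 73.83` — a closed-form oracle used by
the acceptance suite.

Each node of the main (whole-alignment) analysis is then classified by
three numbers: its support in the main analysis (`pp`), its SBP, and
its reproduction index `nrep` (the number of window consensus trees
containing it). Nodes with `pp >= 0.95`, `SBP >= 95` and
`nrep >= ceiling(n/2)` are `signal_genome_wide`; nodes failing both the
SBP and reproduction thresholds are `signal_weak_or_local`; the rest
are `intermediate`. A `conflict_suspect` flag marks robust main-analysis
splits (`pp >= 0.95`) that are incompatible — by the four-intersection
rule — with a robust supertree split (`SBP >= 95`): simultaneous strong
support for incompatible groupings is the signature of heterogeneous
signal, such as a chimeric sequence.

## 4. Calibration priors

Given a node's fossil bounds `(Min, Max)` in Mya, the package builds
either a uniform prior on `[Min, Max]` (strategy `"U"`) or an offset
lognormal prior (strategy `"L"`): offset at `Min`, real-space mean
above the offset `M = (Max - Min) / 4`, and shape `S` solved so that
the prior's 97.5% quantile lands exactly on `Max`. Writing the
lognormal with `meanlog = log(M) - S^2/2` (so its real-space mean is
`M`), the quantile constraint becomes

```
log(M) - S^2/2 + z * S = log(Max - Min),    z = qnorm(0.975)
```

whose smaller root is `S = z - sqrt(z^2 - 2 log 4)`. The constant
`log 4` appears because `(Max - Min) / M = 4`; `S` is therefore the
same for every bounds pair, `0.926` to three decimals
(`solve_lognormal_shape()`). Nodes marked `N` in a calibration sheet
instead get a normal prior centered at the bounds midpoint with the
bounds as the central 95% interval. A worked 22-row carnivoran
calibration sheet ships in `inst/extdata/calibrations_carnivora.tsv`;
`export_priors` writes both a TSV of derived parameters and
BEAST-style XML fragments.

## 5. The synthetic generator and fixture design

`simulate_sequences` evolves sites down a tree under GTR with
discrete-gamma rate variation (four categories) and a proportion of
invariant sites; defaults (`base_freq = (0.31, 0.26, 0.13, 0.30)`,
`gamma_alpha = 0.5`, `p_inv = 0.425`) are typical of mammalian
mitogenome alignments. The simulator is validated against closed forms:
zero-length branches yield identical sequences, the two-taxon
Jukes–Cantor special case matches `p = (3/4)(1 - e^{-4t/3})`, and long
branches approach the stationary base frequencies.

The standard 12-taxon fixture (`simulate_fixture`) has four families of
three taxa. Its branch lengths are not arbitrary. For the chimera
acceptance test, a host taxon's columns in eight of the ten windows are
replaced by a donor from another family. Under distance-based
inference, the concatenated tree abandons the donor's family for a
(host, donor) pairing once the contaminated fraction `alpha` exceeds
roughly `1 - p(donor, kin) / p(donor, host)`, where the `p` are clean
p-distances. For the conflict flag to fire, the concatenated tree must
*robustly keep* the donor's family while most windows *robustly vote*
(host, donor) — so that flip point must sit well above the
window-majority point. The fixture therefore uses short within-family
branches (0.004–0.012) under long family stems (0.14–0.35), pushing the
flip point near `alpha = 0.95` while 80% of windows are fully donated.
Similarly, taxon D3 carries a deliberately long terminal branch (0.25):
a compositional shift (`clade_shift`) accumulates over branch length,
and a long lone branch is the realistic substrate for a
single-taxon base-composition outlier. Both designs were derived from
this analysis, not by tuning against test outcomes.

Perturbation injectors — `inject_near_duplicates` (intra-species
haplotypes within a p-distance ceiling), `inject_chimera` (interval
replacement with a manifest), `inject_singleton_insertion`
(single-taxon insertion columns) — each record a manifest attribute so
tests can assert exactly what should be detected and removed.

## 6. Numerical choices

* Distances use pairwise deletion; a pair with no comparable columns is
  `NA` with a warning, and NJ refuses matrices containing `NA`.
* Weighted Fitch is implemented on bitmask state sets, vectorized over
  characters; `?`/`NA` cells are treated as fully ambiguous.
* All stochastic entry points take explicit seeds and restore
  `.Random.seed`, so runs compose without contaminating the caller's
  RNG stream; the pipeline writes a manifest of md5 checksums and
  reproduces it exactly for an identical configuration.
* Canonical split labels (sorted smaller side, complement-pooled) make
  split identity stable across functions and file formats.

## 7. Limitations

* The built-in per-window inference is NJ-bootstrap on p-distances, a
  stand-in for model-based posterior samples; `pp` from it is a
  bootstrap proportion, not a posterior probability.
* Heuristic supertree search (NNI hill-climbing) is only checked
  against the exact searches on small instances; for large taxon sets
  it inherits the usual local-optimum caveats, mitigated by restarts.
* Fitch scoring of multifurcating trees folds children sequentially,
  which is exact on the binary trees the search actually scores.
* Calibration export produces prior specifications only; the package
  does not run a dating analysis.
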