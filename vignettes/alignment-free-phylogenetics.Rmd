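---
title: "Alignment-free phylogenetic inference for marker-gene surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free phylogenetic inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aftree)
```

# The problem

Microbiome-wide surveys of a marker gene (typically 16S rRNA) end up with
thousands of representative OTU sequences whose phylogeny is needed twice:
once to interpret community structure, and once as the input of
phylogeny-aware statistics such as weighted UniFrac. The classical route —
multiple sequence alignment followed by maximum-likelihood inference — is
expensive and fragile at this scale. `aftree` implements the alternative:
pairwise evolutionary distances computed directly from unaligned sequences,
neighbor joining on those distances, and a consensus ensemble over several
distance definitions. Because the three distances probe different features
of the sequences, their trees disagree with each other more than
alignment-based trees do, and the majority-rule consensus of the ensemble
discards exactly the poorly supported, method-specific branches. A
taxonomy-derived tree serves as the gold standard for scoring.

# The three distances

All three operate on DNA over `{A,C,G,T,N}`. `N` (any ambiguity code, any
gap or stray character on input) matches nothing — not even another `N` —
and voids k-mer windows; this is a deliberate, conservative treatment of
ambiguity rather than an attempt to model it.

## Average common substring (ACS)

The matching statistic `l[i]` is the length of the longest substring of `X`
starting at position `i` that occurs anywhere in `Y`; `L(X,Y) = mean(l)` is
a similarity. It is converted to a directed distance by inverting and
removing the self-similarity baseline,

```
d(X -> Y) = log(m) / L(X,Y) - log(n) / L(X,X),    L(X,X) = (n+1)/2,
```

with `n = |X|`, `m = |Y|`; the reported distance is the mean of the two
directions. The closed form `L(X,X) = (n+1)/2` makes the distance exactly 0
for identical sequences. Natural logarithms are used; the base only
rescales all distances jointly, and cancels in the identity case. When two
sequences share no character at all, `L = 0` is replaced by the finite cap
`1/(2n)` with a warning.

## Composition vectors (CVTree)

For word length `k` the empirical probabilities `p(w)` of all `k`-, `(k-1)`-
and `(k-2)`-words are counted (windows containing `N` are skipped, and the
denominators shrink accordingly). A `(k-2)`-order Markov background predicts

```
p0(a1..ak) = p(a1..a_{k-1}) * p(a2..ak) / p(a2..a_{k-1}),
```

and the vector component for `w` is the relative deviation
`(p(w) - p0(w))/p0(w)` (0 where `p0 = 0`). The distance between two vectors
is `(1 - cos)/2` over the union of supports, in `[0,1]`, with the
convention 0.5 for an all-zero vector. The default `k = 6` (configurable
3–9) balances resolution against sparsity for ~0.5–1.5 kb marker
sequences: `4^6` possible words against a few hundred observed ones keeps
the background estimable without collapsing the signal.

## Shortest unique substrings (Kr)

The shustring length `sl[i]` is the shortest prefix of `X[i..]` absent from
`Y`; identically `sl = l + 1`, including the sentinel when the whole suffix
occurs in `Y`. Under a mismatch process, match lengths are roughly
geometric, so `1/mean(sl)` estimates a per-position mismatch rate; the
self-baseline `1/mean(sl(X,X)) = 2/(n+3)` is subtracted, the two directions
averaged, and the result mapped through the Jukes-Cantor correction
`-(3/4) log(1 - (4/3) pi)`. The cap `pi <= 0.74` keeps the logarithm
finite and triggers a warning. This estimator is a simplified stand-in for
the original published Kr (which corrects the expectation with coalescent
arguments); it preserves the properties the pipeline relies on — zero on
identity, symmetry, monotonicity in true divergence — and is documented as
such rather than presented as a reimplementation.

# Trees

Neighbor joining follows the standard Saitou–Nei agglomeration with the
Studier–Keppler criterion. Two numerical choices make it bit-reproducible:
ties in the Q matrix are broken by the lexicographically smallest pair of
cluster labels (a cluster is labelled by the smallest leaf it contains),
and negative intermediate branch lengths are clamped to 0.

Robinson–Foulds distances count the symmetric difference of non-trivial
bipartition sets; the normalized variant divides by `2(N-3)`. The
branch-score distance sums squared branch-length differences over the
union of bipartitions, pendant branches included, and treats missing
lengths as 0. Trees are unrooted before bipartition extraction, so a
rooted input's two root edges merge into one bipartition with summed
length.

# The consensus ensemble

The ensemble pipeline is: majority-rule consensus (bipartitions in more
than half the trees; the *extended* variant then greedily adds compatible
minority bipartitions in decreasing frequency, ties broken by canonical
bipartition order — this mirrors the PHYLIP CONSENSE default), deterministic
resolution of the remaining polytomies into caterpillars of zero-length
branches (children ordered by smallest descendant label; because inserted
branches have length 0, patristic distances and all positive-length
bipartitions are untouched, so the arbitrary shape is harmless), a
least-squares branch-length fit of the common topology against each
method's distance matrix, and finally a per-branch arithmetic mean of the
fitted lengths.

The branch fit minimises `sum (d_ij - p_ij)^2 / d_ij^power` subject to
non-negative lengths, with `power = 2` by default — the Fitch–Margoliash
weighting. Zero observed distances borrow the smallest positive entry for
their weight. The solver is Lawson–Hanson non-negative least squares on the
path-incidence system, run on precomputed normal equations so that
200-taxon fits stay interactive. The fit is performed on the
binary-resolved topology (the least-squares system on a polytomous tree
would be rank-deficient); zero-length resolved branches typically stay at
zero because nothing in the data supports them.

# The taxonomy gold standard

`taxonomy_to_tree()` converts rank strings (domain through species) into a
tree: one internal node per distinct named taxon, keyed by its full path —
so a genus name recurring under two families yields two nodes. Two
semantic decisions the rank-string format leaves open are fixed as
follows. First, an *empty* rank label (e.g. `g__`) creates no node:
sequences attach at their deepest named ancestor. Creating a node per
empty label would wrongly cluster all unassigned genera into one fake
taxon. Second, unary chains — named taxa with a single child and no
directly attached sequences — are collapsed, which keeps the tree
comparable under Robinson–Foulds with inferred trees whose internal nodes
are anonymous. Child order is lexicographic throughout, so the generator is
deterministic under row permutation.

# Community statistics

Weighted UniFrac is `sum_b l_b |p_A(b) - p_B(b)|` over branches, where
`p_X(b)` is the fraction of community X's abundance below `b`; the
normalized variant divides by `sum_b l_b (p_A(b) + p_B(b))`. Raw is the
default, matching the dominant pipeline convention. Because the raw value
depends on root placement, unrooted trees are always midpoint-rooted
first — a fixed, documented rule rather than a claim that this placement is
"correct".

PERMANOVA decomposes `SS_total = sum_{i<j} d_ij^2 / N` into within- and
between-group parts and assesses the pseudo-F by label permutation (within
strata when given). The p-value uses the add-one estimator
`(exceedances + 1)/(B + 1)`, so it is never 0 and is reproducible
bit-for-bit given the seed. Default 10,000 permutations. The effect size

```
omega^2 = (SS_A - df_A * MS_W) / (SS_T + MS_W)
```

is reported unclamped: under the null it is negative about half the time,
and truncating it would bias power-study averages. `omega^2 < R^2` holds
whenever the residual mean square is positive.

The sequential test (factor B conditioned on factor A) uses the Gower
inner-product matrix `G = -1/2 J D^(2) J` and projection traces:
`SS(B|A) = tr(H_{A+B} G) - tr(H_A G)`, residual from the full model.
Permutations shuffle the raw observations within levels of A — the
simplest scheme consistent with a location-conditional design; residual
permutation schemes would be an alternative but are not implemented. A
factor adding no rank beyond the conditioning factor is an error
(confounding), and a constant conditioning factor reduces exactly to the
one-factor test.

# What the simulator emulates — and what it does not

`simulate_tree()` draws a Yule (pure-birth) topology and fresh i.i.d.
exponential branch lengths rescaled to mean root-to-tip depth 1, so the
`scale` parameter reads directly as expected substitutions per site from
root to tip. Sequences evolve under Jukes–Cantor only: the evaluation
design does not hinge on a richer substitution model, and JC matches the
assumption built into the Kr estimator. The default `scale = 0.3` gives
moderate divergence of the kind seen across distant 16S clades; default
sequence length 500 and 64–200 taxa are desk-scale stand-ins for the
~1.5 kb, ~5,000-OTU scale of real surveys (reachable via configuration,
at cluster-sized runtimes).

Taxonomies are derived from the generating tree by depth cuts: rank `r` of
a leaf is the deepest ancestor not deeper than `cut_depths[r]` (seven
evenly spaced cuts by default). This guarantees the taxonomy is consistent
with the true tree, which is what makes the gold-standard comparison
meaningful in simulation.

Communities are two groups of samples around log-normal per-OTU baseline
abundances (`sigma = 1.5`, a long-tailed, stool-like rank-abundance
shape); per-sample noise is multiplicative log-normal with `sigma = 0.5`,
chosen once as a realistic sample-to-sample dispersion. The between-group
effect is injected by permuting the baseline abundances of a uniformly
chosen set of OTU labels in group 2's baseline (not per sample). Label
permutation changes *which* taxa are abundant without touching the
phylogeny — which is exactly what lets the power study vary effect size
with the tree held fixed.

A green simulation test therefore establishes: internal consistency of the
whole stack, correct calibration of the permutation test, and the expected
qualitative orderings (distances increase with divergence, power increases
with injected effect, inferred trees beat random baselines). It does not
establish performance on real amplicon data, which has chimeras,
sequencing error, compositional artifacts and non-JC evolution that the
simulator deliberately omits.

# Numerical choices and degenerate inputs

* Distance matrices are symmetrized on construction (tolerance `1e-9`;
  larger asymmetry is an error) and validated for zero diagonal and
  non-negativity.
* Identical sequences: all three distances return exactly 0 (the baselines
  cancel algebraically, not approximately).
* Zero-divergence simulation (`scale = 0`): all distance matrices are zero;
  NJ resolves ties by label order and returns a zero-length tree; the
  harness reports without crashing.
* PCoA drops negative-eigenvalue axes but reports all eigenvalues.
* The matching-statistics engine is O(nm) longest-common-extension dynamic
  programming in C++; an O(n^2 m) brute-force oracle in the test suite
  pins its exactness on random ACGTN inputs.

# Known limitations

* The Kr estimator is a simplified geometric-match-length version, not the
  original coalescent-corrected formula.
* Reverse-complement matching is off by default (same-strand amplicons);
  `rc = TRUE` takes the minimum over orientations but doubles the work.
* The sequential PERMANOVA implements exactly one conditional pair, not
  general multi-factor designs.
* Consensus requires identical leaf sets; supertree methods are out of
  scope.
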