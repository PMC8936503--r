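---
title: "Edge-replacement fractal scale-free networks: model, theory, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-replacement fractal scale-free networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsfn)
```

## The model and its assumptions

A *generator* `G` is a small connected simple graph with two designated
*root nodes*. The generation-`t` network is obtained from the
generation-`t−1` network by replacing **every** edge with a fresh copy of
`G`, identifying the edge's endpoints with the roots. The initial graph is a
single edge (an arbitrary initial graph is accepted by `build_network()`,
but the closed-form size formulas then no longer apply and the package flags
them as such).

Three properties of `G` control the character of the limit network:

1. **Root degree** `κ ≥ 2` — otherwise degrees never multiply and the degree
   distribution decays exponentially instead of as a power law.
2. **Root distance** `λ ≥ 2` — adjacent roots make the diameter grow only
   additively, producing a small-world rather than fractal network
   (`D_f = log m_gen / log λ` diverges at `λ = 1`).
3. **Root symmetry** — the two roots are interchangeable (deleting either
   root yields isomorphic graphs). Symmetric generators give deterministic
   networks; asymmetric ones require a fair coin flip per replaced edge to
   choose the orientation, and all structural statements become
   expectations over that randomness.

`validate_conditions()` reports violations as warnings rather than errors:
sizes, clustering, joint degree tables and the whole percolation theory
remain valid for degenerate generators; only the scale-free, fractal and
degree-correlation sections are flagged inapplicable.

We deliberately restrict generators to simple graphs (no parallel edges,
no self-loops). Root order `(r1, r2)` is meaningful only for asymmetric
generators; for symmetric ones every output is invariant under swapping the
roots, which the test suite checks explicitly.

## What is exact and what is iterated

All integer descriptors (`m_gen`, `κ`, `λ`, remaining degrees, triangle
counts, root-neighbourhood profiles) are computed exactly from the generator.
Downstream:

- **Sizes, symmetric degree tables, finite-generation moments** — exact
  integer/rational arithmetic (doubles are exact well past the generations
  anyone materializes; the table builder refuses sizes above a configurable
  cap).
- **Symmetric infinite-generation clustering** — a geometric series summed
  until terms drop below `1e-15`; the terms decay at least as fast as
  `(κ m_gen)^{-s}`, so the truncation error is bounded by a geometric tail
  well below the reported precision.
- **Asymmetric quantities** — the orientation-averaged degree recurrence
  redistributes each degree `k` binomially; we truncate the binomial sums to
  `k/2 ± 5√k` for `k > 64` (omitted mass `< 1e-22`). Quantities without a
  closed-form limit (asymmetric average clustering, both correlation
  measures) are evaluated at increasing generations until two successive
  values differ by less than a tolerance: `1e-6` for clustering, `1e-4` for
  the correlation coefficients. Convergence is geometric — each extra
  generation suppresses the new contributions by roughly
  `1/(m_gen κ̄)` — so these loops terminate after a handful of steps.
- **Assortativity limit** — when `γ ≤ 4` the third degree moment diverges
  and the finite-generation assortativity decays to zero without ever
  converging numerically at any practical generation; the limit is
  therefore reported as 0 in that regime rather than iterated.
- **Spearman's coefficient** uses mid-ranks on the endpoint-degree marginal
  (the standard tie treatment), expressed as mass fractions; Pearson
  correlation of ranks is affine-invariant, so this choice only fixes a
  convention.

## Percolation theory: numerical choices

The reliability polynomial is built by exhaustive enumeration of all
`2^{m_gen}` edge subsets of the *core subgraph* (edges on at least one
simple root-to-root path — edges off the core cannot affect two-terminal
connectivity, and generators sharing a core share all percolation
quantities). Connectivity per subset uses union-find; the enumeration cap
defaults to 24 edges. Exactness over cleverness: at generator scale there
is nothing to approximate.

The critical point is located by a sign scan of `π(p) − p` on a `1e4`-point
grid of (0, 1) followed by bisection to `1e-12`, keeping the root with
`π'(p_c) > 1`. The trivial stable fixed points 0 and 1 are excluded by the
open-interval scan; a core that is a tree has `π(p) < p` everywhere inside
and is reported as "no transition below 1" instead of a critical point.
Should a generator ever produce several unstable fixed points, the package
raises an error listing them rather than silently picking one.

The transfer matrix propagates the pair (probability of reaching exactly
one of the two oldest nodes, probability of reaching both) across
generations. Its coefficients are counted by removing each edge `e0` in
turn (the copy containing the tracked node), enumerating occupation
patterns of the remaining `m_gen − 1` copies, and classifying how many
roots are reachable from one terminal of `e0` (state entering via a single
attachment; both terminal choices counted, normalized by 2) or from both
terminals treated as internally connected (state entering with the copy's
own terminals joined). The two eigenvalues of the resulting 2×2 matrix are
taken in closed form from the quadratic formula, avoiding any numerical
eigensolver ordering ambiguity. The identity `ν̃ = D_f ν` is asserted to
`1e-9` as a consistency check wherever both sides are computed.

## The builder and its provenance scheme

New node identifiers are the triple (generation, parent-edge index in the
lexicographically sorted edge list, local generator label), so two builds of
the same configuration are bit-identical and diffable, and the two
generation-0 nodes (the *renormalized root nodes*, RRNs) are always
recoverable. For a single symmetric generator no randomness is consumed at
all, making the result seed-independent by construction. Stochastic builds
(asymmetric or multi-generator) draw one categorical generator choice and
one orientation flip per edge, in sorted-edge order, from the single seeded
stream; a build is therefore a pure function of (generators, t, seed).

## What the simulator emulates — and what it does not

The Monte-Carlo module removes each edge independently with probability
`1 − p` and measures largest-component fractions, RRN connectivity and
diameters on explicitly built networks. It emulates exactly the idealized
bond-percolation process of the theory: independent edge failures on a
perfectly hierarchical substrate. It does **not** emulate features of real
fractal networks — degree-correlated or geometric edge failures, disorder
in the replacement rule, finite measurement noise — so agreement between
simulator and theory validates the implementation of the model, not the
model's fit to any particular biological network.

Two finite-size effects matter when comparing simulation with the
`t → ∞` theory, and both are handled explicitly rather than hidden:

- **Diameter offset.** The diameter obeys `L_t = λ L_{t−1} + L_0` with a
  generator-dependent constant `L_0` (for the asymmetric fixture `C`,
  `L_t = 2 L_{t−1} + 2`). A raw least-squares slope of `log N` against
  `log L` over small generations is biased low by this offset — for `C` at
  `t ≤ 5` it gives ≈ 2.26 against the true `log 7 / log 2 ≈ 2.81`. The
  successive-ratio estimator `log(N_t/N_{t−1}) / log(L_t/L_{t−1})`, in which
  the offset cancels asymptotically, lands within 5% at `t = 5` and is what
  `estimate_fractal_dimension()` reports (the regression slope is kept as a
  secondary field).
- **Pre-asymptotic amplitude scaling.** At criticality the order parameter
  contracts per generation by `ω_c` only asymptotically; at `t = 3..6` the
  measured per-generation ratio for fixture `C` is ≈ 0.87–0.89 against
  `ω_c = 0.8587`, i.e. the *effective* amplitude exponent `β/ν̃` is ~20%
  below its limit. A scaling-collapse comparison that perturbs `β` alone
  can therefore "win" at these sizes for physical reasons. The collapse
  check consequently perturbs the exponent **pair** `(β, ν̃)` by ±20% in
  all four sign combinations — these distort the abscissa map that the
  collapse is actually sensitive to — and the theory exponents beat every
  such perturbation by more than the documented factor-2 margin. The
  collapse quality score is the mean squared vertical spread between
  generation curves after interpolation to the common rescaled abscissa,
  normalized at each abscissa by the squared mean level; without that
  normalization, shrinking `β/ν̃` would shrink the absolute spread
  trivially and the score would be meaningless.

All stochastic tests use three-standard-error bands with a Poisson floor on
the standard error (degrees so rare that they may not occur at all in an
ensemble would otherwise produce a zero empirical standard error and a
vacuously impossible band).

## Problem sizes used by the test-suite

The suite validates closed forms against explicit builds at generations
`t ≤ 5` for symmetric fixtures and `t ≤ 6` for the asymmetric one
(58,826 nodes), uses 200-seed ensembles for orientation-averaged
expectations, 2,000 percolation replicates for RRN-connectivity
comparisons, and 16–240 replicates per occupation probability (decreasing
with network size) for the collapse study. These sizes were chosen so the
statistical bands are a small multiple of the systematic finite-size
effects discussed above; growing them further sharpens nothing that the
closed forms do not already pin down exactly.

## Known limitations

- Generators must be simple graphs; multigraph generators (parallel edges
  between the roots, which generate certain fractal trees) are out of scope.
- Site percolation (node failure) is not treated; its renormalization does
  not close over a scalar map the way bond percolation does.
- Average shortest-path analytics and spectral properties are not
  implemented; the diameter is only measured empirically.
- The asymmetric infinite-generation clustering and correlation limits are
  convergence-based evaluations, not closed forms; their tolerances
  (`1e-6`, `1e-4`) are recorded in the corresponding function signatures.
- The symmetry test is the deletion-based definition (delete either root,
  compare up to isomorphism). This is not the same as requiring an
  automorphism exchanging the roots, and the two can disagree on contrived
  generators; the deletion-based reading is the one the growth process
  actually depends on for orientation-independence of the *degree*
  statistics.
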