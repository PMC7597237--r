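---
title: "Path-based partial information decomposition: model, conventions, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-based partial information decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpid)
```

## The model and its assumptions

`pathpid` treats a set of discrete random variables as a probabilistic
graphical model in which every undirected edge is a pair of discrete
memoryless communication channels, one per orientation. This presumes the
data are stationary and ergodic realizations of the variables, that the
Markov condition holds (a variable is independent of its non-effects given
its direct causes), and that the alphabets are finite and declared. Under
these assumptions a channel is fully characterized by its row-stochastic
transition tensor $A_x^y = p(y\mid x)$, pmf propagation is the linear map
$p^y = \sum_x p^x A_x^y$, and the tensor of a cascade is the matrix product
of the constituent tensors.

A *path* $\{X_1\}\{X_2\}\cdots\{X_\ell\}$ is an ordered sequence of vertex
groups; each node may be a join such as $\{XY\}$, represented on the product
alphabet in lexicographic order (first listed variable slowest). Its
path-based mutual information is

$$I_{\{X_1\}\cdots\{X_\ell\}} \;=\; \sum_{x_1, x_\ell}
  q(x_1,x_\ell)\,\log_2 \frac{T_{x_1}^{x_\ell}}{m(x_\ell)},$$

where $T$ is the ordered product of the per-edge channels. The defining
texts leave open which joint weights the logarithm; the worked tables for
the two-bit copy and the common-cause system are only reproduced when both
the joint $q = \mathrm{diag}(p(x_1))\,T$ and the target marginal
$m = p(x_1)\,T$ are the **path-propagated** distributions rather than the
empirical endpoint distributions, so that is the convention implemented
(`path_joint()` exposes all of them). With a single edge the two notions
coincide and the measure reduces to ordinary mutual information. Per-edge
channels are always estimated from the full joint pmf, including for
overlapping groups such as $\{Y\}\to\{XY\}$, where the conditional is the
consistent-state probability (inconsistent combinations have probability
zero); this is what makes join targets — and with them the identity
property $R(X,Y;XY) = I(X;Y)$ — computable without special cases.

## Redundancy, admissibility, and the two pruning regimes

Redundancy is the minimum path-based MI over the admissible permutation
paths that visit all sources once and end at the target. Three conventions
here were genuinely open and are fixed as follows.

**Empty admissible set means zero redundancy.** When the sources are
independent (Xor, And, two-bit copy, 5B) there is no source–source edge and
hence no indirect path. No convention is stated in the source material, but
$R = 0$ is the only choice consistent with the published atom tables for
those systems, and it is what `path_redundancy()` returns.

**Absent edges disqualify paths; cascade-explained edges do not (by
default).** `infer_graph()` distinguishes edges whose channel has identical
rows (*absent* — the channel transmits nothing) from edges whose tensor is
exactly reproduced, in both orientations, by a length-2 cascade through a
third vertex (*indirect*, with every witness path recorded). Only absent
edges make a permutation path inadmissible by default. The triadic system
forces this choice: each of its three edges is explained by a cascade
through the others, the candidate prunings are mutually exclusive, and
excluding indirect edges from path enumeration would leave no admissible
path at all — contradicting the known result that the triadic target
carries 1 bit of pure redundancy. The graph therefore reports *all*
candidate prunings and leaves the edges traversable.

**Strict pruning is available, and is what makes the Markov-chain
consequence exact.** For a noisy chain $X \to Y \to Z$ the proposition
"all information shared between the distal source and the target is
redundant" ($U(X;Z)=0$) does *not* hold under the default rule: the reverse
permutation path $\{Y\}\{X\}\{Z\}$ generally carries strictly less
information than $I(X;Z)$ (e.g. two cascaded binary symmetric channels with
10% flips give 0.198 vs 0.320 bits), dragging the minimum below $I(X;Z)$.
The consequence is exactly recovered when the cascade-explained $X$–$Z$
edge is excluded, i.e. when the inferred structure is taken seriously.
`decompose(..., strict = TRUE)` enables this regime; the package's
parameter-recovery property tests run under it, while all published-table
comparisons use the default.

Unique information is $U = I(\text{source};\text{target}) - R$. A negative
$U$ beyond $10^{-9}$ bits raises an error rather than being clipped — in
this framework it signals inconsistent inputs. Synergy is the additivity
remainder, which makes $U_1+U_2+R+S = I(X,Y;Z)$ exact by construction and
turns the interaction-information identity
$S - R = I(X;Y|Z) - I(X;Y)$ into a genuine cross-check of $R$ and $U$
(asserted across the test suite). Negative synergy is *reported*, never
suppressed: it is the diagnostic signature of an unobserved common cause
(the common-cause benchmark) or of an over-determined system.

## Tunable parameters

* `tol` (default $10^{-9}$, dimensionless probability/bits scale) — the
  null-channel, cascade-equality and axiom-check tolerance. The default is
  calibrated for exact rational fixtures and the strictly positive
  Dirichlet systems of the generator; for plug-in estimates from finite
  samples the user must widen it explicitly (no silent adaptivity).
* File normalization tolerance (default $10^{-6}$) — documents whose
  probability column is off by more than this are rejected with the deficit
  named; within it, probabilities are renormalized exactly.
* `strict` / `--strict-pruning` — see above.
* Display rounding is 4 decimals in tables (2 where the published tables
  print 2); machine output (JSON/TSV) is full double precision.

## Zero-probability states and other numerical choices

All logarithms are base 2 (results in bits) with $0\log 0 := 0$. Alphabets
are declared, not inferred, and zero-probability states are retained in the
table so channel row indexing is stable. A conditional row for a
zero-probability source state is undefined; it is set to the uniform row,
flagged, and flagged rows are excluded from the null-channel and
channel-equality comparisons — tensors stay total, but unreachable states
can never drive edge pruning. Möbius inversion is computed recursively
bottom-up along a linear extension of the lattice order; re-summation
reproduces the cumulative values to $10^{-12}$.

The two-source lattice is the numerically validated decomposition. The
three-source lattice (18 nodes) ships with cumulative-value plumbing —
single-collection nodes take $I(\text{join};\text{target})$, multi-collection
nodes the path redundancy of their collections — but is labeled
experimental: no published three-source atom table exists to validate
against.

## What the synthetic generator emulates — and what it does not

`random_channel_system()` draws a DAG in a fixed topological order (each
forward edge present with probability `edge_density`) and samples every
conditional row from a flat Dirichlet, then propagates an equally sampled
root pmf. This generates exactly the world the method assumes: Markovian,
stationary, strictly positive joint pmfs over declared finite alphabets;
`random_markov_chain()` is the special case whose non-adjacent associations
are cascade-explained *by construction*, which is what the pruning and
parameter-recovery tests need. Defaults (3–4 variables, binary/ternary
alphabets, density 0.8 or 1.0) mirror the scale of every published worked
example.

The generator does **not** emulate finite-sample estimation noise,
non-stationarity, hidden confounding (except through the dedicated
`hidden_cause_system()` constructor), or continuous variables. A green
property sweep therefore establishes the *mathematical* invariants of the
implementation on in-model systems — DPI, traverse invariance, bounds,
Möbius consistency — not robustness of the decomposition to estimation
error.

Two published inequalities (the three-variable redundancy inequality and
the endpoint lower bound over multiple paths) are proven under the standing
assumption that any connected pair of vertices has at least one alternative
path. They are demonstrably false without it (for And, $R(X,Y;Z)=0$ under
the empty-set convention while $R(Z,Y;X) \approx 0.082$), so the
corresponding property sweeps condition on fully connected systems — the
regime in which the claims are made. Sweep sizes: the cheap three-variable
checks run on 1000 seeded systems; the brute-force oracle comparison,
four-variable monotonicity and chain-recovery sweeps are scaled to 60–300
systems to keep the default test run around a minute.

## Known limitations

* Numeric decomposition is limited to two (possibly joint) sources; the
  lattice machinery stops at three sources. Atom counts explode
  super-exponentially beyond that.
* Plug-in counting is the only estimator; no bias correction for sampled
  data.
* Several published atom tables are not derivable from the stated
  definitions (the 5A redundancy/unique atoms, the 5C table, the Sum
  bottom atom, the ReducedOr unique/redundancy atoms); the package computes
  what the definitions give, documents the discrepancy, and the test suite
  covers those distributions through structural identities instead of the
  printed numbers. The 5C table as printed repeats a full state; the
  fixture sums the duplicates and flags the distribution as internally
  inconsistent.
* Directionality inference (transfer entropy) and systems with hundreds of
  variables are out of scope.
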