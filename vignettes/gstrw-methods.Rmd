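---
title: "Two-tier global-similarity random walks for miRNA–disease prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier global-similarity random walks for miRNA–disease prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gstrw)
```

## The problem

Experimentally validating that a microRNA is involved in a disease is slow
and expensive, so computational prioritization of candidate miRNA–disease
pairs is used to focus bench work. The premise this package builds on is the
standard one in the field: functionally similar miRNAs tend to be implicated
in phenotypically similar diseases. Given three inputs — a miRNA functional
similarity matrix $SM$, a disease phenotype similarity matrix $SD$ (both
symmetric, entries in $[0,1]$), and a sparse binary association matrix $A$
(rows miRNAs, columns diseases) — the predictor scores every pair, including
pairs involving *orphan diseases* (no known miRNA) and *new miRNAs* (no
known disease), and without requiring negative training examples.

## The model

**Family fusion.** miRNAs in the same miRBase family share targets and are
more functionally alike than their pairwise score suggests, so family
co-membership doubles the functional score:
$$SIM(i,j) = SM(i,j)\,\bigl(1 + SM^{fam}(i,j)\bigr),$$
where $SM^{fam}(i,j) = 1$ iff $i \ne j$ belong to the same family. The
diagonal is never boosted (the fusion is about pairs; self-similarity is
handled by the walk itself), and fused entries may exceed 1 — the column
normalization below absorbs the scale, so clamping would only distort
relative weights.

**Global similarity.** Local similarity (direct neighbours) ignores most of
the network. Each entity's *global* profile is the Laplacian graph score:
with $\bar S$ the column-normalized similarity matrix and $e_j$ the query
indicator, the smoothed profile solves a penalized fit balancing smoothness
along edges against fidelity to the query, with closed form
$$\tilde d = (1-\alpha)\,(I - \alpha \bar S)^{-1} e_j .$$
All profiles at once form $G = (1-\alpha)(I-\alpha\bar S)^{-1}$; column $j$
is entity $j$'s profile. For $\alpha \in (0,1)$ the system matrix is
strictly diagonally dominant on stochastic columns, so the direct solve is
safe; entries are non-negative (a Neumann series of non-negative terms) and
columns over fully stochastic networks sum to exactly 1. As
$\alpha \to 0$, $G \to I$: no propagation.

**Seed optimization.** A disease's walk seed is its known miRNA indicator
augmented by its globally similar diseases' indicators,
$$\tilde D_i = D_i + \lambda \sum_{j \ne i} sim\tilde D(d_i,d_j)\, D_0^j ,$$
and symmetrically for miRNAs with weight $\eta$. This is what makes orphan
queries possible: a disease with an empty column still gets a seed through
its similar diseases. Two choices here were genuinely open and are fixed as
follows. The self term $j = i$ is excluded — including it would re-add
$D_i$ scaled by the self-similarity, double-counting the query's own
evidence. And the similarity weights are read from the query's *column* of
$G$ (its smoothed-indicator profile), the natural object the closed form
produces; $G$ is close to symmetric in practice so this choice is mild.
Seeds are L1-normalized so the walk iterates on a probability vector; this
does not change any ranking (the walk is linear in its seed and Pearson
correlation is scale-invariant) but keeps the stationary vectors on a common
scale. An all-zero seed is legitimate (an orphan disease in a similarity
vacuum) and short-circuits to all-zero scores.

**Restart walks and scoring.** The optimized disease seed walks on the
miRNA network,
$$x_{t+1} = (1-\gamma)\,\overline{SIM}\, x_t + \gamma\, \tilde D_i ,$$
until the L1 change between iterates drops below $10^{-6}$. (The stopping
rule in the source method is written with a bare absolute value; L1 is the
natural norm for probability vectors, and both restart equations are taken
to restart to the *optimized* seed — the printed subscript on the miRNA
side is inconsistent, but the accompanying text is not.) The stationary
vector is then correlated (Pearson) with every miRNA's global profile,
giving the disease×miRNA tier $F_m$; the mirror walk on the disease network
gives $F_d$; the final score is
$$F = w\,F_m^{\mathsf T} + (1-w)\,F_d .$$
Correlation against a constant vector is defined as 0 rather than NaN, so
degenerate queries rank by tie credit instead of poisoning the ranking.
Pearson uses the full vectors, including the query's own coordinate; the
source method never masks it and masking would break the self-correlation
sanity property ($x$ against its own profile scores 1).

## Parameters

| parameter | meaning | default |
|---|---|---|
| $\gamma$, $\theta$ | restart probability of the disease-seed / miRNA-seed walk | 0.2 |
| $\alpha$, $\beta$ | Laplacian balance of the disease / miRNA network | 0.8 |
| $\lambda$, $\eta$ | seed-optimization weight, disease / miRNA side | 0.2 |
| $w$ | tier mixture: 1 = miRNA network only, 0 = disease network only | 0.6 |
| tol | L1 convergence threshold of the walks | $10^{-6}$ |
| max_iter | walk iteration cap | 1000 |

The defaults are the setting of the method's comparison experiments. The
source's sensitivity discussion remarks that $w = 0.4$ once gave the best
single result while its comparisons fix $w = 0.6$; the defaults here follow
the comparison setting, and `parameter_sweep()` reproduces the
one-group-at-a-time sensitivity design for anyone who wants the curve. At
$\gamma = 0.2$ the walks converge in a few dozen iterations; the cap of
1000 is far from binding and exists to turn a miswired transition matrix
into an error instead of a hang.

## What the synthetic generator emulates — and what it does not

`synthetic_generate()` draws block-structured stand-ins for the real
inputs: miRNA and disease similarity matrices with planted communities
(within-block mean 0.7, between 0.1 by default, uniform ±0.05 noise drawn
on the upper triangle and mirrored, truncated to $[0,1]$, unit diagonal),
families as random subsets of size 2–4 nested inside single miRNA blocks
(half the miRNAs covered by default — enough that the family boost is
exercised without dominating the functional scores), and an association
matrix that is Bernoulli(0.5) on matched block pairs and Bernoulli(0.02)
elsewhere. One integer seed drives four fixed per-component sub-seeds, so
regenerating any single component is reproducible.

The default sizes (60 miRNAs × 30 diseases, 3 aligned blocks) are the
package's reference study condition: large enough that block structure,
orphan queries and family boosts are all non-trivial, small enough that a
full leave-one-out sweep is a routine test-suite operation.

Real similarity matrices are not block-constant: they have heavy-tailed
degree distributions, nested community structure, and similarity scores
correlated with annotation depth. Real association matrices are biased
toward well-studied diseases. Passing tests on these fixtures therefore
demonstrates that the machinery recovers planted structure of the assumed
kind — not that it will reach any particular accuracy on curated benchmark
data. Note also an intrinsic ceiling of the fixture design: the
`noise_density` positives are, by construction, unrelated to any similarity
structure and cannot be ranked above chance, and with `assoc_density` 0.5
half of each matched block consists of unassociated pairs that are
statistically indistinguishable from held-out positives. Cross-validated
AUC on the reference condition consequently plateaus around the mid-0.8s
even for an exact implementation; `scripts/acceptance.R` computes the
actual values.

## Evaluation protocols

`gstrw_loocv()` removes each known pair in turn, reruns the predictor and
records the held-out score. Candidate negatives are all pairs unknown in
the full matrix. Two pooling conventions are shipped because the
literature's presentation (one ROC per method) does not determine one: the
default **pooled-global** convention scores the negatives once with a
reference run on the full matrix and ranks every held-out positive against
that single pool; **per-disease** pooling ranks each positive only against
its own disease's candidates, scored within the same fold. The per-disease
convention is the more forgiving of the two on block-structured data (a
positive never competes with other diseases' look-alike negatives) and is
selected with `pooling = "per_disease"`.

Orphan-disease and new-miRNA protocols zero an entire column (row), rerun
the predictor, and rank the removed pairs against the entity's never-known
pairs from the same run. The evaluation path scores exclusively from the
zeroed matrix — the tests enforce this by recomputing queries from
explicitly zeroed inputs and requiring exact agreement.

ROC/AUC is computed in-house by a threshold sweep whose trapezoidal area
equals the Mann–Whitney convention $P(s^+>s^-)+\frac12 P(s^+=s^-)$ exactly;
a constant predictor scores exactly 0.5. The test suite certifies this
against exhaustive pair counting and against an established ROC package.
Because global similarities and transition matrices do not depend on $A$,
they are computed once per dataset and shared across all folds.

"Negatives" are, of course, merely unlabeled pairs — the no-negative-sample
premise of the method means every reported AUC is computed against a
candidate pool that certainly contains undiscovered true associations.

## Numerical choices

* Similarity input validation symmetrizes deviations up to $10^{-6}$ by
  transpose-averaging (quietly up to $10^{-8}$, with a warning above) and
  rejects anything grosser.
* All-zero similarity columns (isolated entities) stay zero under column
  normalization; the walk and the solve remain well-defined, and such
  entities simply receive no propagated mass.
* The global-similarity solve asserts finiteness and tolerates round-off
  negatives only below $10^{-10}$ in magnitude (clamped to zero).
* TSV writers emit 17 significant digits so write/read round trips are
  bit-exact.
* Everything is deterministic: there is no randomness anywhere in the
  predictor or the protocols, and the generator restores the caller's RNG
  state.

## Known limitations

* Dense linear algebra throughout; the operating regime is
  $n \approx 10^2$–$10^3$ entities per network, not genome-scale graphs.
* Pearson is the only profile-scoring rule, the source method's choice;
  rank-based alternatives are out of scope.
* No identifier normalization across database versions: the loaders require
  label universes to agree exactly.
* The tier mixture calibrates nothing: $F_m$ and $F_d$ are correlation
  matrices with different empirical distributions, and $w$ mixes them
  as-is. A fused score is therefore not comparable across datasets.
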