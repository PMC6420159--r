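---
title: "Testability of OTU associations: models, simulator and benchmarks"
author: "AssocTestability maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testability of OTU associations: models, simulator and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AssocTestability)
```

## The problem

Microbiota surveyed by 16S rRNA sequencing contain hundreds to thousands
of OTUs, most of them rare: a typical count table is dominated by zeros.
Association network analysis asks whether pairs of OTUs co-occur (or
co-vary in abundance) more or less than expected, but the test statistics
used for this question are *bounded* by the OTUs' prevalences.  When two
OTUs are each present in only a handful of samples, the most negative
value the Phi coefficient or the Pearson correlation can possibly attain
may sit inside the acceptance region of its null distribution — in which
case no dataset of that shape can ever yield a significant negative
association.  Such a pair is *non-testable* in the negative direction, and
testing it anyway produces silent false negatives.

This package provides the closed-form machinery to decide, per pair of
prevalences, whether positive and negative associations are testable; the
distributional models needed to ask how common non-testable pairs are in
realistic communities; a simulator that generates zero-inflated count data
with known association structure; and a network-inference pipeline that
exploits testability as a principled data filter.

## Closed-form bounds and critical values

For occurrence (presence/absence) data, the Phi coefficient of a 2x2
co-occurrence table with marginal prevalences $P_A, P_B$ is constrained by
the feasible range of the joint prevalence
$P_{11} \in [\max(0, P_A+P_B-1),\ \min(P_A, P_B)]$, giving

$$\min(\phi) = \max\!\left(-\sqrt{\tfrac{P_AP_B}{(1-P_A)(1-P_B)}},\
-\sqrt{\tfrac{(1-P_A)(1-P_B)}{P_AP_B}}\right),\qquad
\max(\phi) = \min\!\left(\sqrt{\tfrac{P_A(1-P_B)}{P_B(1-P_A)}},\
\sqrt{\tfrac{P_B(1-P_A)}{P_A(1-P_B)}}\right).$$

The maximum branch is implemented with positive sign: $\max(\phi) = 1$
exactly at $P_A = P_B$ (the occupied samples can coincide), and a
brute-force maximization of $\phi$ over all feasible tables confirms both
branches; the package's test suite re-derives them by enumeration.  Under
independence $N\phi^2$ is approximately $\chi^2_1$, so the critical value
is $\sqrt{\chi^2_{1,1-\alpha}/N}$; because $\phi^2$ folds both signs into
one tail, no further $\alpha$ splitting is applied.  Fisher's exact test
is handled separately by exact hypergeometric enumeration of the two
extreme tables, one-sided per direction, with a boundary p-value equal to
$\alpha$ counted as testable (the test *can* reach significance there).

For read-abundance data the Pearson correlation of two non-negative
vectors with $P_A + P_B < 1$ is bounded below by
$-\sqrt{P_AP_B/((1-P_A)(1-P_B))} > -1$, attained by constant positive
abundances on disjoint supports.  When $P_A + P_B \ge 1$ the supports must
overlap and co-present values can be arranged anti-monotonically, so the
bound is taken to be $-1$.  The maximum is always $1$ and is not
prevalence-limited, which is the structural reason positive associations
are always testable from abundances while negative ones often are not.
The Student-based critical correlation
$t_{1-\alpha/2, N-2}/\sqrt{N-2+t^2_{1-\alpha/2, N-2}}$ uses the two-sided
convention; the identical floor applies to the Spearman coefficient, since
ranking preserves the zero/non-zero pattern.

A pair's verdict is one of four categories (`full`, `positive_only`,
`negative_only`, `none`); `testabilityMask()` vectorizes the classifiers
over all pairs of a community, flags degenerate OTUs (prevalence 0 or 1)
with a warning rather than an error, and encodes the verdicts in a
symmetric S4 container used downstream as an inference mask.

## Prevalence models

Two prevalence distributions drive the population-level questions:

* **Uniform**: `uniformProportions()` enumerates every integer occupancy
  pair $(a, b)$, $1 \le a, b \le N-1$ — the discrete grid of prevalences
  actually observable at sample size $N$ — and returns exact category
  frequencies.  The discrete grid was preferred to the continuum because
  it makes the enumeration exact and matches what finite data can show.
* **Truncated power law**: density $\propto p^k$ on $[p_{\min}, 1]$,
  sampled by CDF inversion and fitted by 1-D maximum likelihood
  (`powerlawSample()`, `powerlawFit()`).  Exponents between $-2$ and $-1$
  reproduce the rare-OTU-dominated shape of real communities; the smaller
  the $k$, the larger the share of rare OTUs.

The lower truncation of the power law matters and is a genuine modelling
choice.  `powerlawProportions()` defaults to $p_{\min} = 1/N$, the
smallest prevalence observable at sample size $N$ (an OTU present in one
sample).  With this convention the Monte-Carlo proportions of
negative-non-testable pairs at $N = 100$ are about 0.63 ($k=-1$) and 0.98
($k=-2$) for occurrence data and about 0.63 and 0.98 for abundance data,
in line with the published characterizations of realistic communities.
The whole-community simulator instead uses the explicit floor $5/300$ in
the filtering benchmark (below), where the rarest OTU is expected in about
five of 300 samples so that no simulated OTU is absent from every sample.

A caveat worth stating: with $p_{\min} = 1/N$ the non-testable
(`none`-category) share for occurrence data at $N = 60$, $k = -1$ is about
11%, slightly above the ~10% often quoted for $N > 50$; the quantity is
sensitive to the truncation in exactly the region the truncation is least
identifiable.

The uniform-grid partial-testability proportion deserves its own note: it
exceeds 0.25 for all $N \lesssim 115$ (it peaks around 0.56 at $N = 11$,
where the equal-prevalence diagonal — always positively testable — is a
large fraction of the grid) and falls below 0.25 only beyond
$N \approx 115$.  Statements that partial testability "never exceeds
0.25" therefore hold only for sample sizes above that point.

## The copula simulator

`simulateCommunity()` composes three pieces:

1. **Signed structure**: `nEdges` edges are placed uniformly at random
   among OTU pairs, half positive and half negative by default.
2. **Correlation matrix**: a precision-like matrix $\Theta = dI - wA$ is
   formed from the signed adjacency $A$ (the minus sign makes the
   *correlation* carry the edge's sign after inversion), and the diagonal
   inflation $d$ is solved by a 1-D root find so that the condition number
   of the standardized inverse equals `conditionTarget` (default 100,
   within 1%).  The condition-number constraint — not any particular
   weight scheme — is treated as the binding contract; infeasible targets
   raise an error reporting the achievable bound.
3. **Marginals**: latent Gaussian samples with that correlation are pushed
   through the probability integral transform into zero-inflated negative
   binomial marginals.  The NB component is parameterized by mean $\mu$
   (default 1000) and dispersion $\theta$ (default 0.5) with variance
   $\mu + \mu^2/\theta$ — heavy overdispersion; note some texts call
   $1/\theta$ the dispersion.  Prevalence enters as the structural-zero
   probability $p_0 = 1 - \text{prevalence}$, and the structural zeros
   absorb the lower $p_0$ tail of the copula uniform.

Realized prevalence is slightly below structural prevalence because the NB
component itself yields zeros with probability
$(\theta/(\theta+\mu))^\theta \approx 0.022$ at the defaults; benchmark
code treats structural prevalence as nominal and records the realized
value.  Latent correlation levels of $\pm 1$ are clamped to $\pm 0.999$
(a singular 2x2 correlation is infeasible); this is the strongest
representable coupling.  All randomness flows through explicit integer
seeds, the global RNG state is never touched, and identical seeds
reproduce datasets bit for bit.

## Association measures

Six measures are provided for the response-surface experiments: Pearson,
Spearman (mid-ranks for the pervasive zero ties), the Phi coefficient on
binarized counts, Bray-Curtis dissimilarity *between OTU profiles across
samples* (an ecological sample-space statistic deliberately repurposed for
OTU pairs), plug-in mutual information, and the maximal information
coefficient.  Two implementation choices are not dictated by any standard:

* **MI binning**: zeros form their own category and positive values are
  split into five equal-frequency bins.  Quantile binning alone would put
  a zero-dominated bin boundary in an arbitrary place; keeping the zero
  class explicit preserves the occurrence signal under heavy inflation.
* **MIC**: grid search with bound $B(n) = n^{0.6}$; one axis is
  equipartitioned (ties never split) and the other optimized by dynamic
  programming over tie-respecting candidate cuts, taking the maximum of
  the normalized score over grid shapes and both orientations, which makes
  the statistic symmetric by construction.  The candidate-cut density
  (`clumpFactor`, default 5 per allowed bin) trades search completeness
  against runtime.

`responseSurface()` reuses the same simulated pairs across measures so
that surfaces are comparable cell by cell.  At the strongest negative
coupling, Spearman and MIC respond clearly at moderate prevalence while
Pearson is pinned near its floor; Bray-Curtis saturates at 1 for
near-disjoint supports — which also happens under the null at low
prevalence, the source of its poor discrimination.  These are magnitude
statements: with 100-replicate medians, even the "insensitive" measures
show statistically detectable (though practically negligible) systematic
shifts at moderate prevalences.

## Masked inference and evaluation

`inferNetwork()` is a stability-path pipeline: centered log-ratio
transform (pseudocount 1 by default, configurable), then, over random
80% subsamples (50 by default) and a geometric penalty path (20 values
from the largest absolute off-diagonal correlation down to a tenth of
it), an L1-penalized precision estimate with an *element-wise* penalty
matrix.  Masked pairs get $10^3$ times the base penalty — finite for
solver stability, but far beyond the level at which an entry can stay
non-zero, and the masked entries of the estimate are exactly zero.  Each
pair's score is its selection frequency across fits, signed by its mean
partial correlation; stability selection was chosen because ROC/PR
evaluation needs a continuous confidence, and the published tools differ
in how they produce one.  The graphical-lasso solver (block coordinate
descent with warm starts along the path) is compiled code in the package;
convergence failures are flagged, not silently ignored.

Three filter modes mirror the benchmark design: `none`; `testability`
(abundance-mode mask at $\alpha$, the default, matching clr-based
abundance inference; occurrence modes are configurable); and
`prevalence`, which greedily removes lowest-prevalence OTUs (ties broken
by index) until at least as many pairs are removed as the testability
mask flags — the severity-matched conventional baseline.

`signedAuc()` evaluates positive and negative true edges separately over
unmasked pairs only, ranking by $+$score and $-$score respectively; AUC
uses the Mann-Whitney rank identity, AUPRC uses step-interpolated
precision (average precision) to avoid the optimistic bias of trapezoidal
interpolation.  Zero surviving true edges of a sign gives a flagged `NA`,
never a silent number.

## Benchmark problem sizes

The filtering benchmark's reference configuration is 300 samples, 300
OTUs, 1000 edges, power-law prevalence $k=-1.5$ truncated at $5/300$,
condition number 100.  Under the default abundance-mode mask at
$\alpha = 5\%$, about 70% of all pairs are problematic (not fully
testable).  The shipped acceptance script runs the inference comparison at
half scale — 150 OTUs with the edge count reduced proportionally to the
number of pairs, preserving edge density, $k$, $\alpha$ and the condition
number — with 5 simulations, 20 stability subsamples and a 15-value path;
the unit-test suite uses still smaller communities.  These sizes were
chosen so the full suite runs on a single CPU in minutes while leaving the
qualitative and most quantitative conclusions unchanged: testability
filtering lifts the sign-resolved AUC above 0.9 for both signs, clearly
above unfiltered inference for every simulation and sign.  One difference
from the published full-scale SPIEC-EASI runs is worth noting: at reduced
dimension our unfiltered *positive*-sign AUC (~0.85-0.9) sits above the
0.8 reported at full scale; the negative sign (~0.72) matches.  The
ordering between filtered and unfiltered inference — the load-bearing
claim — is scale-robust.

## What the simulator does and does not emulate

The generator reproduces zero inflation with controlled prevalence, heavy
overdispersion, a sparse signed dependence structure with a controlled
condition number, and power-law community composition.  It does *not*
model sequencing-depth effects: counts are not compositional by
construction (no fixed library size or multinomial resampling), and zeros
are purely structural plus NB sampling zeros, with no depth-dependent
detection component.  Tests passing on these simulations therefore
demonstrate correctness of the statistical machinery and the benefit of
testability filtering under the stated model — not robustness to
compositional artifacts, batch effects, or ambiguous zeros in real
sequencing data, where presence/absence itself shifts with depth.

## Numerical and degenerate-input conventions

Prevalences exactly 0 or 1 are rejected by the closed-form functions
(the bounds are undefined) but tolerated by `testabilityMask()` with a
warning, marking every pair involving the degenerate OTU non-testable.
Fisher-mode masks convert proportions to counts by `round(p * n)` and
treat conversions hitting 0 or $n$ as degenerate.  Boundary p-values equal
to $\alpha$ count as testable.  The power-law quantile and CDF switch to
the logarithmic closed form within $10^{-9}$ of $k = -1$.  Precision
entries below $10^{-7}$ in absolute value are treated as unselected by the
stability path.  Equal prevalences in `prevalenceFilter` are removed in
index order, making the baseline deterministic.
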