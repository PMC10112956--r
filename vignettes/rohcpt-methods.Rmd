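---
title: "Methods: penalized block segmentation and ROH island calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized block segmentation and ROH island calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Model

The data are n independent samples of a random vector X = (X₁, …, X_m); the
coordinates are aligned variables (SNP markers, in the ROH application). The
distribution is blockwise constant: there is a change-point set
C\* = {0 = c₀ < c₁ < … < c_k = m} such that the variables inside each block
(c_{j−1}+1):c_j are identically distributed with a block parameter θ_j, and
adjacent blocks have different parameters. Blocks are treated as independent
in the likelihood; this is a working assumption of the fitting criterion, not
a requirement for consistency of the change-point locations.

Two families are implemented behind one contract (sufficient-statistic prefix
sums plus a block negative log-likelihood):

* **Bernoulli** — block frequency p̂ = S/N with S the ones and N the observed
  entries in the block; nll = −[S log p̂ + (N−S) log(1−p̂)], with
  0·log 0 ≡ 0 so degenerate blocks (all zeros/ones) contribute 0.
* **Gaussian, unknown mean and variance** — μ̂ the block mean, σ̂² the MLE
  variance; nll = (N/2)(log 2πσ̂² + 1).

Missing entries are excluded through an observation mask; all likelihoods run
over observed entries only. The model is per-entry i.i.d. within a block, so
dropping unobserved entries leaves a valid likelihood; a block with no
observed entries contributes zero.

The estimator minimizes PL(C) = −l(C) + λ·J(n)·R(C) with additive
regularization R(C) = Σ_j ρ(c_{j−1}+1, c_j). With ρ ≡ 1 the penalty counts
blocks. The ROH regularization replaces the count by the physical block span
in megabases and assigns +∞ to blocks spanning at most T megabases, making T
a hard floor on island size rather than a soft preference.

## Solvers

`fit_dp()` computes the exact optimum by optimal partitioning:
F(0) = 0, F(i) = min_{0 ≤ c < i} F(c) + Q((c+1):i), where
Q(r:s) = nll(r:s) + λ·J(n)·ρ(r, s). Prefix sums of the per-column
sufficient statistics make each Q evaluation O(1), so a fit costs
O(nm + m²). The block cost table is never materialized. Infinite-cost blocks
(ρ = +∞) simply never enter a finite-cost path; if no finite-cost
segmentation exists (T at least the whole span), the solver raises an error
naming the conflict.

`fit_hierarchical()` is greedy binary segmentation: for the current interval
I = r:s it evaluates h_I(c) = PL(r:c) + PL((c+1):s) for c in I (with
h_I(s) = PL(I), using PL(∅) = 0), splits at the minimizer only when that
*strictly* improves PL(I), and recurses on both sides. Strict improvement is
the stopping rule: a non-improving split is never taken, which generalizes
the convention that selecting c = s leaves the set unchanged. Typical cost is
O(nm + m·k̂).

**Tie-breaking.** Both solvers take the leftmost minimizer, so outputs are
deterministic functions of the input. At λ = 0 refinement never increases the
likelihood, so many segmentations may tie at the optimum; code that compares
solvers at λ = 0 should compare PL values, not sets.

**Numerical choices.** The Gaussian variance MLE is clamped below at
`variance_floor` (default 1e-8, exposed everywhere a fit is requested);
without the clamp a constant block has −∞ nll and the optimizer would
isolate every constant column. The Bernoulli boundary cases use the entropy
convention above. Costs are computed in log space from block totals, never by
per-entry loops at query time. The R-side cost evaluator and the C++ solvers
use the same operation order, so a segmentation's PL evaluated in R equals
the solver's internal total bitwise — the test suite exploits this by
comparing the dynamic program against exhaustive enumeration *exactly* (for
m ≤ 12), while block costs themselves are validated against a per-entry
brute-force oracle at 1e-9.

## Penalty selection: First Repeated Value

`frv_select()` scans λ over the grid {γ, 2γ, …, bγ}, b = ⌊λmax/γ⌋, refitting
at each point, and tracks the proportion of change-points k_C/m, where k_C
counts the blocks of the fitted set. The reference value before the first fit
is 1: an unpenalized fit splits everywhere (k_C = m). The scan returns at the
first grid point whose proportion equals the previous one; if the grid is
exhausted without a repeat, γ is halved and the scan restarts (at most
`max_halvings` times, then an error carrying the full trace). The selection
interval for the true count grows with n while the intervals for
over-segmentation shrink, which is why the *first* repeat is the right
stopping rule and the procedure inherits the consistency of the underlying
estimator.

Defaults: λmax = 10 and γ = 1/log(n), a step that shrinks slowly with n
(when n ≤ 2, where log n is not a usable step, γ falls back to λmax/20);
both exposed. Two corners are flagged with warnings rather than hidden: a
selected proportion of 1 (a saturated model repeated the initial reference
value — the data carry no block structure at this resolution) and a return at
the very first grid point. Counts are compared as integers, which is exact
and equivalent to comparing the proportions.

The reported `k_hat` in results is the number of *internal* change-points
(k\* = 10 means 12 points including 0 and m); the FRV proportion uses the
block count k_C so that the λ = 0 reference is exactly 1.

**J(n).** The default is √n, with log n and a custom function available.
Consistency needs J(n) → ∞ and J(n)/n → 0; J(n) = n violates the second
condition (the penalty would then grow as fast as the likelihood signal), so
it is deliberately not a preset, though `sample_penalty = "custom"` accepts
any user function.

## What the generator emulates — and what it does not

`draw_scenario()` + `simulate_data()` reproduce a model-based study design:
m = 200 variables by default, k\* internal change-points drawn uniformly
without replacement from 1:(m−1), Bernoulli block frequencies Uniform(0, 1)
(drawn on the open interval, so degenerate p ∈ {0, 1} blocks cannot occur by
accident), Gaussian block means N(0, sd = 5) and variances Exp(1). "sd = 5"
is a reading choice (a dispersion parameter could also be read as a
variance); it is exposed as `mean_sd` so either convention is reproducible.
The scenario — change-points and parameters — is drawn once and shared by
every dataset and sample size, so consistency in n is studied against a fixed
truth; scenario and data seeds are separate arguments, so changing n or the
replication never changes the truth.

Entries are i.i.d. within blocks, rows are i.i.d. samples. Real codified SNP
matrices violate both: linkage disequilibrium correlates nearby markers,
individuals are related, and per-individual ROH calling introduces serial
dependence along the chromosome. The estimator does not require
between-marker independence for change-point consistency, but passing tests
on this generator demonstrates correctness of the *procedure* under its own
model, not calibrated performance on real genotype panels. Uniform parameter
draws also produce occasionally unidentifiable scenarios (adjacent
frequencies differing by less than sampling noise at a given n); the
scenario validator warns only on exact coincidence, since near-ties are a
property of the design, not an error.

Evaluation uses the Jaccard index |C₁∩C₂|/|C₁∪C₂| over the full point sets
(0 and m included, so the index is always positive and equals 1 only on exact
recovery) plus the raw change-point count.

## ROH island calling

`roh_segment()` segments each chromosome independently (change-points cannot
cross chromosome boundaries), wiring the physical-distance regularization
from a marker map (TSV: marker, chrom, pos; 1-based positions strictly
increasing within a chromosome). T defaults to 1% of each chromosome's mapped
span, in megabases (β = 10⁶).

`call_islands()` flags blocks whose fitted frequency reaches the empirical
quantile cutoff (default 95%) of the fitted frequencies. The cutoff is taken
over *per-marker* values — each marker inherits its block's p̂, weighting
blocks by length — for comparability with per-SNP frequency distributions
from individual-based pipelines; `weighted = FALSE` switches to one value per
block. Blocks at or above the cutoff are flagged and adjacent flagged blocks
are merged (a merged island reports the length-weighted mean frequency).
Output coordinates are 0-based half-open: an island over markers r:s spans
[B(r)−1, B(s)), the single-base right-edge convention.

`intersect_islands()` compares two island lists in base pairs; the headline
percentage is the interval Jaccard 100·|a∩b|/|a∪b|. A comparison against
another tool's islands could normalize by that tool's total length instead;
the union denominator is this package's convention, chosen because it is
symmetric.

## Test and study sizes

The shipped suite exercises: exact equivalence of the dynamic program with
exhaustive enumeration over all 2^(m−1) segmentations (m ≤ 12, n = 50, 100
datasets per family); dominance of the exact solver over the greedy one on
500 random instances; a consistency study on the m = 200, k\* = 10 Bernoulli
design with 100 replications at n ∈ {50, 200, 500} and FRV-selected λ for
both solvers; parameter recovery at 3 standard errors conditional on exact
recovery of C\* (well-separated block parameters, so the conditioning event
actually occurs); and 100 random marker maps checking that no fitted block
ever spans ≤ T megabases. These sizes were chosen as the smallest designs
that exercise each property convincingly; the whole suite runs in well under
a minute thanks to the C++ solvers.

## Limitations

* Families are Bernoulli and Gaussian; no Poisson/exponential/Markov
  families, no covariates, no within-block dependence modeling.
* Offline only; no confidence intervals on change-point locations.
* The dynamic program is the plain O(m²) recursion; no PELT-style pruning,
  so very large m (whole-genome marker counts on one chromosome) pays the
  quadratic cost with the exact solver — the greedy solver is the practical
  choice there.
* Per-individual ROH codification (the 0/1 matrix) is an upstream step,
  consumed but not produced here.
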