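---
title: "Stagewise optimization of cytokine schedules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stagewise optimization of cytokine schedules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In vitro T-cell differentiation from CD34+ hematopoietic progenitors runs
through developmentally distinct stages (proT, CD4 immature single
positive, early/late double positive, CD8 single positive) over roughly
six weeks, and the cytokine requirements of the culture change as the
cells mature. A single fixed cocktail is therefore suboptimal: a cytokine
that drives early expansion (e.g. IL-3 or TNF&alpha;) can inhibit
maturation later. `cytokinedoe` implements a stagewise
design-of-experiments campaign that (i) screens many candidate cytokines
cheaply, (ii) models the dose response of each cell population in each
7-day interval with a quadratic response surface, (iii) finds per-interval
optimal concentrations by maximizing a multi-objective desirability, and
(iv) collapses the six per-interval optima into a practical three-stage
protocol.

# Experimental designs

Two coded designs are generated from first principles:

* **Definitive screening design (DSD).** For m factors the design is the
  row stack [C; &minus;C; 0] of a conference matrix C (zero diagonal,
  &plusmn;1 off-diagonal, C&thinsp;C&#8242; = (m&minus;1)I), giving
  2m&thinsp;+&thinsp;1 runs in which every factor takes three levels, every
  non-center run has a mirror run, and main effects are orthogonal to each
  other and to two-factor interactions. Conference matrices of orders 6,
  8, 10, 12, 14 and 16 ship as static data and are verified at package
  load; intermediate factor counts drop trailing columns of the next
  larger order. A dropped column means a few runs lose their single zero
  entry — unavoidable in this construction, and harmless for the design's
  estimation properties.
* **Central composite design (CCD).** Two-level factorial core (full up to
  5 factors, a resolution-V or better half fraction for 6–8), 2k axial
  runs at &plusmn;&alpha;, and n&#8320; center runs (default 8). The
  default "orthogonal" axial distance
  &alpha; = [((&radic;N &minus; &radic;F)&sup2;F)/4]^(1/4) decouples the
  pure-quadratic coefficients from the linear ones; "rotatable"
  (&alpha; = F^(1/4)) and "face" (&alpha; = 1) are available. For the
  six-cytokine campaign with the half-fraction core and 8 center runs,
  N = 52 and &alpha; &asymp; 2.097.

Factor coding is affine on the natural ng/ml scale by default
(coded &minus;1/0/+1 at low/center/high), with log10 coding available for
log-spaced dose grids. The default six-cytokine ranges (SCF, Flt3L, IL-7,
CXCL12: 30–70 ng/ml; IL-3: 6–14; TNF&alpha;: 3–7) put the usual working
concentrations at the center and keep all axial points at non-negative
concentrations.

# Screening analysis

Counts are standardized per donor, interval and population as
z = (count &minus; mean&#8203;(control)) / sd(control), using the n&minus;1
sample standard deviation of at least two control replicates, so that
populations with very different abundances share a better-or-worse-than-
control scale. Donors are pooled as independent observations (no random
effect), matching how a small screen is normally read.

Model selection is forward stepwise with the Gaussian profile BIC
n&thinsp;ln(RSS/n) + k&thinsp;ln(n), k counting the intercept. Strong
effect heredity is enforced by *group entry*: a quadratic or interaction
candidate is scored as the BIC of the model augmented by the term plus its
missing parent main effects, and the whole group enters together. This is
the only forward rule that can reach an interaction whose parents carry no
marginal signal while still never producing a heredity-violating model.

**Limitation worth knowing.** At screening sizes (13 runs, ~12 candidate
terms) minimum-BIC forward selection has essentially no type-I control:
the best-of-candidates selection effect means some spurious term almost
always clears the BIC bar, and the profile BIC diverges as the model
approaches saturation. Power is excellent — effects of 3 noise SD or more
are recovered essentially always — but the selected set should be read as
"contains the actives plus possible hangers-on", which is the appropriate
reading of any small screen. The test suite asserts the power property and
the per-term expected BIC penalty, not a false-selection rate the
procedure cannot deliver.

# Response-surface models

For each population and 7-day interval, ordinary least squares fits
&radic;count on the full second-order expansion in coded units
(1 + k + k(k&minus;1)/2 + k coefficients; 28 for six factors). The square
root is the variance-stabilizing scale for count-like flow-cytometry
readouts. Replicate runs (donors, repeated centers) pool into one fit; no
lack-of-fit test is run by default. Counts of zero are allowed
(&radic;0 = 0), and no offset is added.

Predictions back-transform as count = max(&#375;, 0)&sup2;: a negative
sqrt-scale prediction means "no cells", and squaring it un-clipped would
invent them. No retransformation bias correction (such as adding
&sigma;&sup2;/4) is applied — the optimizer only needs a monotone, order-
preserving map, and the correction would add a nuisance parameter without
changing any argmax. Points outside the coded hull [&minus;&alpha;,
&alpha;] raise an error unless extrapolation is explicitly requested.

# Desirability and basin-hopping

Each maximized population contributes a Derringer–Suich larger-is-better
desirability d = ((&#375; &minus; L)/(T &minus; L))^s clipped to [0, 1],
with L = 0 cells and s = 1 by default. The target T defaults to `"auto"`:
the maximum count-scale prediction over a coarse pre-pass grid (9 points
per marginal axis through the center, plus the center). Because that
pre-pass only walks the axes, it underestimates the joint maximum of
surfaces with positive interactions or several active factors, so the
desirability can saturate at 1 in a neighborhood of the optimum. The
saturated region is the intersection of convex superlevel sets, so
averaging points inside it stays inside it — which is exactly the property
the stage search relies on — but when a unique interior argmax matters
(e.g. verifying optimizer accuracy against an analytic vertex), supply an
explicit T above the surface maximum. Overall desirability is the
weighted geometric mean, so any population at d = 0 vetoes a condition.

The global search is basin-hopping on &minus;D: a uniform perturbation of
at most `step_size` (default 0.5 coded units) per coordinate, a bounded
derivative-free Nelder–Mead local search with boundary clipping (relative
tolerance 1e-12; Brent in one dimension), and Metropolis acceptance at
`temperature` (default 1.0 on the D scale). The exported default is
`n_iter = 200`; the analysis scripts and tests use 20–50 iterations
because the fitted surfaces are smooth and concave, so every local search
finds the same basin — the top-k retained solutions then agree in D to
well below 1e-6, which is also the convergence diagnostic reported per
interval. All randomness flows from one root seed through a documented
splitting rule (per-interval seeds derived linearly modulo 2&sup3;&sup1;
&minus; 1), iterations consume the stream sequentially (so increasing
`n_iter` can only improve the best value under a fixed seed), and the
caller's RNG state is restored afterwards.

# Three-stage protocol search

Stage boundaries t&#8321; &lt; t&#8322; range over multiples of 7 in
[7, 35], giving 10 candidate partitions of the 42-day assay into
[0, t&#8321;), [t&#8321;, t&#8322;), [t&#8322;, 42]. Weekly intervals
belong to the stage containing their start day. Each stage's
concentration vector is the arithmetic mean of its member intervals'
optimal concentrations in natural ng/ml units — the units in which media
are actually formulated; coded-unit averaging is available behind a flag
for sensitivity analysis. Each interval's desirability is then
re-evaluated at its stage concentration with that interval's own
objectives (the resolved L/T from the optimization step, so the score is
comparable), and the partition with the highest mean desirability wins;
exact ties resolve to the lexicographically earliest pair. The search is
exhaustive, so the returned partition is the global optimum by
construction.

# The synthetic-data generator

`default_ground_truth()` builds one quadratic surface per population per
interval with three coefficient regimes: days 0–7 (SCF/IL-3/TNF&alpha;
active, IL-3&times;TNF&alpha; and SCF&times;TNF&alpha; synergies, IL-7
inert), days 7–21 (SCF/IL-7 driven, IL-3 flattened to zero), and days
21–42 (TNF&alpha; linear term negative, IL-3 inert). Flt3L is inert
throughout, CXCL12 modestly positive, every factor has a negative pure
quadratic so optima are interior, and within a regime population surfaces
are scaled copies sharing one optimum. Baseline (intercept) levels are
set high enough that the sqrt-scale signal is positive over the whole
design region, so noiseless simulation is exactly invertible by OLS.
Noise is Gaussian on the sqrt scale (default SD 0.5, roughly 5% of the
smallest baseline); optional per-donor additive offsets exercise the
pooling paths.

The regime breaks at exactly days 7 and 21 are a deliberate fixture
property: they give the partition search a known correct answer, (7, 21),
and the 20-seed recovery panel in the acceptance tests measures exactly
that. What the generator does **not** emulate: overdispersed counts
(a negative-binomial observation model would break the constant-variance
assumption the sqrt transform targets), donor-by-condition interactions,
temporal coupling between intervals (real populations inherit cells from
the previous week; the published models, like these, are fitted
independently per interval), and any plate/edge effects. Passing tests
therefore demonstrate that the pipeline recovers what its own model class
generates — a necessary correctness property, not evidence about any
particular culture system.

# Numerical choices and edge cases

* Exact ties in the partition search resolve lexicographically;
  `which.max` guarantees determinism.
* ED50 interpolation normalizes to the dose-0 response, uses the first
  50% crossing of a (possibly non-monotone) curve and flags
  non-monotonicity; curves never reaching 50% are censored at the top
  dose. Choosing a 4-parameter logistic fit instead was rejected: linear
  interpolation is the stated method and is exact for the piecewise-
  linear oracle used in testing.
* Cumulative fold expansion multiplies weekly per-cell expansions
  (counted/seeded), so it is invariant to the fraction carried forward at
  each passage.
* The normality-gated comparison (Shapiro–Wilk p &lt; 0.05 in any group
  &rarr; Kruskal–Wallis + Dunn + Benjamini–Hochberg, else one-way ANOVA +
  Tukey) skips with a warning when a group has zero variance, where the
  normality test is undefined. Dunn's z statistics are computed directly
  (standard rank-mean form with tie correction).
* OLS goes through the QR decomposition with explicit rank checks;
  rank-deficient expansions raise an error naming the aliased terms
  rather than silently dropping columns.
* R&sup2; of a constant response is defined as 0.

# Problem sizes

The shipped analysis uses the 52-run CCD (half-fraction core, 8 center
runs), 22 population-interval models, 20–50 basin-hopping iterations per
interval and a 20-seed recovery panel — sizes at which the full campaign
runs in well under a minute while leaving every statistical property
measurable. All of them scale up through function arguments.

# Known limitations

* Stepwise screening at 13 runs has no meaningful type-I control (see
  above); treat selections as candidate sets.
* The auto-resolved desirability target is marginal, not joint, so D can
  plateau at 1 near the optimum; supply explicit targets when a unique
  argmax is required.
* Desirability scalarization cannot expose trade-offs between
  populations; there is no Pareto view.
* The staging search is restricted to weekly boundaries and exactly three
  stages.
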