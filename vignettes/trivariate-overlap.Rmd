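---
title: "Quantifying three-way polygenic overlap: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying three-way polygenic overlap: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trimix)
```

## The model

`trimix` models the direct (not LD-induced) allelic effects of each
genome-wide variant on three phenotypes as a mixture of eight Gaussian
components.  A variant belongs to the null component (probability
$\pi_0$), to one of three trait-specific components ($\pi_1,\pi_2,\pi_3$),
to one of three pair-specific components ($\pi_{12},\pi_{13},\pi_{23}$),
or influences all three phenotypes ($\pi_{123}$).  Within a component the
active effects are zero-mean Gaussian: each trait has a single
discoverability scale $\sigma_i$ shared across all its causal variants,
and shared components carry effect correlations $\rho_{ij}$.  The
observed z-score of tag variant $j$ aggregates its LD neighborhood:

$$z_{ij} = \sum_k \sqrt{h_k}\, r_{jk} \sqrt{N_i}\, \beta_{ik} +
  \epsilon_{ij},\qquad \epsilon_j \sim N(0, \Sigma_0),$$

where $h_k = 2f_k(1-f_k)$ is heterozygosity, $r_{jk}$ the genotype
correlation, $N_i$ the GWAS sample size and $\Sigma_0$ the residual
covariance ($\sigma_{0i}$ capture inflation, $\rho_{0ij}$ capture sample
overlap between cohorts).  Because every component is zero-mean, the
likelihood depends on LD only through $w_k = h_k r_{jk}^2$, so the LD
reference is stored as unsigned r² neighbor lists.

Key assumptions inherited with this model family: causal variants are
uniformly distributed along the genome; effect size is independent of
allele frequency and local LD; all causal variants of a trait share one
effect-size scale; residuals are Gaussian with per-variant marginals.
Phenotypes combining a few very strong loci with a weak polygenic
background violate the single-scale assumption and are poor targets.

## Likelihood by characteristic-function inversion

Each tag variant's density is a finite mixture with $8^M$ terms ($M$ =
neighborhood size), which is intractable directly but has a closed-form
characteristic function: a product over neighbors of convex combinations
of Gaussian CFs.  `pdf_cf()` recovers the density by a trapezoidal sum
over a symmetric grid, using evenness to halve the grid and, in two and
three dimensions, skipping the corner regions where the residual Gaussian
envelope is negligible.  `pdf_exact()` enumerates the mixture exactly for
small neighborhoods and is the oracle the inversion is validated against
(agreement to 1e-6 absolute over random models in the test suite, plus a
10⁶-sample Monte-Carlo check of the enumeration itself).

Two step-size rules govern accuracy:

* **Envelope**: the integrand decays like
  $\exp(-\sigma_0^2 t^2/2)$, so the grid half-width is
  $T = \mathrm{tail}/\sigma_0$ with `tail = 6` (`5` for trivariate
  grids), leaving tail mass below $10^{-7}$ of the density scale.
* **Aliasing**: a trapezoidal sum with step $\delta t$ computes the
  periodization of the density with period $L = 2\pi/\delta t$.  The
  nearest image must be negligible not merely beyond the observed z
  range but beyond it by a multiple of the *widest mixture component's*
  SD $s_w = \max_S \sqrt{\sigma_{0i}^2 + N_i w_{\max} \Sigma_S[i,i]}$.
  The package uses $\delta t = \pi/(z_{\max} + m)$ with
  $m = (\sqrt{z_{\max}^2 + 2\log(1/\varepsilon) s_w^2} - z_{\max})/2$
  and $\varepsilon = 0.02$.  Ignoring the $s_w$ term looks harmless but
  systematically inflates the density of moderate-|z| variants under
  wide-component parameter values, which in turn biases fits toward
  small-$\pi$/large-$\sigma$ solutions; this failure mode is why the
  margin is parameter-adaptive.

For dataset likelihoods (`loglik()`), variants are stratified by their
largest absolute z (boundaries 4, 8, 16, 32) and each stratum integrated
on a grid satisfying its own aliasing bound, so the near-null bulk uses
small grids and rare strong signals get a fine step.  The batched kernel
additionally bins neighborhood weights onto 128 shared geometric bins
(≤ ±2.5% weight error) and runs single-precision inner loops with
double accumulators; the per-variant reference path keeps exact weights
in double precision and the suite checks the two agree.  Densities are
floored at 1e-300 before logs; at extreme z under badly mismatched
parameters the true density can fall below the quadrature's absolute
resolution (~1e-9), in which case both paths return effectively "very
unlikely", which is all the optimizer needs.  Parameters implying a
component SD beyond ~0.9 of the data's z range are rejected by a barrier:
such components cannot be resolved by any admissible grid and are outside
the data's support.

## Stepwise estimation

1. **Univariate** (per trait): maximize over
   $(\log_{10}\pi^u, \log\sigma^2, \log\sigma_0)$ by Nelder–Mead from
   three log-spaced polygenicity starts ($10^{-4}, 10^{-3}, 10^{-2}$),
   with $\sigma^2$ moment-matched to the mean z² excess at each start.
2. **Bivariate** (per pair, univariate parameters frozen): maximize over
   $(\pi^b, \rho, \rho_0)$ with $\pi^b$ logistic-transformed into
   $[0, \min(\pi_i^u, \pi_j^u)]$ and correlations atanh-transformed;
   started from moment estimates ($\rho_0$ from the z correlation among
   near-null variants), with a second start only if the first collapses
   onto a box boundary.
3. **Trivariate**: the single scalar $\pi_{123}$ within its feasibility
   interval, by grid pre-scan plus local refinement.  The three pairwise
   effect (and residual) correlations were estimated separately; if they
   are jointly infeasible as a 3×3 correlation matrix they are shrunk
   toward zero just enough to restore positive definiteness before the
   trivariate likelihood is evaluated.

Two parsimony tie-breaks resolve directions in which the likelihood can
be flat.  On signal-free data the univariate surface is a ridge trading
$\pi\sigma^2$ against $\sigma_0$, so after optimization an explicit null
model ($\pi$ at the floor, $\sigma_0$ refit) is adopted unless the
mixture beats it by more than two log-likelihood units (a two-parameter
margin); likewise the bivariate stage prefers the no-overlap model
unless the fitted overlap earns its two extra parameters.  Genuine
signal at the study scales below clears these margins by orders of
magnitude; the tie-breaks only pin down what would otherwise be
start-point-dependent output on null data.

When a run's univariate and bivariate estimates are jointly infeasible
(the $\pi_{123}$ interval is empty), the run is flagged non-converged,
$\pi_{123}$ is set to the pairwise ceiling and the reported pattern is
clipped to non-negative components (its margins are then inexact, and
the object carries a `clipped` marker).

Each run operates on a seeded random subset of variants: filters (MAF ≥
0.05 against panel frequencies, INFO ≥ 0.8 where available, |z| ≤ 32,
MHC excluded), then random pruning at r² ≥ 0.8, then uniform subsetting;
one seed drives both random stages.  Runs with different seeds are
aggregated by per-parameter medians — the median pattern need not be
feasible, so the package reports both a feasibility-clipped
median-margin pattern and the representative run minimizing the
union-normalized distance from the median.  Uniform per-variant weights
are used throughout; non-convergent stages flag the run rather than
aborting an ensemble.

## Decomposition and the maximum-entropy baseline

The identities $\pi_{ij} = \pi^b_{ij} - \pi_{123}$ and
$\pi_i = \pi^u_i - \pi_{ij} - \pi_{ik} - \pi_{123}$ convert the stage
estimates into the seven disjoint components; feasibility of
$\pi_{123}$ is exactly the interval
$[\max(0, \pi^b_{ij}+\pi^b_{ik}-\pi^u_i, \ldots),\ \min_b \pi^b]$.
Tiny negative components (|x| < 1e-10) are clipped; larger violations
raise errors.

The naive baseline asks: given only the univariate and bivariate
estimates, what $\pi_{123}$ would one expect?  `naive_max_entropy()`
selects the value whose seven-component pattern, **as a relative
distribution**, has maximal Shannon entropy.  The normalization is a
deliberate design decision: the seven components' total varies with
$\pi_{123}$ (it equals $\sum\pi^u - \sum\pi^b + \pi_{123}$), and the
entropy of the raw proportions grows with total mass, so a raw-entropy
argmax systematically rewards larger triple overlap — under it, a
perfectly balanced pattern (all seven components equal) would *not* be
its own expectation, which defeats the baseline's purpose of serving as
the uninformative reference that fitted patterns are compared against.
On the relative scale the balanced pattern is exactly the argmax.
`overlap_entropy()` itself computes the plain
$\sum -p\log p$ (natural log, $0\log 0 = 0$) so both conventions are
available.  Because the baseline reuses the fitted margins, fitted and
naive patterns always share their univariate and bivariate totals;
they differ only in how overlap is apportioned between pair-specific
and triple regions.

## The simulator and what passing tests mean

`simulate_scenario()` generates data from the model itself: a block LD
panel (block sizes uniform on 1–10; within-block genotype correlation
AR(1) with per-block squared decay Beta-distributed around 0.6, which
guarantees positive-definiteness; frequencies uniform on [0.05, 0.5];
pairs below r² = 0.01 absent, as in a PLINK-derived panel), causal
assignment with per-trait totals hitting `round(pi_u * n)` exactly,
standard-normal effects correlated within shared components, exact
scaling to the target heritability ($\sum_k h_k\beta_{ik}^2 = h^2$), and
z-scores assembled from the signed within-block correlations plus
residuals.  Residuals are drawn independently per variant by default —
the per-variant marginal is what the composite likelihood models — with
an optional AR(1) `ld_noise` mode for robustness experiments.

Because the generator implements the estimator's own data-generating
process (plus real-data features the model also faces: LD-shared causal
effects across neighboring tags, exact-count rather than Bernoulli
assignment), recovery tests validate the numerics, the likelihood and
the stepwise procedure.  They do not validate the model assumptions
against real GWAS data: frequency-dependent architectures, stratified
residuals correlated along the genome, or a handful of outlier loci are
outside what passing tests demonstrate.

The canonical scenarios are simulated at per-trait polygenicity 0.002
and heritability 0.4 with three geometries: `core` (only triple
overlap), `ring` (only pairwise overlaps), `equilibrium` (all seven
components equal).

## Study scale of the bundled scenario analyses

The scenario studies in the test suite and in `scripts/acceptance.R`
run on 10⁵-variant panels with 2×10⁴ optimization variants per run and
three independent simulation seeds per scenario.  The GWAS sample size
is set to N = 20,000 per trait: with 200 causal variants per trait each
carries z² non-centrality ≈ N·h²/n\_causal = 40 at its own position
(roughly 16 after typical heterozygosity and LD weighting), so the
~100-fold reduction in causal-variant count relative to a biobank-scale
panel is offset by proportionally stronger per-variant signal.  Below roughly this sample size the univariate and bivariate
margins acquire a systematic small-sample distortion (polygenicity
under-, discoverability over-estimated along their shared ridge) that
propagates into the pattern; at N = 20,000 the margins are
approximately unbiased and the three scenario geometries are cleanly
separated.  At this scale one full run (three univariate, three
bivariate and one trivariate fit on 2×10⁴ variants) takes about two
minutes on one core.

## Known limitations

* Three phenotypes only; the mixture and the 3-D inversion are
  hard-wired, and cost grows geometrically with dimension.
* Per-trait sample sizes enter the batched likelihood as medians;
  strongly variant-dependent N (meta-analyses with very uneven
  coverage) is only approximated (the per-variant reference path is
  exact but slow).
* No standard errors: run-to-run spread across seeds is the intended
  stability diagnostic.
* The median pattern across runs can be infeasible; the package reports
  it alongside feasible aggregates rather than hiding the fact.
* Euler diagrams are best-effort circle layouts; exact three-set
  area-proportional diagrams do not always exist, and the numerical
  pattern JSON is the source of truth.
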