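---
title: "Rare-variant association tests under extreme phenotype sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant association tests under extreme phenotype sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rveps)
library(dplyr)
```

## The problem

Rare variants (minor allele frequency, MAF, below 3%) are hard to test
individually: almost nobody in a cohort carries any given one. Region-based
tests therefore aggregate the `p` variants of a gene or region. Two
aggregation philosophies dominate. *Burden* tests collapse the region into a
single per-individual count $C_i = \sum_j G_{ij}$ (with $G_{ij}$ the
minor-allele count of individual $i$ at site $j$) and test its effect; they
are powerful when all causal variants push the trait the same way, and can
fail badly when risk and protective variants mix. *Variance-component*
tests treat per-variant effects as random with mean zero, testing whether
their variance is zero; they tolerate mixed directions but waste the shared
component of the signal.

`rveps` implements a joint model that keeps both pieces. For a quantitative
trait,

$$Y_i = \theta_0 + \theta_1 C_i + \beta_1 G_{i1} + \cdots + \beta_p G_{ip}
  + \varepsilon_i, \qquad
  E(\beta_j) = 0,\; \mathrm{cov}(\beta) = \sigma_\beta^2 I_p ,$$

where $\theta_1$ is the fixed common effect of the burden and the random
$\beta_j$ are individual deviations from it. No association means
$H_0\!: \theta_1 = 0,\ \sigma_\beta^2 = 0$, and the score statistic of
$H_0$ has two components,

$$S_1 = \frac{1}{\hat\sigma^2} \sum_i C_i (Y_i - \bar Y), \qquad
  S_2 = \tfrac12 U'U - \frac{1}{2\hat\sigma^2}\,\mathrm{tr}(G'G), \qquad
  U_k = \frac{1}{\hat\sigma^2} \sum_i G_{ik} (Y_i - \bar Y),$$

with $\hat\sigma^2$ the sample variance of $Y$. The two component p-values
($p_1$ two-sided for $S_1$, $p_2$ upper-tailed for $S_2$) are combined
either by Fisher's statistic $-2\log p_1 - 2\log p_2$ or by
$\min\{p_1, p_2\}$, both calibrated by permutation.

The second ingredient is the *study design*. Instead of randomly sampling
`n` individuals (RS), one can sequence only the phenotypic extremes (ES):
the top `n/2` of a screened population become cases, the bottom `n/2`
controls, and the logistic analogue of the model applies, with

$$S_1 = \sum_i (Y_i - \bar Y) C_i, \qquad
  S_2 = \tfrac12 U'U - \tfrac12 \bar Y (1 - \bar Y)\,\mathrm{tr}(G'G),$$

$\bar Y$ now the case fraction. Extreme sampling enriches rare alleles in
the sample, which is where its power advantage comes from. The seven tests
the package reports are `RS_burden`, `RS_Fisher`, `RS_min-p`, `JOINT`
(the sum of permutation-standardized $|S_1|$ and $S_2$), and their
extreme-sampling counterparts `ES_burden`, `ES_Fisher`, `ES_min-p`.

### A note on the burden statistic

The burden score statistic is implemented as the square of the whole
centered cross-product, $[\sum_i C_i (Y_i - \bar Y)]^2 / \hat\sigma^2$
(linear; without the variance divisor in the logistic case). The square has
to sit outside the sum: $S_1$ of the joint model is exactly the unsquared
version of the same quantity, and a per-term square would destroy the
score-test's sensitivity to effect direction. Under permutation the choice
of variance denominator ($n-1$ here) is a constant scale factor and cannot
change any p-value; a test asserts this.

## Permutation calibration

All p-values come from permuting the phenotype vector while the genotypes
stay fixed. One pool of `B` reorderings (default `B = 500`) is drawn per
design and shared by every test, so an analysis is reproducible end to end
from (data, seed, B). Component p-values use the add-one estimator
$(\#\{\text{exceedances}\} + 1)/(B + 1)$ with ties counted as exceedances —
conservative, never zero, and valid by construction.

Combining p-values inside a permutation framework raises the usual
chicken-and-egg problem: each permuted statistic also needs component
p-values. A nested permutation would cost $O(B^2)$ statistic evaluations;
instead the engine ranks each permutation's $(|S_1|, S_2)$ within the single
shared pool (ties counted), the standard single-pass shortcut. The observed
statistic uses the add-one component p-values, which are never smaller than
the pool ranks — a slightly conservative asymmetry. The `JOINT` comparator
standardizes $|S_1|$ and $S_2$ by their permutation means and standard
deviations; permutation moments are the natural null moments available
here.

Two numerical choices matter:

* **Tie quantization.** Two phenotype orderings that are mathematically
  tied produce sums of the same multiset of products in different orders,
  which differ by floating-point ulps and would break ties arbitrarily.
  Statistics are therefore snapped to a grid of about $10^{-9}$ of an
  a-priori bound on the statistic (never derived from the realized values,
  so it is permutation-invariant) before ranking. Degenerate inputs — a
  region whose columns are all equal, a constant burden — then give exactly
  tied pools and p-values of 1, and the engine agrees *exactly* with
  brute-force enumeration on small problems.
* **Exhaustive mode.** For `n` with $n! \le 5040$ the engine can enumerate
  all orderings instead of sampling; the test suite uses this to compare
  against an independently coded brute-force oracle, exactly, for all seven
  tests.

## The simulation framework

The generator emulates a sequenced gene region the way the simulation
studies in this literature do: a pool of `H = 1394` phased binary
haplotypes over `p = 40` sites stands in for a real gene's haplotypes
(ADAMTS4-like in size), genotypes are formed by drawing two haplotypes
uniformly with replacement (random union of gametes, hence Hardy–Weinberg
proportions at the pool MAF), and traits follow

* null model: $Y_i = \beta_0 + \varepsilon_i$,
* alternative: $Y_i = \beta_0 + \sum_j \beta_j G_{ij} + \varepsilon_i$,

with $\beta_0 = 0.1$, standard normal noise, and causal effects
$|\beta_j| = -0.2 \log_{10}(\mathrm{MAF}_j)$ (0.4 at MAF 1%, 0.6 at 0.1%),
using the pool MAF — effects are properties of the generating model, not of
a sample. A `pct_causal` fraction of the rare sites (MAF < 0.03) is causal,
a `pct_positive` fraction of those positive, both rounded half-up to
integers, sampled uniformly.

Because the real haplotypes behind the published study are not
redistributable, the default pool is synthetic: per-site target MAFs drawn
from a Beta(0.2, 4) truncated to $[1/H, 0.3]$ — rare-dominated with a
common minority — and alleles sampled independently per haplotype, redrawing
fixed sites. Two honest caveats follow. The synthetic pool has *no linkage
disequilibrium* (sites are independent), and its exact MAF spectrum is a
modelling choice; null calibration does not depend on either (permutation
validity is distribution-free), but absolute power numbers do, so power
results should be read as orderings and trends, not as portable absolute
rates. Users with real phased haplotypes can supply them via
`load_haplotype_pool()` and inherit their LD.

The two designs draw from one simulated population whose size is tied to
the extreme design's per-tail fraction: each tail must hold `n/2`
individuals equal to `tail` of the population, so
$N = n / (2 \cdot \mathrm{tail})$ — 10% tails with `n = 2000` mean
`N = 10000`. "10%" is read as 10% *per tail*; this matches the observation
that larger tail fractions approach random sampling (at `tail = 0.5` the
extreme design is a median split of the whole pool). The population (and
the causal set) is regenerated every replication; the haplotype pool is
fixed per experiment. Ties at the phenotype cut are broken by population
index — deterministic, and measure-zero for continuous traits anyway.

## Experiments

`run_type1_experiment()` and `run_power_experiment()` drive the Monte-Carlo
studies: per replication, simulate the population, draw the requested
designs, rare-filter the *drawn sample* (orientation to the minor allele,
monomorphic columns dropped, then strict MAF < 0.03 — the threshold itself
is excluded), and run all tests from a shared pool per design. Rejection
rates use the strict rule `p < alpha`, and every estimate ships with its
binomial Monte-Carlo standard error; comparisons in the test suite use
3-SE intervals. Replication seeds are drawn up front from the root seed, so
any experiment is bit-for-bit reproducible from its configuration. In the
rare event that a drawn sample has no rare polymorphic variant at all, that
replication records p = 1 for the affected design (no evidence) rather than
failing.

Default grids mirror the usual study layout: `n` in {500, 1000, 2000},
tails in {0.1, 0.2}, causal fractions {0.4, 0.6, 0.8}, positive fractions
{0.5, 0.8, 1.0}, `B = 500` permutations, 1000 replications for type-I
error and 500 for power at $\alpha = 0.05$.

### Problem sizes used by the shipped checks

The package's own test suite exercises the calibration claim on the
(n ∈ {500, 1000}) × (tails ∈ {0.1, 0.2}) cells at 400 replications with
`B = 200`, and the power-ordering claims at `n = 1000`, 10% tails, 60%
causal, 200 replications with `B = 300` — sizes chosen so the whole suite
runs comfortably on a laptop while leaving every assertion's 3-SE margin
meaningful. `scripts/acceptance.R` recomputes selected grid cells at the
full scale (1000 replications, `B = 500`). With the synthetic pool and one
BLAS thread the full-scale `n = 2000` extreme cell takes a few minutes.

## A small worked example

```{r example}
pool <- synthesize_haplotype_pool(seed = 7)
G <- generate_genotypes(pool, N = 5000, seed = 8)
eff <- assign_effects(pool, pct_causal = 0.6, pct_positive = 0.5, seed = 9)
y <- simulate_alt_phenotypes(G, eff, seed = 10)
pop <- rv_population(G, y)

es <- extreme_sample(pop, n = 500)
rv_test(es$genotypes, es$phenotype, B = 500, seed = 11,
        maf_threshold = 0.03)
```

The `ES_Fisher` and `ES_min-p` rows are the headline tests; `p1` and `p2`
are the common-effect and variance-component component p-values they
combine.

## Limitations

* Quantitative traits only; no covariate adjustment (age, sex, principal
  components) — the score statistics here are the unadjusted forms.
* No asymptotic p-values: everything is permutation-based, so detection is
  floored at $1/(B+1)$ and genome-wide significance levels need large `B`.
* The synthetic haplotype pool carries no LD and one parametric MAF
  spectrum; see the caveats above.
* Extreme sampling is supported as the symmetric two-tail design only.
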