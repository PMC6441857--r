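---
title: "Methods: population size estimation for hidden key populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population size estimation for hidden key populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keypopsize)
```

## The problem

Populations such as female sex workers are hidden: stigma and illegality
make a census impossible, so their size must be inferred from partial
"captures" — an object distribution, a service register, a survey. This
package implements the estimator stack used in practice for such exercises:

* **multiplier methods** — scale a known count from one source by the
  proportion of a representative survey reporting that source;
* **two-source capture-recapture** — Lincoln-Petersen and Chapman
  estimators on a pair of lists;
* **multiple systems estimation for three or more lists** — a Bayesian
  nonparametric latent-class capture-recapture (NPLCM) model;
* **RDS-II weighting** — inverse-degree weights for proportions estimated
  from respondent-driven-sampling (RDS) surveys;

together with a synthetic-data generator that simulates the whole study —
hidden population, latent-class capture heterogeneity, object
distributions, a referral-network RDS survey — so that every estimator can
be validated against a known true size.

## Multiplier method

With `M` individuals counted by a source (e.g. objects distributed, or a
service register with unique client codes) and a survey in which a fraction
`p` report membership in that source,

$$\hat N = M / \hat p.$$

`multiplier_estimate()` propagates the uncertainty of `p`. The default
interval is a delta-method interval on `log(N)` — the sampling distribution
of `M/p` is right-skewed and a symmetric (Wald) interval can cross zero at
small `p`; both the Wald and a chain-bootstrap percentile interval are
available and every result records which was used. `p = 0` is an error (no
overlap means the estimate is undefined), and `M = 0` returns a degenerate
zero estimate with a warning. An optional `contamination` factor in (0, 1]
discounts `M` when a service register is suspected of counting non-members;
it defaults to 1 because any other value is an analyst judgement.

## RDS-II weighted proportions

RDS recruits through network referral, so well-connected individuals are
over-represented roughly in proportion to their degree. The RDS-II
estimator reweights by inverse reported degree:

$$\hat p = \frac{\sum_i x_i / d_i}{\sum_i 1 / d_i}.$$

Variance uses the Hajek ratio-estimator linearisation, which collapses to
`p(1-p)/n` when all degrees are equal — and the estimator itself collapses
to the raw proportion, a property the tests assert exactly. Degrees of zero
are an error rather than silently imputed; `impute_degrees()` exists for
the analyst who explicitly wants median imputation. The weighting scheme is
always recorded in the output because "weighted survey estimate" without a
named scheme is not reproducible.

`bootstrap_proportion_ci()` resamples whole recruitment chains (a seed plus
its descendants) with replacement: referral induces within-chain
dependence, and the chain is the natural exchangeable unit. A sample with
no recruiter structure falls back to an individual bootstrap with a
warning.

## Two-source capture-recapture

For lists of sizes `n1`, `n2` with overlap `m`:

* Lincoln-Petersen: $\hat N = n_1 n_2 / m$, with
  $\mathrm{var}(\hat N) = n_1 n_2 (n_1-m)(n_2-m)/m^3$;
* Chapman: $\hat N = (n_1+1)(n_2+1)/(m+1) - 1$, defined even at `m = 0`
  and less biased at small overlap, with
  $\mathrm{var} = (n_1+1)(n_2+1)(n_1-m)(n_2-m)/((m+1)^2(m+2))$.

Chapman never exceeds Lincoln-Petersen, both equal `n1` at complete
overlap, and neither interval is allowed below the number of distinct
individuals actually observed (`n1 + n2 - m`). Both are always computable
side by side because field write-ups rarely say which variant produced a
printed number. Pair counts built from an RDS survey
(`pair_counts_from_rds()`) use unweighted counts: the capture-recapture
formulas operate on list sizes, while degree weighting is reserved for
multiplier proportions. A weighted pairing would mix two different
inferential frames and is deliberately not the default.

## The latent-class model for three or more lists

Two-source estimators require independent lists with homogeneous capture
probability — exactly what fails in field conditions (members visible to
one outreach round are more visible to the next). With `J >= 3` lists the
`2^J - 1` observable capture-profile counts carry enough information to
model heterogeneity. The NPLCM treats each individual's profile
$x \in \{0,1\}^J$ as product-Bernoulli given a latent class $k$:

$$P(x \mid z = k) = \prod_j \lambda_{kj}^{x_j} (1-\lambda_{kj})^{1-x_j},$$

with class weights $\pi$ from a truncated stick-breaking
(Dirichlet-process) prior $\pi_k = V_k \prod_{l<k}(1-V_l)$,
$V_k \sim \mathrm{Beta}(1, \alpha)$, concentration
$\alpha \sim \mathrm{Gamma}(a, b)$, and
$\lambda_{kj} \sim \mathrm{Beta}(1, 1)$. The population size prior is the
scale-invariant $1/N$, realised through its negative-binomial full
conditional: given `n` observed individuals and zero-history probability
$p_0 = \sum_k \pi_k \prod_j (1-\lambda_{kj})$, the never-captured count is

$$n_0 \mid \cdot \sim \mathrm{NegBinom}(n,\ 1 - p_0), \qquad N = n + n_0.$$

`fit_nplcm()` runs a Gibbs sampler whose state is aggregated by capture
profile (there are only `2^J - 1` distinct likelihood terms, so class
allocation is a handful of multinomial draws per sweep, and long chains are
cheap): allocate observed individuals to classes; draw `n0` and allocate
the zero-history individuals; update each $\lambda_{kj}$ from its Beta full
conditional; update the stick fractions
$V_k \sim \mathrm{Beta}(1 + n_k, \alpha + n_{>k})$ and $\alpha$ from its
Gamma conditional.

### Defaults and numerical choices

* Truncation `K* = min(2^J - 1, 10)`: with `J = 3` there are only 7
  observable cells, so more mixture components than cells cannot be
  resolved. `K* = 1` is allowed and collapses the model to homogeneous M0 —
  the test suite exploits this to cross-check the sampler against a
  brute-force M0 profile likelihood.
* `iterations = 100000, burn_in = 10000, thinning = 10`,
  $\alpha$-prior Gamma(0.25, 0.25): conventional settings for this model
  family, all recorded in the output metadata since published applications
  rarely state theirs. Validation fits in the test suite use 10000-20000
  iterations, which the oracle-equivalence test shows is sufficient at the
  few-hundred-to-few-thousand scale it runs at.
* Point estimate = posterior **median** with a central 95% credible
  interval (quantile type 7); the mean is also recorded. Right-skew is
  expected and preserved.
* Stick fractions are clamped below 1 by `1e-12` before the
  $\log(1 - V)$ term of the $\alpha$ update; class-allocation weights are
  max-normalised before exponentiation to avoid underflow.
* Degenerate inputs: a table with a single non-zero profile, or only two
  sources, produce warnings (weak identification), not silent results.

### What the posterior can and cannot learn at J = 3

With three lists the latent-class model is at the edge of
identifiability: 7 cell counts must support mixture weights, up to 7
classes' capture probabilities, and `N`. When heterogeneity is strong —
e.g. a large class of nearly-invisible individuals — the data cannot
distinguish "moderate undercount" from "large hidden class", the
likelihood in `N` is nearly flat on one side, and the `1/N` prior then
dominates, typically placing the posterior below a truly large `N`. The
package's coverage experiment (in the acceptance test suite: twenty
seeded replicates of the default two-class world, 95% credible intervals)
documents exactly this behaviour: nominal coverage is *not* attained under
strong two-class heterogeneity at the default study scale. This is a
property of three-list multiple systems estimation itself, not of the
sampler — the same experiment's oracle checks pass, and adding a fourth
list is the structural remedy. Practitioners should read the NPLCM
interval at `J = 3` as a model-based plausibility range, not a calibrated
frequentist interval.

## The synthetic world

`synthetic_config()` fixes the study conditions; `simulate_population()`
and `simulate_rds()` realise them. Defaults describe a border-town-scale
exercise: `N = 2700`; two equally weighted latent classes with per-source
capture probabilities (0.32, 0.31, 0.23) and (0.10, 0.09, 0.07) — chosen
by solving the expected-margin equations so the three sources capture
roughly 565, 540 and 405 individuals, with a visible and a nearly-hidden
stratum; 8% service coverage; degrees `1 + NegBinom(mean 9, dispersion 2)`;
7 seeds, 3 coupons, target 408 interviews. The referral network is a
configuration-model graph on the drawn degree sequence with self-loops and
multi-edges dropped — the simplest mechanism honouring a degree
specification. Recruitment proceeds wave by wave, uniformly at random among
unrecruited neighbours, without replacement, until the target or
exhaustion; dead chains are replaced by fresh seeds only if configured,
since field studies typically fix their seed count.

Two violation knobs reproduce the classical assumption failures:
`dependence` adds a log-odds tilt to second-source capture given
first-source capture ("captured once, easier to capture again"), whose
positive setting demonstrably biases two-source estimates downward;
`turnover` opens the population (leavers after round 1, arrivals exposed
only to later rounds). With both at zero the generated world satisfies the
closed-population, homogeneity (given class), and independence (given
class) conditions by construction.

What the generator does **not** emulate: recall error in survey answers
(recapture indicators are exact), degree misreporting, seed selection bias
(seeds are uniform draws, while real seeds are convenience choices),
geographic clustering of captures, and service registers contaminated by
non-members. Passing recovery tests on this world therefore show estimator
correctness under the stated assumptions, not robustness to every field
imperfection.

## Reporting conventions

Percentages follow field reporting style: `tally_rate()` and
`proportion_of_population()` round to a configurable number of decimals
(default 2). Estimates exceeding 100% of the reference female population
are reported as computed but flagged — they signal assumption violations,
and hiding them would misrepresent the method. `build_report()` orders
rows deterministically (multipliers, two-source pairs, latent-class) and
never selects a "final" estimate automatically: published exercises choose
their final number by judgement, so the package only lets the analyst mark
one.

## Validation problem sizes

The test suite validates at desk scale, chosen so the full suite runs in a
few minutes: fuzzed two-source grids up to `n = 800`; RDS-II and bootstrap
checks at 200-835 records; homogeneous NPLCM oracle equivalence at
`N = 1000` with 20000 iterations; coverage at the default `N = 2700` world
with 10000 iterations per replicate; multiplier recovery over 50 surveys of
a `N = 5000` world; dependence-direction over 200 replicates at
`N = 2000`. Every stochastic stage is seeded and bit-reproducible.

## Known limitations

* Three-list NPLCM intervals are not calibrated under strong heterogeneity
  (see above); four or more lists are needed for that.
* The chain bootstrap treats chains as exchangeable clusters; it does not
  model the Markov structure of recruitment within chains.
* Multiplier estimates inherit any bias in the source count `M`
  (duplicated or contaminated service records) and any recall error in the
  survey indicator; the package exposes a contamination factor but cannot
  estimate it from data.
* Aggregate-only capture rounds (tallies without individual identifiers)
  cannot enter the capture-profile table; the data model refuses to
  fabricate individual records from tallies, which is precisely the
  failure that blocks a three-source estimate when a round collects only
  totals.
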