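---
title: "Bayesian mixture profiles of neighbourhood social determinants of health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian mixture profiles of neighbourhood social determinants of health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nsdohmix` derives latent profiles of neighbourhood social determinants of
health (NSDoH) from binary census-tract indicators and relates profile
membership to a binary care outcome. This vignette is the package's account
of the methods: the models and their assumptions, the parameters that
matter, what the synthetic generators do and do not emulate, and the
numerical and design choices made where the method left them open.

## 1. From raw indicators to a binary design matrix

The analysis starts from a tract-by-indicator table of 14 area-level
measures in four thematic domains — housing conditions and resources
(renter occupancy, no vehicle, crowding, incomplete plumbing), economic
security (household income, female-headed households, SNAP participation,
unemployment, working-class occupation), educational attainment (no
high-school diploma), and social and community context (limited English
proficiency; Hispanic/Latino, non-Hispanic Black, non-Hispanic Asian
population shares). Because many of these proportions are strongly skewed,
each is dichotomized at its **state median**, a robust nonparametric
cutpoint: `1` codes greater disadvantage.

Three direction rules cover the catalog (`default_variable_catalog()`):

* **standard** — `1` iff strictly above the median;
* **reversed** (median household income) — `0` iff at or above the median,
  so a tie codes to the non-disadvantaged side;
* **zero-threshold** (incomplete plumbing, whose median is 0) — `0` only
  for exactly-zero values.

The tie rule for standard variables is not dictated by the method; we code
ties to `0`, extrapolating the income rule's convention of sending the
boundary to the non-disadvantaged side. Tracts with missing indicator
values are dropped with a warning rather than imputed — the intended input
is a complete extract, and silent imputation would change the medians. The
median is the usual empirical one (mean of the central order statistics at
even n).

## 2. The multivariate Bernoulli mixture

With `x_i ∈ {0,1}^p` the indicator vector of tract `i`, the observed
likelihood is

$$\mathcal{L}(\pi,\theta \mid X) \;=\; \prod_{i=1}^n \sum_{k=1}^K \pi_k
\prod_{j=1}^p \theta_{j|k}^{x_{ij}} (1-\theta_{j|k})^{1-x_{ij}},$$

where `π` is the profile-membership probability vector and `θ_{j|k}` the
probability of high exposure to indicator `j` within profile `k`. The
model assumes indicators are independent *given* the profile (local
independence, as in latent class analysis); all marginal dependence
between indicators is induced by the mixing. The number of profiles `K` is
unknown: the model is overfit with a generous bound and a prior on `K`
lets the data decide how many components are nonempty.

Priors (all defaults of `mixture_prior()`):

| parameter | prior | default | role |
|---|---|---|---|
| `K` | truncated Poisson(λ) on 1..K_max | λ = 1, K_max = 50 | parsimony over components |
| `π` | symmetric Dirichlet(γ) | γ = 1 | uniform over weights |
| `θ_{j|k}` | Beta(α, β) | α = β = 1 | uniform over exposures |

λ is exposed for sensitivity analyses; larger values favour more
components. All four conjugate hyperparameters may be changed without
touching the sampler, because inference is collapsed.

## 3. Collapsed allocation sampling with tempered chains

Conjugacy lets `π` and `θ` be integrated out exactly, leaving a posterior
over the allocation vector `z` and `K` alone:

$$\log p(X, z \mid K) = \log\frac{\Gamma(K\gamma)}{\Gamma(K\gamma+n)}
 + \sum_k \log\frac{\Gamma(n_k+\gamma)}{\Gamma(\gamma)}
 + \sum_{k,j}\log\frac{B(\alpha+s_{jk},\, \beta+n_k-s_{jk})}{B(\alpha,\beta)},$$

a function of the sufficient statistics `n_k` (tracts per component) and
`s_{jk}` (per-component indicator counts) only. Every sampler move
evaluates this collapsed joint through incrementally maintained statistics;
nothing rescans the data, which keeps a full Gibbs pass at
`O(n · K · p)` additions and makes the 1,478 × 14 × 50 setting routine.

Each sweep applies one move, drawn with probabilities `move_mix`
(default 0.70 / 0.10 / 0.10 / 0.10):

1. **Gibbs pass** — every `z_i` resampled from its full conditional
   `p(z_i = k | z_{-i}) ∝ (n_k^{-i}+γ) ∏_j (α+s_{jk}^{-i})^{x_{ij}}
   (β+n_k^{-i}-s_{jk}^{-i})^{1-x_{ij}} / (α+β+n_k^{-i})`.
2. **Block reallocation** — a small random set of rows proposes fresh
   uniform labels; symmetric Metropolis.
3. **Eject** (`K → K+1`) — a uniformly chosen source component sheds each
   member independently with probability `u ~ Beta(1, 1)` into a new
   component, which is then placed at a uniformly chosen label slot. The
   acceptance ratio uses the subset-marginal proposal probability
   `B(1+m, 1+r)/B(1, 1)`.
4. **Absorb** (`K → K−1`) — a uniformly chosen ordered pair merges; with
   the slot bookkeeping above this is the exact reverse of eject, so the
   pair satisfies detailed balance on labelled states.

Four heated chains (`t_c = 1/(1+0.3(c−1))`) target the posterior raised to
`t_c`; one adjacent-pair state swap per sweep is accepted with the
standard Metropolis-coupled ratio, and only cold-chain draws are retained.
The mild ladder is adequate for a dozen binary indicators; both the ladder
and the move mix are config-exposed (`chain_config()`).

Two representational choices deserve note. First, after each sweep the
labels are permuted so nonempty components occupy the lowest labels. This
is only a relabeling — the model's `K` (which may include empty
components) is retained, because deleting empty components outright would
change the target distribution: states with empty components carry
positive posterior mass under these priors. The *reported* `k_trace` is
the count of nonempty components, which is the quantity of scientific
interest. Second, impossible configurations propagate `-Inf` log
densities rather than raising errors, so Metropolis ratios evaluate
rejections naturally.

Correctness is enforced by enumeration, not by trusting the algebra: on
instances small enough to enumerate every `(K, z)` state, the sampled
posterior over the number of nonempty components and over set partitions
must match exhaustive summation within Monte-Carlo error (batch-means
standard errors). This is the package's primary acceptance property; the
trans-dimensional acceptance ratios were debugged against it.

Defaults: 11,000 total sweeps (1,000 burn-in), thinning 10, 4 chains,
initial allocation spread over `min(20, K_max)` components. The method
itself prescribes no chain lengths; these are desk-scale settings whose
adequacy is demonstrated by the recovery results below, and heavier runs
only need a config change.

## 4. Post-processing: K_map, ECR, and hard assignment

`select_kmap()` takes the mode of the nonempty-component trace (ties to
the smaller count, favouring parsimony). Conditional inference then uses
only the draws with exactly `K_map` nonempty components; the rest are
excluded with a logged count.

A mixture posterior is invariant to label permutations, so draws cannot be
averaged naively. The ECR (equivalence classes representatives) algorithm
fixes a pivot allocation and, for every draw, applies the label
permutation minimizing disagreement with the pivot. We take the pivot to
be the retained draw with the highest log posterior among those at
`K_map` — the conventional choice; any fixed pivot differing by a
permutation yields identically permuted summaries (a tested invariant).
The optimal permutation maximizes the label co-occurrence count, a
`K_map × K_map` assignment problem solved *exactly* with a hand-written
`O(K³)` Hungarian algorithm (`solve_assignment()`; no assignment solver is
among the package's dependencies). Exhaustive search over all `K!`
permutations verifies it in the tests.

Profile summaries are Rao-Blackwellized: given a draw's allocations,
`θ_{j|k}` has a `Beta(α+s_{jk}, β+n_k−s_{jk})` conditional posterior, so
its mean `(α+s_{jk})/(α+β+n_k)` is averaged across draws — same
expectation as averaging sampled `θ` values, lower variance. Equal-tailed
95% intervals come from one Beta draw per retained allocation, which
propagates allocation uncertainty into the interval. Membership
probabilities are relabeled-draw frequencies; `assign_profiles()` takes
the row argmax (ties to the lowest profile index) and reports the median
and IQR of the assignment probabilities plus profile shares.

## 5. Outcome regression

Patients are linked to the profile of their residential tract by hard
assignment — the two-stage approach; when assignment probabilities are
near 1, as in the settings here, the attenuation this can induce is small,
but propagating membership uncertainty is explicitly out of scope. The
outcome model is a Bayesian logistic regression of the binary care outcome
on profile indicators (profile 1 the reference) and categorical covariates
(year of diagnosis, age group — `<50`, `50–64`, `≥65` —, insurance status,
facility type), dummy-coded full rank by `build_design()`.

Coefficients get independent Normal(0, sd²) priors — sd 2.5 for indicator
predictors, 10 for the intercept. These weakly-informative scales
regularize sparse profile-by-covariate cells against separation while
leaving estimates at these sample sizes essentially likelihood-driven
(with sd 10⁶ the posterior mode matches the Newton–Raphson MLE to several
decimals, a tested property). Sampling is adaptive random-walk Metropolis
on the exact posterior: the proposal covariance is the Laplace curvature
at the posterior mode scaled by `2.38/√d`, with the global step size tuned
toward 23% acceptance during a discarded adaptation phase. Repeated
covariate patterns are collapsed to binomial counts first, so likelihood
cost is independent of the number of patients (a few hundred patterns
instead of 10⁵ rows). Defaults: 4 chains × 5,000 draws after 1,000
adaptation iterations; effective sample sizes are estimated by batch
means. Odds-ratio tables apply `exp` to posterior means and 2.5%/97.5%
quantiles. `crude_or_from_table()` provides the descriptive two-by-two
comparator, with an optional 0.5 continuity correction for zero cells.

## 6. The Yost-type comparator

`yost_index()` implements the standard one-dimensional SES index: seven
variables (income, house value, gross rent, poverty, unemployment,
working class, no high-school diploma), disadvantage-direction variables
sign-flipped, all standardized, projected on the leading eigenvector of
the correlation matrix, oriented to correlate positively with income, and
rank-cut into quintiles (1 = lowest SES; ties broken by stable tract
order). The exact seven ACS columns and missing-value handling of any
particular published application vary, so the catalog is user-overridable.
`compare_indices()` cross-tabulates quintiles against profiles with a
chi-square statistic — descriptive only: the comparison's point is that a
single score cannot represent qualitatively different co-occurrence
patterns, not a formal test.

## 7. What the synthetic generators emulate — and what they do not

The generators exist so that every stage is testable against known truth
without any download.

* `simulate_mbmm()` draws exactly from the mixture: allocation, then
  independent Bernoulli indicators.
* `study_truth()` fixes the reference truth at the study's dimensions:
  p = 14, five profiles with weights (0.32, 0.25, 0.18, 0.15, 0.10)
  echoing the reported profile shares, and exposure probabilities 0.9/0.1
  in blocks chosen so every pair of profiles differs in at least six
  indicators. "Well separated" is thus a design property, not luck: at
  these settings the Bayes classification error between the closest pair
  is below 10⁻³, so five profiles, an adjusted Rand index above 0.95, and
  high assignment certainty are the *expected* outcome of a correct
  implementation, and failures indicate bugs rather than noise.
* `simulate_acs_like_raw()` wraps the binary truth in raw-scale clothing:
  each tract's value is placed strictly on the matching side of a
  per-variable anchor (anchors echo the Massachusetts medians, as
  proportions) with a right-skewed Beta(2, 5) offset, reproducing the
  skewness that motivates median splits; the income column is unbounded
  and the plumbing column zero-inflated. Because anchors and empirical
  medians differ slightly, median re-binarization recovers the intended
  binary matrix approximately (>90% of cells), which is the realistic
  situation.
* `simulate_patients()` draws outcomes from the exact logistic model, with
  covariate frequencies echoing the registry sample.

Not emulated: spatial autocorrelation between neighbouring tracts, ACS
sampling error and margins, within-profile residual dependence between
indicators, and outcome confounding structures beyond the declared
covariates. Passing tests therefore demonstrate computational correctness
of the inference machinery under the model's own assumptions — they do not
certify that real neighbourhoods satisfy local independence, nor that hard
assignment is harmless when profiles are poorly separated.

## 8. Problem sizes, runtimes, and reproducibility

Test and acceptance runs are sized for a single desktop core: exactness
checks use 4–5-row matrices with `K_max = 3` and 50,000 retained sweeps
(runtime seconds); the study-scale recovery uses 1,478 × 14 with
`K_max = 50`, four chains, and 5,000 total sweeps thinned to 600 retained
draws (a few minutes); regression recovery uses 10⁵ synthetic patients.
These sizes are stated choices, demonstrated sufficient by the enumeration
agreement and recovery margins above.

All randomness flows from explicit integer seeds: `run_mc3()` and
`fit_bayes_logistic()` seed R's generator (the compiled code draws from
R's RNG, so results are reproducible across machines), the generators
default to the seed stored in their truth objects, and `run_pipeline()`
derives per-stage seeds deterministically from one global seed — reruns of
the same config are byte-identical, and the manifest records a semantic
config hash.

## 9. Known limitations

* Local independence within profiles is an assumption, not a finding;
  correlated indicators within a true profile will be split into extra
  profiles.
* Binary indicators discard within-side variation; a bounded-data mixture
  (e.g. Beta components) would use the full distributions at the cost of
  conjugacy.
* Hard assignment understates uncertainty for tracts with split
  membership; the membership matrix is exported so users can propagate it.
* The sampler's mixing at much larger p or weakly separated components may
  need longer runs or a steeper temperature ladder; the acceptance-rate
  report and the nonempty-K trace are the diagnostics to watch.
* Median cutpoints are state-specific: profiles are defined relative to
  the analysed region and survey window, and do not transfer across
  either.
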