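# nsdohmix

Neighbourhood conditions — housing, economic security, education, social and
community context — shape whether patients receive guideline-concordant
care, but composite deprivation indices (Yost, ADI) compress them into one
or a few scores and lose how disadvantages co-occur. `nsdohmix` implements a
fully Bayesian alternative for researchers working with census-tract
indicator tables: it clusters tracts into latent **neighbourhood
social-determinants-of-health (NSDoH) profiles** with a multivariate
Bernoulli mixture model whose number of components is learned from the
data, and relates profile membership to a binary care outcome with a
Bayesian logistic regression. A Yost-type first-principal-component SES
index is included as the one-dimensional comparator.

## The model

Each tract `i` contributes a vector of binary disadvantage indicators
`x_i ∈ {0,1}^p`, obtained by dichotomizing raw ACS-style proportions at the
state medians (recoded so 1 always means greater disadvantage). The
likelihood is the multivariate Bernoulli mixture

    L(π, θ | X) = ∏_i ∑_{k=1}^K π_k ∏_j θ_{j|k}^{x_ij} (1 − θ_{j|k})^{1−x_ij}

with priors `K | K_max ~ Poisson(λ=1)` truncated to `{1, …, K_max=50}`,
`π | K ~ Dirichlet(1, …, 1)`, and `θ_{j|k} ~ Beta(1, 1)`. Weights and
exposure probabilities are integrated out analytically (Dirichlet-multinomial
and Beta-binomial conjugacy), and a collapsed allocation sampler draws
`(K, z)` directly: full Gibbs reallocation passes, a Metropolis block
reallocation move, and an eject/absorb pair that adds or removes
components, all accelerated by Metropolis-coupled heated chains with state
swaps. Post-processing selects the maximum a posteriori number of nonempty
profiles `K_map`, resolves label switching with the ECR algorithm (exact
assignment-problem relabeling against the highest-posterior pivot), and
assigns every tract to its maximum-probability profile. Outcome models are
fit by adaptive random-walk Metropolis on the exact posterior under
weakly-informative Normal priors, with repeated covariate patterns
collapsed to binomial counts.

## Worked example

Simulate 400 tracts from a known five-profile truth, dichotomize, and
recover the structure end to end:

```r
library(nsdohmix)

truth <- study_truth(seed = 20150)          # 5 profiles, 14 indicators
sim <- simulate_acs_like_raw(400, 14, truth)
X <- binarize(sim$raw)

samples <- run_mc3(X, mixture_prior(),
                   chain_config(n_iter = 3000, burn_in = 500, thin = 5,
                                seed = 7))
samples
#> Posterior allocation samples: 600 retained draws, 400 rows x 14 indicators
#> Nonempty-component counts:
#>   5   6
#> 531  69

k_map <- select_kmap(samples)               # 5
relab <- ecr_relabel(samples$z_draws, pick_pivot(samples, k_map), k_map)
#> ECR: excluding 69 draw(s) without exactly 5 nonempty components
set.seed(1)
post <- summarize_profiles(X, relab, samples$prior)
assignments <- assign_profiles(post, X$tract_ids)
attr(assignments, "summary")
#> $median_prob          [1] 1
#> $iqr_prob             [1] 0.007532957
#> $shares               [1] 0.2625 0.1025 0.3450 0.1450 0.1450
```

The mode of the nonempty-component trace recovers the generating five
profiles; tracts are assigned with near-certainty (median membership
probability 1, IQR 0.008), and `post$theta_post_mean` holds the
profile-specific posterior exposure probabilities that characterize each
profile. The bundled published cross-tabulation of optimal-care status by
profile gives the descriptive comparator:

```r
crude_or_from_table(optimal_care_counts(), ref = 1)
#>   profile  crude_or
#> 1       1 1.0000000
#> 2       2 0.7937085
#> 3       3 0.9712726
#> 4       4 0.9477437
#> 5       5 0.7802598
```

The numbered drivers under `analysis/` run the same stages as a narrative
workflow (simulate → binarize → fit → profiles → regression → Yost
comparison), writing tables under `results/`. `run_pipeline()` executes the
whole sequence from one YAML/list config with a single seed and
byte-identical reruns.

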