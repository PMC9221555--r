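# tacifa

Bayesian **t**ime-**a**ligned **c**ommon and **i**ndividual **f**actor
**a**nalysis for paired multivariate time series.

## The problem

Two multivariate series recorded side by side — facial-feature tracks of two
people in conversation, paired behaviour streams of two animals, two evolving
shapes — usually share structure, but not on the same clock: who leads and by
how much changes over time. Separating what the two series share from what is
specific to each, while estimating the time alignment *jointly* with
everything else (instead of warping first and modelling second), is what this
package does. It is aimed at statisticians and quantitative behavioural
scientists who want likelihood-based inference with honest uncertainty on the
alignment, the shared structure, and a similarity score.

## Model

For series $X, Y \in \mathbb{R}^{p\times T}$ on a common grid $t \in [0,1]$:

$$
x_t = \Psi\Gamma_1\zeta_1(t) + \Lambda\Xi_1\eta(t) + \epsilon_{1t},
\qquad
y_t = \Psi\Gamma_2\zeta_2(t) + \Lambda\Xi_2\eta(M(t)) + \epsilon_{2t},
$$

where $\eta$, $\zeta_1$, $\zeta_2$ are smooth B-spline latent factor curves,
$\Lambda$ spans the shared subspace,
$\Psi = I - \Lambda(\Lambda^\top\Lambda)^{-1}\Lambda^\top$ forces the
individual-specific loadings into its orthogonal complement, and
$M:[0,1]\to[0,1]$ is a monotone B-spline warp
($M(t)=\sum_j\gamma_jB_j(t)$ with cumulative-softmax coefficients
$\gamma_j = \sum_{l\le j}e^{\kappa_l}/\sum_k e^{\kappa_k}$, $\gamma_1=0$)
that aligns the second series' shared factors to the first's.
Multiplicative-gamma shrinkage priors on the loading columns adapt the ranks;
columns that collapse are pruned during burn-in. Posterior computation is
HMC-within-Gibbs with analytic gradients (certified against finite
differences in the test suite); loading chains are identified afterwards by
sequential orthogonal Procrustes alignment. The similarity of the two
series' shared structure is summarized by $\text{Syn}\in[0,1]$, one minus
the mean absolute difference of the per-feature relative shared-variance
contributions.

See `vignette("tacifa-methods")` for the full model, priors, sampler and
design choices.

## Worked example

Simulate the package's factor-model study design (15 features, true shared
rank 3, true warp $M_0(t)=\sqrt{t}$, unit noise), hold out 10% of the time
columns, fit, and summarize:

```r
library(tacifa)
set.seed(1)
sim <- generate_sim1(T = 300)
fit <- tacifa_fit(sim$data,
                  sampler_config(n_iter = 3000, n_burnin = 1500, K = 10),
                  holdout_fraction = 0.1, syn_method = "draws")
print(fit)
```

```
tacifa_fit
  draws: 1500  terminal ranks (r, r1, r2): 8 6 6
  important shared factors (SP >= 0.9): 3
  Syn similarity: 0.956
  held-out MSE: 1.088 1.0466
  95% band coverage: 0.953 0.951
```

Reading the output: the rank-adaptive prior pruned the shared space from the
conservative start $r = p = 15$ down to 8 columns of which 3 carry
sign-determined loadings (the true rank); held-out columns are predicted
with mean squared error ≈ 1, the observation-noise floor, and the 95%
posterior-predictive bands cover ≈ 95% of held-out entries; Syn ≈ 0.95 says
the warped shared structure explains nearly the same relative variance in
both series. `fit$warp` holds the posterior mean and 95% band of the warp
(compare with `sqrt(sim$data$t)`), `fit$sp` the per-entry importance tables.

A thin command-line front end with `simulate`, `fit` and `select-k`
subcommands ships in `inst/cli/tacifa.R` (after installation:
`system.file("cli", "tacifa.R", package = "tacifa")`).

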