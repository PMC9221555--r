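---
title: "Time-aligned common and individual factor analysis: model and computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-aligned common and individual factor analysis: model and computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two multivariate series — say, facial-feature tracks of two people in
conversation, paired animal behaviour streams, or two evolving shapes — share
structure, but not on the same clock: who leads and by how much changes over
time. `tacifa` models a pair of $p \times T$ matrices $X, Y$ observed on a
common grid $t \in [0,1]$ with a single generative model that separates

* a **shared subspace**, common to both series up to an unknown monotone time
  warping, and
* two **individual-specific subspaces**, orthogonal to the shared one,

and quantifies, with full posterior uncertainty, how similar the two series'
shared structure is.

## Model

$$
x_t = \Psi\Gamma_1\zeta_1(t) + \Lambda\Xi_1\eta(t) + \epsilon_{1t}, \qquad
y_t = \Psi\Gamma_2\zeta_2(t) + \Lambda\Xi_2\eta(M(t)) + \epsilon_{2t},
$$

with $\epsilon_{it} \sim N(0, \Sigma_i)$, $\Sigma_i$ diagonal with
feature-specific variances. $\Lambda$ ($p\times r$) spans the shared space;
$\Xi_1,\Xi_2$ are diagonal scales; $\Psi = I_p -
\Lambda(\Lambda^\top\Lambda)^{-1}\Lambda^\top$ projects the individual
loadings $\Gamma_1,\Gamma_2$ onto the orthogonal complement of the shared
space, which makes the two mean components orthogonal by construction and is
what identifies "shared" against "individual". All factor curves are
B-spline expansions: $\eta_i(t) = \sum_j \beta_{ij}B_j(t)$ with $K$ bases,
$\zeta_{ij}(t)$ with $K_1$ (resp. $K_2$) bases.

The second series' shared factors run on a warped clock. The warp is a
monotone B-spline with $J$ bases,
$$
M(t) = \sum_{j=1}^{J}\gamma_j B_j(t), \qquad
\gamma_j = \frac{\sum_{l=2}^{j} e^{\kappa_l}}{\sum_{k=2}^{J} e^{\kappa_k}},
\quad \gamma_1 = 0,
$$
so $M(0)=0$, $M(1)=1$ and $M$ is non-decreasing for every unconstrained
$\kappa \in \mathbb{R}^{J-1}$ — the parametrization that makes
gradient-based sampling possible. $M(t) < t$ means the second series lags
the first at time $t$.

Degree and knots are not part of the model statement; the package uses cubic
splines with clamped boundary knots and equidistant interior knots, so the
basis is a partition of unity, endpoint interpolation pins $M(0)=0$ and
$M(1)=1$ exactly, and evaluation at $t=1$ follows the right-closed
convention (the last basis equals 1, never a zero row).

## Priors and rank adaptation

Loading entries carry multiplicative-gamma shrinkage:
$\Lambda_{lk} \sim N(0, \phi_{lk}^{-1}\tau_k^{-1})$ with
$\phi_{lk}\sim\text{Gamma}(\nu_1,\nu_1)$ and
$\tau_k = \prod_{h\le k}\delta_h$, $\delta_1\sim\text{Gamma}(a_1,1)$,
$\delta_h\sim\text{Gamma}(a_2,1)$ — column precisions grow with the column
index, so superfluous columns collapse toward zero. The same construction is
used for $\Gamma_1$ and $\Gamma_2$. Noise precisions are Gamma; the scale,
warp and factor-spline coefficients are $N(0,\omega)$ with $\omega$ a
variance.

Defaults (`sampler_config()`): $\nu_1 = 3$; all $\delta$-shapes 5; noise
shape/rate 0.1 (weakly informative); $\omega = 100$. Ranks start at the
conservative upper bound $r = r_1 = r_2 = p$. During burn-in, with
probability $\exp(-1 - 5\cdot 10^{-4}\,i)$ at iteration $i$, any loading
column whose entries all lie within $\pm 10^{-3}$ is deleted together with
its factor row, scale entry and shrinkage parameters (ranks never fall below
1, and pruning never runs after burn-in, so the retained draws are
conformable).

Two pruning choices deserve a note. First, pruning here only ever *removes*
columns, while the adaptive scheme it follows can also re-add them — a
deletion is irreversible. Under the ordered prior initialization the tail
columns are born orders of magnitude below the pruning threshold, and a true
factor whose signal emerges slowly (a weak direction at a rank the shrinkage
has already collapsed) can lose the race against the prune clock; once
deleted it never comes back, and losing it degrades everything downstream
(the warp included, since the shared factors are what identifies it). The
schedule therefore defers the first attempt (`prune_start`, default 300)
until after initial step-size adaptation and ramps the threshold linearly
from zero to its final $10^{-3}$ over the first 1000 iterations, so early
prunes clear only columns that are truly collapsed. Second, the
$\pm 10^{-3}$ entry rule removes the collapsed tail but can leave mid-tail
columns whose prior-equilibrium entry scale is of order $10^{-2}$: the
pruned rank is an upper bound on the number of *important* factors, which is
instead estimated from the SP measure below (this is also how the factor
count is read off in practice).

## Posterior computation

All blocks except $\Lambda$ and $\kappa$ are conditionally conjugate and are
updated by exact Gibbs draws: the factor-coefficient blocks row by row, the
$\Gamma$ loadings column by column, the diagonal scales jointly, then the
noise precisions and the shrinkage locals/globals from their Gamma full
conditionals. (A scan over rows/columns is itself a valid Gibbs sweep; each
sub-draw is the standard Bayesian linear-regression posterior, which is what
the unit tests check it against.)

$\Lambda$ and $\kappa$ get Hamiltonian Monte Carlo with a fixed leapfrog
length of 30 and step sizes tuned every 100 iterations to keep acceptance in
$[0.6, 0.8]$ (multiplicative 0.8/1.25 adjustments, strengthened to 0.5/2
when acceptance is extreme; a short bracketing search sets the initial
scale; all adaptation freezes after burn-in). Each column of $\Lambda$ is
updated separately: writing $\Psi$ through the rank-one update
$\Psi = \Psi_{-j} - vv^\top/v^\top v$ with $v = \Psi_{-j}\Lambda_{\cdot j}$
(equal to the block-matrix form $(I-P_1)(I-P_2)(I-P_1)$) gives the exact
gradient of the negative log posterior in $O(pT)$ per leapfrog step,
including the dependence of the individual-specific means on
$\Lambda_{\cdot j}$ through $\Psi$. The $\kappa$ gradient chains through
$\eta'(M(t))$ and the softmax Jacobian
$\partial M(t)/\partial\kappa_j = w_j\{\sum_{l\ge j}B_l(t) - M(t)\}$. Both
gradients are certified against centered finite differences in the test
suite (relative error $<10^{-5}$); the finite-difference check, not any
printed formula, is treated as ground truth.

Two scheduling safeguards matter in practice. The warp block is the
stiffest coordinate — it must traverse a narrow likelihood ridge while the
noise variances collapse on low-noise data — so it receives five HMC
repetitions per sweep. And the noise variances are held at their initial
value (1) for the first 200 iterations: otherwise a strong feature left
unexplained in the very first sweeps can have its variance blow up,
lose its likelihood weight, and stay unfit for the rest of the run
(variance absorption).

Each iteration ends with sign-flip group moves: negating a loading column
together with its factor row leaves the likelihood and the (symmetric)
prior unchanged, so the flip is accepted with probability one and mixes the
chain across the sign symmetry of the factorization. Identified columns are
re-oriented afterwards by the Procrustes alignment; columns the data does
not pin down keep random signs, so their SP importance correctly tends to
zero instead of accumulating spurious sign coherence from a slowly mixing
chain.

Numerical safeguards: precision matrices are symmetrized before Cholesky
factorization (with a tiny-jitter retry); the projector is computed as
$I - UU^\top$ from the SVD of $\Lambda$, which is stable when shrunk columns
are nearly collinear (a warning is raised on genuine rank deficiency); warp
values are clamped into $[0,1]$ against floating-point overshoot; a
non-finite state aborts the run with the iteration number. The whole
iteration loop is compiled (RcppArmadillo) and draws all randomness from R's
RNG, so a single `set.seed()` reproduces a chain bitwise.

## Post-processing

Loadings are only identified up to a right rotation, and the loading/curve
split is only identified up to a per-factor scale. `align_chain()` first
normalizes every draw's factor curves to unit norm on the training grid,
absorbing the scale into the loading columns (likelihood-invariant; loading
magnitudes then measure actual contributions — without this a strong factor
can hide in a small loading column multiplied by a large curve). It then
resolves the rotation by walking the chain front to back: draw $m$ of
$\Lambda_1 = \Lambda\Xi_1$ is rotated by the orthogonal Procrustes solution
toward the aligned draw $m-1$ (SVD of the cross-product; `procrustes_rotation()`),
the same rotation is applied to $\Lambda_2 = \Lambda\Xi_2$ and, transposed, to
the shared coefficients, so each draw's likelihood is unchanged (asserted in
the tests). The first draw is pre-rotated by the right singular vectors of
the residual cross-product so that leading columns explain the most data.
The individual blocks $\Psi\Gamma_1, \Psi\Gamma_2$ are aligned the same way
with their own rotations; the SVD pre-rotation is applied to the shared
block only, where the significance ordering is defined.

From the aligned chain:

* **SP importance**: $SP_{ij} = |0.5 - P(A_{ij} > 0)|/0.5$ per loading
  entry; a factor (column) counts as important when its largest entry
  reaches 0.9. The column maximum is used because the designs' true columns
  are sparse — a 15-feature column loading 5 features would be diluted by a
  column mean.
* **Warp summary**: pointwise posterior mean and 95% band of $M(t)$; bands
  are degenerate at the endpoints by construction.
* **Prediction**: held-out columns are predicted by the posterior mean of
  the per-draw mean curves (splines evaluate anywhere in $[0,1]$); 95%
  posterior-predictive bands add observation noise per draw.

## The Syn similarity

For feature $l$ and time $t$, each series has a relative shared-variance
contribution, e.g.
$(\Lambda_l\Xi_1\eta(t))^2 / \{(\Psi_l\Gamma_1\zeta_1(t))^2 +
(\Lambda_l\Xi_1\eta(t))^2 + \sigma^2_{1l}\}$ for the first series, and with
$\eta(M(t))$, $\Xi_2$, $\Gamma_2$, $\sigma^2_{2l}$ for the second.
$\text{Syn} \in [0,1]$ is one minus the average (over features and time)
absolute difference of the two contributions: 1 means the warped shared
structure carries the same relative weight in both series everywhere.

At which parameter value Syn is evaluated is a genuine choice:
`posterior_syn()` offers the posterior mean of the aligned blocks
(`method = "mean"`) and the average of per-draw Syn values
(`method = "draws"`). The draw average is the estimator consistent with
posterior summarization of a nonlinear functional and is what the
simulation-study ladder (sin/linear/quadratic individual factors) is
reported with; the mean-state variant is slightly higher because averaging
the blocks first smooths away per-draw disagreement before the absolute
value is taken.

## Synthetic designs

`generate_sim1()` draws from the model itself: $p = 15$, grid $t = i/T$,
three shared factors equal to the first three orthogonal polynomials on the
grid, block-diagonal $\Lambda$ (5 features per column, entries
$N(15, 0.1^2)$), $\Gamma_1,\Gamma_2$ with $N(0,0.1^2)$ entries, ten
individual factors $\zeta_{1k}(t)=\sin(kt)$, $\zeta_{2k}(t)=\cos(kt)$, true
warp $M_0(t)=t^{1/2}$ (or the direction-changing
$M_0(t)=\{(0.33\sin 2\pi t)^2+t^2\}^{1/2}$, `warp_turn`), unit noise.
Variants replace $\zeta_{1k}$ by $kt$ or $(kt)^2$, making the two series'
individual structure increasingly dissimilar — Syn should fall
monotonically across sin, linear, quadratic.

`generate_sim2()` is deliberately *not* from the model: 12 landmarks on an
area-preserving ellipse ($a(t)b(t) = 4$), 24 coordinate features, the second
series deforming on the warped clock ($M_0 = t^{1/2}$), noiseless by default
(the low signal-to-noise variants add $sd$ 1 or 1.5). Four landmarks have one
coordinate identically zero and the rest form 10 mirror pairs, so about 10
independent shared factors are expected.

The generators emulate the study designs exactly and are deterministic given
a seed, but they are simulations: unit or zero observation noise, a single
global warp, and no missingness, artifacts or nonstationarity of real
tracking data — passing tests here show correctness of the machinery, not
field performance.

## Problem sizes used in the checks

The packaged acceptance runs use a 90/10 column split throughout, with
$K = K_1 = K_2 = J = 10$ for the factor-model design and 8 for the ellipse
design. The sin-family factor-model run uses the full protocol ($T = 500$,
6000 iterations with 3000 burn-in); the linear and quadratic Syn variants
run at $T = 300$ with 3000/1500, where the Syn ladder is already stable.
The ellipse design runs at $T = 300$ with the full 6000/3000 iteration
count — its noiseless posterior is extremely peaked and needs the longer
run for the warp to travel from its identity initialization. Basis-size
selection cross-validates $K \in \{6, 8, 10, 12\}$ at a reduced iteration
count, since only the ranking of held-out errors matters there.

## Limitations

* Equal $T$ and equal $p$ for both series; diagonal noise covariances.
* One global warp for all shared factors.
* The per-iteration cost of the $\Lambda$ update is $O(rp^2 + rpT)$;
  large-$p$ problems will be slow.
* Rank adaptation only deletes columns; a factor whose signal emerges late
  could in principle be lost if pruning starts too early (hence the deferred
  default and the threshold ramp).
* When a series' individual signal shares its time course with a shared
  factor curve (as in the quadratic variant of the factor-model design,
  whose individual family is a single large-amplitude $t^2$ direction), the
  shared space can absorb part of it through one-sided scale columns; Syn is
  then estimated lower than the generative truth would give.
* On data whose matrix rank is smaller than the number of geometrically
  meaningful factors (the ellipse design is algebraically rank two), the
  number of high-SP columns reflects how the sampler distributes the
  subspace across columns and varies between runs.
* No WAIC/LOO model comparison and no alignment across independent chains.
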