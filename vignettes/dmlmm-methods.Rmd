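---
title: "Deep mixtures of linear mixed models: model, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep mixtures of linear mixed models: model, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`dmlmm` models unbalanced longitudinal data: subject $i$ contributes
responses $y_i = (y_{i1}, \dots, y_{in_i})^\top$ at times $t_i$, with $n_i$
varying freely across subjects (including $n_i$ smaller than the basis
dimension, or $n_i = 1$). The regression layer is

$$ y_i = B(t_i)\,\beta_i + \varepsilon_i, \qquad
   \varepsilon_i \sim N(0, \sigma^2 I_{n_i}), $$

where $B(t_i)$ is a known $n_i \times d$ design matrix of basis evaluations
(Legendre polynomials, or periodic B-splines plus a trend block for seasonal
series) and $\beta_i \in \mathbb{R}^d$ is a subject-specific coefficient
vector. The coefficients are the "projection" of each subject's unequal-length
record into a common $d$-dimensional space; everything the model learns about
the population lives in the prior for $\beta_i$.

That prior is a deep mixture of factor analyzers (DMFA). With
$z^{(0)}_i := \beta_i$, each layer $l = 1, \dots, L$ generates

$$ z^{(l-1)}_i = \mu^{(l)}_k + B^{(l)}_k z^{(l)}_i + \epsilon^{(l)}_{ik},
   \qquad \epsilon^{(l)}_{ik} \sim N(0, \delta^{(l)}_k), $$

with the component $k$ drawn with probability $w^{(l)}_k$, lower-triangular
loadings $B^{(l)}_k$, diagonal noise $\delta^{(l)}_k$, and a standard normal
top layer $z^{(L)}_i \sim N(0, I)$. Dimensions must decrease fast enough for
identifiability: construction enforces $D^{(l+1)} \le (D^{(l)} - 1)/2$ for
every consecutive pair, and `dmfaArchitecture()` rejects violations naming
the offending layer.

Marginalizing the layers, the prior for $\beta_i$ is an explicit Gaussian
mixture with one component per *path* $k = (k_1, \dots, k_L)$:
$w_k = \prod_l w^{(l)}_{k_l}$, and with $A_l = B^{(1)}_{k_1} \cdots
B^{(l)}_{k_l}$,

$$ \mu_k = \sum_{l=1}^L A_{l-1}\mu^{(l)}_{k_l}, \qquad
   \Sigma_k = \sum_{l=1}^L A_{l-1}\,\delta^{(l)}_{k_l}\,A_{l-1}^\top
   + A_L A_L^\top . $$

The final $A_L A_L^\top$ term carries the unit variance of the top layer; the
single-layer special case reduces to the familiar factor-analysis covariance
$B_k B_k^\top + \delta_k$, and `collapseToGMM()` is cross-checked against the
generative sampler by a moment-matching oracle in the test suite.

All prediction flows through this collapsed mixture. The marginal likelihood
of a subject, the joint law of observed and unobserved responses, and the
conditional predictive law at new times are all Gaussian mixtures with
closed-form parameters (`subjectMarginalLoglik()`,
`conditionalPredictive()`, `marginalPredictive()`). The conditional
predictive uses the standard Gaussian conditional per component, with
component weights reweighted by each component's marginal likelihood of the
observed record — the observation-noise term $\sigma^2 I$ is included both in
the reweighting density and in the predictive covariance. This convention is
pinned down by a brute-force oracle (form the joint mixture, divide by the
marginal) rather than by any printed display.

# Priors

All scale-type priors are heavy-tailed and expressed hierarchically so that
every conditional is conjugate:

* error sd: $\sigma \sim \mathrm{HC}(A)$ via
  $\sigma^2 \mid \psi \sim \mathrm{IG}(\tfrac12, 1/\psi)$,
  $\psi \sim \mathrm{IG}(\tfrac12, 1/A^2)$; default $A = 5$ on the response
  scale;
* layer noise sds $\sqrt{\delta}$: the same half-Cauchy hierarchy, scale
  `A_delta` defaulting to $A$;
* component means: elementwise Cauchy$(0, c_\mu)$ as a normal–inverse-gamma
  mixture; default $c_\mu = 2.5$;
* loadings: horseshoe on the free (lower-triangular) entries — normal with a
  per-entry local scale and a per-layer global scale, each half-Cauchy in
  IG–IG auxiliary form; default global scale 1;
* weights: Dirichlet$(\alpha, \dots, \alpha)$ per layer with $\alpha = 1/2$,
  small relative to the per-component parameter count so that an overfitted
  mixture can empty superfluous components.

The exact hyperprior scales are package defaults (configurable through
`dmlmmPrior()`), declared rather than tuned: weakly informative on a
response scale of order one. `logPriorSigma()` and `logPriorDMFA()` expose
the joint hierarchical log-densities; quadrature tests confirm that the
hierarchies integrate to their intended marginals (half-Cauchy for
$\sigma$; the horseshoe's logarithmic spike at zero for loadings).

# Variational inference

The posterior is approximated by a fully factorized family chosen so the
evidence lower bound (ELBO) is available in closed form: Gaussian factors
for all location parameters (diagonal for $\mu^{(l)}_k$; full within each
loading row), inverse-gamma factors for every variance-type parameter and
auxiliary, Dirichlet factors for the weights, and per subject a
diagonal-covariance Gaussian for $\beta_i$, a diagonal Gaussian for each
$z^{(l)}_i$, and a categorical responsibility vector per layer.
Responsibilities are kept per layer and combined multiplicatively into path
responsibilities, so training cost scales with $\sum_l K^{(l)}$ rather than
$\prod_l K^{(l)}$.

Optimization alternates local and global moves:

1. **Local updates** (`n_inner` cap 20, tolerance $10^{-8}$): block
   coordinate ascent over responsibilities, $q(\beta_i)$ and $q(z^{(l)}_i)$.
   Each block is set to its exact optimum within its family given the
   others — for a diagonal Gaussian the objective separates, so the optimal
   mean solves the full-precision system while the variances are the
   reciprocal precision diagonals — which makes every sweep monotone in the
   local ELBO.
2. **Global natural-gradient step**: every global factor moves along a convex
   combination (weight $\rho_m$) of its current natural parameters and the
   conditionally-conjugate target computed from the minibatch, with subject
   sums rescaled by $n/|{\rm batch}|$. With a full batch and $\rho_m = 1$
   this is exact coordinate-ascent VI and the full-data ELBO is monotone —
   the master regression test. For genuine minibatching the step size
   follows the Robbins–Monro schedule $\rho_m = (m + \tau)^{-\kappa}$,
   defaults $\kappa = 0.75$, $\tau = 10$, minibatch $\min(n, 64)$ drawn
   without replacement and reshuffled each epoch. Steps that would leave a
   factor's domain are halved (at most ten times).

The closed-form ELBO, decomposed into regression and prior-layer parts, is
validated against a Monte-Carlo estimate of
$E_q[\log h(\theta) - \log q_\lambda(\theta)]$ on a small instance — the
strongest single check of the update algebra, since any missing or mistaken
expectation breaks the agreement.

After the outer loop a full-data local pass is run, path components whose
argmax-responsibility count is zero are pruned (weights set to zero and the
rest rescaled; means and covariances untouched), and the collapsed mixture
is evaluated at the variational posterior mean. Because the quantity that
enters every predictive formula is the collapsed parameter set
$(w_k, \mu_k, \Sigma_k)$, the point estimate takes the exact $q$-expectation
of $\Sigma_k$ — a backward recursion
$C^{(l-1)} = E[\delta^{(l)}] + E[B^{(l)} C^{(l)} B^{(l)\top}]$ whose
correction terms involve the loading-row posterior covariances — rather than
plugging posterior-mean loadings into the deterministic collapse. The two
differ by little, but the expectation version is the better-calibrated
density estimate.

## Initialization

Initialization is deterministic given the seed and matters for the quality
of the optimum. The package:

* projects each subject by ridge regression (penalty $10^{-3} I$, so
  $n_i < d$ is harmless) to seed $q(\beta_i)$;
* clusters subjects for the first layer by k-means on the *smooth curves*
  implied by a moderately penalized projection (penalty
  $0.1 \times \overline{\mathrm{diag}(B^\top B)}$), evaluated on a fine grid.
  Clustering raw near-unpenalized coefficients fails badly whenever the
  observation pattern leaves some coefficient directions ill-conditioned:
  those directions oscillate by orders of magnitude and dominate the
  distances;
* seeds the loadings of each layer with the principal directions of the
  pooled within-cluster residuals — one shared orientation across
  components, so deeper layers see comparable factor scores — scaled by each
  component's excess standard deviation (a probabilistic-PCA decomposition);
  layer noise starts at the per-dimension residual variance left over after
  the retained directions, and factor-score locals start at the whitened
  projections;
* clusters deeper layers by k-means on those scores; responsibilities start
  near-hard (0.98) for layer one and uniform for deeper layers;
* starts $\sigma^2$ at the mean residual variance of the penalized
  projections.

# The synthetic designs

Three generators reproduce standard benchmark designs and drive the entire
test surface; all are seed-deterministic and verified symbol-for-symbol
against their defining formulas by tests that recompute the curves from the
stored latent draws.

* **Two-group sinusoids** (default 600 subjects): 10 sorted uniform times on
  $[0,1]$; $y = g\,\sin(4\pi t) + 2\sum_{k=1}^4 \xi_k \sin(k\pi t) +
  \varepsilon$ with $g = \pm 1$ equiprobable, $\xi$ sds
  $(0.1, 0.045, 0.01, 0.001)$, noise sd 0.3. Two latent groups with means
  $\pm\sin(4\pi t)$ and Karhunen–Loève-style functional errors.
* **Stochastic Van der Pol oscillator** (default 100 subjects):
  $\theta_i = e^{U(1,5)}$; Euler–Maruyama integration (step $10^{-3}$ from
  $t = 0$, diffusion 0.5 on both coordinates, $f(0)=1$, $g(0)=0.1$);
  $n_i \sim U\{15,\dots,25\}$ times uniform on $[10,20]$ snapped to the
  grid; $y = f(t)$ with no extra noise. Paths that blow up are regenerated
  at a halved step with a logged message. The sd-superscript notation in the
  source designs is read as variances of the printed sds throughout.
* **Trigonometric grid with removals** (default 120 subjects): 40 grid
  points $t_j = (j-1)/39$; $y_j = b_1\cos(w_1\pi t_j) + b_2\sin(w_2\pi t_j)
  + \varepsilon$ with $b_1, b_2 \in \{1, 0.1\}$, $w_1 \in \{1,2,3\}$,
  $w_2 \in \{7,8,9\}$ (36 cells), noise sd 0.1; 15–20 positions per subject
  removed uniformly and held out. The modeling basis for this design is the
  standard $d = 10$ Legendre family on $[0,1]$ — deliberately mismatched
  with the high-frequency sine block, as in the source benchmark, so the
  best attainable imputation error is the projection residual of that block
  (about 0.33 RMSE averaged over cells).

`generateFromDMLMM()` simulates from any collapsed mixture truth and records
coefficients and component labels, which the parameter-recovery experiments
use as ground truth.

# Benchmark protocol and experiment sizes

`runTable1Experiment()` runs, per replication: generate independent training
and test sets; fit (default architecture $D = (10, 4, 1)$, $K = (6, 3)$,
i.e. an 18-path overfitted mixture with pruning); for the grid design,
condition on each test subject's observed entries and predict the removed
entries; for the other designs, condition on a random half (rounded up) of
each test subject's points and predict the rest. Reported per replication:
the log of the subject-averaged RMSE of the predictive mean over held-out
points, and the subject-averaged negative log marginal density of each test
subject's observed vector. The experiment default is 5 replications with
500 full-batch unit-step iterations per fit; at these sample sizes the ELBO
plateaus within 200–400 iterations, and full-batch coordinate ascent reaches
visibly better optima than the minibatch schedule with the same budget, so
the experiment overrides the fitting default.

Test-suite experiment sizes (chosen once, stated here as the package's
protocol): parameter recovery uses a separated two-component factor truth in
$d = 6$ with 300 training and 200 test subjects on a balanced 25-point grid
with noise sd 0.2, 10 seeds, 300 iterations per fit — a balanced design
keeps the design columns near-orthogonal, which is where the factorized
family's variance approximation is most accurate (see Limitations); the
monotonicity check runs 200 full-batch iterations on 30 subjects; the
conflict-check calibration uses 50 null replicates with 60 reference
simulations and 300 divergence draws each.

# Prediction utilities

* `thresholdRisk()`: the mixture CDF at one query time — the probability of
  the response falling below a threshold.
* `pointwiseInterval()`: equal-tailed intervals from the scalar mixture CDF
  inverted by bisection to $10^{-10}$.
* `ellipticalSetCoverage()`: moment-matches the predictive mixture to one
  Gaussian and reports the fraction of truth samples inside the
  Mahalanobis ellipsoid at the chi-squared quantile. Chosen as the simplest
  elliptical construction; for strongly multimodal predictives it is biased
  — severely undercovering at low levels (the central ellipsoid can contain
  no mode at all) and overcovering at high levels — and the tests quantify
  exactly that bias.
* `clusterAssign()`: posterior path probabilities
  $\propto w_k\,N(y_i; B_i\mu_k, B_i\Sigma_k B_i^\top + \sigma^2 I)$, argmax
  labels, ties to the lowest index.
* `conflictPvalue()`: the prior-data-conflict check for within-subject
  forecasting. The statistic is the Kullback–Leibler divergence from the
  conditional predictive law of the future segment (given the observed past)
  to its marginal law, estimated by plain Monte Carlo from the conditional
  (no closed form exists between Gaussian mixtures; default 2000 draws); the
  reference distribution comes from replicate past segments drawn from the
  model's own marginal (default 200), and the tail probability uses the
  add-one correction. Calibration under the null and agreement with the
  closed-form Gaussian divergence in the single-component case are tested.

# Numerical choices

* Unnormalized Legendre polynomials on the affinely rescaled domain; the
  coefficient vector absorbs any normalization, and a fixed convention keeps
  tests deterministic. The basis domain defaults to the observed time range
  at fit time and is stored with the model; evaluation outside it is an
  error, never extrapolation.
* Cubic trend B-splines with equispaced interior knots (count
  `nTrend` − 4); the periodic block is built from wrapped uniform-knot
  cubic B-splines evaluated at $t \bmod$ period, exactly periodic by
  construction.
* Near-singular covariances get a $10^{-8}$ diagonal jitter before Cholesky
  factorization (logged under `options(dmlmm.verbose = TRUE)`); failure
  after jitter is an error naming the offending matrix.
* Mixture log-densities always go through per-component Cholesky
  log-densities and log-sum-exp; zero-weight components are skipped.
* Path enumeration is lexicographic in $(k_1, \dots, k_L)$, fixing component
  indexing for serialization and tests.
* All randomness flows from one integer seed; derived seeds for sub-tasks
  keep every entry point reproducible run-to-run.

# Limitations

* **Mean-field component merging.** The factorized family shares one
  $q(\beta_i)$ across all mixture components, so every component's expected
  quadratic form pays the same local-variance penalty; tight components are
  penalized relative to broad ones whenever per-subject information is
  moderate, and coordinate ascent then merges the overfitted mixture more
  aggressively than the generative structure warrants. On the trigonometric
  grid design (36 latent cells, 18 paths available) fits retain only about
  5–8 active paths; predictive means remain accurate, but the marginal
  density (log-score) is noticeably worse than a finer mixture would give,
  and on the two-group design the fit typically keeps one or two small
  satellite components beside the two real ones. Emptied components cannot
  revive: their expected log-weight is far below any active component's, so
  the active count is effectively decided early.
* **Variance under-dispersion under correlated designs.** The
  diagonal-covariance $q(\beta_i)$ uses reciprocal precision diagonals,
  which understate marginal variances when the subject-level design matrix
  has correlated columns; fitted component covariances are then biased
  downward by roughly the neglected cross-terms. The effect vanishes for
  balanced, near-orthogonal designs and grows with design correlation and
  shrinkage.
* Plug-in prediction only: predictive laws are evaluated at the posterior
  point estimate, not integrated over the posterior.
* Errors are uncorrelated within subjects, and no covariate effects enter
  the model.
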