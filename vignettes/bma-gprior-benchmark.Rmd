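---
title: "Model uncertainty in linear regression: g-prior BMA and its empirical benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model uncertainty in linear regression: g-prior BMA and its empirical benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its priors

Everything in this package concerns the normal linear model with an
uncertain predictor set,

$$ y = \alpha 1_n + X_\gamma \beta_\gamma + \epsilon, \qquad
   \epsilon \sim N(0, \sigma^2 I), $$

where $\gamma \in \{0,1\}^p$ indicates which of the $p$ candidate columns
enter the model. Continuous predictors are standardized to mean zero and
unit variance and the response is centered on entry
(`regression_data()`), which is also what makes the marginal likelihood a
function of each model's $R^2_\gamma$ alone. The intercept and error scale
carry the flat prior $\pi(\alpha, \sigma) \propto \sigma^{-1}$ throughout,
and the coefficients of each model the Zellner g-prior

$$ \beta_\gamma \mid \alpha, \sigma^2
   \sim N\!\big(0,\; g\,\sigma^2 (X_\gamma^T X_\gamma)^{-1}\big). $$

Under this prior the Bayes factor of $M_\gamma$ against the null
(intercept-only) model has the exact closed form

$$ \log B_\gamma = \tfrac{n-1-d}{2}\log(1+g)
   - \tfrac{n-1}{2}\log\{1 + g(1 - R^2_\gamma)\}, $$

with $d = \sum_j \gamma_j$. All log marginals in the package are reported
relative to the null model (the shared additive constant is dropped), so
the null model is the anchor at zero and only differences ever matter.

The supported treatments of $g$ are:

* **fixed g** — rules `sqrt-n`, `n` (unit-information), `one`,
  `benchmark` ($\max\{n, p^2\}$), or any positive number;
* **hyper-g** — $\pi(g) \propto (1+g)^{-a/2}$, default $a = 3$. The
  literature's closed form is
  $B = \frac{a-2}{d+a-2}\,{}_2F_1(\frac{n-1}{2}, 1; \frac{d+a}{2}; R^2)$;
* **local empirical Bayes** — $\hat g = \max(F-1, 0)$ per model, the
  maximizer of the fixed-g evidence;
* **JZS** — the Zellner–Siow Cauchy prior, an inverse-gamma$(1/2, n/2)$
  mixture over $g$;
* **BIC / AIC** — half-deviance information-criterion weights used as
  approximate log marginals.

Two consequences of these choices are worth keeping in mind. Fixed-g Bayes
factors are bounded even at $R^2 = 1$ (the *information paradox*), with
ceiling $\frac{n-1-d}{2}\log(1+g)$ — already above four million at
$n = 20$, $g = \sqrt{20}$, so the bound is practically irrelevant — while
hyper-g and EB-local diverge there. Conversely, letting $g \to \infty$ at
fixed data drives every fixed-g Bayes factor to zero (*Bartlett's
paradox*), which is why the adaptive treatments of $g$ exist at all.
Per added variable the $g=\sqrt n$ prior charges $\log(1+\sqrt n) \approx
\frac{1}{2}\log n$, effectively half of BIC's $\log n$ penalty.

The model-space prior is beta-binomial$(1,1)$ by default (every model
*size* equally likely a priori, $P(M_\gamma) = 1/\{(p+1)\binom{p}{d}\}$);
when $p > n$ it is truncated at size $n-2$ and renormalized. Models that
are rank deficient or larger than $n-2$ always receive prior mass zero
rather than raising errors inside a search — the same intent as the
truncation.

## Numerical evaluation of the mixed marginals

The hyper-g and JZS Bayes factors are one-dimensional integrals of the
fixed-g Bayes factor against their respective $\pi(g)$. Both are computed
after the substitution $u = g/(1+g) \in (0,1)$, which turns the heavy
right tail into a finite interval; the integrand is evaluated on the log
scale and shifted by its maximum before exponentiation. Because the
posterior scale of $g$ grows with $n$, the integrand peaks at
$u^\ast \approx 1 - O(1/n)$; the quadrature therefore places its segment
boundaries geometrically toward $u = 1$ (edges $1 - 2^{-k}$, resolving
peaks down to width $\sim 4\times 10^{-6}$, i.e. comfortably below
$1/n$ for any realistic $n$). Inside each segment the R implementation
uses `stats::integrate` (relative tolerance $10^{-10}$) and the C++
implementation adaptive Simpson; the two agree to $\sim 10^{-9}$ and are
cross-checked in the test suite against three independent oracles: the
direct hypergeometric power series at moderate $n$, a Monte Carlo average
of the fixed-g Bayes factor over $10^6$ prior draws of $g$, and a Laplace
approximation on the $\log g$ scale.

At $R^2$ numerically equal to 1 the hyper-g function reports $+\infty$
when the integral genuinely diverges ($d + a \le n + 1$) and the finite
limit $(a-2)/(d+a-n-1)$ otherwise; inside the C++ sampler $R^2$ is capped
at $1 - 10^{-12}$, since a chain state with a numerically perfect fit is a
degenerate-data symptom, not a usable posterior.

## Searching the model space

For small $p$, `enumerate_posterior()` scores all $2^p$ models and
normalizes with log-sum-exp (exact inclusion probabilities fall out of the
same pass). Beyond that, `mc3_sample()` runs Markov chain Monte Carlo
model composition: a Metropolis–Hastings random walk on inclusion vectors
whose proposal mixes, with probability one half each, a uniform
single-coordinate add/delete move and a random swap of one included for
one excluded variable. The swap degenerates to add/delete at the empty and
full models, which makes the add/delete proposal density state-dependent
there; the acceptance ratio carries the corresponding correction so the
chain targets the exact posterior. Visited models are cached by
inclusion pattern so each distinct model is fit once per chain. Posterior
masses and inclusion probabilities use visit frequencies over the whole
chain — the estimator recommended for this sampler family — with
renormalized-marginal masses over the visited models stored alongside as a
diagnostic; there is no burn-in by default, and the default chain length
is 10,000 iterations. Chains are deterministic given `(data, seed)`.

## Estimation and prediction

Conditional on a model and on $g$, the coefficient posterior is
multivariate Student-t with $n-1$ degrees of freedom, location
$\frac{g}{1+g}\hat\beta_\gamma$, and scale
$\frac{g}{1+g} s^2_g (X_\gamma^TX_\gamma)^{-1}$ where
$s^2_g = \mathrm{TSS}\{1 - \frac{g}{1+g}R^2_\gamma\}/(n-1)$. BMA
summaries mix this over the model posterior: the posterior mean is
computed analytically (mass-weighted shrunken OLS; for hyper-g and JZS
the shrinkage factor $E[g/(1+g) \mid \gamma, y]$ is evaluated on a
1024-point grid of the conditional posterior of $u$), while intervals are
equal-tailed Monte Carlo quantiles of the full mixture, the exclusion
point mass at zero included. Adaptive variants draw $g$ per draw by
inverse-CDF on the same grid (EB-local plugs in $\hat g$; BIC/AIC weights
carry no $g$, so their draws use the unshrunk flat-prior OLS posterior).
Predictive draws add the intercept posterior
$\alpha \sim N(0, \sigma^2/n)$ and new-observation noise. Equal-tailed
(not highest-density) intervals were chosen because the interval score
that evaluates them is defined by a pair of bounds. Model selection (BMS)
reuses the identical machinery conditioned on the MAP model (`bms()`),
with posterior-mass ties broken toward the smaller model and then
lexicographically.

Two consequences of the mixture-quantile convention: an excluded variable
(inclusion probability zero) gets mean 0 and the degenerate interval
$[0,0]$; and for variables with intermediate inclusion probability the
equal-tailed interval is *conservative*, because the atom at zero can
absorb more than the nominal tail mass at an endpoint. The package's
calibration study (in the acceptance tests) self-simulates from the
unit-information prior and finds exactly this: predictive intervals —
continuous mixtures — cover at the nominal 95% to within Monte Carlo
error, while coefficient intervals never under-cover but run one to two
points above nominal. The conservatism is a property of the interval
convention, not an error, and it grows as the fixed $g$ weakens (more
mid-range inclusion probabilities, more atom-straddling endpoints).

## Penalized baselines

The frequentist reference methods minimize
$\|y - \alpha 1_n - X\beta\|^2 + h_\lambda(\beta)$ with the lasso or
elastic-net penalty. The package fixes the protocol — a 100-point
log-spaced grid from $\lambda_{\max} = \max_j |x_j^Ty|/(n\,\mathrm{mix})$
down to $10^{-4}\lambda_{\max}$, K-fold cross-validation with shared
folds, CV-minimum and one-standard-error selection rules, and a
$\{0.25, 0.5, 0.75\}$ grid for the elastic-net mixing weight — and
delegates the inner coordinate descent to glmnet. Returned coefficients
below $10^{-10}$ in magnitude are restored to exact zeros (solver fuzz at
the grid boundary). Support sets along the penalty path feed the
precision–recall sweep for variable selection; these methods provide no
uncertainty intervals, which is exactly how they enter the benchmark.

## Deriving a generating model and re-simulating data

The benchmarking design re-simulates from an empirically fitted truth
rather than an arbitrary one. `select_generating_model()` implements the
pipeline: for wide candidate sets, sure independence screening (two-round
iterative SIS: top half by univariate $R^2$, refit, re-rank the rest
against the residuals) down to 30 variables; all-subsets regression by a
residual-sum-of-squares branch and bound (`best_subset_search()`; any
submodel fits no better than its full candidate set, and variables are
pre-ordered by marginal $R^2$ to tighten pruning — exhaustive in effect at
small $p$); then the *largest* size whose best model has every
coefficient two-sided $t$-test $p < 0.05$, refit by OLS to give
$(\beta_{DG}, \alpha_{DG}, \sigma_{DG})$. The significance filter is
applied to the best model of each size only — scanning all models of a
size would make the filter's meaning depend on an exponential candidate
list. If no size qualifies the best single-variable model is used, with a
warning. `parametric_bootstrap()` then draws replicate responses
$y^* = \alpha_{DG} + X\beta_{DG} + \epsilon$ with the design held fixed,
and `train_test_split()` provides reproducible 75–25 partitions (train
size rounded up).

## The synthetic benchmark suite

Because the underlying real data collections cannot be shipped, the
`synthetic_data` generator emulates their statistical regimes: Gaussian
designs with independent, AR(1), equicorrelated-block, or latent-factor
correlation, standardized empirically like the real data; sparse truths
with random support and signs; and the noise SD solved analytically so
the generating model's population $R^2$ hits a target in the 0.5–0.9
range observed for empirically derived generating models. Four presets
span the documented $n$–$p$ regimes:

| preset | n | p | support | correlation | target $R^2$ |
|---|---|---|---|---|---|
| `tall_small` | 500 | 15 | 5 | AR(1), $\rho=0.5$ | 0.8 |
| `tall_large` | 2000 | 30 | 8 | AR(1), $\rho=0.5$ | 0.7 |
| `square` | 150 | 100 | 8 | AR(1), $\rho=0.5$ | 0.7 |
| `wide` | 60 | 300 | 6 | AR(1), $\rho=0.5$ | 0.8 |

Nonzero magnitudes decay geometrically (ratio 0.8, so the weakest of
eight signals is about a fifth of the strongest): real regression problems
mix strong and weak correlated effects, and it is the weak ones that keep
model uncertainty alive — with equal strong effects the posterior
concentrates on one model and averaging, selection and penalized methods
become indistinguishable. What the generator does **not** emulate:
discrete and skewed covariates, interaction/squared-term design columns,
heteroscedastic or non-Gaussian noise. Conclusions from passing tests are
therefore about the methods' behavior under correlated Gaussian designs
with sparse decaying truths, not about any particular real dataset.

## The benchmark harness

`run_benchmark()` crosses datasets × replicates × methods. On each full
replicate it computes coefficient RMSE (PointEst), the mean interval
score of 95% coefficient intervals (IntEst), $1-$AUPRC of support
recovery (Inference; inclusion probabilities for Bayesian methods, the
penalty path for lasso/elastic net), and the average model size (expected
size $\sum_j P(\gamma_j = 1 \mid y)$ for BMA, with the MAP size reported
for BMS; nonzero count for penalized fits). Prediction metrics come from
random 75–25 splits within each replicate: test-set $R^2$, test RMSE, and
the mean interval score of predictive intervals (IntPred), averaged over
splits then over replicates. `relative_score_table()` divides each
method's dataset-mean metric by the reference method's (JZS by default),
averages ratios across datasets with equal weight, and ranks by `Score`
(mean of the five relative metrics), interleaving interval-free methods
by `PartScore` (mean of PointEst, Inference, Prediction) as highly as
possible without disturbing the Score order. The relative Prediction
column uses test RMSE so that every column is a loss and lower is better
throughout; the raw $R^2_{\mathrm{test}}$ average is reported alongside.
The area under the precision–recall curve is step-integrated (average
precision) over achievable recalls, tie groups treated as single
thresholds — no trapezoidal interpolation, which is optimistic on sparse
curves. One failing method on one replicate is recorded as missing, not
fatal, and excluded pairwise from the relative averages.

`compare_bma_bms()` computes averaging and MAP-selection versions of each
Bayesian method from the same posteriors, and summarizes the signed
BMA−BMS differences on the raw metric scale (the relative scale is
undefined whenever the reference attains a perfect inference score).

The package exposes all of this as ordinary functions plus this vignette
and the repository's `scripts/acceptance.R`; there is no shell entry
point, since the intended user drives analyses from R.

## Problem sizes used by the shipped tests

The test suite exercises the full machinery at desk scale, chosen once:
four presets × 25 bootstrap replicates, 3 train–test splits per
replicate, 10,000 MC3 iterations (the package default), 2,000 posterior
draws per interval summary inside the harness (10,000 elsewhere), and a
150-replicate prior-draw calibration study at $n = 60$, $p = 5$ under
the unit-information prior. Sampler-vs-enumeration agreement is checked
at $p = 8$ with 10,000 and 100,000 iterations.

## Known limitations

* Enumeration is capped (default 25 variables) and MC3 convergence on
  very wide problems is assessed only through the shipped agreement and
  recovery tests; no formal MCMC diagnostics are produced.
* The EB-local "draws" use the plug-in $\hat g$, understating $g$
  uncertainty relative to a fully Bayesian treatment.
* The hyper-g hyperparameter defaults to $a = 3$; it is configurable but
  the benchmark does not tune it.
* Best-subset branch and bound is exact but can be slow near its 30-
  variable cap on weakly structured data; screening first is the
  intended path.
* Coefficient intervals are conservative at intermediate inclusion
  probabilities (see above); interval *scores* are unaffected by this
  caveat since they evaluate the reported bounds as-is.
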