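---
title: "Combining biased small-area prevalence estimates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining biased small-area prevalence estimates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, how the non-identified directions are handled,
the priors and tuning parameters with their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices that an
implementer had to make.

## 1. The data and the core model

The input is a grid of aggregate prevalence estimates: one row per
(area, source) pair with a point estimate $y_{ij}$ on the percent scale and
a sampling standard error $\sigma_{ij}$ in percentage points, treated as
known. Sources that publish only a 95% confidence interval have
$\sigma_{ij}$ recovered as width/3.92, which assumes a symmetric Wald
interval; `read_estimates()` warns when an interval's midpoint sits more
than 0.1 points from the estimate, since the conversion is then dubious.
When a file carries both an `se` column and interval columns, `se` wins and
a disagreement beyond $10^{-6}$ is reported — explicit precedence beats
silent averaging. Cells a source did not cover are simply absent: every
model treats them as missing likelihood terms, so unbalanced grids work
throughout (each source still needs at least two cells, otherwise its bias
variance is unidentifiable, and validation blocks the fit).

The core model gives every source an additive, exchangeable-across-areas
bias:

$$y_{ij} \sim N(\theta_i + \delta_{ij},\, \sigma_{ij}^2), \qquad
  \delta_{ij} \sim N(\mu_j,\, \tau_j^2).$$

The bias mean $\mu_j$ captures a source's systematic shift; $\tau_j$ its
area-to-area wobble. The normal sampling model is an approximation that is
comfortable at the sample sizes aggregate sources typically report; a
binomial likelihood for very small samples is out of scope.

### Identification by anchoring

The additive structure is invariant to moving a constant between the
$\theta$'s and the $\mu$'s, so the overall level must come from outside the
data: an externally supplied regional mean prevalence (the *anchor* — for example, a regional
household survey putting smoking prevalence at 23% across a region's 48
districts). Rather than sampling under a hard constraint, the sampler runs
unconstrained — with a very flat normal working prior on the $\theta_i$ —
and `recenter_draws()` identifies each retained draw: the shift
$\varphi = \overline{\theta} - \text{anchor}$ is subtracted from every
$\theta_i$ and added to every $\mu_j$ and $\delta_{ij}$, leaving all fitted
cell means, hence the likelihood, bit-for-bit unchanged. This preserves the
exchangeable geometry the sampler sees (it mixes much better than a
constrained walk) and makes the identity `mean(theta) == anchor` exact in
every draw. A consequence worth knowing: changing the anchor translates
every prevalence by the same amount and leaves all between-area differences
untouched, which the test suite checks. The anchor can optionally carry its
own standard error (`prior_config(anchor_se =)`), implemented as a per-draw
random anchor in the recentring; it widens every prevalence interval without
moving differences, and is off by default because a firmly anchored level is
what makes the rest of the machinery stable.

### Priors

Vague but proper defaults, all configurable through `prior_config()`:
$\mu_j \sim N(0, 100^2)$, $\tau_j \sim U(0, 100)$ (percentage points — an
enormous range relative to any plausible bias). The anchored-source variant
replaces the regional anchor with $\mu_{j^*} = 0$ for a source declared
unbiased-on-average and then needs proper priors on the prevalences,
$\theta_i \sim U(0, 100)$. The exchangeable-$\tau$ variant pools the bias
SDs through a half-normal with $\sigma_\tau \sim U(0, 100)$; the equal-$\tau$
variant shares a single $\tau$. These variants matter mostly when sources
or areas are few.

## 2. Correlated biases

Sources built from the same underlying survey should not be treated as
independent witnesses. The extension makes each area's bias vector
multivariate, $\delta_{i\cdot} \sim \mathrm{MVN}(\mu, \Sigma)$, with a
scaled inverse-Wishart prior that separates scales from correlations. Two
parameterizations of that family were piloted. The textbook form —
$\Sigma = \mathrm{Diag}(\xi)\, Q\, \mathrm{Diag}(\xi)$ with
$Q^{-1} \sim \mathrm{Wishart}(S{+}1, I)$ and lognormal $\xi_j$ — leaves the
Gibbs/slice samplers JAGS assembles with effective sample sizes of a few
dozen per ten thousand iterations once some sources are very precise. The
package therefore uses the equivalent *stochastic-diagonal-scale* form:

$$\Sigma^{-1} \sim \mathrm{Wishart}\!\big(S{+}1,\ \mathrm{Diag}(\lambda)\big),
  \qquad \lambda_j \sim \mathrm{Gamma}(0.5,\ 0.04),$$

together with a centered latent cell-mean parameterization
($\eta_{i\cdot} \sim \mathrm{MVN}(\theta_i + \mu, \Sigma)$,
$y_{ij} \sim N(\eta_{ij}, \sigma_{ij}^2)$). Every full conditional is then
conjugate and mixing improves by an order of magnitude. With $S + 1$
degrees of freedom the marginal prior on each correlation is near-uniform;
the gamma hyperprior makes each marginal bias SD heavy-tailed with median
around 2 percentage points — weakly informative on the scale of plausible
biases. Correlations are reported as $\rho_{kj} = \Sigma_{kj} /
\sqrt{\Sigma_{kk}\Sigma_{jj}}$ per draw, so every reported matrix is exactly
unit-diagonal and positive definite by construction.

One genuine statistical limit surfaced while designing the recovery
experiments: the correlation between two sources' *latent* biases is only
well identified when the remaining sources pin the area effects tightly. If
all sources carry large bias SDs, an area effect and a shared bias component
are nearly exchangeable explanations, and the honest posterior for $\rho$ is
wide no matter how long the chain runs. The packaged demonstration
therefore plants the correlation in a pair of high-precision,
high-bias-variance sources (the "two synthetic-estimation products sharing
one survey" situation that motivates the model) and surrounds them with
lower-bias direct surveys.

## 3. Time trends and forecasting

The trend model gives each area an intercept $\alpha_i$ (its level at the
reference year 2005) and a random slope on $x_j = 2005 - \text{year}_j$:

$$y_{ij} \sim N(\alpha_i + \beta_i x_j + \delta_{ij},\, \sigma_{ij}^2),
  \qquad \beta_i \sim N(\mu_\beta, \sigma_\beta^2),$$

with the anchor now constraining $\overline{\alpha}$. Mind the sign
convention: $x$ runs *backwards* in time, so declining prevalence means
positive $\beta$; summaries also report the calendar-year slope $-\beta$.

The time covariate is constant within a source, which creates a second
exactly-flat direction: adding $c$ to every slope while subtracting
$c\,x_j$ from every bias mean changes nothing in the likelihood. Left
alone, a vague-prior sampler performs a slow ridge walk and the reported
$\mu_\beta$ is meaningless. The package identifies this direction the same
way it identifies the level: per draw, the least-squares slope of the
$\mu_j$ on $x_j$ is attributed to the regional trend (moved into
$\mu_\beta$ and the $\beta_i$), leaving the bias means trend-free by
construction. The interpretive consequence is worth stating plainly: "mean
trend" here means *the linear-in-time signal in the data that is not
absorbed by trend-free source biases*. Recovery experiments must compare
against the identically identified functional of the truth; across
replicates the two coincide in expectation. Forecasts
(`predict_prevalence()`) evaluate $\alpha_i + \beta_i (2005 - \text{year})$
per draw and summarize predictive means, intervals and rank distributions —
interval widths grow with extrapolation distance, and ranks far from the
data are appropriately unstable. A table whose sources all share one year
is rejected by default (the slope would be prior-only); an
`allow_constant_year` flag admits it for reduction checks against the
static model.

## 4. The classical counterpart

The same additive model can be fitted classically by alternating a weighted
two-way ANOVA with a random-effects meta-analysis:

1. weighted ANOVA of $y_{ij}$ on area and source with weights
   $1/(\sigma_{ij}^2 + \tau_j^2)$, starting from $\tau^2 = 0$;
2. recentre the area effects onto the anchor (a shift, exactly as in the
   Bayesian identification — multiplicative rescaling would break the
   additive structure);
3. per source, deviations $d_{ij} = y_{ij} - \hat\theta_i$ with variances
   $\sigma_{ij}^2$ feed the DerSimonian–Laird moment estimator
   $\hat\tau_j^2 = \max\{0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\}$;
4. repeat until the largest change in any $\hat\tau_j^2$ drops below `tol`
   (default $10^{-8}$);
5. multiply the reported SEs by $\sqrt{\mathrm{MSE}}$ with
   $\mathrm{MSE} = \sum w r^2 / (N - A - S + 1)$ — with weights that are
   true reciprocal variances the expected MSE is 1, so the factor calibrates
   misstated inputs. The denominator counts the two-way additive parameters
   less the one degree of freedom returned by the identification constraint.
   The factor is applied unconditionally; a `mse_floor_1` flag floors it at
   1 for users who never want SEs shrunk.

The ANOVA step solves the constrained weighted least-squares problem through
a reduced design plus shift, and is tested against an independent
Lagrange-system oracle to $10^{-8}$. Degenerate grids whose area/source
bipartite graph is disconnected are detected and rejected as singular.

On convergence speed, measured behaviour deserves honesty: the plain
alternation is a linearly convergent fixed-point map whose rate depends on
the data (observed ratios 0.4–0.75 per pass on study-scale grids), so
reaching $10^{-8}$ can take from under twenty to over fifty passes. The
practical convergence this algorithm is known for — stabilizing in well
under ten passes — refers to looser, practically sufficient tolerances
($10^{-3}$–$10^{-4}$ on $\tau^2$). `accelerate = "anderson"` offers a
safeguarded Anderson-mixing update (one ANOVA/meta-analysis pass per
iteration, history reset at the $\tau^2 = 0$ truncation boundary, same
fixed point) that reaches $10^{-8}$ in ten to fifteen passes; about eleven
is its floor, since a secant method must first learn the map's curvature in
$S$ directions. The fixed point satisfies the ANOVA normal equations and
the DL equations simultaneously, which the tests check directly, and is
reached from either update.

`fit_mixed_model()` fits the marginal form
$y_{ij} \sim N(\theta_i + \mu_j, \sigma_{ij}^2 + \tau_j^2)$ by REML over
$\tau_j \ge 0$ (L-BFGS-B on the $\tau$ scale, which is smooth at the
boundary), profiling the fixed effects by GLS at each evaluation. It is the
same estimand approached from the likelihood side; the two classical routes
agree to within a tenth of a percentage point on study-scale grids, and
both ignore the uncertainty in $\hat\tau^2$ itself — the classical
convention, and the main inferential advantage the Bayesian fits keep.

## 5. Weights, adjusted estimates, residuals, DIC

With known $\mu_j, \tau_j$, combining sources within an area is a
fixed-effect meta-analysis of the bias-adjusted estimates
$y_{ij} - \mu_j$ with marginal variances $\sigma_{ij}^2 + \tau_j^2$;
`pooling_weights()` reports the normalized inverse-variance weights and
their across-area averages, `bias_adjusted_estimates()` the shifted,
variance-inflated per-source estimates. For Bayesian fits the plug-ins are
posterior means, and `model_weights()` additionally evaluates the weights
per retained draw to give intervals for both the per-cell weights and the
per-source averages (both are summarized, since either might be the
quantity of interest). Weight rows sum to 1 by construction; inflating one
source's $\tau$ strictly drains its weight everywhere.

Fit is assessed by standardized residuals
$r_{ij} = (y_{ij} - \hat\theta_i - \hat\mu_j) / \sqrt{\sigma_{ij}^2 +
\hat\tau_j^2}$. For MCMC fits, `posterior_residuals()` evaluates the sum of
squares per draw and reports its posterior mean: plug-in residuals at
posterior means systematically understate the variation the fitted
parameters absorbed, while the per-draw version restores it, sitting near
one degree of freedom per present cell for well-specified data. Either way
the $\chi^2$ reference is approximate — residuals share fitted parameters —
so reports say "compatible/incompatible with the central 95%" and never
headline a p-value.

Model comparison uses DIC at the fitted-cell-mean focus
($\theta_i + \delta_{ij}$, plus trend terms where present), with
$p_D = \bar{D} - D(\text{posterior mean cell means})$. DICs are comparable
only between fits sharing this focus (all fits in this package do; the
marginal Model-1 sampler, which integrates the biases out, deliberately
carries no DIC). Differences of about 2 or less are flagged as not
distinguishing the models.

## 6. The synthetic-data generator

`simulate_dataset()` inverts the model: true prevalences
$\theta_i \sim N(\text{anchor}, \text{theta\_sd}^2)$ are drawn and then
recentred so their mean equals the anchor *exactly* — mirroring the hard
anchor and making anchor-recovery tests sharp; bias vectors come from
`simulate_correlated_biases()` (multivariate normal via a PSD matrix square
root, so exactly singular cases like $\rho = 1$ or $\tau = 0$ work);
observations add $N(0, \sigma_{ij}^2)$ noise with the generating
$\sigma_{ij}$ reported as the known standard errors.

Defaults describe a realistic regional study: 48 areas, 7 sources, anchor
23%, between-area SD 3 percentage points (a typical spread for a behavioural
risk factor across districts; not an empirical estimate), bias means drawn
on $[-3, 3]$, bias SDs on $[0.5, 2]$. Per-cell standard errors derive from
per-source nominal sample sizes via $\sqrt{p(100-p)/n}$ at $p =$ anchor
(sample sizes uniform on 1500–5000 by default), reproducing the feature
that commercial sources report larger samples and hence tighter claimed
precision; a `se_range` alternative draws them uniformly. A single seed
drives everything through fixed sub-streams, so adding sources does not
perturb the area-level draws.

What the generator does *not* emulate: non-normal sampling error (binomial
proportions near the boundary), spatial correlation between neighbouring
areas, biases that scale with prevalence (a log-scale proportional-bias
model would capture that), misreported standard errors (tests construct
those on top, by halving a source's stated values), and real sources'
unknown, possibly non-exchangeable bias structure. Passing calibration
tests on these data therefore shows the estimators are correct *under the
model's own assumptions* — it cannot certify any real source as unbiased.

## 7. Numerical choices and study sizes

* Convergence flags: R-hat above 1.05 (two chains by default) or a Monte
  Carlo SE above 3% of the posterior SD flags a parameter; flagged fits are
  returned with the report attached, never silently.
* Default chains: 2 × 5000 iterations (1500 burn-in, thin 2) for the
  univariate models — study-scale fits take a couple of seconds. The
  correlated-bias model defaults to 14000/3000/thin 6 and its acceptance
  experiment uses 55000/5000/thin 25: the Wishart block has the longest
  autocorrelation time, and stable 2.5% quantiles for 21 correlations need
  a few hundred effective draws.
* Per-chain RNG seeds derive from one master seed; simulation sub-streams
  keep components independent.
* The $\tau^2$ iteration truncates at zero (DL convention); the REML
  optimizer works on the $\tau$ scale with a zero lower bound; the Anderson
  safeguard resets history when extrapolation hits the boundary or jumps
  more than an order of magnitude past the residual.
* Degenerate inputs are contracts, not accidents: zero-width intervals,
  empty tables, one-cell sources, disconnected designs, all-equal years and
  residual-free fits (MSE factor 0 with a warning) each have a defined
  response.
* Test-suite problem sizes: the calibration study runs 20 replicates of the
  48 × 7 default; correlation recovery runs 5 replicates at long chain
  length; trend recovery 10 replicates. These sizes give the tests stable
  pass/fail behaviour while keeping a full run in the minutes range.

## 8. Known limitations

The bias decomposition is only as good as the anchor: a biased regional
mean biases every prevalence by the same amount (differences are immune).
Bias means are only identified *relative* to the weighted average bias
being absorbed into the level — declaring a trusted source (the
anchored-source variant) is the honest alternative when no external mean
exists. The correlated-bias model's correlations are weakly identified
unless precise sources pin the area effects, and its classical counterpart
is absent by design (the variance structure has no clean mixed-model
formulation). The trend model's mean slope is a model-dependent attribution,
as the trend section explains. And all standard errors are taken at face value up to the
global MSE factor and the bias variances — there is no per-cell robustness
against adversarially misstated precision.
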