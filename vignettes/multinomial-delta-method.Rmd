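---
title: "Multinomial delta-method standard errors for reliability coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multinomial delta-method standard errors for reliability coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarel)
```

## The model and its assumptions

A test of $k$ items administered to $N$ respondents yields a score matrix;
for any particular coefficient only some derived variables matter — a single
item score, a pair of items, an item and its rest score (sum minus the
item), the two half sums of a split, or all $k$ items jointly. The unique
observed patterns of those derived scores, collected in a matrix $R$ with
frequency vector $n$ (rows sorted lexicographically, last column fastest),
are a sufficient statistic. The only distributional assumption made is that
$n$ is one draw from a multinomial distribution over response patterns. No
normality, no factor structure, no restriction on the shape of the item
score distribution — which matters, because item scores are bounded and
discrete, and normal-theory standard errors for their variances and
covariances are demonstrably too optimistic (see the benchmark comparison
below).

Under multinomial sampling the estimated covariance matrix of $n$ is
$V(n) = \mathrm{diag}(n) - n n^\top / N$. For a coefficient
$\hat\theta = g(n)$ with Jacobian $G = \partial g / \partial n$, the first-order
Taylor expansion gives the estimated asymptotic variance
$\widehat{\mathrm{Var}}(\hat\theta) = G\, V(n)\, G^\top$. When $g$ is
*homogeneous of order 0* — $g(cn) = g(n)$ for all $c > 0$, true of every
coefficient that depends on proportions only — one has $G n = 0$ and the
variance simplifies to $G\, \mathrm{diag}(n)\, G^\top$. The package computes
both forms and checks their agreement whenever homogeneity is verified
(`chain_homogeneous0()`); the simplified form is never used otherwise.

Two implementation routes produce every standard error:

* **Generic engine.** The coefficient is written as a *generalized exp-log
  chain*: alternating design matrices and elementwise transforms
  (`log`, `exp`, plus `sqrt`, `square`, `reciprocal`, `none` — the extended
  vocabulary is convenient for square roots of sums of squared covariances
  and for signed quantities). Each chain is pure data
  (`chain_to_json()`), evaluated by `chain_eval()` and differentiated by the
  chain rule in `chain_jacobian()`.
* **Closed forms.** The gradient of each coefficient with respect to $n$ was
  derived analytically (for example, for the unbiased covariance
  $g_c = [(x_c-\bar x)(y_c - \bar y) - s_{xy}]/(N-1)$, giving
  $\mathrm{Var}(s_{xy}) = [N m_{22} - (N-2) s_{xy}^2 - s_{xy}^2/N]/(N-1)^2$
  with $m_{22}$ the joint (2,2) central moment; analogous gradients exist
  for the correlation, split-half and lambda coefficients). These are the
  defaults in `se_*()`.

The two routes share no code beyond the pattern table, so their agreement
(relative $10^{-8}$ over hundreds of random fixtures in the test suite) is a
strong guard against derivation errors on either side. A third, slower
oracle — the SD of each coefficient across multinomial resamples — calibrates
the absolute scale.

## Chain construction and numerical choices

Logarithms inside chains must only ever see positive arguments. Rather than
special-casing non-positive sums, every chain shifts its raw scores so all
values are at least 1; shifting changes nothing about variances,
covariances, correlations or lambdas, and the mean chain undoes its shift
with a final linear step. Signed quantities (covariances, correlation
numerators) are formed only in linear steps, after all products and ratios
of positive ingredients have been routed through `log`/`exp` pairs; sums of
squared covariances go through the `square` transform, which is safe on
negatives.

Other numerical decisions, all visible as constants in the code:

* **Unbiased versus ML estimators.** Variances and covariances use the
  $N-1$ denominator throughout, matching standard reliability output. The
  delta-method SE of the mean is based on the ML variance
  ($\sqrt{\hat\sigma^2_{ML}/N}$); the conventional $s/\sqrt N$ is exposed as
  `variant = "conventional"` and is the better choice in practice, being
  unbiased — `reliability_analysis()` uses it by default for its mean rows.
* **Boundary detection.** A coefficient is *at* a boundary within $10^{-12}$
  (relative) and *near* it within $10^{-3}$. A covariance at the
  Fréchet bound implied by its margins has no SE and raises a classed
  boundary error. For a variance the Fréchet rule is vacuous (the
  comonotone bound of a variable with itself *is* its variance), so the
  boundary is declared when the delta variance of $s^2$ degenerates to zero
  while the variable is non-constant — for two-point data this is exactly the
  sample variance reaching $N(b-a)^2/(4(N-1))$, e.g. a dichotomous item with
  $\hat p = 1/2$, where the sampling distribution of $s^2$ is one-sided and
  no meaningful Wald interval exists. The study harness drops and counts
  such replications.
* **The $\varepsilon$-limit device.** At $|r| = 1$ the correlation SE is 0
  by definition (flagged `boundary`). Within $10^{-3}$ of $\pm 1$, and for
  $\lambda_2$ when all inter-item covariances vanish (the square-root term
  sits at 0 where it is not differentiable), the SE is computed by
  evaluating at a perturbed value and letting the perturbation
  $\varepsilon$ descend through $10^{-4}, \ldots, 10^{-10}$ until two
  successive values agree to $10^{-6}$ relative (`eps_limit()`); results are
  flagged `epsilon-device`.
* **Low samples.** $N = 2$ evaluates everywhere it can but is flagged
  `low-N`; no small-sample corrections are invented.
* **Homogeneity probe.** Scale factors $\{0.5, 2, 10\}$ with relative
  tolerance $10^{-9}$, plus the $G n \approx 0$ check.

## Confidence intervals

Wald intervals $\hat\theta \pm z_{(1+\ell)/2}\,\mathrm{SE}$ everywhere,
except the mean, which uses a $t$ quantile with $N-1$ degrees of freedom.
Wald intervals are not range-preserving; they are reported raw (a `clip`
argument exists but is off by default), because clipping hides exactly the
boundary pathologies a user should see. Benchmarks: Feldt's interval builds
on $(1-\alpha)/(1-\hat\alpha) \sim F_{N-1,\,(N-1)(k-1)}$; Fisher-Z uses
$\operatorname{atanh} r \pm z/\sqrt{N-3}$; the normal-theory SEs are
$s^2\sqrt{2/(N-1)}$, $s/\sqrt{2(N-1)}$ and
$\sqrt{(s_x^2 s_y^2 + s_{xy}^2)/(N-1)}$. The Agresti–Coull interval
(adjusted proportion $\tilde p = (x + z^2/2)/(n + z^2)$) is used to decide
whether a simulated coverage percentage is consistent with the nominal
level; for 95% coverage over 2,000 replications the band, floored at one
decimal in percent, is $[93.9\%, 95.8\%]$.

## What the simulator emulates — and what it does not

`sim_design()` / `simulate_responses()` generate dichotomous scores from a
two-dimensional five-parameter acceleration model:
$P(X_j = 1 \mid \theta) = \gamma_j + (1 - \gamma_j - \delta_j)\,
\Psi_j(\theta)^{\xi_j}$ with logistic core
$\Psi_j = \operatorname{logit}^{-1}\!\big(\sum_d w_{jd} a_{jd} (\theta_d -
b_{jd})\big)$, latent traits bivariate standard normal with correlation
$\rho$. Setting $\gamma = \delta = 0$, $\xi = 1$ recovers the 2PL model;
the two model variants share one random stream, so a 5PAM with degenerate
supports reproduces the 2PLM bit for bit. Defaults, chosen once as
realistic questionnaire conditions and configurable in `sim_design()`:
discriminations lognormal(0, 0.1); locations evenly spaced on $[-2, 2]$;
$\gamma \sim U(0, 0.2)$, $\delta \sim U(0, 0.2)$, $\xi \sim U(0.5, 2)$ for
the 5PAM; $\rho = 0.5$; in two dimensions odd items load $(1, 0.5)$ and
even items $(0, 1)$.

The harness focuses on two deliberately awkward items, chosen by position,
not re-estimation: item A is the *first* item (the easiest; its mean is the
closest to the bound of 1) and item B the *middle* item,
$\lfloor k/2 \rfloor + 1$ (mean nearest $1/2$, hence variance nearest its
two-point maximum). Population coefficient values for a design cell are
computed once from a large generated sample (default $10^6$ respondents;
the sampling error of order $1/\sqrt M$ is negligible against the
quantities studied), and the "true" SE of a coefficient is *defined* as the
SD of its estimates across replications — an empirical, not formulaic,
truth.

What passing this harness does **not** show about real data: real item
responses are not locally independent given a low-dimensional trait, real
samples are not simple random samples, and real scales contain polytomous
or missing responses (missing data are rejected by design — the multinomial
framework assumes complete patterns). The simulator also produces
dichotomous items only; the estimators themselves accept any discrete or
even real-valued scores, but with nearly-all-distinct scores the pattern
table approaches $N$ categories and the method, while valid, loses its
point — continuous-data alternatives are then preferable.

## The study harness

`run_study()` replicates generation → estimation → CI per coefficient,
reporting scaled bias $100(\overline{\mathrm{SE}} -
\mathrm{SE}_{true})/\mathrm{SE}_{true}$ and coverage, with the
Agresti–Coull band recomputed from the post-omission replication count.
Replications are driven by child seeds drawn once from the master seed, so
results are reproducible and independent of evaluation order. Display
follows the three-decimal convention, with `*` marking coverage outside the
band or $|$bias$| > 10\%$.

Default problem sizes keep a full run at desk scale (500 replications,
$N = 2000$, $k = 10$, $10^6$-draw population evaluation — about two
minutes); the full-size experiment (2,000 replications, three sample
sizes, both models, both dimensionalities) is available by configuration.

```{r, eval = FALSE}
design <- sim_design(N = 2000, k = 10, model = "2PLM", replications = 500, seed = 1)
study <- run_study(design)
study          # formatted table with flags
autoplot(study)
```

## Known limitations

* The standard errors are first-order asymptotics. At $N = 100$ the SEs of
  the strongly nonlinear coefficients (the lambdas, split-half,
  correlation) carry relative bias of a few percent — visible in the test
  suite's Monte-Carlo calibration, which passes tightly at $N = 500$ but
  not for those coefficients at $N = 100$ — and their Wald intervals can
  undercover slightly in small samples.
* Near parameter-space boundaries (item proportions near 0, 1/2 or 1;
  $|r| \to 1$) sampling distributions are skewed and Wald intervals
  undercover even in large samples; the flags exist precisely to mark this.
* Coefficients defined through sample maxima/minima (the remaining Guttman
  lambdas, optimal split-half searches) violate the differentiability the
  delta method needs and are out of scope, as are McDonald's omega,
  Revelle's beta, and resampling-based intervals.
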