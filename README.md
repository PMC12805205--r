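# deltarel

Analytic standard errors for classical-test-theory reliability analysis.

Reliability analyses report coefficients about measurement precision — item
and scale means, variances, standard deviations, inter-item covariances and
correlations, item-rest correlations, the split-half coefficient, and
Guttman's λ₁, λ₂ and λ₃ (Cronbach's alpha) — yet the software that prints
them rarely prints a standard error next to them. `deltarel` fills that gap
for discrete item scores, for which normal-theory standard errors are often
unrealistic.

## The method

The unique observed response patterns **R** and their frequencies **n** are
the sufficient statistic: **n** is modelled as one draw from a multinomial
distribution, so its estimated covariance matrix is

```
V(n) = diag(n) − n nᵀ / N .
```

Every coefficient is a smooth function θ̂ = g(**n**). Writing g in
*generalized exp-log notation* — an alternating product of design matrices
and elementwise transforms,
`g(n) = A_q exp(A_{q−1} log( … A_1 n))` — makes the Jacobian
**G** = ∂g/∂**n** a mechanical chain-rule product. The delta method then
gives the estimated asymptotic variance

```
Var(θ̂) = G V(n) Gᵀ,        SE(θ̂) = sqrt(Var(θ̂)),
```

which simplifies to `G diag(n) Gᵀ` when g is homogeneous of order 0 (i.e.
depends on proportions only, as the mean, correlation, split-half and lambda
coefficients do). The package implements both the generic engine
(`explog_chain()`, `se_generic()`) and closed-form standard errors derived
from the analytic gradient of each coefficient (`se_mean()`,
`se_covariance()`, `se_variance()`, `se_sd()`, `se_correlation()`,
`se_split_half()`, `se_lambda1()`, `se_lambda2()`, `se_lambda3()`,
`coefficient_covariance()`); the two routes agree to near machine precision
and are tested against each other, against finite differences, and against
multinomial resampling.

Benchmark intervals from the literature are included for comparison: the
Feldt F-based interval for alpha, the Fisher-Z interval for correlations,
normal-theory standard errors for variances/SDs/covariances, and the
Agresti–Coull interval used to judge simulated coverage.

A built-in item response theory simulator (two-dimensional five-parameter
acceleration model, with the 2PL model as a special case) and a study
harness (`run_study()`) reproduce the kind of bias/coverage experiment used
to validate the standard errors.

## Worked example

```r
library(deltarel)

design <- sim_design(N = 426, k = 3, model = "2PLM", seed = 2)
x      <- simulate_responses(design)     # 426 x 3 matrix of 0/1 scores
fit    <- reliability_analysis(x)        # every coefficient + SE + 95% Wald CI
tidy(fit)
```

The (abridged) output:

```
   type       coefficient     item        estimate    se  lower upper flags
 1 item       mean            item1          0.84  0.018  0.805 0.875 ""
 5 item       variance        item2          0.251 0      0.25  0.251 "near-boundary"
13 scale      lambda1         <NA>           0.142 0.042  0.06  0.223 ""
15 scale      lambda3         <NA>           0.213 0.062  0.091 0.335 ""
16 scale      split_half      <NA>           0.257 0.071  0.118 0.397 ""
22 inter-item correlation     item2,item3    0.154 0.046  0.063 0.246 ""
32 rest       lambda3_deleted item1          0.256 0.068  0.123 0.389 ""
```

Reading it: Cronbach's alpha (λ₃) for this 3-item scale is 0.213 with
standard error 0.062, so the 95% Wald interval [0.091, 0.335] says the
sample is far too small to pin the reliability down. Item 2's variance
(0.251) sits essentially at the dichotomous-item maximum N/(4(N−1)) — its
sampling distribution is skewed, the delta SE degenerates, and the row is
flagged `near-boundary` as a warning that the Wald interval is not to be
trusted there. A proportion of a dichotomous item at exactly 1/2 has no
variance SE at all; such cases raise a flagged boundary error and are
dropped (and counted) by the study harness.

`glance(fit)` summarises (N, k, alpha, its SE); `autoplot(fit)` draws the
coefficients with their intervals. CSV-file input works through
`analyze_file()`, or from a shell through the thin CLI in
`inst/cli/relcli.R` (`analyze`, `simulate`, `evaluate` subcommands).

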