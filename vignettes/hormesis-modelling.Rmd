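---
title: "Hormetic dose-response models with directly estimable effective doses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hormetic dose-response models with directly estimable effective doses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hormfit)
```

## The models

Hormesis is the biphasic response of an endpoint — here a continuous,
non-negative one such as root length — to a toxicant: stimulation at low
doses, inhibition at high doses. `hormfit` implements the two empirical
families most used for this pattern in plant biology, both built on the
log-logistic decay term $L(x) = \exp\{b(\ln x - \ln e)\} = (x/e)^b$:

$$\mu_{BC}(x) = c + \frac{d - c + f\,x}{1 + L(x)}, \qquad
  \mu_{CRS}(x) = c + \frac{d - c + f\,e^{-x^{-a}}}{1 + L(x)}.$$

Both reduce exactly to the monotone four-parameter log-logistic
$\mu(x) = c + (d-c)/(1+L(x))$ at $f = 0$, and both take the value $d$
(the untreated-control mean) in the limit $x \to 0$. In the
Brain–Cousens (BC) family $f$ is a stimulation rate (response per dose
unit); in the Cedergreen–Ritz–Streibig (CRS) family $f$ is an
upper-bound-type parameter in response units and the exponent $a > 0$
shapes how fast the stimulation switches on. Small $a$ gives an early,
broad hormetic zone; large $a$ a late, narrow one, possibly preceded by a
dip of the curve below $d$ (the *pre-hormetic drop*). $f > 0$ is
necessary for hormesis in either family.

Assumptions worth stating plainly: the endpoint is continuous with
additive, dose-level-specific Gaussian-like noise; replicates are
independent; the control (dose 0) is part of the design; and the
inhibitory branch is decreasing ($b > 0$). The BC family is known to
struggle with gently sloping or early-rising hormetic curves; the CRS
family with pre-hormetic toxicity — which is exactly why the package fits
and compares both.

## Weighting

Replicate spread in such bioassays grows with the mean, so responses are
variance-stabilized by weighting each observation with the inverse
standard deviation of its dose group (`compute_weights()`, scheme
`inverse_sd`); the fitted objective is $\sum_i w_i (y_i - \mu(x_i))^2$.
The weight enters as a multiplier of the squared residual. Because an
inverse-SD weight is not an inverse-variance weight, `inverse_variance`
is offered as well; `inverse_sd` is the default since it is the protocol
the models' applied literature uses. Both schemes require at least two
replicates per dose. A dose group with zero spread would get infinite
weight; by default its SD is replaced by the smallest positive per-dose
SD (logged), which preserves strong down-weighting without a singular
objective.

## Reparameterization: making ED_K, LDS and M parameters

The reported quantities of a hormetic curve are the dose of maximal
stimulation $M$, the response there $y_{max}$, the limited dose for
stimulation $LDS$ (where stimulation disappears), and effective doses
$ED_K$ (dose causing $K\%$ inhibition). None is a natural parameter. The
package constructs, for each target, a model in which it is:

- **ED_K / LDS** — the defining relationship "the mean at $x = ED_K$
  equals the target level" is linear in $d$. With the default
  `relative_to_control` convention the target level is $(1 - K/100)\,d$;
  with `relative_to_range` it is $c + (1 - K/100)(d - c)$. Writing
  $D = 1 + L(ED_K)$, $p = 1 - K/100$ and $s(\cdot)$ for the stimulation
  term ($s(x) = x$ for BC, $e^{-x^{-a}}$ for CRS), solving gives
  $d = \{c(1-D) - f\,s(ED_K)\}/(1 - pD)$ (control convention) or
  $d = c - f\,s(ED_K)/(1 - pD)$ (range convention). Substituting this
  back eliminates $d$; $ED_K$ becomes a free parameter. $LDS$ is the
  special case $K = 0$, where the two conventions coincide — as they do
  whenever $c = 0$, the constraint under which these assays are usually
  analysed.
- **M** — the stationarity condition $\mu'(M) = 0$ is linear in $f$:
  $f = (d-c)\,bL/M \,/\, (D - bL)$ for BC and
  $f = (d-c)\,bL/M \,/\, (s'(M)D - s(M)\,bL/M)$ for CRS, with everything
  evaluated at $x = M$. Substituting eliminates $f$; $M$ becomes free.

The same elimination ($d$ for ED/LDS, $f$ for M) is used for both
families. Which natural parameter is eliminated is immaterial up to
reparameterization: the package enforces *curve-set equivalence* — the
reparameterized mean evaluated at any admissible parameters is identical
to the natural mean with the implied parameter — in its test suite, and
cross-checks every direct estimate against an independent numeric oracle
(`effective_doses_numeric()`: golden-section-style bounded maximization
for $M$, bisection with geometrically expanded brackets for $LDS$ and
$ED_K$ on the inhibitory branch). Both routes must agree; on the
packaged synthetic bank they do to better than $10^{-6}$ relative, with
identical weighted SS_res to $10^{-12}$.

The reparameterized ED/LDS functions have more than one root when the
curve dips below $d$ before rising; the package always takes the
inhibitory-branch root (right of $M$) and reserves the pre-hormetic roots
for `pre_hormetic()` (below).

## Fitting

`fit_hormesis()` minimizes the weighted SS by Levenberg–Marquardt
(`minpack.lm::nls.lm`) under the constraints $c \ge 0$, $e > 0$, $a > 0$
(box bounds), with a central-difference Jacobian. Two practical
safeguards matter for these families:

- **Polishing.** BC and CRS fits produce long, curved valleys of
  strongly correlated parameters in which damped least squares can stall
  just short of stationarity — close enough for point estimates, too far
  for the natural and reparameterized coordinate systems to agree at
  tight tolerance. After LM convergence the engine therefore alternates
  a bounded quasi-Newton pass (`nlminb`) on the summed objective with LM
  restarts until the SS is stationary to $10^{-12}$ relative. The loop
  exits immediately when LM already converged fully.
- **Starting-value ladder.** Starts are deduced from the data the way a
  practitioner reads a raw-data graph: $d$ at the control mean, $c$ at
  0, $e$ at 0.8 times the dose whose mean is nearest half the control
  (slightly below the anticipated $ED_{50}$), $b = 2$, $f$ matched to
  the apparent maximum stimulation (0 if the means never exceed the
  control). If a fit fails, presets are retried — $f$ over a menu of
  \{0, 1, 10, 100\} scaled to the data's units (outermost), then $a$
  over \{0.1, 0.5, 1\}, then $b$ over \{1, 2, 3\} — and every attempt is
  recorded in the fit's `ladder_trace`. A converged fit with an inverted
  inhibitory branch ($b \le 0$) is treated as improper and the ladder
  continues; if nothing better exists it is returned with a warning.

Convergence uses relative tolerances of $10^{-10}$ on the SS and the
parameters with at most 1000 iterations (`hm_control()` exposes the
knobs). The covariance is $s^2 (J^\top W J)^{-1}$ with
$s^2 = SS_{res}/df_{res}$ and $J$ the Jacobian of the mean in the free
parameters at the optimum; a numerically singular $J^\top W J$ is
reported as rank deficiency naming the least-identifiable direction.

**The shape exponent a.** The CRS $a$ can rarely be estimated freely from
realistic designs. The default `a = "auto"` first tries free estimation
and, if the fit fails, is rank-deficient, or leaves $f$ without a finite
standard error, falls back to profiling: refitting with $a$ fixed at each
value of a grid over $[0.07, 1.75]$ (step 0.02, 85 values — the stated
range, discretized finely enough that the grid never binds before the
data do) and keeping the smallest-SS_res fit. A profiled or fixed $a$
does not count as an estimated parameter in the degrees of freedom. BC's
$b$ is deliberately *not* constrained to $b > 1$; a warning is emitted
when $\hat b \le 1$ with $\hat f > 0$.

## Inference

Intervals are Wald/t intervals, $\hat\theta \pm t_{df_{res}}\,SE$, the
default of the nonlinear-regression routines this methodology grew up
with (a knob switches to normal quantiles). Hormesis is significant when
the two-sided 95% CI for $f$ excludes zero with $\hat f > 0$ — a
two-sided interval used with one-sided interest, kept that way
deliberately rather than replaced by a one-sided test. The test works
identically on natural and ED/LDS-parameterized fits ($f$ stays free
there); an M-parameterized fit has $f$ eliminated and is not testable.

$y_{max}$ is the prediction at $\hat M$ with a delta-method standard
error. Because the curve is stationary at $M$, the gradient of
$\mu(M(\theta), \theta)$ reduces to the partial gradient at fixed dose
(envelope argument), so `y_max_estimate()` shares the
`predict_response()` code path exactly; the same argument covers the
relative form $100\,y_{max}/d$ with full covariance propagation.

**Pre-hormetic drop.** A CRS curve always dips below $d$ infinitesimally
near zero (the stimulation kernel is exponentially flat there while the
logistic decay is polynomial), so `pre_hormetic()` only reports a drop
when its relative depth exceeds `min_depth` ($10^{-4}$ by default) —
separating a structural dip from that mathematical artifact. The drop is
quantified by $M_{min}$ (dose of maximal drop), $y_{min}$ (absolute and
as % of $d$), and $LDS_{min}$ (where the drop disappears). Their
intervals exploit the multi-root structure: both $M_{min}$ and $M$ are
stationary points of the *same* fitted curve, so refitting the
M-parameterized model started at $M_{min}$ sits at the same optimum and
its covariance prices the pre-hormetic root; likewise the
LDS-parameterization at $LDS_{min}$. When such a refit escapes to the
main root, a delta-method fallback differentiates the implicitly defined
dose numerically (the `source` column records the route). The drop is
flagged significant when the CI of $100\,y_{min}/d$ excludes 100 — an
exploratory criterion, labelled as such in reports.

## Model comparison

`compare_hormesis_models()` fits both families and reports, per model:
the lack-of-fit F test (weighted decomposition
$SS_{res} = SS_{lof} + SS_{pure}$ about per-dose means, pure-error df
$n - \#doses$), the pseudo-R² $1 - SS_{res}/SS_{corrected}$ (a
descriptive index, flagged "with caution" — it can flatter visibly poor
hormetic fits), and $SS_{res}/df_{res}$. Across models it reports the
per-quantity relative bias $100(\hat\vartheta_2 -
\hat\vartheta_1)/\hat\vartheta_1$ with $\hat\vartheta_1$ from the
better-fitting model (better = significant hormesis first, then lower
$SS_{res}/df$), a CI-overlap screen (whether each model's interval
covers the other's point estimate — an *indication*, not a test, since
the rule does not hold a 5% error rate), and a four-case classification:

1. neither model shows significant hormesis;
2. only BC does, or both do and BC fits clearly better;
3. the CRS mirror image;
4. both significant with diagnostics inside configurable margins
   (|ΔPseudo-R²| < 0.01 and SS/df ratio within [0.9, 1.1] by default —
   the "marginal difference" thresholds are design choices exposed as
   knobs, since no canonical values exist).

Visual observed-vs-fitted agreement is a human judgment; its
reproducible surrogate here is a runs test on dose-ordered signed
residuals, recorded in the classification rationale rather than used as
a gate. When neither model shows significant hormesis the comparison is
assigned case 1 outright and the screen outcome is only annotated; the
classification is deterministic given fits and margins.

## The synthetic-data generator and what the experiments show

`simulate_dose_response()` emulates the structure of replicated
germination/elongation bioassays: a geometric dose series with an
untreated control (default \{0, 0.1, 0.3, 1, 3, 10, 30, 100\}), 5
replicates per dose, and Gaussian noise with per-dose SD proportional to
the local mean (5% of the control mean, floored at 1% of it) so the
inverse-SD weighting has something real to stabilize. The default truth
is a CRS curve with $b = 2$, $c = 0$, $d = 100$, $e = 10$, $f = 50$,
$a = 1$ — a mid-sized hormetic response (true $M = 2.35$,
$LDS = 6.55$, $ED_{50} = 13.9$, $y_{max} = 126$% of control). Negative
draws are truncated at zero, mimicking the measurement floor of a length
endpoint; truncations are counted and stay below 1% of observations
under the default scenario.

What the generator does *not* emulate: non-Gaussian or correlated
errors, plate/batch effects, non-constant replicate numbers, or real
chemistry — so passing experiments demonstrate the estimators' internal
consistency and calibration under the stated noise model, not robustness
to every feature of real bioassay data.

Three harnesses quantify behaviour at those conditions (sizes chosen to
give stable Monte-Carlo summaries at desk scale; each runs in minutes on
one CPU):

- `coverage_experiment()` — 300 simulations by default: generate,
  weight, fit the natural model, refit the ED_50 parameterization,
  record CI coverage of the truth and relative error. Observed: median
  |bias| near 1%, coverage near 95%.
- `type1_experiment()` — 500 simulations from an $f = 0$ (monotone)
  truth, fitting the BC family and applying the CI-excludes-zero rule.
  The BC family is the vehicle because the CRS exponent $a$ is
  unidentifiable at $f = 0$, which would confound a Wald calibration
  check. Observed rates sit well below the nominal 5% — the Wald
  interval for $f$ is conservative at these sample sizes.
- `misspecification_experiment()` — data from a broad-hormesis CRS truth
  ($a = 0.25$, otherwise the default) fitted by BC; effective doses of
  the fitted curve are extracted by the numeric oracle and compared to
  the truth functionals. The hormetic-zone quantities, $M$ above all,
  take far larger bias than $ED_{50}$ (an order of magnitude in the
  median) — the quantitative echo of why model choice matters most for
  exactly the quantities hormesis studies care about.

All experiments derive per-simulation seeds as `seed + i`, making every
run reproducible from its configuration.

## Numerical choices and limitations

- The logistic exponent is clamped at ±700 before exponentiation and the
  CRS kernel is evaluated in log space, so extreme $b$, doses spanning
  hundreds of decades, or tiny $a$ cannot produce non-finite responses.
  Dose 0 is always evaluated as the analytic limit $d$, never by
  perturbation.
- Dose levels differing by less than $10^{-9}$ relative are merged at
  the data layer.
- Root brackets for $LDS$/$ED_K$ start at $(M, 10e]$ and expand tenfold
  up to $10^6 e$; absence of a sign change there is reported as a
  root-not-found error rather than silently capturing a wrong root.
- $c \le d$ is a warning, not an error; bounds are enforced only where
  the model is undefined without them.
- The t-vs-normal choice for $y_{max}$ intervals and the exact
  convergence tolerances are exposed as knobs; defaults are stated
  above.
- Known limitations: no 5-parameter log-logistic, Weibull, or
  switching-function alternatives; no binomial/count endpoints; no
  mixed-effects structure; profile-likelihood intervals and simultaneous
  bands are out of scope. Where both families fit poorly (e.g. extremely
  steep inhibition with only one or two stimulated doses), the honest
  output is case 1 of the comparison — neither model suitable — rather
  than a forced estimate.
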