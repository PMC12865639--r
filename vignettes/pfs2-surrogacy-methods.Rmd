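---
title: "Trial-level surrogacy of PFS2 for overall survival: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-level surrogacy of PFS2 for overall survival: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Overall survival (OS) is the definitive endpoint of oncology trials, but in
metastatic breast cancer — where patients receive many lines of therapy and
survive for years — mature OS data arrive long after a trial reads out its
progression endpoint. Progression-free survival 2 (PFS2), the time from
randomization to progression on the *next* line of therapy or death, has been
proposed as an intermediate endpoint that captures part of the
post-progression treatment history while maturing much earlier than OS.

`pfs2surr` evaluates whether treatment effects on PFS2 (or conventional PFS1)
predict treatment effects on OS *at the trial level*: across a collection of
randomized trials, does the hazard ratio (HR) for the surrogate track the HR
for OS? No patient-level data are used anywhere; the unit of analysis is the
published trial summary.

## The model

For trial $i$ with observed hazard ratios $\mathrm{HR}^{\mathrm{PFS2}}_i$ and
$\mathrm{HR}^{\mathrm{OS}}_i$, write $x_i = \ln \mathrm{HR}^{\mathrm{PFS2}}_i$
and $y_i = \ln \mathrm{HR}^{\mathrm{OS}}_i$. The surrogacy model is the
weighted linear regression

$$ y_i = \beta_0 + \beta_1 x_i + \varepsilon_i, $$

with weights $w_i$ equal to the total number of randomized patients in trial
$i$ and $(\beta_0, \beta_1)$ minimizing $\sum_i w_i (y_i - \beta_0 - \beta_1
x_i)^2$. Natural logarithms are used throughout; the base cancels in the
correlation and $R^2$ and only rescales the slope, but it must be fixed for
slopes to be comparable. Association strength is summarized by

* the sample-size-weighted Pearson correlation $r_w$, computed from weighted
  central moments;
* $R^2 = r_w^2$, the share of between-trial variance in the OS effect
  explained by the surrogate effect ($R^2 \ge 0.7$ is the conventional
  trial-level surrogacy threshold in oncology);
* a two-sided $t$-test for the slope on $n - 2$ degrees of freedom.

All weighted statistics are invariant to rescaling the weights by a positive
constant (an identity the test suite enforces to $10^{-12}$), so "total
randomized patients" needs no normalization convention. The slope standard
error uses the weighted residual sum of squares on $n-2$ degrees of freedom;
because the residual variance estimate and the weighted spread of $x$ scale
together in the weights, the $t$-statistic is weight-scale invariant too.

### Bootstrap confidence interval for $r_w$

The 95% CI for $r_w$ resamples *trials* — triples $(x_i, y_i, w_i)$ jointly —
with replacement, recomputes $r_w$ per replicate, and takes percentile
bounds. Design choices, made once:

* **Percentile method, 2000 replicates by default.** BCa or normal-theory
  intervals are plausible alternatives; percentile is the simplest method
  whose bounds respect the $[-1, 1]$ range after clamping, and the only one
  that reproduces degenerate printed intervals such as "CI $-1$ to $1$" at
  subgroup sizes of 3–5 trials.
* **Degenerate replicates** (a single distinct trial drawn $n$ times, giving
  zero weighted variance) are discarded and counted, not retried; retrying
  would bias the replicate distribution toward high-variance draws.
* **A seed is mandatory**, and resampling happens after sorting trials by
  identifier, so the CI is independent of input row order.

At $n = 15$ the percentile interval is known to undercover slightly: the
package's own calibration experiment (150 simulated trial sets per seed,
low-estimation-noise regime, population correlation 0.714) measures coverage
near 0.90–0.93 against a nominal 0.95. The property test therefore asserts
coverage within $[0.85, 0.995]$ plus two-seed agreement rather than exact
nominal coverage; users should read small-$n$ bootstrap CIs as rough
uncertainty statements.

### Classification rules

Two rule sets label each analysis:

* **Strength bands** on the point correlation: $r < 0.5$ poor-to-fair,
  $0.5 \le r \le 0.7$ moderate, $r > 0.7$ strong. Both boundaries are closed
  into "moderate" (the band is stated as a range 0.5–0.7). The bands apply to
  the *signed* $r$ — no absolute value — so a strongly negative correlation
  reports "poor_fair"; because the banding literature never labels negative
  correlations, results flag negative $r$ prominently instead of inventing a
  band for them.
* **IQWiG validity** on the CI: valid if the lower 95% bound is $\ge 0.85$,
  invalid if the upper bound is $\le 0.70$, inconclusive otherwise.

$p$-values are two-sided at 0.05 with no multiplicity adjustment, matching
standard practice in trial-level surrogacy reports, which present each
subgroup analysis as exploratory.

## Maturity, information fraction, and stratification

*Maturity* is observed events divided by intention-to-treat patients;
*information fraction* is observed events divided by the protocol-planned
event count for the final analysis. The information fraction legitimately
exceeds 1 when an analysis occurs after the planned count is surpassed, and
is never clamped. Both are stored as exact quotients; rendering to the
printed percentage uses three significant figures (39/315 prints 12.4;
171/152 prints 112).

Subgroup analyses split trials at fixed thresholds: PFS2 maturity at 55%, OS
information fraction at 75%, OS maturity into $<40\%$ and 40–60%, control-arm
crossover exposure into 0–30% and 30–50%, and treatment line by whether PFS2
reflects progression on second-line versus later-line therapy (derived from
prior lines at study entry: previously untreated patients progress onto
second-line therapy, so their PFS2 is a second-line endpoint). Conventions
decided once and documented:

* Boundary values land in the closed-upper stratum ("$<55\%$ versus
  $\ge 55\%$").
* The OS-maturity criterion defines no stratum above 60%; such trials are
  logged as unassigned rather than silently pooled.
* The crossover boundary at exactly 30% is ambiguous in the "0–30% versus
  30–50%" phrasing; the lower stratum is closed at 30% ($[0, 0.30]$,
  $(0.30, 0.50]$).
* Trials missing the criterion value are excluded from that stratification
  and logged — never imputed.
* Strata with fewer than 3 analyzable trials are reported as "insufficient
  trials", not fitted.
* Per-stratum bootstrap seeds derive as base seed + stratum index, so a
  stratified table is reproducible as a whole.

## Secondary analyses

* **Long-term OS validation** reruns the engine with the long-term follow-up
  OS hazard ratio as the true endpoint, restricted to trials reporting one.
* **Drift**: for trials with OS at both cuts, $\Delta \ln \mathrm{HR_{OS}} =
  \ln \mathrm{HR^{long}_{OS}} - \ln \mathrm{HR^{init}_{OS}}$ is correlated
  (Spearman) with $\ln \mathrm{HR_{PFS2}}$; a negative $\rho$ means trials
  with larger PFS2 benefit saw their OS effect attenuate at follow-up.
* **Arm-level medians**: median PFS2 versus median OS across all arms
  (Spearman), plus the per-arm distribution of the ratio median PFS2 /
  median OS. The "median ratio" is the across-trial median of per-trial
  ratios — the phrasing "the median ratio was 0.60, with values ranging..."
  implies a distribution of per-trial ratios — with the ratio-of-pooled-
  medians alternative deliberately not used. Counting trials whose PFS2
  median fell in the earlier half of the OS timeline uses a strict
  $< 0.50$ rule; a tie at exactly 0.50 does not count.
* **Subtypes**: the same engine restricted to one breast-cancer subtype.
  Initial OS is the true endpoint (the long-term alternative is available via
  the ordinary engine); with exactly 3 trials the result carries an
  insufficient-precision warning, and below 3 it is an error.
* **Spearman's $\rho$** uses average ranks for ties and an exact permutation
  $p$ for $n \le 9$ (subgroup sizes here are tiny, where the large-sample
  approximation is poorest), the asymptotic approximation otherwise.

## Leave-one-out sensitivity

Each analyzable trial is excluded in turn and the full engine rerun on the
remainder. The report collects per-iteration $r$, $R^2$, slope and slope $p$,
their extrema, and two robustness flags (every $r > 0$; every $p < 0.05$).
Per-iteration bootstrap seeds derive from the base seed plus a stable string
hash of the left-out trial identifier, making the report independent of
iteration order. Bootstrap CIs are computed per iteration but the headline
table shows point estimates and $p$-values, which is how such sensitivity
analyses are conventionally tabulated.

## The synthetic generator

`generate_trials()` draws trial sets with known ground truth so every
estimator in the package can be validated without external data. Structure:

1. Latent effects: $x^*_i \sim N(\mu_x, \tau^2)$,
   $y^*_i = \beta_0 + \beta_1 x^*_i + N(0, \sigma^2)$ — the surrogacy model
   itself, with between-trial spread.
2. Observation: each log HR is the latent value plus
   $N(0, (2/\sqrt{\text{events}})^2)$ noise — the standard large-sample
   approximation to the standard error of a log hazard ratio in a 1:1 trial,
   applied to total events even for 2:1 trials (a documented
   simplification). CIs are estimate $\pm 1.96$ SE, exponentiated. Trials
   drawing fewer than 5 events are redrawn and counted.
3. Long-term OS: the latent OS effect shrunk toward zero by
   (attenuation $\times$ crossover proportion), re-observed at long-term
   event counts — encoding the hypothesis that control-arm exposure to the
   experimental agent class dilutes the long-term OS benefit. PFS2 itself is
   not attenuated.
4. Medians: arm medians consistent with the hazard ratio under an
   exponential proportional-hazards approximation (median ratio $= 1/$HR),
   with control OS medians uniform on 20–40 months and PFS2/OS ratios
   uniform on 0.45–0.85.
5. Missingness: optional fields deleted completely at random at a configured
   rate, HR triplets jointly (a CI never survives its point estimate). Real
   missingness in the literature is publication-driven, not random; the
   generator does not model that, so passing tests say nothing about
   informative missingness.

Defaults are the observed conditions of recent metastatic breast-cancer
RCTs: total N 112–1050 per trial, OS maturity 12.4–59.5%, PFS2 maturity
27–82.4%, OS information fraction 24–157%, long-term OS for 10/18 of trials,
crossover 0–48%, and a 2:1 randomization probability of 0.4. The effect
model defaults to $\beta_1 = 0.53$, $\tau = 0.25$, $\sigma = 0.13$, $\mu_x =
\ln 0.65$, placing the *latent* trial-level correlation
$\beta_1\tau/\sqrt{\beta_1^2\tau^2 + \sigma^2}$ at $\approx 0.71$ — the
regime a moderate-to-strong surrogate produces. Note that the *observed*
correlation centers below the latent one, because estimation noise in both
axes attenuates it; that attenuation is exactly the errors-in-variables
phenomenon the validation experiments quantify
($\lambda = \tau^2/(\tau^2 + \bar v)$ for weighted mean noise variance
$\bar v$), and it is why small, immature trials weaken apparent surrogacy
even when the underlying relationship is strong.

`paperlike_fixture()` post-processes an 18-trial draw into the shape of the
target literature — exactly 15 trials with complete (PFS2, OS) HR pairs,
10 with long-term OS, at least one information fraction above 100% — for
end-to-end demonstrations. It is synthetic and named accordingly; it stands
in for, and must not be confused with, a transcription of published trial
results.

## Numerical and reproducibility choices

* Degenerate inputs (zero weighted variance) raise errors; nothing silently
  returns 0 or NA.
* Fits with fewer than 3 trials are refused ("insufficient trials");
  leave-one-out needs 4.
* All RNG flows through explicit seeds; seed derivations stay below
  $2^{31}$; RNG state of the caller is saved and restored, so library calls
  do not perturb user scripts.
* Reports are pure functions of (input table, configuration): reruns are
  byte-identical, machine-readable JSON carries full precision, and the text
  rendering rounds to 3 decimals / 3 significant figures for display.
* Problem sizes used by the validation suite: 500 replicates of 15 trials
  for slope-recovery experiments; 150 simulated sets per seed (two seeds,
  400 bootstrap replicates each) for CI calibration; 1200 trials for
  generated-CI coverage. These sizes put Monte-Carlo error well below the
  effect sizes being checked while keeping the default test run fast.

## Known limitations

* Trial-level analysis only: patient-level surrogacy (e.g. copula or
  bivariate survival models) is out of scope, as it is for any analysis of
  published summaries.
* No adjustment of long-term OS effects for crossover (RPSFT, IPCW): the
  methodology evaluates published, unadjusted HRs and treats crossover as a
  stratification factor instead.
* Bootstrap CIs at subgroup sizes of 3–5 trials routinely span $[-1, 1]$;
  they are reported as computed, with the insufficient-precision warning at
  $n = 3$.
* The weighted regression weights by sample size, not inverse variance of
  the log HR; this follows the established surrogate-validation convention
  the package implements, but readers should note the two differ when event
  fractions vary widely across trials.
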