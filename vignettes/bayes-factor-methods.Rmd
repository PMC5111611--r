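---
title: "Methods: Bayes factors for trial summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayes factors for trial summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfrct)
```

## The model

Everything in this package rests on one summary-statistic model: a
published effect estimate $\hat\theta$ (a mean difference, or the natural
log of an odds/risk/rate ratio) is treated as normally distributed about
the true effect $\theta$ with known standard deviation equal to its
standard error $se$. The Bayes factor contrasts a point null
($\theta = 0$) with an alternative under which $\theta$ follows a prior
$\pi$:

$$
BF \;=\; \frac{\int N(\hat\theta;\,\theta,\,se)\,\pi(\theta)\,d\theta}
             {N(\hat\theta;\,0,\,se)} .
$$

The normal-likelihood assumption is standard for trial summaries but is
an approximation: it requires reasonably large arms and, for 2x2 tables,
no very small cells (which is why `se_log_or_from_counts()` rejects zero
cells outright rather than applying a continuity correction).

## Priors and the orientation convention

Three prior shapes are supported.

* **Half-normal** (`prior_halfnormal(sd)`) — peak at 0, folded onto the
  predicted direction of benefit, with `sd` set to the *expected effect
  size* taken from earlier studies or judgement. This encodes "some
  effect in the predicted direction, smaller effects more likely" and is
  the deliberately conservative default. On $\theta \ge 0$ its density is
  $2N(\theta; 0, sd)$.
* **Normal** (`prior_normal(mean, sd)`) — the two-sided generalisation;
  included for completeness, integrated over the whole line.
* **Uniform** (`prior_uniform(lower, upper)`) — for the case where a
  minimally important effect and a plausible ceiling can both be stated.

The half-normal is one-sided, so a direction convention is needed. The
package requires the estimate to be *magnitude-oriented*
(`effect_estimate(value, se, oriented = TRUE)` with `value >= 0`):
the observed effect is entered as its absolute distance from the null on
the analysis scale, with the prior living on the predicted-benefit side.
`to_analysis_scale()` applies this automatically — including when the
observed effect points *against* the prediction. Folding an opposing
effect onto the predicted side is not the only defensible choice (one
could instead keep the sign and let the one-sided prior penalise it), but
it is the convention under which the packaged re-analysis reproduces its
published Bayes factors, e.g. the trial with observed OR 0.51 against a
predicted OR 1.51 giving BF 1.8. Users who prefer the signed convention
can pass a signed value with a two-sided `prior_normal()`.

The prior SD itself comes from `prior_sd_from_prediction()`:
$|{\rm prediction}|$ for mean differences, $|\ln({\rm prediction})|$ for
ratio measures. A prediction equal to the null value (MD 0, ratio 1) is
rejected — it would collapse the alternative onto the null. One record in
the packaged fixture has exactly this defect (a sensitivity prediction of
RR 1.00); its Bayes factor is reported as `NA` with a note rather than
being fudged.

## Effect-scale conversions

Ratio measures are analysed on the natural-log scale, where their
sampling distribution is approximately normal. Standard errors are
resolved, in order of preference, from: the reported SE (taken to be on
the log scale for ratio measures), a 95% CI
($({\rm transformed\ upper} - {\rm transformed\ lower})/3.92$ — the
divisor is the conventional 3.92, not $2 \times 1.959964$), a t statistic
($|{\rm effect}/t|$), 2x2 counts ($\sqrt{1/a+1/b+1/c+1/d}$), or group
SDs and sizes ($\sqrt{sd_1^2/n_1 + sd_2^2/n_2}$ — with the square root,
the standard formula, even though summary-statistic write-ups sometimes
print the variance sum without the radical).

## Numerical evaluation

The marginal likelihood is evaluated two independent ways:

* **Quadrature** (`method = "quadrature"`, the default):
  `stats::integrate()` at relative tolerance $10^{-8}$. For
  normal-family priors the integrand is an (unnormalised) normal density
  in $\theta$ centred at the posterior mean with the posterior SD, so the
  integration range is that centre $\pm 12$ posterior SDs clipped to the
  prior's support — the spike is always resolved, however narrow the
  prior or the likelihood. The integrand is rescaled by its value at the
  mode and the result assembled in logs.
* **Closed form** (`bf_halfnormal_closed()`, `bf_uniform_closed()`, and
  the normal-prior convolution): exact expressions used as oracles in the
  tests, where the two routes are required to agree to $10^{-6}$ relative
  error over 1,000 random (value, se, sd) triples with scales spanning
  four orders of magnitude.

All ratios are formed in log space. An effect many standard errors from
the null has a null likelihood that underflows double precision, and a
Bayes factor that can *overflow* it; `bayes_factor()` therefore carries
`log_bf` alongside `bf`, and the closed form takes `log = TRUE`.
Degenerate input $se = 0$ is rejected rather than treated as a point
likelihood. The Bayes factor is scale-invariant (multiplying value, se
and all prior scales by $c > 0$ changes nothing), which the tests assert
to $10^{-9}$.

## Evidence classification

`threeway()` implements the working rule: `supports_effect` iff
$BF > 3$, `supports_null` iff $BF < 1/3$, otherwise `insensitive`.
`jeffreys_band()` implements the full eleven-band scale with boundaries
at $1/100, 1/30, 1/10, 1/3, 1, 3, 10, 30, 100$; bands are left-closed
and right-open on the BF axis (a BF of exactly 3 is already "moderate
evidence"), with exactly 1 its own "no evidence" point.
`direction_subclass()` splits the insensitive zone by which hypothesis
the data lean toward, judged **on the 1-decimal rounded value**: the
published tallies this package reproduces count four Bayes factors as
exactly 1, which can only happen at reporting precision.

One genuine inconsistency surfaced while reproducing the published
summary counts from the fixture's published Bayes factor columns: the
all-effects tally (11 / 42 / 22) requires the two effects printed as
BF 3.0 to count as supporting the effect, while the non-significant
subset tally (11 / 42 / 2) requires the one non-significant BF 3.0 to
count as insensitive. No single boundary convention reproduces both.
`bf_tally()` therefore exposes the boundary handling per tally
(`boundary_all = "inclusive"`, `boundary_subset = "exclusive"` by
default, matching the published counts) rather than silently picking one.

## The packaged fixture and its flags

The fixture transcribes 75 effect estimates from 12 addiction RCTs: per
effect, the measure type, observed value, SE, printed p value, a main
expected effect and two sensitivity predictions, and the three published
Bayes factors (1 decimal). Significance is parsed strictly
($p < 0.05$; "> 0.05" and "0.06" are non-significant), giving 55
non-significant and 20 significant effects.

`reproduce_trials()` recomputes all 225 (record, prior) pairs and
compares them with the published values at tolerance
$\max(0.1\ {\rm absolute},\ 1\%\ {\rm relative})$. Two groups of rows are
flagged and excluded from the agreement criterion because their input
conventions cannot be recovered:

* `scale_ambiguous` — the entire block from the web-based alcohol
  screening trial (four rate-ratio and two odds-ratio effects). Its
  printed BF 17.5 row recomputes to about 19.0 under a raw-scale entry
  and 28.4 under a log-scale entry; its OR rows are similarly
  irreproducible under every convention tried (19.0 printed vs 23.5 log /
  7.2 raw). Both conventions' outputs are reported (`computed` is the
  log-scale value, `bf_raw` the raw-scale one) so the ambiguity is
  visible rather than fitted.
* `unit_mismatch` — the four clinic-retention effects whose observed
  values are on the proportion scale (about 0.003) while their
  predictions are in percentage points (5–10). Tiny either way, their
  published BFs of 0.00–0.01 are insensitive to the mismatch, but the
  units cannot be harmonised from the printed record.

With those flags, 90.3% of the 195 unflagged pairs agree within
tolerance. The residual disagreements are themselves informative: the
legacy grid calculator used for the published values diverges from
high-precision quadrature by a few percent for large Bayes factors
(e.g. 120.0 printed vs 140.1 recomputed), and a handful of
sensitivity rows with predictions opposing the observed direction only
reproduce under an un-oriented entry. The tallies, by contrast, are
computed from the published BF columns and reproduce every summary count
exactly — classification logic and engine conventions are deliberately
decoupled.

## The synthetic-trial generator

`trial_scenario()` emulates the one thing the engine consumes: two-arm
trial summaries. Continuous outcomes are i.i.d. normal per arm (the trial
reports the difference in sample means and its SE from sample SDs);
binary outcomes are binomial per arm with the treated rate shifted on the
log-odds scale (the trial reports the sample log OR with its 2x2-count
SE; tables with a zero cell are redrawn and the redraw count recorded,
mirroring the engine's refusal to continuity-correct).

It deliberately does *not* emulate dropout, covariate adjustment,
clustering, overdispersed counts or skewed outcomes. Passing tests
therefore show that the Bayes-factor machinery behaves correctly for
clean normal/binomial summaries, not that the normal approximation is
adequate for any particular messy real trial.

Default study conditions used in the package's own simulations were
chosen once as typical of the addiction-trial literature the fixture
comes from: arms of 50–500 participants, unit outcome SD, control event
rates around 0.3, true effects of 0 (null) or about half an outcome SD
(log OR about 0.4 for binary), and half-normal priors scaled to the true
effect. Operating characteristics use 300–2,000 Monte-Carlo replicates
and sequential monitoring 40 replicate trials with batches of 25–50 up
to 200–500 per arm — sizes at which the asserted orderings (futility
crossings dominate under the null; the probability of $BF > 3$ grows
toward 1 with $n$ under a real effect; efficacy stops dominate under a
strong effect) are stable across seeds. Simulation helpers default to
the closed-form path, which the oracle tests prove equivalent to
quadrature at $10^{-6}$.

`sequential_bf_monitor()` implements the proposed use of the Bayes
factor as a stopping rule: recruit in batches, recompute the BF at each
look, stop at $BF > 3$ (efficacy) or $BF < 1/3$ (futility), continue
while insensitive, up to a cap. Looks happen only at batch boundaries
and no multiplicity correction is applied across looks — the Bayes
factor at each look is simply the current evidence. A binary-outcome
look whose cumulative table still has a zero cell is skipped.

## Known limitations

* The normal-likelihood model is the whole story: no exact binomial or
  survival likelihoods, no JZS/default-prior t-test Bayes factors, no
  hierarchical modelling.
* The magnitude-orientation convention folds opposing effects onto the
  predicted side; see above for the alternative.
* Published-value agreement is bounded by the legacy calculator's grid
  resolution; exact bit-reproduction of that calculator is not attempted.
* The flagged fixture rows are transcribed faithfully but cannot be
  independently recomputed from the printed record.
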