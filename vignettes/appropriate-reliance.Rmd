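---
title: "Quantifying appropriate reliance on fallible AI advice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying appropriate reliance on fallible AI advice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relianceSDT)
```

## The analysis in one paragraph

A two-session classification experiment measures the same people once
without and once with scripted AI advice on the same stimuli. Because the
advice schedule is known (a Wizard-of-Oz design with blocked Bernoulli
advice correctness), every advised trial is labelled correct or incorrect,
and the change in each participant's sensitivity from Session 1 to
Session 2 can be split by advice correctness. That split is the package's
central quantity: an improvement on correctly advised trials together with
no loss on incorrectly advised trials is *appropriate* reliance; an
improvement bought at the price of a marked loss on incorrect advice is
*general* (indiscriminate) reliance. Sensitivity is estimated with a
hierarchical Bayesian equal-variance SDT model so that the uncertainty of
every participant- and group-level estimate — which differs strongly
between the large correct-advice and small incorrect-advice trial cells —
is carried through to the final difference posteriors.

## The hierarchical SDT model

For participant *i* in analysis cell *g* (condition, optionally crossed
with phase or advice correctness), with $n_s$ signal and $n_n$ noise
trials, hits $H_i$ and false alarms $F_i$:

$$h_i = \Phi(D_i/2 - C_i), \qquad f_i = \Phi(-D_i/2 - C_i)$$
$$D_i \sim \mathrm{Normal}(D_{\mu,g},\ \lambda_D), \qquad
  C_i \sim \mathrm{Normal}(C_{\mu,g},\ \lambda_C)$$
$$D_{\mu,g} \sim \mathrm{Normal}(0,\ 1.9), \qquad
  C_{\mu,g} \sim \mathrm{Normal}(0,\ 0.95), \qquad
  \lambda_D, \lambda_C \sim \mathrm{Gamma}(0.001,\ 0.001)$$

The second arguments of the group-mean priors are standard deviations;
$\lambda_D$ and $\lambda_C$ are precisions of the participant-level
Gaussians. The scales are justified by the theoretical range of the
estimates: with at most 108 hits and 108 false alarms and the log-linear
correction (add 0.5 to each frequency, 1 to each total), corrected rates
lie in $[0.5/109,\ 108.5/109]$, so $|d'| \le 5.21$ and $|c| \le 2.61$, both
within three prior SDs ($3 \times 1.9 = 5.7$, $3 \times 0.95 = 2.85$).

Model assumptions worth stating plainly:

* **Equal-variance Gaussian evidence.** One sensitivity and one additive
  criterion per participant-cell; no unequal-variance or ROC variants.
* **Likelihood on corrected frequencies.** The binomial kernel is
  evaluated at the corrected frequencies and totals (so the observables
  are the corrected counts, not the raw ones). Since corrected counts are
  half-integers, the log-likelihood enters JAGS through the Poisson zeros
  trick rather than `dbin`. A practical consequence, verified in the
  tests: for a single participant under diffuse group priors the posterior
  mean reproduces the closed-form point estimate
  $d' = \Phi^{-1}(h^*) - \Phi^{-1}(f^*)$ to within Monte-Carlo error.
* **Two independent precisions.** The prior line for $\lambda_D$ and
  $\lambda_C$ could be read as one shared parameter; we use two
  independent ones, one per parameter family, shared across group cells.
* **One model per session.** Session 1 and Session 2 are fitted
  separately (Session-1 participants grouped by their eventual
  condition), and d′ differences are formed by pairing posterior draws at
  equal index after pooling chains. The two posteriors are independent,
  so only marginal summaries (mean, HDI) of the difference are
  interpreted, not draw-wise joint statements.
* **Signal designation.** One stimulus category is designated "signal"
  throughout. A consistent global swap leaves d′ (and all d′ differences)
  unchanged and flips the sign of c; this is asserted in the test suite.

MCMC uses 4 chains of 10,000 draws with the first 2,000 discarded as
tuning (8,000 retained per chain) by default. Convergence is flagged by
split-$\hat R > 1.01$ on any group-level parameter (bulk ESS is also
reported); a non-converged fit is returned with a warning rather than
discarded. Chains are initialized at the closed-form point estimates.
Cells with zero trials on one side (possible in the small incorrect-advice
strata of short designs) are excluded from the fit with a warning naming
the participant and cell, rather than imputed.

## Reliance metrics

The **acceptance rate** is the share of advised trials whose final
decision equals the advice. The **switch percentage** conditions on
disagreement: among advised trials whose stimulus-paired Session-1
decision differed from the advice, the share where the Session-2 decision
equals the advice. Pairing is by participant × stimulus identity — the
definition presupposes a per-stimulus unadvised decision, which the
two-session design supplies and the simulator guarantees; identically
shaped real data must provide a stimulus key. Contingency tables carry
explicit margins computed by summing cells, so margin consistency is
auditable; cells with empty denominators are reported as undefined rather
than dropped. Rates are stored at full precision and displayed at 2
decimals.

One documented inconsistency in published tables of this design: a pooled
switch table can label its switched/not-switched columns in reverse of
the cell-level table it aggregates. The implementation follows the verbal
definition (numerator = switched to the advice) and the cell-level
convention everywhere.

## The self-report regression

Trust, distrust and advice-use ratings (1–7 Likert) at five time points
are modelled as Gaussian:
`rating ~ Condition * queryCount + (1 | participant)`, fitted by MCMC.
Treating Likert ratings as metric is a deliberate simplification — the
coefficient scale of the published analyses implies it, and an ordinal
model is out of scope.

The time-point factor enters through the planned contrast weights
(rows: $(-1,1,0,0,0)$, $(-1,-1,2,0,0)$, $(0,0,2,-1,-1)$, $(0,0,0,1,-1)$).
The rows sum to zero but are *not* mutually orthogonal (rows 2 and 3
overlap; their dot product is 4, a property of the printed weights that
the tests assert rather than "fix"). Weights are therefore mapped to
design columns through the Moore–Penrose generalized inverse — the
standard convention for user-supplied contrast matrices — under which each
fitted coefficient equals exactly its weighted combination of time-point
means (verified in a noiseless test). Condition is a 0/1 indicator with
information-only = 1, so a positive Condition coefficient means higher
ratings in the information-only condition; an uncontrasted categorical
coding of the time points is also available because the published
Condition row came from an analysis without contrasts whose coding is not
stated.

Priors are weakly informative relative to the 1–7 scale:
Normal(0, 5) on all fixed effects, half-Normal(0, 5) on the
random-intercept SD and residual SD. The SD priors are truncated below at
$10^{-3}$ purely so that degenerate constant-response inputs remain
sampleable; with any real variation the truncation is inert. A coefficient
is read as supported when its equal-tailed 95% credible interval excludes
zero; summaries report Estimate, Est.Error (posterior SD) and the CI in a
fixed row order.

## What the synthetic cohort emulates — and what it does not

`simulate_experiment()` generates the full design: 131 participants split
evenly at random over the distrust / information-only conditions,
216 unadvised Session-1 trials, nine Session-2 blocks of 24 trials with
advice-correctness probabilities (0.9, 0.9, 0.9 | 0.75, 0.60, 0.45 | 0.9,
0.9, 0.9) forming pre-error, error and post-error phases, the same 216
stimulus identities in both sessions (50% signal, exactly balanced within
each Session-2 block to stabilize small cells), and trust/distrust/use
ratings after blocks 2, 4, 6, 8 and 9.

The response mechanism is the minimal model consistent with the SDT
analysis: an equal-variance Gaussian observer (evidence
$\mathcal{N}(\pm d'/2, 1)$ against criterion $c$ — the exact inverse of
the model's reparametrization) produces an own judgment; if shown advice
conflicts with it, the advice is adopted with a participant-specific
probability (the *adoption weight*), otherwise the own judgment stands.
This produces distinct acceptance/switch signatures for over- and
under-reliance: adoption weight 0 reduces Session 2 to the unadvised
observer, adoption weight 1 makes every advised decision equal the advice.

Generator defaults (all overridable in `profile_params()`): unadvised d′
$\sim \mathcal{N}(0.95, 0.8)$ matching the reported Session-1 cohort
distribution; criterion $\sim \mathcal{N}(0, 0.4)$; Session-2 practice
gain 0 (the mechanism exists because advised-session unaided skill can
exceed Session 1's, but the neutral default attributes all improvement to
advice); adoption weight Beta with mean 0.4 and concentration 10, between
the values implied by published acceptance rates on correct (~0.53) and
incorrect (~0.20) advice — a single trial-independent weight cannot
reproduce both, which is itself informative: real participants partially
discriminate advice quality, the stand-in generator does not. Self-report
trajectories are a step: baselines (trust 4.5, distrust 3.0, use 4.5,
between-participant SD 1 on the latent scale) until the error phase has
been fully experienced — time point 3 under the default schedule — then a
persistent drop in trust and rise in distrust of mean 0.5 points (SD
0.25), with the use item dipping only transiently; Gaussian noise (SD 1)
is added and the latent value rounded and clamped to 1..7. The
round-and-clamp discretization was chosen over an ordered-threshold model
as sufficient for a stand-in generator.

Consequently, passing recovery tests show that the pipeline correctly
estimates what this generative world contains: SDT-consistent responses, a
constant adoption policy, a step-shaped self-report trajectory. They do
not certify behavior absent from it — trial-order learning, fatigue,
advice-quality discrimination, reaction times, certainty, ordinal
threshold effects, or the lab/online and scenario sub-structure of real
cohorts (a scenario label can be carried as an extra column but no
analysis in scope distinguishes it).

## Numerical choices and reproducibility

* Log-linear correction applied once, at tabulation boundary; rates are
  then strictly inside (0, 1) and `sdt_invert()` refuses anything else.
* JAGS `phi()` is clamped to $[10^{-12}, 1-10^{-12}]$ inside the
  likelihood to keep logs finite for extreme latent values.
* The highest-density interval uses the sorted sliding-window estimator
  (ties broken by the first minimal window); it agrees exactly with
  `coda::HPDinterval` and is tested against Gaussian closed forms. For
  skewed posteriors it is narrower than the equal-tailed interval.
* All randomness is seed-controlled. `run_pipeline()` derives per-stage
  seeds from the master seed by a fixed Lehmer step
  ($s_k = (48271\,s + k) \bmod (2^{31}-1)$), so stages can be re-run in
  isolation and a full run is byte-reproducible apart from manifest
  timings. The reduced MCMC profile (2 chains × 1,500 draws, 500 tuning)
  is a named profile, never a silent substitution.
* Problem sizes in the shipped tests are scaled for a desk machine:
  recovery studies use 20 replications at 40 participants per condition
  with 4 chains × 2,000 draws (SDT) and the full 131-participant design
  with 2 chains × 2,500 draws (regression); oracle-equivalence checks use
  8,000 retained draws. The full 4 × 10,000/2,000 configuration remains
  the package default for real analyses.

## Known limitations

* Gaussian treatment of Likert ratings; no ordinal/cumulative-link models,
  no Bayes factors, no model comparison — deliberately out of scope.
* The d′-difference pairs independent session posteriors; statements
  about the joint distribution of the two sessions' parameters are not
  supported.
* Group cells need at least two participants for the hierarchical means
  to be meaningful; the fit warns otherwise.
* The simulator's adoption mechanism is advice-quality-blind; effects
  that depend on participants detecting advice quality cannot be
  generated, only measured on real data of the same shape.
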