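---
title: "Methods: simulating and analysing connectivity neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing connectivity neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnf)
```

## The measurement model

Connectivity neurofeedback presents a participant with a live readout of
the statistical coupling between two brain regions. Here the readout is a
*moving-window partial correlation*: with PFC signal $x$, amygdala signal
$y$ and a control signal $c$ from the corticospinal tract, the value at
volume $t$ is

$$ r_p(t) = \frac{r_{xy} - r_{xc}\,r_{yc}}
  {\sqrt{(1-r_{xc}^2)(1-r_{yc}^2)}} $$

computed over the window of the $L=20$ most recent volumes, current volume
included. Partialling out the control region removes globally shared,
task-unrelated signal (scanner drifts, arousal, motion residue) from the
coupling estimate. The closed form above equals the correlation of the
least-squares residuals of $x$ and $y$ on $c$; the test suite keeps both
routes and checks their agreement to $10^{-12}$.

Two consequences of the inclusive-of-current-volume window drive the whole
analysis design:

* at the $k$-th volume of a 20-volume fc-NF mini-block the window contains
  exactly $k$ fc-NF volumes (the 1:19, 2:18, …, 20:0 ratio sequence), and
* any window straddling a block boundary mixes conditions, so raw
  fc-NF/no-NF mean differences are strongly attenuated. The informative
  group-level quantity is therefore the correlation between the
  per-position profile of $r_p$ and the number of fc-NF volumes in the
  window at that position ($N=40$ points in the standard design).

In the long-block variant (40-volume fc-NF blocks) the window sits entirely
inside an fc-NF block for its second half. With the inclusive convention
this yields 21 window positions whose composition is 20:0 (positions 20
through 40); descriptions that count "twenty volumes at 20:0" treat the
boundary volume as the block's entry point instead. The engine reports
every position's composition and leaves the off-by-one reading to the
caller; nothing downstream depends on it.

## The thermometer

The displayed segment is the linear quantization
$\mathrm{clamp}(\lfloor n_\mathrm{seg} \cdot r_p / u \rfloor, 0,
n_\mathrm{seg})$ with lower bound fixed at 0 and the upper bound $u$
defining the implementation: $-1$ (negative), $-0.3$ (weighted negative) or
$+1$ (positive), with $n_\mathrm{seg} = 10$. One segment therefore spans
$|u|/10$ correlation units: 0.1, 0.03 and 0.1. Floor-then-clamp was chosen
because it is deterministic and tie-free, attains the full thermometer
exactly at the upper bound, and reproduces the printed one-segment spacings;
whether the original display interpolated within segments is unknowable
from the outside, so integer segments are assumed. During no-NF blocks the
display is frozen at segment 6 of 10; a degenerate window (zero variance,
or control collinear with a channel) during fc-NF also renders the frozen
segment, because a closed-loop display must always render something.

## The synthetic generator

No subject data are distributed with (or required by) the package; every
analysis stage is exercised on synthetic cohorts whose structure mirrors
what the analysis assumes:

* **Coupling.** PFC and amygdala innovations are bivariate Gaussian with
  instantaneous correlation
  $\rho(t) = \rho_\mathrm{base} + \delta\,[t \in \text{fc-NF}] +
  d\,(\mathrm{run}-1)$, realised by Gaussian mixing
  ($y = \rho x + \sqrt{1-\rho^2}\,e$), which fixes the correlation exactly.
  Each channel then passes through an AR(1) filter (coefficient 0.3 by
  default — a mild, realistic BOLD autocorrelation at TR ≈ 1 s).
* **Nuisance.** A shared standard-Gaussian component loads with weight
  $\gamma$ (default 0.5) on PFC and amygdala. The control channel is
  modelled as an almost-pure readout of that component
  (`cst = nuisance + 0.05 · own AR(1) noise`). This idealisation is
  deliberate: it makes partialling out the control remove the nuisance
  essentially exactly, which is the assumption the online method itself
  makes when it places a control ROI. Real control ROIs are noisier; with a
  noisy control the partial correlation retains a share
  $\approx \gamma^2\sigma_c^2/(\gamma^2+\sigma_c^2)$ of the confound, a
  regime the generator can produce by raising `cst_noise_sd` but which the
  default conditions exclude.
* **No hemodynamic model.** Block transitions change the coupling
  instantaneously; the analysis never deconvolves, and the moving window
  itself supplies the transition smearing that matters for the position
  profiles.
* **Cohort links.** Covariates are Gaussian with configurable moments
  (questionnaire ranges are not enforced — every downstream statistic is
  scale-free). On z-scored covariates, trait anxiety raises
  $\rho_\mathrm{base}$ (+0.08 per SD) and thought-control ability lowers it
  (−0.08); state anxiety attenuates the feedback response $\delta$ (+0.08
  per SD against a responsive mean of $\delta = -0.25$), optionally
  moderated by PFC GABA, ACC GABA and their product; and the across-run
  drift is negatively linked to the session change in thought-control
  ability. The GABA moments default to typical adolescent MRS values
  (PFC 5.29 ± 2.25, ACC 5.81 ± 1.40 % of total creatine). No observational
  study pins down the *magnitudes* of these generative links; the defaults
  were chosen once for adequate statistical power at cohort sizes of 20–500
  and are otherwise arbitrary.

What passing tests show, and what they do not: the suite demonstrates that
the pipeline recovers the structure the generator put in (sign patterns,
interaction coefficients, calibrated nulls). It cannot certify behaviour
under real-data pathologies the generator omits — motion artefacts,
physiological noise, hemodynamic lag, non-Gaussian questionnaire
distributions.

## Subject-level measures

* **Initial fc** — the flat average of defined $r_p$ over the first two
  post-fixation mini-blocks of run 1, irrespective of condition. Because
  start conditions are counterbalanced, the measure mixes one fc-NF and one
  no-NF block for every subject, and a single definition serves the whole
  cohort. Only defined-window volumes contribute; an entirely undefined
  block degrades to the remaining block with a warning.
* **Practice-related change** — the OLS slope of per-run *total fc* (mean
  of all defined $r_p$ in the run, both mini-block conditions) on run
  index. The all-volumes reading is the most inclusive one; `slope_scope`
  switches to single-condition variants.
* **fc-NF-effect** — mean no-NF $r_p$ minus mean fc-NF $r_p$, pooled
  across runs; positive = connectivity more negative under feedback. Each
  volume is attributed to its own mini-block's condition even when its
  window straddles the boundary, consistent with the per-volume ratio
  bookkeeping.

## Group statistics

Group profiles weight subjects equally (average of subject means), matching
the averaging order "across mini-blocks, runs, then individuals". The
profile-vs-count correlation is an ordinary two-tailed Pearson test; two
such correlations (e.g. different thermometer implementations) are compared
by Fisher's r-to-z with the normal reference,
$z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. A Student-t flavoured variant
(df $= n_1+n_2-6$) sits behind `variant = "t"`; at $n = 40$ per group the
two are practically indistinguishable, so no conclusion depends on the
choice.

Multivariate outliers in brain–behaviour scatter plots are flagged by
bootstrapping the Mahalanobis distance: B = 1,000 resamples with
replacement, each contributing every original point's squared distance to
the resample's mean and covariance, flagged when the bootstrap-averaged
distance exceeds the χ²(2) 0.975 quantile (≈ 7.378). The cutoff and B are
explicit, configurable arguments; the flagging is seeded and deterministic,
and affine-invariant as a Mahalanobis construction must be. Correlations
are always reported both raw and after removal, with pairwise deletion of
missing values and no multiple-testing correction by default (a
Benjamini–Hochberg option exists, off by default).

## Moderation

`fit_model3()` mean-centers X, W, Z, forms all products *after* centering
(the standard moderation convention — the products are not re-centered),
and fits OLS with 7 predictors, so the residual df is always $n-8$ and the
overall test has the F(7, n−8) shape. Simple slopes
$b_1 + b_3 w + b_5 z + b_7 wz$ are evaluated at the nine combinations of
moderator levels $\{-1\,SD, 0, +1\,SD\}$ — sample SDs by default, since no
other spread is canonical — with standard errors from the
linear-combination variance of the coefficient covariance and t tests on
the full model's residual df (df = 11 at n = 19). Confidence intervals are
t-based at 95%. A batch specificity mode refits the model with alternative
moderator pairs (e.g. glutamate in place of GABA) and reports each model's
overall F.

One structural caveat for parameter-recovery experiments: the measured
fc-NF-effect is an *attenuated* transform of the generating response
$\delta$ (window mixing scales block contrasts by the mean fc-NF fraction
difference between conditions, ≈ 0.05 in the standard design), so
moderation coefficients fitted to the measured effect estimate the
attenuated coefficients. Recovery of the generating coefficients is
therefore checked against the latent subject response (which
`simulate_cohort()` returns) or by direct simulation of the regression
model, and the time-series path is checked for sign and significance
rather than unbiasedness.

## Numerical and reproducibility conventions

* The streaming engine's reference path recomputes every window from
  scratch; a running-sum path (globally centered cumulative sums, for long
  simulations) must agree within $10^{-10}$ and is tested to.
* Degenerate windows yield an explicit `NA` that propagates to the display
  as the frozen segment; the affected positions are flagged exactly.
* All tables are UTF-8 tab-separated with one header row; numbers are
  serialized with shortest-round-trip precision so every table round-trips
  losslessly through its reader, which the tests assert byte-for-byte via
  re-reading.
* One global seed fans out to per-stage seeds through a fixed splitting
  rule (`split_seed()`), making the full pipeline byte-reproducible (the
  report JSON is identical across repeated runs) while letting stages rerun
  in isolation.
* Simulation-based tests run at deliberately desk-sized problem sizes
  (cohorts of 20–500 subjects, series of 300–10,000 volumes, 50–1,000
  Monte-Carlo replicates), chosen as the smallest scales at which the
  distributional checks have comfortable margins.

## Known limitations

* No hemodynamic convolution, motion simulation or physiological noise; the
  generator validates analysis logic, not preprocessing robustness.
* The control-ROI idealisation above (near-noiseless nuisance readout).
* The supplementary scenario-frequency analysis of the original paradigm
  and image-space preprocessing are out of scope; ROI time series are the
  package's input boundary.
* Questionnaire covariates are Gaussian surrogates; floor/ceiling effects
  and item structure are not modelled.
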