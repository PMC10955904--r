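---
title: "Modelling elliptical excision forces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling elliptical excision forces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excisionforce)
```

This vignette is the package's own account of the model it implements: the
assumptions behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one reasonable option
existed.

## The physical model

A scalpel moving through a viscoelastic medium is approximated by a Maxwell
body: a spring (coefficient $E$, N cm$^{-1}$) and a damper (coefficient
$\eta$, N s cm$^{-1}$) in series. The incision force $f(t)$ and the blade's
*virtual* velocity $\dot x(t)$ obey

$$\eta\,\dot x(t) = f(t) + \frac{\eta}{E}\,\dot f(t),$$

equivalently the displacement-to-force transfer function
$G(s) = \eta s / \left(\tfrac{\eta}{E}s + 1\right)$. Two consequences anchor
the whole package:

* a **displacement step** produces a force that decays exponentially with
  time constant $\eta/E$ (0.5 s at the defaults), and
* a **constant velocity** $v$ produces a step-like force settling exactly at
  $\eta v$.

Polynomial division of $G(s) = Es/(s + E/\eta)$ gives the single-state
realization $\dot g = \alpha g + \beta u$, $y = \gamma g + \delta u$ with
$\alpha = -E/\eta$, $\beta = 1$, $\gamma = -E^2/\eta$, $\delta = E$; at the
default coefficients these are $(-2, 1, -2, 1)$
(`state_space_constants(1, 0.5)`).

"Virtual" deserves emphasis: the displacement and velocity are the
trajectory the Maxwell model *implies* given the measured force, not a
measured kinematic quantity. We treat them as cm and cm s$^{-1}$ without
asserting physical calibration; the default coefficients are chosen so that
implied displacements are on the order of the distance a blade actually
travels.

## From force to regimes

Model fitting runs measured profiles through four stages:

1. **Alignment and cropping** (`align_and_crop`). The analysis window is
   120 samples at 30 Hz (4 s). Recordings are aligned to their force onset —
   the first sample exceeding 10% of the per-recording maximum — and cropped
   bit-exactly, with no filtering or resampling. How the original study
   aligned its recordings is not specified; the onset-threshold rule is this
   package's deterministic, testable choice, and the fraction is
   configurable.
2. **Dataset-global normalization** (`normalize_dataset`). All samples are
   divided by the single maximum over the whole dataset, so the global
   maximum is exactly 1. The constant is stored with the result: fitted
   velocity levels scale linearly with force, so keeping the constant lets
   `fit_force_model` report parameters on the original force scale and lets
   simulated and measured data share a scale.
3. **Maxwell inversion and differentiation**. The virtual displacement is
   $x(t) = f(t)/E + \eta^{-1}\int_0^t f\,\mathrm{d}\tau$, evaluated with a
   cumulative trapezoid rule (second-order accurate; it matches a
   10×-resolution quadrature oracle in the tests). Velocity is the forward
   finite difference at $\mathrm{d}t = 1/30$ s; the result is one sample
   shorter (119 samples) and is deliberately not padded — the HMM accepts
   sequences of any length.
4. **EM fitting** (`fit_regime_hmm`). The velocities of one subject/trial
   (typically 12 profiles) are treated as independent sequences of a
   Gaussian-emission hidden Markov model with $K = 2$ regimes, fitted by
   Baum–Welch in log space.

Two regimes suffice for elliptical excision — a lower regime L (reduced
force: hesitation, re-tensioning, interruption) and an upper regime U
(steady cutting) — but $K$ is configurable for more complex, multi-phase
tasks.

### EM details

* **Initialization** is a deterministic quantile split of the pooled
  velocities (lower/upper tercile means and variances for $K = 2$), so a
  fit is reproducible without any seed; random restarts are available but
  off by default.
* **Variance floor** $10^{-6}$: prevents emission collapse on noiseless
  fixtures (piecewise-constant velocities) while being far below any
  realistic velocity variance.
* **Termination**: the log-likelihood is tracked per iteration and EM stops
  when the absolute improvement falls below `tol` (default $10^{-6}$) or at
  `max_iter` (200). Monotonicity of the trace is asserted in the tests on
  every fit.
* **Canonical labelling**: states are reordered so $v_L < v_U$ after
  fitting, making parameter vectors comparable across trials regardless of
  initialization.
* $\pi_0$ is estimated freely from the per-sequence posteriors.

The long-run behaviour of the fitted chain is summarised by the stationary
distribution; for two states $\pi_U = q_{12}/(q_{12}+q_{21})$. The general-
$K$ solver uses a least-squares solve of $\pi Q = \pi,\ \sum\pi = 1$
polished by power iterations to machine precision, and flags reducible
chains rather than failing on them.

## Forward simulation and the synthetic cohort

The generative direction draws a state path from $Q$, velocities from the
regime Gaussians, and integrates $\dot f = -(E/\eta) f + E \dot x$ forward
from rest. Two discretizations are provided: forward Euler at
$\mathrm{d}t = 1/30$ (default, matching the discrete-time framing of the
switching model) and the exact zero-order-hold map
$f_{t+1} = e^{-\mathrm{d}t\,E/\eta} f_t + (1 - e^{-\mathrm{d}t\,E/\eta})\,\eta v_t$,
which reproduces the continuous dynamics without discretization error for
piecewise-constant velocity. Euler at 30 Hz carries an $O(\mathrm{d}t)$ bias
of about 3% in the decay rate (its discrete decay factor is
$1 - \mathrm{d}t\,E/\eta$ rather than $e^{-\mathrm{d}t\,E/\eta}$), which is
why physics checks of the *continuous* model — the $\eta/E$ time constant —
use the exact map, while the inverse-then-forward round trip, which is
self-consistent, meets its 2%-of-peak RMS bound under either scheme. The
published discrete dynamics matrix for this system contains an obvious
typographical defect (a zero row that would annihilate its constant state),
so the package implements the unambiguous continuous-time equation and
treats the discretization scheme as a numerical choice, not part of the
model.

**Archetypes** (`archetype_spec`, `default_archetypes`) specify cutting
styles as regime parameters. Velocity levels are given in mm s$^{-1}$ inside
the physical blade range $[0, 8]$ mm s$^{-1}$ with Gaussian noise of sd
0.35 mm s$^{-1}$ — the conditions of the study this package models — and are
converted to the Maxwell body's cm scale at render time, which places
steady-state forces ($\eta v$, up to 0.4 N at $v = 8$ mm s$^{-1}$) on the
same amplitude scale as normalized recordings. A trial is 12 profiles (six
elliptical excisions, each an upper and a lower cut) of 120 samples; all
sampling is seeded, with per-profile seeds derived deterministically from
the trial seed so reruns are bit-identical.

Four named archetypes ship with the package (smooth/steady,
steady-high-persistence, abrupt-with-recovery, interrupted). Their
transition probabilities follow published per-subject estimates where such
exist (0.037/0.037 and 0.124/0.028 for the two steady styles); velocity
levels and variances for the individual styles are *not* published anywhere,
so those are chosen once as qualitatively plausible values and are part of
this package's fixture design, not a reproduction.

Simulated forces are rectified at zero: the linear model can produce small
negative excursions when the noisy velocity dips below zero near a low
regime, but the instrument being emulated measures a unidirectional cutting
force bounded below by zero.

**What the generator does not emulate.** Sensor noise and drift, hysteresis,
blade-angle and excision-depth geometry, tissue-phantom heterogeneity, and
any within-profile non-stationarity beyond the two-regime switching. Passing
parameter-recovery tests on these cohorts therefore demonstrates the
correctness and self-consistency of the inference chain — not that real
incision forces obey a two-regime Maxwell/HMM model; that judgement belongs
to the measured data.

Synthetic expert scores serve the same purpose for the rater statistics:
each archetype carries a latent quality and each synthetic rater grades it
with configurable noise (0–3 scale), so agreement statistics have known
targets (identical raters give ICC(2,1) = 1; independent random raters give
ICC ≈ 0).

## Skill features

`descriptive_metrics` computes the six conventional metrics (mean, sd, peak,
scaled force = mean/peak, mean absolute derivative, trapezoid integral). The
published record does not define its derivative metric precisely; this
package uses the mean absolute forward-difference slope in profile units per
second, and documents rather than asserts any correspondence with published
values. The integral uses the trapezoid rule over the sample grid, so a
profile of $n$ samples integrates over $(n-1)/\text{rate}$ seconds.

`parameter_vector` fixes the PCA layout
$(v_L, v_U, \sigma^2_L, \sigma^2_U, q_{12}, q_{21})$: the diagonal entries
of $Q$ are excluded because $q_{11} = 1 - q_{12}$ exactly, and variances
(not standard deviations) enter by default — whether the original analysis
standardized or used sds is unstated, so both are left as explicit choices
of this implementation, with z-scored variances the default.

`fit_feature_space` z-scores each coordinate, runs PCA, and retains three
components. Principal axes are sign-indeterminate, so a deterministic
orientation ties each component to its documented meaning: PC1 loads
positively on $q_{21}$ (frequent loss of applied force), PC2 positively on
$q_{12}$ (sharp rises), PC3 negatively on $v_U$ (reduced upper force
level). The three skill axes are unit-normalized diagonals of the score
planes:

* abruptness $= (PC1 + PC2)/\sqrt 2$ — discontinuity of execution;
* energy $= -(PC1 + PC3)/\sqrt 2$ — amplitude × duration of force
  application;
* confidence $= (PC3 - PC1)/\sqrt 2$ — steady, narrow-envelope force
  application.

The energy and confidence *axes* are orthogonal directions in the PC1–PC3
plane by construction. Their per-cohort score vectors are uncorrelated only
up to the difference of component variances
($\sum \text{energy}\cdot\text{confidence} = (\sum PC1^2 - \sum PC3^2)/2$);
the tests assert this identity rather than pretending the scores themselves
are orthogonal. An optional exclusion list supports dropping outlier
subjects from feature-space analyses; it is off by default.

`score_surface` reproduces assessor-analysis contour plots: the scored
trials are Delaunay-triangulated (Bowyer–Watson, implemented in-package) and
scores are interpolated barycentrically within each triangle; queries
outside the convex hull are `NA`, and collinear configurations are rejected.

## Statistical toolkit

All five tests are written from their defining formulas and return the full
decision trail; where an established implementation exists it serves as an
independent cross-check in the test suite.

* **Levene**: ANOVA on absolute deviations from the group centre;
  mean-centred by default with the Brown–Forsythe median variant as an
  option (the original analysis does not state its variant).
* **Welch ANOVA**: inverse-variance-weighted $F$ with Satterthwaite-type
  denominator degrees of freedom; reduces to Welch's $t^2$ for two groups.
* **Games–Howell**: pairwise Welch statistics referred to the studentized
  range distribution, controlling the family-wise error rate across pairs.
  Null calibration of both tests at $\alpha = 0.05$ is verified by
  simulation (2000 replicates) in the test suite.
* **Spearman with permutation critical value**: rho via midrank-Pearson;
  the critical value is the empirical $(1-\alpha)$ quantile of rho under
  random permutations of one margin. The convention is **one-sided**
  $\alpha = 0.05$: the tabulated critical value 0.446 for $n = 15$ is the
  one-tailed 5% point (two-tailed 10%), and the permutation estimate
  reproduces it to within ±0.01 at $10^5$ permutations.
* **ICC(2,1)**: two-way random effects, single measures, absolute
  agreement, from the two-way ANOVA decomposition; the ANOVA table is
  returned alongside the coefficient.

## Problem sizes, tolerances, degenerate inputs

The test suite exercises the study-scale geometry throughout: 120-sample
profiles at 30 Hz, 12 profiles per trial, EM on 12 × 119 velocity samples,
$10^5$ permutations for the Spearman critical value, 2000-replicate null
simulations for the calibration checks, and chains of $3\times10^5$ steps
for law-of-large-numbers checks of the sampler (long enough that the ±0.01
band on the stationary fraction sits at ≈ 4.5 sigma for the most
autocorrelated chain tested). Parameter-recovery tolerances are ±0.15
mm s$^{-1}$ on velocity means and ±0.03 on transition probabilities at that
data size.

Degenerate inputs are handled deliberately: all-identical velocities
converge with coinciding regime means and a warning (never a crash);
noiseless piecewise-constant sequences fit exactly under the variance floor;
absorbing transition matrices return their absorbing distribution with a
`reducible` flag; all-zero profiles are rejected wherever an onset, a
normalization constant or a scaled force would be undefined.

## Known limitations

* The Maxwell body is the only tissue model: no Kelvin–Voigt or generalized
  variants, no 2-D/3-D cutting mechanics, no blade geometry.
* Virtual velocities are nominal; absolute parameter values depend on the
  chosen $E$ and $\eta$ and on the normalization constant.
* The two-regime HMM assumes velocities are fully observable given the
  Maxwell inversion; joint inference over continuous and discrete hidden
  states (variational SLDS) is out of scope.
* Published per-subject fitted parameters and expert-score analyses from
  the original measured cohort are not reproduced here: they require the
  deposited measurement data. The synthetic cohort provides ground-truthed
  stand-ins for every downstream statistic instead, and `read_profiles_csv`
  ingests measured long-format data when it is available.
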