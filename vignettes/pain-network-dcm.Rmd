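---
title: "Methods: dynamic causal modeling of a cortical-limbic pain network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic causal modeling of a cortical-limbic pain network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painDCM)
```

## Scope and scientific question

`painDCM` implements effective-connectivity analysis of a three-region
nociceptive network — primary somatosensory cortex (S1), amygdala (AMY)
and hypothalamus (h) — measured with block-design fMRI. The question the
workflow answers is twofold: *which directed wiring* of the three regions
best explains the measured BOLD responses to a repeated noxious stimulus
(model/family selection), and *how the retained couplings change* across
experimental groups and time points (parameter comparison). Because the
kind of small-animal dataset this design targets is not publicly
deposited, the package treats a synthetic cohort with known ground truth
as a first-class input: every downstream claim is validated by recovery
from data the generator produced, and the same entry points accept real
per-ROI series from TSV.

## Generative model

### Neural dynamics

The bilinear DCM state equation governs the regional neural states
$z \in \mathbb{R}^3$:

$$\dot z = \Big(A + \sum_j u_j B^{(j)}\Big) z + C u$$

* $A$ (Hz): intrinsic coupling. Off-diagonal $A_{ij}$ is the influence of
  region $j$ on region $i$; the diagonal is self-inhibition and is
  parameterized as $-0.5\,e^{\theta}$ so it can never become positive.
* $B^{(j)}$: modulation of coupling by input $j$. The experimental input
  here is a driving stimulus, not a contextual modulator, so $B = 0$
  throughout; the slot is retained for generality.
* $C$: driving-input weights. The stimulus enters at S1 only.

Stability requires all eigenvalues of $A$ to have negative real part;
the integrator refuses systems that diverge and reports the offending
eigenvalue.

### Hemodynamics and BOLD

Each region's activity drives a balloon–Windkessel cascade with states
(s, f, v, q) and constants

| parameter | meaning | unit | default |
|---|---|---|---|
| `kappa` | vasodilatory-signal decay | 1/s | 0.64 |
| `gamma` | flow autoregulation | 1/s | 0.32 |
| `tau`   | mean transit time | s | 2.0 |
| `alpha` | Grubb vessel-stiffness exponent | — | 0.32 |
| `E0`    | resting O₂ extraction fraction | — | 0.4 |
| `V0`    | resting venous blood-volume fraction | — | 0.04 |

These are the conventional defaults of the DCM literature; nothing in
the target design constrains them, so they are fixed during inversion
(a 150-scan, 3-ROI run cannot identify per-region hemodynamics on top
of ten coupling parameters) and exposed as arguments everywhere.
`boldObservation()` returns the fractional signal change
$y = V_0[k_1(1-q)+k_2(1-q/v)+k_3(1-v)]$; `integrateDCM()` scales it to
percent so that noise levels are specified in percent signal.

### Numerical integration

Fixed-step classical Runge–Kutta (RK4) at `dt = TR/8` by default,
sampling BOLD at scan times $k \cdot TR$. Two choices matter:

* $v$ and $q$ are integrated in log-space, so positivity is structural
  rather than step-size dependent.
* The boxcar input is evaluated once per step at the step midpoint and
  held for all four stages. For designs whose on/off switches align
  with the step grid (true for all defaults) the input is then exactly
  constant within every step and RK4 keeps its full order; the
  dt-halving test in the suite verifies sub-0.1% agreement.

The step size is a genuine accuracy/stiffness parameter, not just a
speed knob: coupling matrices close to the stability boundary produce
slowly amplifying neural modes whose hemodynamic response is stiff, and
halving the step from TR/4 to TR/8 is what keeps such systems
integrable. The inversion therefore uses the same TR/8 default as the
generator.

## The model space

Sixteen hypotheses over the three regions, all with input at S1, in
three families of propagation:

* **family 1** (models 1–4): serial S1→AMY→h; each of the two links
  forward-only or bidirectional.
* **family 2** (models 5–8): serial S1→h→AMY, same two binary choices.
* **family 3** (models 9–16): closed loop over all three pairs, each
  pair forward-only (loop direction S1→AMY→h→S1) or bidirectional —
  eight members; model 16 carries all six directed edges.

The published figure defining the exact per-model wiring is artwork we
could not consume as text; this 4+4+8 reading is the unique partition
consistent with a 16-model space, three families, an 8-member winning
family, and a six-edge fully recurrent top model. It is deliberately
isolated in `enumeratePaperModels()` so a different reading replaces one
function without touching model numbering elsewhere. Models are numbered
in family order with model 16 the fully bidirectional closed loop.

## Synthetic cohort

`cohortConfig()` describes the emulated study: 2 groups
(untreated "model" vs. treated "EA") × 8 subjects × 3 time points (pre,
post, treated), a 5-minute run of 10 equal stimulus blocks (15 s on, 15 s
off), TR 2 s, 150 scans. Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `selfCoupling` | −0.5 Hz | conventional DCM self-decay |
| `forwardCoupling` (S1→AMY, S1→h) | 0.20 Hz | mid-range excitatory coupling |
| `lateralCoupling` (AMY↔h) | 0.10 Hz | weaker limbic interconnection |
| `backCoupling` (h→S1, AMY→S1, baseline) | 0.10 Hz | weak feedback at baseline |
| `painEffect` | +0.30 Hz | pre→post increase of both feedback couplings, both groups |
| `eaEffect` | −0.25 Hz | post→treated decrease, treated group only |
| `inputWeight` | 0.5 | standard driving-input scale |
| `noiseSd` | 0.3 % signal | high-field block-design ROI noise |
| `noiseAR` | 0 | white noise; optional AR(1) flag |
| `subjectDispersion` | 0.05 Hz | between-subject coupling variability |

The condition effects live on the two limbic-to-S1 couplings; all other
couplings are constant across conditions and both groups are identical
at baseline. All A matrices were verified to sit strictly inside the
stability region (the post condition, the closest, has a largest
eigenvalue real part of about −0.05 Hz). Per-subject jitter is Gaussian
on the couplings present in the generating structure, redrawn until the
realized matrix has largest eigenvalue real part below −0.02 Hz; the
realized (post-redraw) values are what the manifest records and what
recovery is scored against, so the truncation never biases the scoring.
Every stream is seeded deterministically from
(seed, group, timepoint, subject); nothing depends on platform entropy.

What the generator does *not* emulate: voxel-level images and spatial
preprocessing, physiological (cardiac/respiratory) noise structure,
scanner drift, hemodynamic variability across regions or subjects, and
repeated-measures correlation of subjects across time points (each
subject × timepoint series is drawn independently). Passing recovery
tests on these data therefore demonstrates the estimator's correctness
under its own assumptions, not robustness to every real-data nuisance.

## ROI-level GLM and eigenvariate

The activation check fits each ROI series by OLS on a design whose
stimulus regressor is the boxcar convolved with a double-gamma canonical
HRF (peak 6 s, undershoot 16 s, ratio 1/6, 32-s support), sampled to scan
times; nuisance columns (e.g. motion) are accepted, the intercept is
last. The rodent hemodynamic response is faster than the human
canonical form, so the peak delay is a parameter (a 2.8-s preset suits
rat data); the GLM here gates ROI inclusion only and feeds nothing into
the DCM likelihood. No serial-correlation model is applied — the
synthetic noise is white by default, and the type-I calibration of the
t-test at the 1% two-tailed level is part of the acceptance suite.
`firstEigenvariate()` implements the usual VOI summary: first left
singular vector scaled by its singular value over $\sqrt{n_{vox}}$,
sign-aligned with the across-voxel mean series. Voxel selection is the
caller's responsibility (a mask or matrix); peak-finding over
whole-brain maps is out of scope.

## Inversion: variational Laplace

Free parameters per model: one coupling per directed edge
(prior $N(0, 1/16)$), one log self-scale per region
($N(0, 1/64)$, so $a_{ii} = -0.5e^{\theta_{ii}} < 0$ always), and the
input weight at S1 ($N(0,1)$). A single log noise precision $\lambda$
shared across ROIs has hyperprior $N(4, 1)$. The prior covariance is
diagonal. These are conventional shrinkage choices — the target design
prints no priors — and all are arguments.

Each outer iteration:

1. **Linearize.** The prediction Jacobian is computed by central finite
   differences on the integrator (relative step $10^{-4}$); proposals
   whose neural matrix is unstable return no prediction and are treated
   as rejected steps, not errors.
2. **E-step.** Damped Gauss–Newton step on the parameters:
   the posterior precision is $e^{\lambda}J^\top J + \Pi_0$ and the step
   solves the Levenberg-damped system. A step is accepted only if the
   free energy (computed with the fresh prediction) does not decrease;
   otherwise damping increases eightfold and the step is retried.
3. **M-step.** $\lambda$ is updated by 1-D Newton on its conditional
   objective using the accepted residuals and the *posterior* covariance
   in the expected-sum-of-squares term. Ordering matters: updating
   $\lambda$ from prior-scale uncertainty instead would collapse the
   data weight before the parameters ever move.

Convergence is declared on the free-energy increment (default
$10^{-2}$ nats — F is the quantity BMS consumes, so parameter-change
criteria are beside the point), capped at 64 iterations; the best-F
iterate is returned and the accepted-iteration F trace is exposed and
asserted non-decreasing in the tests. The whole procedure is
deterministic given inputs and options.

`freeEnergy()` itself is the Laplace-form bound
$E_q[\log p(y\mid\theta)] - KL(q\,\|\,p)$ for fixed $\lambda$; on a
model that is exactly linear in its parameters it reproduces the
conjugate closed-form log evidence to machine precision (the acceptance
suite checks this against an independently coded closed form).
`variationalLaplace()` adds the $\lambda$ hyperprior and entropy terms
to the F it reports; these are consistent across models and cancel in
comparisons.

## Bayesian model selection

Subjects are pooled under fixed effects — group log evidence is the sum
of subject free energies, the procedure the target analysis names (the
word "exceedance probability" belongs to random-effects BMS; what is
computed and reported here are FFX posterior probabilities, labelled as
such). Family inference uses a uniform prior over families *split
equally among members*, so the 4/4/8 partition does not favor the large
family; the family posterior is the sum of its members' model
posteriors. Selection is two-stage: winning family first, then model
posteriors renormalized within it; ties break toward the lowest model id
with a warning. Bayes factors are $e^{\Delta F}$ with log10 values
alongside; with FFX pooling over many scans they are routinely
astronomical, which is why the posterior probabilities are the primary
statistic. All softmax arithmetic is max-subtracted and safe to
$|F| \sim 10^4$.

## Group comparison

Posterior-mean couplings of the winning model enter a per-connection
two-way ANOVA (group, timepoint, interaction) followed by Tukey HSD on
the group × timepoint cells, keeping the contrasts of interest:
within-group across time points and between-group at each time point,
flagged at adjusted p < 0.05. The source analysis names both Tukey's
test and false-discovery-rate control, which are different procedures;
Tukey HSD (FWER) is implemented as primary because it is the named
test, and a Benjamini–Hochberg mode over the same contrasts is provided
(`method = "BH"`), with the choice recorded in the output metadata.
Subjects recur across time points in the emulated design but the
analysis is a plain two-way ANOVA, faithful to the procedure it
mirrors; a mixed model would be the statistically stricter choice and
is deliberately not silently substituted.

## Validation design and problem sizes

The test suite and `scripts/acceptance.R` validate, at these scales:

* free-energy oracle: 60-observation linear-Gaussian model, exact
  conjugate closed form, agreement within $10^{-3}$ nats;
* parameter recovery: 8 subjects simulated from model 16 at default
  noise; pooled correlation between realized true and estimated
  off-diagonal couplings above 0.8, mean bias within 0.1 Hz;
* model recovery: 20 cohorts of 8 subjects, BMS over one model per
  family plus model 16; the closed-loop family must win in at least
  18 of 20;
* calibration: 1000 null GLM simulations at the 1% two-tailed
  threshold, and 1000 group-label permutations of a null coupling
  table at the 5% ANOVA level;
* consistency identities: probability normalization, reciprocal Bayes
  factors, monotone F traces, exact ANOVA sum-of-squares
  decomposition, integrator step-halving convergence.

These sizes match the emulated study where it has a stated size
(8 subjects per group, 10 blocks, 5-minute runs) and otherwise are the
package's own choices for a deterministic, desk-scale validation.

## Known limitations

* Hemodynamic parameters are fixed, not estimated; regionally varying
  hemodynamics would alias into coupling estimates on real data.
* One noise precision is shared across ROIs.
* Only the driving-input (C) pathway is exercised end-to-end; B-matrix
  modulation is modeled and integrated but not part of the emulated
  design.
* Random-effects BMS is not implemented; fixed effects is what the
  mirrored analysis used.
* Near the stability boundary the inversion landscape is multimodal;
  the optimizer is deterministic damped Gauss–Newton from the prior
  mean, and `init` exposes the starting point for sensitivity checks.
* Real-data entry is per-ROI TSV series; 4-D NIfTI ingestion and voxel
  selection are out of scope.
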