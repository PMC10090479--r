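---
title: "Simulating alpha-desynchronizing neurofeedback trials: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating alpha-desynchronizing neurofeedback trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphanfb)
```

## The scientific question this package operationalizes

Resting-state alpha rhythms (8–12/13 Hz) index cortical inhibition, and
patients with PTSD reliably show *reduced* relative alpha power, most
prominently over anterior midline cortex belonging to the default mode
network. Down-training alpha with closed-loop neurofeedback has been
reported to trigger a counterintuitive *rebound*: after twenty weekly
sessions of suppression training, resting alpha is higher than at baseline,
specifically in the regions that were deficient — an effect attributed to
homeostatic regulation of cortical excitation/inhibition balance, and
accompanied by clinically meaningful symptom reduction.

`alphanfb` implements the full computational chain needed to state and test
that claim quantitatively — synthetic cohorts, preprocessing, source-space
relative power, the closed-loop controller with yoked sham, and the group
statistics — so that each analytic step can be validated against known
ground truth.

## The generative model

### Resting EEG

Each simulated subject's 19-channel, 250 Hz resting recording is built in
source space and projected to the scalp:

* every source carries a **1/f aperiodic background** with exponent
  `aperiodic_slope` (default 1), synthesized by frequency-domain shaping of
  white noise (gain clamped below 0.5 Hz so the lowest bins do not dominate
  the variance);
* every source adds an **alpha oscillator** near 10 Hz (frequency jittered
  in 9.2–10.8 Hz per source) with a slow positive waxing-waning envelope.
  Regional base amplitudes follow the eyes-closed topography — posterior
  alpha strongest (2.4 source units), anterior-medial next (1.8),
  anterior-lateral 1.4;
* the **anterior alpha deficit** multiplies anterior-source alpha amplitude
  by `1 - alpha_deficit`. The deficit magnitude is not identifiable from
  published group statistics (which report T-values, not effect
  amplitudes), so it is a free simulation parameter; the pipeline default
  of 0.45 produces baseline group separations comfortably detectable at
  the trial's sample sizes, which is the regime the analysis chain is
  meant to be exercised in;
* a per-subject, per-region **trait multiplier**
  `exp(N(0, trait_sd))` (default `trait_sd = 0.25`) models the large
  inter-individual spread of resting alpha amplitude. This is what gives
  the group statistics a realistic between-subject variance: without it,
  even the faint leakage of the anterior effect into other compartments
  would reach significance at any sample size;
* optional **transient artifacts** (Poisson-placed step-plus-exponential
  transients, ~8x the ongoing RMS, random cross-channel topography) at
  `artifact_rate` per minute give the amplitude/variance rejection rule a
  well-defined target;
* projection uses a fixed random dipole orientation per source and the toy
  leadfield described below, plus 5 % sensor noise, with the result scaled
  to a realistic ~10 µV RMS.

The generator is deterministic given `subject_profile(seed = ...)`, and the
trait multipliers are drawn *before* the per-source loop, so changing
`alpha_deficit` alone changes nothing else — anterior relative alpha is
then strictly monotone in the deficit at fixed seed, which the tests
exploit.

### What the synthetic EEG does *not* model

No biophysically realistic cortical dynamics, no ocular/muscle artifact
morphology (hence no ICA stage), no volume-conduction anisotropy, no
medication or comorbidity effects, and pre/post recordings of the same
subject are independent draws (the subject's trait is not carried across
stages, making the paired rebound test conservative). Passing tests
therefore demonstrate correctness of the *analysis chain* under a
controlled generative model, not fidelity of that model to patient EEG.

### The toy forward model and source space

`make_toy_leadfield()` places sources inside a unit-sphere head,
stratified over three labelled compartments — `anterior_medial` (the
stand-in for medial frontal cortex, where the deficit and rebound live),
`anterior_lateral`, and `posterior` (the stand-in for occipital/cuneus
cortex) — separated by a gap (|y| ≤ 0.25) so the contrast regions are
spatially distinct. Gains are quasi-static infinite-medium dipole
potentials at 19 electrode positions of the 10-20 system on the unit
sphere. This replaces BEM head modelling and template warping: the group
statistics need a labelled voxel set with plausible geometry, not anatomy.

### The homeostatic plant

Session-level alpha amplitude at the feedback site is a two-state
stochastic relaxation model (`plant_state`):

* `alpha_current` relaxes toward `alpha_setpoint` at `relax_rate`
  (1/min; default 2, a ~30 s time constant) and is pulled down by
  `suppression_gain * drive` (fractional rate/min) while the feedback loop
  applies drive;
* `alpha_setpoint` — the homeostatic equilibrium — drifts *upward* at
  `homeostatic_gain` (µV/min of full drive) while suppression is applied;
* additive Gaussian noise scales with the square root of the step.

This is deliberately the simplest mechanism producing both observed
phenomena: within a session, the setpoint drift makes late-period
amplitudes climb back toward the rest baseline; across the intervention,
the raised setpoint makes post-treatment resting amplitude exceed
pre-treatment (the rebound). The model's field list includes `relax_rate`
because relaxation toward the setpoint is part of the dynamics even though
only the two state variables and three gains have behavioural
interpretations. With `homeostatic_gain = 0` the setpoint is exactly
invariant; the tests verify that the rebound sign is positive in at least
95 % of seeded 20-minute suppression runs under the default noise level.

### Clinical cohorts

`gen_clinical_cohort()` draws CAPS-5 total severity at pre/post/follow-up
for both arms. Margins are truncated normals on [0, 80] whose latent
parameters are *moment-matched* (numeric solve of the truncated-normal
moment equations) so the requested group means and SDs hold exactly in
population despite the bound — naive truncation would, for the post-NFB
margin, shift the mean by more than two points. Dependence across
assessments is a Gaussian copula whose latent correlation is solved
numerically (Gauss–Hermite quadrature + root finding) to deliver the
*requested linear correlation* `rho_prepost`; the nonlinear margins would
otherwise attenuate it. With both corrections, the population paired
effect size equals the analytic
$d_z = (\mu_1-\mu_2)/\sqrt{\sigma_1^2+\sigma_2^2-2\rho\sigma_1\sigma_2}$,
which is what the tests assert at n = 10⁴. Default moments are the trial's
reported group values; `rho_prepost` defaults to 0.2, a conservative
pre-post stability for a severity interview over twenty weeks, and is the
single free parameter of the clinical generator.

## The measurement chain

### Preprocessing

Offline preprocessing mirrors the standard chain: common average reference
(idempotent, zero channel-mean at every sample); zero-phase
forward-backward Butterworth band-pass of order 4 (0.5–40 Hz default) —
causal filtering is reserved for the online path; segmentation into
non-overlapping 1-s epochs (trailing remainder dropped); and statistical
rejection of epochs whose channel-averaged mean absolute amplitude or
variance deviates more than 2 SD from the mean across epochs. Two
reductions relative to the full multi-metric artifact-rejection toolbox
are deliberate: only the two stated metrics are used, and metrics are
averaged over channels *before* z-scoring, giving one keep/reject decision
per epoch (the alternative — per-channel z-scores then aggregation — is a
defensible reading; the channel-averaged form matches a single-channel
feedback-site analysis and is what the package implements throughout).
The threshold is symmetric |z| > 2.

### Spectral estimation

`welch_psd` uses 2-s periodic-Hann windows with 50 % overlap and
per-segment mean removal (detrending convention; the estimator is
bit-for-bit compatible with the common scientific-Python implementation,
which the tests freeze as an oracle). Band power integrates the PSD over
half-open intervals [lo, hi), so adjacent bands sharing an edge (4, 8 Hz)
tile the spectrum without double counting; the four canonical bands
(delta 1–4, theta 4–8, alpha 8–13, beta 14–30 Hz) deliberately leave the
13–14 Hz gap of the published band list. Relative power divides by the
1–40 Hz broadband. Two alpha conventions coexist by design: offline
analyses use 8–13 Hz, the online training band is 8–12 Hz; both are
arguments, with defaults following the context in which each appears.

### Source imaging

`sloreta_inverse` implements the standardized minimum-norm estimate for
unconstrained 3-orientation sources with identity noise covariance:
$T = K^\top(KK^\top + \lambda\,\mathrm{tr}(KK^\top)/n_{ch}\,I)^{-1}$, each
source standardized by the inverse matrix square root of its 3×3
resolution block $(TK)_{jj}$. The published analyses do not state the
regularization used; λ here is *trace-scaled* with default 0.1 and exposed
as an argument rather than presented as "the" value. Source power sums the
three orientations. The estimator's defining property — zero localization
error for noiseless point sources — is verified over random sources, and
standardization is checked to give unit expected per-orientation power
under model white noise (15 % tolerance).

## The closed-loop controller

Online amplitude is the RMS of the causally band-passed (Butterworth
order 4, 8–12 Hz) stream over 0.5-s epochs advancing by 0.4 s. The stated
"20 % overlap (i.e. 100 ms)" is read as a 0.1-s overlap of the 0.5-s
epoch, hence the 0.4-s hop; the alternative reading (0.1-s hop) remains
available through the `overlap_s` argument. Epoch count is
`floor(n/hop)` with a truncated final window, so a 20-minute stream yields
exactly 3000 feedback epochs.

Down-training rewards epochs *below* threshold. Calibration sets the
threshold at the 65 % empirical quantile of the 3-minute rest baseline —
the simplest rule that achieves the stated ~65/35 positive/negative
feedback split. At the start of each training period (never mid-period),
if the reward fraction over the preceding 30 s left the (50 %, 90 %)
band, the threshold is fully re-calibrated to the 65 % quantile of that
window; full re-calibration is the least-parameter choice consistent with
"adjusted to meet the ratio". In active mode a rewarded epoch applies
full suppression drive on the next plant step; yoked sham replays a
donor's reward sequence (bit-identical, enforced by test) while the
recipient's plant receives no contingent drive, so displayed feedback is
uncorrelated with the recipient's own amplitude.

Missing data follow two distinct rules, as in the trial: missing
*sessions* are imputed under a multivariate-normal EM across sessions
(subjects as i.i.d. rows; observed-data log-likelihood convergence below
1e-6; conditional-mean imputation with the proper conditional-covariance
correction in the E-step), while missing *periods* within a session use
the subject's mean across sessions for that period. Whether the original
sham sessions re-ran threshold adaptation on the replayed signal, and how
the "successful participant" donor was chosen, are not stated; the
package replays the donor's displayed thresholds verbatim and leaves donor
selection to the caller (the pipeline uses the first experimental
subject).

## Group statistics

Permutation tests build the voxel-wise null by label exchange — group
shuffles for unpaired contrasts (pooled-variance t; a Welch option was
considered and rejected to keep the statistic matched to the permutation
scheme), within-subject sign flips of differences for paired contrasts —
with the add-one two-tailed p estimator $(1+\#\{|T_\pi|\ge|T_{obs}|\})/
(1+n_{perm})$, which cannot produce p = 0. Zero-variance sources are
flagged and given p = 1 rather than an arbitrary statistic. FDR is
Benjamini–Hochberg over whatever collection is submitted — the pipeline
submits sources of one band; submitting sources × bands jointly implements
correction "across frequencies" — and conjunction is the elementwise AND
of individually significant, sign-consistent masks.

The clinical ANOVA is a split-plot (2 groups × 3 assessments) computed via
orthonormal within-subject contrasts with Type III (sum-to-zero)
hypotheses — the convention of SPSS-style output, verified to 1e-10
against an independent reference implementation — with Greenhouse–Geisser
epsilon from Box's definition on the pooled within-group contrast
covariance (no Huynh–Feldt fallback) and partial eta squared from the SSP
traces. Paired effect sizes use $d_z = \bar d/s_d = t/\sqrt n$. CAPS-IV
scores normalize onto the CAPS-5 scale by the ratio of instrument maxima
(136 → 80); the maxima are package constants taken from the instrument
manuals, not estimates. Clinically significant change is a reduction
strictly greater than 30 % of baseline.

## Numerical and scale choices

* Pipeline defaults are sized for a single CPU: 60-s recordings (vs the
  protocol's 180 s), 48 sources, 1000 permutations, 3 NFB sessions. The
  acceptance tests run reduced further (20–30-s recordings, 24 sources,
  300–500 permutations, 12 null seeds); these sizes are stated here as the
  package's chosen simulation scale. Every quantity scales up by changing
  `study_config()` arguments only.
* All generators thread explicit integer seeds; stage seeds derive from
  the master seed by a deterministic string hash kept below 2³¹, and
  rerunning the pipeline with the same seed produces byte-identical JSON
  artifacts.
* EDF export quantizes to 16 bits over ±500 µV (1-s records); round trips
  are accurate to one quantization step (~0.015 µV).
* Degenerate inputs have defined behaviour rather than NaN: zero-variance
  permutation sources get p = 1 with a warning, an all-equal ANOVA returns
  F = 0 with epsilon 1, constant clinical change flags the regression
  rather than fitting it.

## Known limitations

The forward model is a sphere, not anatomy, and 19 electrodes bound the
spatial resolution of any inverse: effects genuinely leak between
neighbouring compartments, which is why the synthetic study conditions
include realistic between-subject amplitude variance (without it, leakage
reaches significance everywhere and regional specificity of masks is
meaningless — as it would be in a real over-powered voxel-wise analysis).
The plant is a phenomenological two-state model, not a circuit model of
homeostatic plasticity. The clinical generator produces the *group-level*
time-course structure; it encodes no dose-response link between simulated
NFB performance and simulated symptom change, so correlation analyses
between the two are expected to be null in simulation — which is exactly
what the specificity tests assert.
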