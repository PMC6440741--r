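---
title: "Dissociating target detection from its covariates: model-based fMRI with random-effects Bayesian model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating target detection from its covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In a near-threshold somatosensory detection task, electrical pulses at
intensities around a participant's perceptual threshold are sometimes
detected and sometimes missed. Classical contrastive fMRI analyses of such
tasks (detected vs undetected at matched intensity) confound perceptual
awareness with everything that co-varies with it: the physical stimulus
intensity, the smooth probability of detection, the trial-by-trial
perceptual uncertainty, and the overt report the participant makes.

`detectbms` implements a model-comparison alternative. Five single-trial
behavioural quantities are each turned into a candidate BOLD model:

1. **intensity** — the linear stimulus intensity (level 1–10);
2. **detection** — the binary detected/missed outcome;
3. **p_detect** — the detection probability read off the participant's
   psychometric function at the presented intensity (a sigmoid in level);
4. **uncertainty** — the *slope* of the psychometric function at the
   presented intensity, an inverse-U over levels that peaks at threshold;
5. **report** — the binary match/mismatch response.

Each model is an otherwise identical GLM whose single trial-onset
regressor is parametrically modulated by the z-scored quantity. Voxel-wise
Bayesian model comparison across subjects then asks, per voxel, *which
description of the trial sequence the BOLD signal actually follows* —
rather than whether a single contrast is non-zero.

The experimental design makes the five modulators separable: matching cues
(white = "stimulus present", dark = "stimulus absent") are counterbalanced
within each intensity level, so the correct report ("match" when the
percept agrees with the cue) is statistically independent of both
detection and intensity by construction.

## The psychometric observer

The observer model is a two-parameter logistic,

$$p(x) = \frac{1}{1 + e^{-4 s (x - t_{50})}},$$

with threshold $t_{50}$ (mA) and slope $s$ (1/mA). The factor 4 makes $s$
exactly the derivative $dp/dx$ at threshold, matching the way the two
parameters are named (threshold, slope at threshold). No lapse or guess
asymptotes are modelled: the intensity grid is built to span the full
0–100% dynamic range, and the task has no stimulus-absent trials, so the
detection rate is the hit rate.

Fitting is by maximum likelihood (`fit_logistic`), bounded quasi-Newton
from a 3×3 grid of starts. The slope is capped (default 50 /mA) and
$t_{50}$ box-constrained to the tested range ± half its width: perfectly
separated data otherwise drive the MLE to infinity. Ties between converged
starts go to the higher likelihood, then the smaller slope (the shallowest
curve consistent with the data). The fit is validated in the test suite
against an exhaustive grid-search MLE oracle.

From a fit, `derive_intensity_grid` solves for T01 and T99 (1% and 99%
detection) and spaces ten levels equidistantly with level 2 = T01 and
level 9 = T99, i.e. a step of $(T99 - T01)/7$. The run-averaged fit is the
unweighted mean of run-wise thresholds and slopes (runs have equal trial
counts by design; the weighting question is therefore moot in practice).
`exclusion_check` drops participants whose averaged curve has
$p(\text{level 1}) > .10$ or $p(\text{level 10}) < .90$ — both strict
inequalities — because their dynamic range was not fully sampled.

## The synthetic cohort: the stated world

Raw data for this paradigm cannot be shared, so the package carries a
first-class generator whose defaults encode the experiment it emulates:

* **Population observers**: $t_{50} \sim N(2.40, 0.69^2)$ mA. The slope
  population is not printed anywhere; the group-mean anchors (T01 = 1.84,
  T50 = 2.40, T99 = 2.96 mA) imply $s = \ln(99)/(4 \cdot 0.56) \approx
  2.05$ /mA, and we draw $s \sim N(2.05, 0.4^2)$ truncated above 0.5 —
  a spread chosen once as realistic inter-individual variability.
* **Design**: 4 runs × (100 experimental trials + 10 null events); session
  totals per level 16, 28, 40, 52, 64, 64, 52, 40, 28, 16. The four
  printed constraints (16 at levels 1/10, 64 at levels 5/6, 400 total) pin
  the ends and the middle; the intermediate counts discretise a normal
  density whose width is fixed by the printed 64:16 ratio, rounded to
  multiples of the run count so every run gets an identical allocation.
* **Timing**: TR 2 s, 378 volumes per run, inter-trial interval uniform in
  2.5–7 s (the design description elsewhere gives 2–7.5 s; the figure-level
  2.5–7 s is the default and both are configurable), fixed 2 s event
  envelope. Onset sequences whose last trial would not be followed by 20 s
  of scanning are redrawn with an incremented subseed — the in-silico
  version of regenerating a protocol that does not fit the scanner slot.
  This truncates the right tail of the total-duration distribution but
  leaves single-ITI statistics essentially untouched.
* **Reaction times**: Gaussian, mean 364 ms, SD 53 ms, truncated to the
  0.15–0.9 s response window, with detected-target trials faster by
  11.77 ms on average.
* **BOLD**: a 20×20×20 desk-scale lattice with six embedded 60-voxel
  regions — one per candidate model plus a pure-noise null region. Signal
  is the canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6)
  convolved with modulator-weighted trial impulses, at 1% signal change
  per SD of modulator on a baseline of 100, plus a shared 1% unmodulated
  onset response. Noise is AR(1) Gaussian (coefficient 0.2, marginal SD
  1%) plus a 0.5% cosine drift of 128 s period and random phase. The noise
  model is a stated assumption — minimal realistic structure that
  exercises the prewhitening and drift-robustness of the GLM — not a
  reproduction of any measured spectrum.

What a green recovery test establishes: that the *analysis machinery*
identifies generating models, separates families, and recovers profile
shapes under the assumed noise. What it does not establish: robustness to
physiological noise, motion, susceptibility artefacts, or spatial
heterogeneity of the HRF, none of which are simulated.

## First-level Bayesian GLM

Each candidate model's design matrix contains the HRF-convolved onset
regressor, its parametric modulation by the z-scored modulator, temporal
derivatives of both, the z-scored RT modulation, optional nuisance columns
(e.g. the first five principal components of tissue-mask time series,
`compute_nuisance_pcs`), and a constant. No spatial smoothing is applied
to the data before first-level estimation.

The reference implementation of this analysis used a spatially
regularised variational GLM. We instead fit the exact conjugate
normal–inverse-gamma model,
$\beta \mid \sigma^2 \sim N(0, \sigma^2 V_0)$,
$\sigma^2 \sim IG(a_0, b_0)$, for which the log marginal likelihood —
the model evidence — is available in closed form and can be verified
against brute-force quadrature (the test suite does, to $10^{-3}$ nats).
Spatial regularisation is then realised by the pipeline's own subsequent
step: smoothing the per-subject log-evidence maps (8 mm FWHM by default)
before group-level selection. Two considerations justify this: only
evidence *differences* across models at a voxel carry meaning downstream,
and the original analysis itself reported that smoothing choices hardly
changed the overlap of effects.

Prior scales: $V_0 = g(X^TX)^{-1}$ with $g = n$ (unit-information), which
makes evidence invariant to column rescaling and handles the correlated
derivative columns gracefully; $a_0 = b_0 = 10^{-3}$ keeps the noise level
data-driven. Autocorrelation is handled by AR(1) prewhitening; in the
vectorised whole-lattice fit a single pooled (median across voxels)
coefficient per run is used so the design matrix can be whitened once —
per-voxel whitening is available through the single-series interface.
Run-wise evidences are summed (runs are conditionally independent);
run-wise betas are averaged.

## Group inference: random-effects BMS

At each voxel the subjects' log evidences enter the standard variational
random-effects scheme over a Dirichlet prior on model frequencies
(`rfx_bms`): iterate
$u_{nk} \propto \exp(\log E_{nk} + \psi(\alpha_k) - \psi(\textstyle\sum_j \alpha_j))$,
$\alpha = \alpha_0 + \sum_n u_n$, to a $10^{-6}$ fixed point. The
exceedance probability of model $k$ — the posterior probability that its
population frequency tops all others — is estimated from Dirichlet
samples ($10^6$ by default for single calls, 5000 per voxel in maps, where
the Monte-Carlo error at EP ≈ .99 is ~0.0014); for two models the exact
regularised-incomplete-beta form is used instead.

Intensity, detection and detection probability correlate positively with
stimulus intensity and share variance; in regions carrying such signal
their evidence splits and an unrelated model can win by *model dilution*.
Family-level inference (`family_bms`) counters this: the three models are
pooled into a "+family", prior mass is equalised per family (each family
gets total $\alpha_0 = 1$, split equally among members), and the family's
frequency is the sum of its members' per Dirichlet sample. Two properties
of the variational scheme are worth knowing. First, with completely flat
evidence the exact posterior equals the prior, but the VB fixed point
drifts toward equal *model* (not family) weights — an artifact that is
irrelevant wherever the data are informative but visible in null regions.
Second, expected frequencies are bounded by $(\alpha_0 + n)/(K\alpha_0 + n)$,
so small cohorts cannot reach extreme EPs: with unit priors over five
models, at least eight subjects are needed before any voxel *can* clear
the .99 threshold.

Voxels of interest are those with EP ≥ .99; clusters smaller than 50
voxels are discarded (`threshold_ep_map`), using 26-neighbour connectivity
by default (the convention is not fixed by the source analysis; 6-neighbour
is available).

## Post-selection statistics

Within each group ROI (for +family members: family clusters partitioned by
argmax of member EPs, `split_family_clusters`), each subject's probability
peak is the voxel maximising that model's evidence share
$\exp(\log E_m - \mathrm{logsumexp}_k \log E_k)$, with ties resolved to
the lowest linear index. Beta estimates at the peaks are tested for
deviation from zero with the JZS (Cauchy-prior, default scale 0.707)
one-sample Bayes factor, computed by the standard single-integral form
and verified against double quadrature. Detection×report independence is
tested per subject with a Dirichlet–multinomial contingency Bayes factor
(joint multinomial by default; a fixed-row-margin variant is selectable —
the source analysis cites the test without fixing the variant). Bayes
factors are banded as negligible (<3), positive (3–20), strong (20–150),
very strong (>150).

Stimulus-response profiles (SRPs) come from a second GLM with ten onset
regressors, one per intensity level (plus RT and constant), whose
smoothed beta volumes are averaged within 4 mm spheres (membership by
centre-to-centre distance) at the subject peaks. Profile shapes are
classified by least-squares fitting of four templates — linear ramp,
sigmoid in level, its derivative (inverse-U), and flat. Flat is treated
as the null hypothesis: the best non-flat template is accepted only if it
beats the intercept-only fit in an F-test at α = .01. With ten points and
three competing templates, an unguarded information-criterion comparison
promotes noise wobble in genuinely flat profiles to a spurious shape in
roughly a third of bootstrap replicates; the conservative gate removes
this failure mode without costing any power against real shapes, whose
F statistics are orders of magnitude above the cut.

## Numerical choices and degenerate inputs

* Z-scoring a zero-variance vector (e.g. every target detected) raises an
  error naming the offending regressor rather than silently producing NaNs.
* Design matrices are rank-checked; the error names the collinear columns.
* Evidence computations are shift-invariant per subject and invariant to
  nuisance column order (tested).
* The variational BMS declares non-convergence after 10,000 iterations
  rather than returning a stale iterate.
* Smoothing uses an edge-renormalised separable Gaussian kernel: constant
  maps are exactly preserved, interior mass is conserved.
* All randomness is seeded; cohorts, runs and stages derive their seeds
  from the master seed in `sim_config`, and every output-writing helper
  records the resolved configuration (`write_config`).

## Known limitations

* The conjugate GLM replaces the spatially regularised variational scheme;
  absolute evidence values differ from that implementation and only
  relative, within-voxel comparisons are meaningful.
* Pooled-AR(1) prewhitening underfits voxels with atypical autocorrelation.
* The generator shares one HRF across regions and subjects;
  HRF-misspecification effects on model selection are not explored.
* Family-level EPs inherit the VB flat-evidence artifact described above.
* The desk-scale lattice has no anatomy: no atlas labelling, no grey-matter
  clipping of SRP spheres (none is applied — sphere membership is purely
  geometric).
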