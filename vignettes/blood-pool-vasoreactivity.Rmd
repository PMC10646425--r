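---
title: "Blood-pool MRI assessment of myocardial vasoreactivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-pool MRI assessment of myocardial vasoreactivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasoreact)
```

## The measurement problem

Microvascular vasomodulation — the ability of small vessels to dilate and
constrict on demand — is impaired early in many cardiac diseases, but the
standard MRI readout (BOLD T2\*) confounds blood volume with oxygenation,
flow velocity and hematocrit. Blood-pool T1 imaging sidesteps this: after
injecting an albumin-binding gadolinium agent that stays (mostly) inside
the vasculature, tissue T1 is governed by how much of the voxel the
agent-laden blood occupies. When a hypercapnic stimulus (10% inspired CO2)
dilates the microvasculature, the agent's distribution space grows and
tissue T1 drops; constriction on return to room air raises it. Percent T1
changes across a normoxia–hypercapnia–normoxia gas regime are therefore a
specific index of blood-volume change, corroborated here by laser Doppler
flowmetry, an invasive perfusion gold standard.

`vasoreact` implements that analysis end to end for rat cardiac MRI at the
standard preclinical protocol, together with a digital phantom that makes
every stage testable without scanner data.

## The relaxation model

A tissue with pre-contrast relaxation time $T_{1,\mathrm{pre}}$ and
microvascular blood-volume fraction $v$ exposed to plasma agent
concentration $C$ relaxes, under fast water exchange, at

$$R_1 \;=\; \frac{1}{T_{1,\mathrm{pre}}} + r_1\, v\, C ,$$

with $r_1$ the agent's longitudinal relaxivity (1/mM/s). This linear
fast-exchange form is the simplest model in which T1 change is driven
purely by the distribution volume $v$, which is precisely the premise of
the blood-pool method. Its two structural consequences are package
invariants: at fixed $C>0$, tissue T1 is strictly decreasing in $v$; and
with no vasomodulation and no elimination, T1 is constant over the regime.

Signal formation uses the spoiled gradient echo (SPGR) steady state,

$$S \;=\; M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1},$$

in both directions: the phantom renders with it, and the fitters invert it.

## T1 quantification

**Pre-contrast mapping** uses the variable flip angle (DESPOT1) scheme at
FA = 2°, 5°, 10°, 15°, 20°, TR = 7 ms: regressing $S/\sin\alpha$ on
$S/\tan\alpha$ gives slope $E_1$ and hence $T_1 = -TR/\ln E_1$ and $M_0$.
We use the linearised regression, not iterative least squares: it is the
standard form of the approach, deterministic, and exactly recovers
noiseless signals. Voxels whose slope falls outside $(0,1)$, whose
intercept is non-positive, or whose regressor is degenerate are flagged
invalid and excluded — never imputed.

**Post-contrast mapping** inverts a single CINE acquisition (FA = 15°,
TR = 6 ms) per timepoint using the pre-contrast $M_0$:

$$E_1 = \frac{M_0\sin\alpha - S}{M_0\sin\alpha - S\cos\alpha}.$$

$M_0$ transfers unchanged between the TR = 7 ms and TR = 6 ms acquisitions
(the equilibrium magnetization does not depend on TR; no rescaling is
applied), while $E_1$ uses the CINE TR. Signals at or above the ceiling
$M_0\sin\alpha$ yield invalid voxels. No B1 correction is applied — flip
angles are taken as nominal.

## Regime bookkeeping

Imaging runs every 5 min through 10 min normoxia, 10 min 10% CO2, 10 min
normoxia (timepoints 0–30 min; t = 0 is the first post-contrast baseline
after the 10-min stabilisation wait). Per timepoint, mean T1 is computed
over the valid voxels of each myocardial ROI (septum, anterior wall,
posterior wall) and the three ROI means are averaged into the pooled
myocardial value. Percent changes follow the reporting convention of the
results table: timepoints inside the hypercapnia phase are referenced to
the end of the first normoxia block (the baseline), and timepoints in the
normoxia return are referenced to the end of hypercapnia. We adopt this
reference-point convention (rather than "previous imaging timepoint")
because only it makes the two hypercapnia rows share a reference, which is
how the row labels read.

## The digital phantom

The phantom is a short-axis annulus on the protocol grid (128 × 128,
70 mm FOV, 16 × 1 mm slices): an LV blood-pool disc (radius 3.5 mm)
inside a myocardial annulus (outer radius 6.5 mm) split into three 120°
sectors. Anatomical realism is explicitly not a goal; the geometry exists
to give the ROI machinery labelled, disjoint regions of realistic voxel
counts.

Per tissue it carries $T_{1,\mathrm{pre}}$, $M_0$, a baseline
blood-volume fraction, and per-phase multiplicative targets on that
fraction; $v(t)$ approaches each phase's target exponentially (default
time constant 3 min — cardiac vasomodulation acts over minutes, unlike
the seconds-scale cerebral response). Plasma concentration decays
mono-exponentially with a 420-min default half-life, chosen so
enhancement drops by under 5% across the regime, consistent with the
agent's stable-enhancement window of roughly 40 min. The agent's
relaxivity (19 /mM/s, typical of the albumin-bound regime), plasma
concentration (0.5 mM) and myocardial blood-volume fraction (0.10) are
configurable defaults, not literature measurements: the source protocol
reports none of them, and the analysis outputs (percent changes) are
invariant to their exact values.

The sex presets (`phantomPreset("female")`, `"male"`) encode the measured
group-mean trajectories — pre-contrast myocardial T1 1195/963 ms,
post-contrast baseline 452/312 ms, hypercapnic steps of −12%/−20%
(female) and −1%/+5% (male), return steps of +18%/+23% and +16%/+19% —
as explicit per-timepoint T1 targets. The generator inverts the
relaxation model to find the $v(t)$ that produces each target (all
implied fractions land in 0.14–0.24, physiologically sensible for
myocardium with an agent that also samples some perivascular space), so
preset ground truth always satisfies the model's own monotonicity
constraint.

Noise is Rician — the magnitude of a complex Gaussian perturbation — as
appropriate for magnitude MR images, with scale expressed relative to the
blood-pool $M_0$ and applied with the spec'd seed for bit-reproducibility.

### What the phantom does and does not emulate

It reproduces the statistical structure the analysis assumes: SPGR signal
formation at the exact protocol parameters, a blood-pool agent confined
to a phase-modulated distribution volume, Rician noise, and labelled
ROIs. It does not simulate k-space, cardiac/respiratory motion or gating,
TE/T2\* decay, coil profiles, first-pass bolus dynamics, B1
inhomogeneity, or partial-volume mixing at tissue borders. Passing
round-trip tests therefore demonstrates the correctness of the estimators
and bookkeeping under the stated model — not robustness to motion or
field imperfections in real data.

### A note on noise levels

Because $T_1 \gg TR$ at this protocol, SPGR signals are small fractions
of $M_0$ (myocardial VFA signals ≈ 3–5% of $M_0$; CINE baseline ≈ 7%).
A noise sigma quoted relative to $M_0$ is therefore an order of magnitude
more aggressive than the same figure quoted as image SNR: sigma = 2% of
the blood $M_0$ puts the myocardium at SNR ≈ 3, where no single-point
inversion can keep median T1 errors near a few percent (we measure ≈ 33%
there with noiseless pre-contrast maps, ≈ 83% when the VFA fit is also
noisy). The regime the physics supports is characterised in the test
suite instead: at sigma = 0.2% of blood $M_0$ (myocardial CINE SNR ≈ 29)
the median voxelwise error of the post-contrast inversion stays below 5%,
in line with the first-order expectation that relative T1 error tracks
1/SNR.

## Laser Doppler analysis

Traces are 10 Hz perfusion samples in relative blood perfusion units
(BPU), modelled as baseline × (phase-modulated gain) × (1 + cardiac
ripple) + noise. Analysis choices:

- **Phase summaries** are means over the final 60 s of each gas phase
  (the summary statistic and window of the original analysis are
  unstated; an end-of-phase mean is the natural estimator of the plateau,
  and percent changes use the same previous-phase reference as the MRI
  table). Windows flagged as corrupted are excluded; a phase whose entire
  end window is corrupted is reported *not measured*, mirroring how
  motion-ruined measurements are reported rather than crashing.
- **Corruption flagging** computes var/mean² per 10-s window (gain
  invariant) and flags windows exceeding 5× the median window metric —
  the described failure mode is probe motion degrading the signal to the
  noise level, i.e. a variance excursion.
- **Heart rate** is the dominant spectral peak per 60-s window, refined
  on a 0.01-bpm grid. Rat heart rates exceed 300 bpm (5 Hz), the Nyquist
  frequency of the fixed 10 Hz sampling, so the raw spectral peak appears
  aliased (a 350-bpm ripple peaks at 4.17 Hz, not 5.83 Hz). Since for real
  signals the periodogram at $f$ and $f_s - f$ coincide, the estimator
  searches candidate rates inside a physiological band (default
  300–550 bpm, which contains exactly one alias partner per peak) and
  reports the true rate. Preset transitions use a 1-min time constant so
  the end-of-phase window sits on the plateau (residual ≈ e^{−9}); this
  is what makes the encoded percent responses recoverable to printed
  precision.

## Statistics

Differences across regime timepoints are tested with a plain one-way
ANOVA followed by Fisher's Least Significant Difference test at P < 0.05:
unadjusted pairwise t statistics on the pooled within-group variance, on
the ANOVA residual degrees of freedom. No further multiplicity
correction is applied — that is what LSD is. The repeated-measures
structure (the same animals appear at every timepoint) is deliberately
ignored to stay faithful to the stated method; a mixed-effects analysis
is out of scope. The factor is the imaging timepoint (with LSD contrasts
available for any pair, including each phase's reference timepoint);
treating gas phase as the factor instead would discard the within-phase
dynamics the 5-min sampling exists to capture.

## Numerical and degenerate-input conventions

- Invalid voxels (failed fit, unphysical inversion) carry NA and a FALSE
  mask entry; ROI means use valid voxels only, and an ROI with none is an
  error naming the region.
- The VFA fit flags rather than throws on degenerate voxels (all-zero
  signals, slope outside (0,1)); it throws only on structural misuse
  (fewer than two distinct flip angles).
- Phase-boundary times belong to the earlier phase, so "10 min into
  hypercapnia" (t = 20) is the end-of-hypercapnia reference.
- All randomness (Rician noise, trace noise, corruption fill) flows from
  the spec/trace seed; identical configurations give identical arrays and
  serialized outputs.
- Voxel indices are 0-based in the NIfTI affine sense with axis order
  (x, y, z, t/flip-angle); world geometry travels in the NIfTI header.

## Problem sizes

The sex presets default to the full 128 × 128 × 16 acquisition matrix
(an end-to-end noiseless run takes a few seconds). The test suite runs
the same checks on 32–64 voxel grids with 2–4 slices purely to keep the
suite fast; every recovery test is a round trip whose exactness does not
depend on grid size. Null-calibration of the LSD test uses 10^4
simulated replicates; the permutation cross-check uses 10^5 shuffles.

## Known limitations

- The phantom's piecewise-constant tissue model has no partial-volume
  voxels, so ROI means are exact; real ROI means blend tissues.
- Percent-change recovery is exact only because the phantom and fitter
  share the SPGR model; model mismatch (B1 error, imperfect spoiling,
  TE decay) biases absolute T1 but largely cancels in percent changes,
  which is why the method reports changes, not absolute times.
- The Doppler synthesizer is a phenomenological trace model (gain ×
  ripple + noise), not speckle physics; corruption is a variance
  excursion, not a motion simulation.
- Group inference assumes exchangeable animals; with n = 5 per sex the
  LSD test is exact under normality but its type-I calibration (checked
  at 0.05 ± 0.01 under a simulated null) is all the protection provided.
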