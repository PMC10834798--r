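---
title: "Compartment-based reconstruction of acquisition-weighted cardiac 31P MRSI: models and design choices"
author: "slamrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-based reconstruction of acquisition-weighted cardiac 31P MRSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cardiac phosphorus-31 MR spectroscopic imaging measures the myocardial
PCr/ATP ratio, a marker of cardiac energetic status, from phase-encoded
chemical shift imaging (CSI) data. The conventional analysis
Fourier-transforms the k-space data and fits the spectrum of a single
mid-septal voxel ("FT-MRS"). Spectroscopy with linear algebra modeling
(SLAM) instead constrains the reconstruction with an anatomically segmented
localizer: if the object is assumed piecewise-constant on C segmented
compartments, the phase-encoded signal equation collapses to an
over-determined system of C linear equations per time point, and the whole
heart compartment contributes to a single spectrum. This package provides a
synthetic test bed for the comparison: a digital thorax phantom, a forward
simulator for acquisition-weighted (AW) CSI with cardiac gating, both
reconstructions, AMARES-style spectral quantification with Cramér–Rao lower
bounds (CRLBs), and the repeatability, field-of-view (FOV) shift and cohort
statistics used to evaluate them.

## Signal model and forward simulation

Every tissue compartment carries a per-voxel time-domain signal

$$\rho_c(t) = \sum_k a_k e^{i\phi_k} \sum_j w_{kj}
  e^{(-d_k + i 2\pi (f_k + \delta_{kj}))t},$$

a sum of Lorentzian resonances with J-coupling multiplets encoded as fixed
sub-offsets $\delta_{kj}$ and relative amplitudes $w_{kj}$ (γ- and α-ATP
doublets at ±8.5 Hz, the β-ATP triplet at ±17 Hz, the blood 2,3-DPG pair at
+270/+320 Hz). Chemical shifts are configuration, not fitted values: PCr
0 Hz, γ-ATP −128 Hz, α-ATP −380 Hz, β-ATP −825 Hz at the 3 T ³¹P Larmor
frequency. Excitation is modelled as ideal and band-limited (1.5 kHz centred
at −250 Hz); components outside the band are attenuated to zero. The
acquired sample for phase encode $k_m$ is the discrete signal equation

$$s(k_m, t) = \sum_c \sum_{r \in c(\theta)} \sigma_{sat}(r)\, \rho_c(t)\,
  e^{-i2\pi k_m \cdot r / N},$$

summed over the acquisition scheme's averages with independent complex
Gaussian noise (SD `noise_sigma` per channel per readout) and an independent
cardiac phase $\theta$ per readout. Gated acquisitions fix $\theta = 0$
(diastasis); ungated readouts draw $\theta \sim U[0,1)$ i.i.d., since TR and
the R–R interval are incommensurate. Averages are **summed**, not averaged,
so the average-count profile $n(k)$ is itself the k-space apodization that
shapes the point spread function — the defining property of AW-CSI.

### Acquisition weighting window

The protocol states only "10 averages at the centre of k-space" and a
10.5-min duration at TR 0.9 s, implying roughly 700 readouts. A rounded
separable Hann window with a centre count of 10 acquires 1252 readouts
(18.8 min) on the 8×16×8 grid — incompatible with the stated duration — so
the default window is cosine-cubed, which acquires 734 readouts (11.0 min).
Hann, Hamming and uniform windows remain selectable.

## The digital thorax phantom

Three compartments on the 240 × 240 × 200 mm, 8 × 16 × 8 grid (30 × 15 ×
25 mm voxels; axis 2 is anterior–posterior):

* **heart** — a 90 × 60 × 100 mm box (3 × 4 × 4 voxels) holding the myocyte
  signal (PCr/γ-ATP amplitude ratio 2.0 by default) mixed with a blood pool
  (volume fraction 0.2) of 2,3-DPG and blood ATP. The blood composition is
  fixed so that blood γ-ATP equals 0.30 × the mean 2,3-DPG amplitude: the
  default blood-correction coefficient κ = 0.30 then inverts the
  contamination exactly, which gives the correction oracle a well-defined
  ground truth. Blood ATP shares the myocyte ATP damping so each compartment
  signal stays inside the fitted model class.
* **chest_wall** — a two-row anterior slab plus lateral "wings" at heart
  depth (in the prone position the pectoral muscle wraps around the
  thorax), with strong skeletal-muscle PCr (PCr/ATP = 4).
* **other** — the catch-all complement (label 0), ATP-dominant with no PCr
  (liver physiology), homogenised over the whole background.

Homogenising "other" keeps the default phantom exactly piecewise-constant on
its three compartments, which is what the SLAM recovery oracles require; the
price is that no localized liver/lung structure exists. Saturation bands
(25 mm) cover the anterior chest slab and the inferior liver region at 95%
efficiency — deliberately imperfect, standing in for T1 recovery between the
saturation pulse and the readout train and for B1 variation. The lateral
wings cannot be covered by an axis-aligned band without nulling the anterior
heart row, and remain the dominant residual PCr contamination, as in vivo.
Cardiac motion displaces the heart along the anterior–posterior axis by
`amplitude × (1 − cos 2πθ)/2` (zero at diastasis, default 10 mm peak).
Masks are rasterized by the voxel-centre convention; partial volume is
intentionally absent from the label model.

## Reconstruction

**FT-MRS** is the inverse 3D DFT of the summed data (zero-filling
unacquired points, no additional filter; the acquisition weighting is the
apodization), normalised so a noiseless unweighted acquisition returns the
true voxel FIDs. The mid-septal voxel is selected deterministically: among
heart voxels with no face-adjacent chest-wall voxel, the one nearest the
heart centroid, ties broken by lowest linear index.

**SLAM** solves, per time point, the weighted least squares problem
$\min_\rho \|\mathrm{diag}(w)(s - E\rho)\|_2$ with
$E_{mc} = n(k_m)\sum_{r\in c} e^{-i2\pi k_m\cdot r/N}$ and
$w_m = 1/\sqrt{n(k_m)}$, the statistically correct whitening for summed
averages. The solve uses an SVD pseudoinverse with relative cutoff `rcond`
(default 1e-8) and always reports the singular values. Because each column
of E already sums the encoding phasors over the compartment's voxels, the
solution **is** the mean per-voxel compartment FID; dividing by the voxel
count again (as a literal reading of one interface note would suggest) would
break the exact equivalence, on full unweighted k-space, between SLAM and
the compartment mean of the FT reconstruction — that equivalence is the
package's primary oracle and was kept authoritative.

### FOV shifts and compensation

`shift_fov` applies the Fourier shift theorem
($s(k) \leftarrow s(k)e^{-i2\pi k\cdot\Delta/N}$); with the package's
inverse-DFT convention the object moves toward positive voxel index.
`shift_mask` compensates the segmentation in two semantics: the default
`"kspace"` method rolls the labels by the integer part (matching the shift
theorem's circular wrap exactly) and stores the sub-voxel remainder $s$ on
the mask, which enters the SLAM encoding as the phase factor
$e^{-i2\pi k\cdot s/N}$ — compartment support at $r + s$. This makes
shift-plus-compensation an exact inverse pair for arbitrary fractional
shifts, which is what "the segmentation mask is correctly defined for the
FOV acquired" means mathematically. The `"rasterize"` method re-rasterizes
the displaced continuous geometry instead; it is the right tool for
session-to-session repositioning but can only approximate a half-voxel shift
of shift-theorem data to the nearest voxel boundary, so it is not used for
compensation.

## Spectral quantification

Both reconstruction paths are post-processed identically: phase correction,
exponential apodization (default 20 Hz, configurable and logged), and
time-domain prior-knowledge fitting. The fit model is the same
damped-sinusoid family as the phantom, with fixed multiplet structure, one
shared damping per group, amplitudes solved by variable projection and the
remaining nonlinear parameters (frequencies, dampings, one shared phase)
optimised with analytic gradients under box bounds. The covariance is
$\sigma^2(\mathrm{Re}\,J^HJ)^{-1}$ at the solution, with $\sigma$ estimated
from the last 104 spectral points (outside the excitation band), the same
region as the SNR denominator for internal consistency. The ratio CRLB uses
the delta method including the amplitude covariance term. Reported linewidth
is the fitted damping over π, so for Lorentzian inputs it equals the true
FWHM plus the applied line broadening exactly.

**Phase correction.** The zeroth-order term comes from the PCr-region peak
phase and is always applied — a global rotation is absorbed exactly by the
fit's shared phase, so it cannot corrupt the model. The first-order term is
applied only from a known acquisition delay (or on explicit request via an
integrated-peak-phase regression): on clean multi-resonance spectra,
slope estimates driven by the data — including minimising the integrated
imaginary magnitude — find spurious first-order terms of order 1e-3 rad/Hz
because overlapping dispersion tails and discrete-bin phase bias shift the
objective's minimum, and applying such a slope destroys the Lorentzian model
class (it breaks the noiseless recovery oracle at the 1e-6 level). The
simulated acquisitions sample t = 0 directly (UTE-style), so the honest
default is $\phi_1 = 0$.

**Corrections.** The blood correction subtracts κ × (mean fitted 2,3-DPG
amplitude) from γ-ATP; saturation correction divides each amplitude by
$(1-E)/(1-E\cos\alpha)$, $E = e^{-TR/T_1}$ (defaults T1 PCr 5.8 s, γ-ATP
3.1 s, α = 30°, all configurable and recorded in the result). The forward
simulator does not model T1 steady-state weighting, so the synthetic
experiment pipelines disable the saturation factor by default; enabling it
against simulated data would bias the ratio by the analytic factor, which is
itself unit-tested.

**CRLB validation.** The Monte-Carlo CRLB check runs without apodization:
line broadening makes the time-domain noise non-stationary, so the
white-noise Fisher matrix is only an approximation there (as it is in
standard practice); without apodization the empirical spread of the PCr
amplitude matches the reported CRLB to within sampling error.

## Statistics

Coefficient of repeatability CoR = 1.96 × SD (n−1 denominator) of the signed
intra-subject session differences; coefficient of variation = SD across all
scans / mean. The Wilcoxon signed-rank test drops zero differences, assigns
average ranks to ties, and computes the exact two-sided p by a
dynamic-programming enumeration of all sign patterns up to n = 25 (doubled
ranks keep tied average ranks integral), falling back to the
continuity-and-tie-corrected normal approximation above. Welch's t-test
operates on summary statistics with the Welch–Satterthwaite degrees of
freedom. Two sample-size conventions are implemented: the normal
approximation $n = \lceil 2\sigma^2(z_{1-\alpha/2}+z_{1-\beta})^2 /
\Delta^2\rceil$ per group and the iterative noncentral-t computation; the σ
choice (group A, group B, or pooled) is explicit and recorded. With the
healthy-cohort SD the normal approximation reproduces the published total of
34 for FT-MRS; no supported convention reproduces the published 16 for SLAM
from the printed summaries, so that number is reported with a caveat rather
than asserted.

## The synthetic cohorts and what a green test establishes

The repeatability experiment draws each subject's true ratio once
(N(2.0, 0.15²) healthy, N(1.6, 0.15²) patients), applies a uniform 0–0.5
voxel anterior–posterior FOV-placement jitter per session, and simulates
gated and ungated scans per session. The default per-readout noise SD (120)
was calibrated once so the ungated FT-MRS mid-septal voxel lands at PCr SNR
≈ 25–30, the published healthy-cohort scale, and then frozen. The patient
preset lowers the true ratio and doubles the noise (larger habitus, lower
SNR).

The synthetic world reproduces mechanisms, not in vivo magnitudes: no B0/B1
maps, no respiratory or bulk motion, no receive-coil sensitivity gradient,
i.i.d. cardiac phases rather than the correlated phase runs of a real
ungated scan, piecewise-constant tissue. Green directional tests therefore
establish that the pipeline exhibits the claimed orderings under its stated
variance sources — not that it reproduces the published human numbers.
Two consequences are documented rather than hidden:

* The gating benefit (CoR gated ≤ ungated for FT-MRS) is demonstrated on the
  noiseless motion-on cohort, where cardiac motion is the only
  gating-sensitive variance source. At the in vivo noise level the fit-noise
  floor (amplified ~2× above the CRLB by residual model mismatch at the
  contaminated septal voxel) dominates the motion term, and with i.i.d.
  per-readout phases the ungated penalty is structurally smaller than in
  vivo, making the comparison a coin flip there.
* In the FOV-shift sweep the compensated-SLAM invariance and the
  SLAM > compensated and FT > compensated orderings reproduce, but the
  published FT > SLAM ordering does not: the selection rule keeps the FT
  voxel two voxels clear of any chest-wall label, bounding its shift
  response by PSF tails, while uncompensated SLAM misregisters a whole
  boundary row of a 48-voxel heart. The corresponding acceptance assertion
  is left red deliberately.

## Numerical conventions

Signed k indices −N/2…N/2−1; forward exponent $e^{-i2\pi k\cdot r/N}$;
voxel-centre coordinates with the FOV centred on 0; half-open boxes (min ≤ p
< max) so rasterization has no boundary ties; deterministic tie-breaks
(lowest linear index) in voxel selection; all experiment randomness derived
from a single config seed through a fixed integer hash, keeping every seed
below 2³¹. Degenerate inputs fail loudly with classed conditions
(`slamrecon_param_error`, `slamrecon_consistency_error`,
`slamrecon_underdetermined_error`, …) rather than returning silent defaults.
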