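---
title: "Methods: multiparametric cardiac MR quantification in the mouse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric cardiac MR quantification in the mouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrquant)
```

cmrquant quantifies the cardiac and adipose phenotype of metabolic heart
disease in mice from reconstructed MR images: fat quantity and quality
(PDFF, T1, fatty acid composition) of the epicardial and subcutaneous
depots, myocardial perfusion and perfusion reserve, systolic and diastolic
strain, and standard cine LV structure and function, followed by
cohort-level statistics. This vignette describes each model, its
assumptions, and the design decisions behind the implementation. Because
raw preclinical image data of this kind are rarely shared, every stage is
paired with a synthetic generator that produces its input modality with
known ground truth; all quantitative claims made here are the ones the test
suite and the acceptance script compute.

## The nine-resonance triglyceride model

Fat is modelled as a mean triglyceride whose ^1^H spectrum contains nine
resonances at fixed chemical shifts (0.90–5.29 ppm; water at 4.70 ppm).
Each resonance's amplitude is the proton count of the corresponding
chemical group, an affine function of three parameters: the mean chain
length `cl`, the mean number of double bonds per triglyceride `ndb`, and
the mean number of methylene-interrupted double-bond pairs `nmidb`. The
table is exposed as data (`default_fat_spectrum()`, JSON load/save) so
alternative literature coefficient sets can be swapped in. A useful
self-consistency check fixes the normalisation: at `(cl = 18, ndb = 6,
nmidb = 3)` the amplitudes sum to 98, the proton count of trilinolein.

Composition follows the established linear relationships
`pufa = nmidb/3`, `mufa = (ndb − 2·nmidb)/3`, `sfa = 1 − mufa − pufa`,
with the exact inverse `nmidb = 3·pufa`, `ndb = 3·mufa + 6·pufa` used by
the phantom generator. The admissible `(cl, ndb, nmidb)` domain is the set
for which all three fractions lie in [0, 1] and all peak amplitudes are
non-negative; violations raise domain errors naming the invariant.

Chain length defaults to 17.3, the conventional adipose estimate, and is
fixed during fitting (fitting `cl` per voxel is unidentifiable at these
echo spacings). The spectrometer frequency defaults to 400.2 MHz (9.4 T);
temperature- or field-dependent shift corrections are out of scope.

## Joint water/fat/T1 estimation

The acquisition is an ECG-gated inversion-recovery multi-echo gradient
echo: 20 echoes from 1.4 ms in 0.2 ms steps, 30 inversion times from
3.7 ms spaced by the RR interval (default 0.12 s). The complex voxel
signal is modelled as

$$S(TI, TE) = \left(1 - 2\beta e^{-TI/T_1}\right)
  \left[W + F\, c_F(TE)\right] e^{-R_2^* TE}
  e^{i(2\pi \psi TE + \phi_0)}$$

with water and fat amplitudes $W, F$, a single shared $T_1$ (the depot
metrics report one T1, and separate water/fat T1s are poorly conditioned
here), inversion efficiency $\beta \in [0.5, 1]$ fitted per voxel, a
single-compartment $R_2^* \in [0, 2000]$ s⁻¹, field offset $\psi$, global
phase $\phi_0$, and the fat dephasing factor $c_F$ from the spectral
model with per-voxel `(ndb, nmidb)`. No Look-Locker apparent-T1 correction
is applied by default: a gated single-readout-per-TI acquisition is
assumed, and the recovery model should be adjusted by the user if a
Look-Locker train applies.

Estimation is complex least squares with variable projection: for any
candidate set of the six nonlinear parameters
$(T_1, R_2^*, \psi, \beta, ndb, nmidb)$ the two complex amplitudes are
solved in closed form from the 2×2 normal equations, whose entries factor
over the TI ⊗ TE grid, making each objective evaluation O(nTI + nTE) after
one O(nTI·nTE) projection of the data. $W$ and $F$ are the moduli of the
solved amplitudes and $\phi_0$ the phase of the dominant one. The field
offset — the classic source of fat–water swaps — is initialised by a
64-node grid over ±1/(2ΔTE) (±2.5 kHz at ΔTE = 0.2 ms); the best two
nodes (ties broken toward the smallest |ψ|) seed box-constrained
quasi-Newton refinement, followed by a tight polish. T1 is initialised
from the inversion-recovery null of the first-echo magnitudes
($T_1 \approx TI_{null}/\ln 2$). A voxel that fails to converge is
flagged in a quality mask rather than raising an error, and `NaN` marks
out-of-mask or unavailable values throughout.

PDFF is $F/(W+F)$. The fitted `(ndb, nmidb)` map to SFA/MUFA/PUFA per
voxel; values that land marginally outside the composition simplex at the
optimiser's box bounds are clamped. On a noiseless 32×32 four-region
phantom (PDFF 0/0.3/0.8/1.0, T1 0.7–1.3 s, SFA 0.3–0.6) the fitter
recovers PDFF to better than 0.005, T1 to 0.5% and composition to 0.01;
at SNR 30 the mean errors stay under 0.02 (PDFF), 5% (T1) and 0.05 (SFA).
These phantom sizes were chosen so the whole recovery suite runs in a few
minutes on one CPU; the per-voxel cost is independent of image size.

## Depot metrics

Depot ROIs come from manual segmentation masks (labels: 1 EAT, 2 SAT,
3 myocardium). To restrict the analysis to fat-dominant voxels, in-depot
voxels with PDFF below 50% are excluded; the boundary value 0.50 itself is
kept, since the operative exclusion rule is "below 50%". A depot with
fewer than 30 surviving voxels is flagged as excluded — small depots carry
disproportionate partial-volume contamination. Both rules apply to the
adipose depots only; the myocardial PDFF is an unthresholded mean. `NaN`
voxels (failed fits) are dropped before averaging so they cannot poison
depot means. The EAT SFA index is the EAT mean SFA referenced to SAT; EAT
volume is the end-diastolic pixel count across all cine slices times the
per-pixel volume (0.2 × 0.2 × 1.0 mm = 0.038 mm³ at the default cine
geometry), indexed to body weight (µL/g). Whether the original depot
means were single-slice or multi-slice is not material here: the summary
operates on whatever slice set the masks provide.

## ASL perfusion

Flow uses the FAIR relation for selective/global inversion pairs,

$$MBF = 60\,\frac{\lambda}{T_{1,blood}}
  \left(\frac{T_{1,glob}}{T_{1,sel}} - 1\right) \textrm{ mL/g/min},$$

with partition coefficient λ = 0.95 mL/g and blood T1 = 2.0 s by default,
both configurable since quantification constants are hardware- and
field-strength-specific. Noise can invert the T1 ordering; nominally
negative flows are reported as 0 with a flag rather than as negative
values. The perfusion reserve (MPR) is stress MBF divided by rest MBF,
undefined at non-positive rest flow. The generator inverts the relation
exactly, so prescribed flow fields are recovered to machine precision and
an MPR of 2 survives 2% T1 noise to within 5%.

## DENSE strain

Displacement encoding stores tissue displacement in image phase at
`ke` cycles/mm; displacement is unwrapped phase over `2π·ke`. Unwrapping
is quality-guided region growing (seed at the highest quality value, ties
to the lowest linear index; constant quality degrades to deterministic
breadth-first growth), which leaves a per-component global 2π ambiguity —
harmless, because strain only sees displacement gradients. The deformation
gradient is computed by mask-aware central differences on the reference
grid (one-sided at wall edges) and the Green–Lagrange tensor
$E = (F^\top F - I)/2$ follows. The "longitudinal" direction on the
long-axis slice is the local wall tangent, taken perpendicular to the ray
from the wall centroid — the arc-length tangent of the mid-wall contour
for an annular wall. The global curve averages the tangential strain over
6 angular segments (configurable; the study's segment count is not
constrained by the data model).

End-systolic strain is the signed extremum of the global curve; PDSR is
the maximum central-difference strain rate after the end-systolic frame,
positive during recovery of negative strain, and missing for curves with
no recovery phase. No temporal smoothing is applied unless explicitly
requested (3-point moving average), because PDSR is derivative-based and a
hidden filter would bias it. The phantom deforms an annulus by uniform
dilation with stretch $\lambda(t) = \sqrt{1 + 2\,\ell(t)}$, making the
tangential strain equal the prescribed curve
$\ell(t) = \epsilon_{es}\sin^2(\pi t/T)$ at every pixel — exact ground
truth for the whole phase → displacement → strain → GLS chain, at the cost
of realism (no incompressibility, no through-plane motion, schematic
geometry). Frame timing defaults to the DENSE TR of 7 ms over a 0.12 s
cycle; at that sampling the central-difference PDSR estimate of the
prescribed curve is biased low by ≈2%, within the 5% recovery band the
tests enforce.

## Cine LV metrics

Volumes are slice-summed (Simpson's rule with contiguous slices): per-slice
mask area times slice thickness, in µL. LV mass is the ED epi–endo shell
volume times 1.05 mg/µL. EF is `100·(EDV − ESV)/EDV`. Wall thickness is
measured on a single mid-ventricular slice as the mean over 24 radial rays
from the epicardial centroid of the difference between outermost
epicardial and endocardial radii; ray count and the single-slice policy
are configurable conventions, since the delegating analysis tool's recipe
is not published. The cine phantom digitises a half-ellipsoid LV
(a = 1.5 mm, c = 4 mm, 8 slices) whose closed-form volume
$(2/3)\pi a^2 c \approx 18.85$ µL anchors the discretisation error, kept
under 5% at 0.2 mm pixels; end-systole shrinks the endocardial radii by
$\sqrt{0.35}$ so the continuous volume ratio, and hence the true EF of
65%, is exact by construction.

## Cohort statistics

GTT AUC is the trapezoid rule on the glucose-time curve (default grid 0,
10, 30, 60, 90, 120 min), in min·mg/dL. Group comparisons follow a
normality-gated policy: any group with n ≤ 10 routes to non-parametric
tests (Mann–Whitney U for two groups, Kruskal–Wallis beyond); larger
groups are tested per group with Shapiro–Wilk at α = 0.05 and use the
two-tailed Student's t-test (Welch form) or ANOVA only when every group
passes. Significance is two-sided at 0.05. Summaries report mean ± SD on
the parametric branch and median [IQR] otherwise. The classical tests
themselves are R's standard implementations; the package owns the
selection policy and reporting. Under the null (equal means, n = 15 per
group) the policy's rejection rate over 2000 simulated cohorts sits at the
nominal 5% within Monte-Carlo tolerance. The cohort generator's default
effect model is the study design assumption of a perfusion-reserve shift
of 0.4 with SD 0.35; simulated two-group power at n = 15 agrees with the
noncentral-t closed form. A power analysis reproducing the original
design's n = 10/13 per group is not implemented: the sidedness and
approximation behind those numbers cannot be reconstructed from the
stated two-tailed α = 0.05, so the package deliberately stops at the
forward simulation.

## Numerical conventions and limitations

Times are seconds internally (reported in conventional units: ms for
TE/TI, s for T1, s⁻¹ for PDSR, mL/g/min for MBF); voxel indices are
1-based in R fashion with geometry carried by NIfTI metadata; all
stochastic generators require an explicit seed and are bit-reproducible
given one. The synthetic phantoms are schematic — uniform regions,
image-space complex Gaussian noise (SNR = mean in-mask magnitude / noise
SD), no k-space sampling, motion, or reconstruction artifacts — so
passing recovery tests demonstrates correctness of the estimators under
their own forward models, not robustness to the full physics of in vivo
acquisition. Undersampled-reconstruction methods, automated segmentation,
B1/slice-profile corrections, tissue tracking and 3-D strain are out of
scope. `run_pipeline()` composes every stage over one synthetic study and
writes per-stage CSV/JSON outputs with a manifest (seed, config hash,
package version, stage status); reruns with the same seed are
byte-identical.
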