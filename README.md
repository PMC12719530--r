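# cmrquant

Multiparametric cardiac MR quantification for preclinical (mouse) studies
of metabolic heart disease. Obesogenic diets remodel the epicardial
adipose tissue (EAT) that shares microcirculation with the myocardium;
characterising that remodelling and its cardiac consequences takes a panel
of quantitative MR readouts. cmrquant implements the full analysis panel
in R, from reconstructed images and manual segmentation masks to cohort
statistics:

- **Joint water/fat/T1 mapping** — complex inversion-recovery multi-echo
  signals are fit voxel-wise with a nine-resonance triglyceride model by
  variable projection, giving PDFF, T1, R2\*, field-offset and fatty acid
  composition (SFA/MUFA/PUFA) maps. The signal model is

  $$S(TI, TE) = \left(1 - 2\beta e^{-TI/T_1}\right)\left[W + F\,c_F(TE)\right]
    e^{-R_2^* TE}\, e^{i(2\pi\psi TE + \phi_0)}$$

  with the fat factor $c_F(TE) = \sum_{p=1}^{9} a_p e^{i 2\pi \Delta f_p TE}$
  and peak amplitudes $a_p$ affine in the mean chain length and
  double-bond counts (ndb, nmidb), which map linearly to SFA/MUFA/PUFA.
- **Adipose depot metrics** — PDFF-thresholded ROI means (voxels below
  50% PDFF excluded, depots with < 30 surviving voxels flagged), the EAT
  SFA index referenced to subcutaneous fat, and the EAT volume index
  (µL/g body weight) from end-diastolic cine masks.
- **ASL perfusion** — FAIR quantification of myocardial blood flow,
  $MBF = 60\,(\lambda/T_{1,blood})(T_{1,glob}/T_{1,sel} - 1)$ mL/g/min,
  and the myocardial perfusion reserve (stress/rest).
- **DENSE strain** — quality-guided phase unwrapping, displacement fields
  from encoded phase, Green–Lagrange strain, global longitudinal strain
  and peak diastolic strain rate (PDSR).
- **Cine LV metrics** — slice-summation volumes, mass, ejection fraction,
  ray-cast wall thickness.
- **Cohort statistics** — trapezoidal glucose-tolerance AUC,
  normality-gated test selection (Mann–Whitney/Kruskal–Wallis for small or
  non-normal groups, t-test/ANOVA otherwise), Spearman correlations.
- **Synthetic data** — every input modality can be generated with known
  ground truth (`make_fatwater_phantom()`, `make_asl_phantom()`,
  `make_dense_phantom()`, `make_cine_phantom()`, `make_cohort()`), so each
  stage is verifiable by parameter recovery without any data download.

Results come back as tibbles; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

Fit a small synthetic phantom and summarise its depots:

```r
library(cmrquant)

sched <- acquisition_schedule(n_ti = 10, rr = 0.3)
ph  <- make_fatwater_phantom(size = 8, schedule = sched)  # noiseless
fit <- fit_stack(ph, ph$mask)
fit
#> <fatwater_fit> 8 x 8 maps, 64 fitted voxels (0 flagged)
#>   PDFF range 0.000-1.000, T1 range 0.700-1.300 s

labels <- matrix(0L, 8, 8)
labels[ph$region_map == 3] <- 1L   # EAT-like region
labels[ph$region_map == 4] <- 2L   # SAT-like region
summarise_depots(labels, fit, label_map = c(EAT = 1L, SAT = 2L),
                 min_voxels = 10)
#> # A tibble: 2 × 9
#>   depot n_voxels_initial n_voxels_kept excluded mean_pdff mean_t1 mean_sfa
#>   <chr>            <int>         <int> <lgl>        <dbl>   <dbl>    <dbl>
#> 1 EAT                 16            16 FALSE        0.800   0.700    0.600
#> 2 SAT                 16            16 FALSE        1.000   0.700    0.450
```

The fitted per-voxel PDFF, T1 and composition match the phantom's
prescribed regions (PDFF 0.8 / T1 0.70 s / SFA 0.60 for the EAT-like
depot); `mean_sfa` ratios give the SFA index
(`sfa_index(0.60, 0.45)` = 1.33).

Strain from a displacement-encoded series with a prescribed
end-systolic strain of −0.15 over a 0.12 s cycle:

```r
crv <- analyse_dense(make_dense_phantom())
glance(crv)
#> # A tibble: 1 × 4
#>      gls es_strain es_frame  pdsr
#>    <dbl>     <dbl>    <int> <dbl>
#> 1 -0.149    -0.149       10  3.83
```

GLS recovers the prescribed −0.15 to within 0.001 and the PDSR of
3.93 s⁻¹ to within 2.5% (the central-difference bias at 7 ms frame
spacing). `run_pipeline(out_dir, seed)` composes all five modalities over
one synthetic study and writes per-stage CSVs plus a manifest.

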