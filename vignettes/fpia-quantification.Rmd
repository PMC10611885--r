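---
title: "Quantifying dynamic PET/MRI of glioma: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic PET/MRI of glioma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpiaquant)
```

## The problem

Gliomas span a wide malignancy range, and conventional contrast-enhanced MRI
discriminates lower-grade (WHO 2, LGG) from higher-grade (WHO 3–4, HGG)
tumours poorly. A short-chain-fatty-acid PET radiotracer that is irreversibly
trapped in tissue offers a complementary axis: its net influx rate constant
and static uptake should scale with malignancy. `fpiaquant` implements the
full quantification chain for a simultaneous dynamic PET/MRI protocol of this
kind — a 66.5-min dynamic PET acquisition with arterial blood sampling,
together with DCE, DSC, pASL and DWI MRI arms — plus the group statistics and
penalised classification used to ask whether the combined feature set
separates LGG from HGG.

Because patient imaging of this kind cannot be publicly deposited, the package
ships a first-class digital-phantom generator (`generate_study()`) that
produces complete synthetic studies with known ground truth. Every estimator
in the package is validated against that ground truth.

## PET kinetic models

**Forward model.** Tissue activity follows an irreversible two-tissue
compartment model (`tissue_response()`):

$$C_T(t) = (1 - v_b)\, h \otimes C_p(t) + v_b C_b(t), \qquad
h(t) = K_1\!\left[\frac{k_3}{k_2+k_3} + \frac{k_2}{k_2+k_3} e^{-(k_2+k_3)t}\right],$$

with $K_1$ (mL/cm³/min) delivery, $k_2$, $k_3$ (/min) efflux and trapping,
$v_b$ the blood volume fraction, and $k_4 = 0$ because the tracer is trapped.
The macro parameter is the net influx rate $K_i = K_1 k_3/(k_2+k_3)$.
Convolution runs on a 1-s grid with a trapezoid-accurate end-point correction,
and frame values are interval averages over each frame — matching how a
scanner integrates counts — rather than point samples.

**Patlak graphical analysis** (`patlak_fit()`) regresses $C_T/C_p$ on the
normalised time $\int_0^t C_p/C_p$ over frames with mid-time $\ge t^*$. We
default $t^* = 15$ min: for the rate constants relevant here
($k_2 + k_3 \approx 0.25$/min) the reversible compartment equilibrates with a
time constant of ~4 min, so 15 min leaves a comfortably linear tail while
keeping 13 frames in the fit; an $r^2$-based warning fires when linearity
fails. The late-time slope estimate carries a small negative bias (~1–2%)
because the reversible transient never fully vanishes; the tests bound it at
5%.

**Nonlinear compartmental fit** (`fit_2tc()`) is bounded Levenberg–Marquardt
(via `minpack.lm`) on the same forward model, weights proportional to frame
duration, with bounds $K_1 \in [0,2]$, $k_2,k_3 \in [0,5]$,
$v_b \in [0,0.2]$ and ten seeded random restarts. On noise-free
self-generated data it recovers all four parameters to better than 0.1%.

**Spectral analysis** (`spectral_analysis()`) decomposes the TAC as a
nonnegative sum of input-convolved exponentials over a 100-point log-spaced
grid of decay rates $\beta \in [0.001, 10]$/min, augmented with $\beta = 0$
(trapping) and a whole-blood column, solved by non-negative least squares
(`pracma::lsqnonneg`). The weight on $\beta = 0$ is a trapping-rate estimate
(`Ki_trap`) independent of the Patlak route; the reversible components give a
distribution-volume summary $V_T^{rev} = \sum_{\beta>0} \alpha/\beta$. An
irreversible-configuration compartment fit has no finite $V_T$, so the
spectral $V_T^{rev}$ is the package's reported partitioning measure.

## Blood processing

The input function is assembled from two arms (`build_input_function()`): a
continuous whole-blood detector covering 0–10 min and discrete samples at
2.5, 15, 30, 45 and 60 min. The continuous curve is least-squares
cross-calibrated to the overlapping discrete samples; plasma is obtained with
a constant plasma/whole-blood ratio fitted from the discrete samples; the
parent fraction is interpolated monotonically with $pf(0)=1$ (the tracer is
essentially non-metabolised, so the default simulation uses $pf \equiv 1$; a
declining-sigmoid mode exercises the correction); and the tail is continued
piecewise-linearly through the discrete points, anchored at the 10-min value
for continuity. A population template (`population_input_function()`)
averages measured curves after SUV-style normalisation by injected dose over
body weight — the normalisation is our choice (it makes the template unitless
and rescalable); leave-one-out tests show Patlak $K_i$ shifts under 15% when
a patient is quantified with the population curve instead of their own.

## Static PET measures

SUV is activity divided by dose per body weight (`compute_suv()`), density
1 g/mL. Two static windows are supported: the duration-weighted mean of the
last five frames (26 min) and the single frame whose mid-time is closest to
60 min. No frame of the default schedule has mid-time exactly 60 min; the
55.5–60.5-min frame (mid-time 58 min) is the one selected, which we flag here
explicitly. Blood-pool correction subtracts a *normalised* sinus signal,
`SUVc = SUV − blood_fraction × mean(sinus SUV)`; the scaling of the sinus
(pure blood) signal to a tissue blood-volume fraction is not fully specified
in the source protocol, so `blood_fraction` is a parameter defaulting to
0.05, a nominal cerebral blood volume fraction. Threshold segmentation keeps
voxels above 30% or 40% of the region maximum restricted to the 26-connected
component containing the hottest voxel — without the connectivity restriction
low-uptake scans select disconnected background. Overlap against the
contrast-enhancing MRI volume is scored by Dice and by percent volume
variation, `(V_mri − V_suv)/V_suv × 100`, whose argument order is asymmetric
by definition.

## MRI arms

* **DCE**: spoiled-gradient-echo signals are inverted to concentration via
  the SPGR signal equation given a native $T_{10}$ and relaxivity
  ($r_1 = 4.5$/mM/s at 3 T); the extended Tofts model
  $C_t = v_p C_p + K^{trans} \int C_p e^{-k_{ep}(t-\tau)}$ is fitted with
  $v_e = K^{trans}/k_{ep}$ exactly consistent in the output. Region-mean
  curves are fitted, matching region-level reporting; the vascular input is
  image-derived from the sagittal-sinus signal.
* **DSC**: $\Delta R_2^*(t) = -\ln(S/S_0)/TE$; CBV is the tissue/arterial
  curve-integral ratio; leakage is corrected Boxerman-style by regressing the
  tissue curve on a non-leaky reference (the mean over non-lesion brain) and
  its running integral, adding the leakage term back for CBVlc; CBF comes
  from block-circulant SVD deconvolution with singular values below 20% of
  the maximum zeroed (a standard oscillation-control threshold); MTT =
  CBV/CBF; TTP is the curve maximum. Perfusion values are reported relative
  to contralateral white matter.
* **pASL**: the QUIPSS-II single-subtraction model,
  $CBF = 6000 \lambda \Delta M / (2 \alpha M_0 TI_1 e^{-TI_2/T_{1b}})$, with
  3-T constants $\lambda = 0.9$ mL/g, $\alpha = 0.98$, $T_{1b} = 1.65$ s.
* **DWI**: ADC by log-linear least squares over b-values, exact for
  noiseless mono-exponential decay.

The water-exchange (shutter-speed) DCE parameterisation is deliberately out
of scope: no generating model is defined for it here.

## The digital phantom

`phantom_spec()` defines a 64×64×48 grid of 2-mm voxels holding a spherical
FLAIR lesion (14 mm radius; concentric contrast-enhancing core at 70%
radius), a mirrored contralateral sphere, a contralateral-white-matter
sphere, and a sagittal-sinus tube carrying the whole-blood curve. The input
function is a tri-exponential (Feng-type) bolus with a sustained tail —
chosen because tissue curves of a trapped tracer keep rising over the whole
scan, which requires late plasma availability. PET frames are
frame-integrated forward-model curves, voxelised, blurred with a 5-mm FWHM
Gaussian (emulating reconstruction smoothing), with zero-mean Gaussian noise
whose variance scales as 1/frame-duration — the testable contract of
post-reconstruction noise on decay-corrected frames, which is approximately
Gaussian rather than Poisson. MRI series are generated voxelwise from the
same forward models the estimators invert.

Grade presets (`grade_presets()`) increase $K_1$ and $k_3$, permeability and
perfusion with grade, elevate $v_e$ only in the grade-4 preset, and give HGG
lower ADC. They were calibrated once so that the simulated cohort reproduces
the qualitative orderings expected of the tracer (SUVmax and $K_i$ grade
II < III < IV; TBR ≥ 2 in high-grade lesions; $v_e$ elevated only in grade
IV) and are configuration of the phantom, not measured values. What passing
tests show is that the estimators invert their generating models and that the
pipeline preserves known orderings through image formation, blur and noise;
they do not show that real tissue follows these models, that real lesions are
spherical or homogeneous, or that scanner artefacts (motion, attenuation,
scatter) are handled.

A region-level companion, `simulate_cohort_tacs()`, draws lesion-mean TACs
directly with noise scaled down by an effective number of independent voxels
(default 64 — a 1–2-cm lesion at 2-mm voxels retains on the order of tens of
independent samples after 5-mm PSF smoothing). It exists for experiments that
need many cohort replicates, such as the power estimate below.

## Statistics and classification

Group comparisons use a two-sided Wilcoxon rank-sum test whose null
distribution is obtained by full enumeration of all $\binom{n+m}{n}$ mid-rank
assignments for $n+m \le 12$ — exact also under ties — and a tie-corrected
normal approximation beyond. No multiplicity correction is applied by
default (a Benjamini–Hochberg option exists). Within-patient lesion-vs-CWM
contrasts use the paired signed-rank test.

Grade classification is an L1-penalised model over the per-patient feature
table with stratified 5-fold cross-validation selecting `lambda.min`
(`glmnet` backend). Logistic loss requires every CV training split to contain
both classes, which is arithmetically impossible when a class has only two
members — exactly the situation of a pilot cohort with two LGG patients. The
default `family = "auto"` therefore uses logistic loss when each class has at
least three members and otherwise falls back to penalised least squares on
0/1 labels, the classical "penalised least-squares classification" shape,
which remains well defined at any class size. Features are z-scored so
coefficients are comparable; perfusion features enter CWM-normalised,
SUV/kinetic features raw.

## Worked example

```{r pipeline, eval = FALSE}
run <- run_pipeline(seed = 7)
run$features |> dplyr::select(patient_id, who_grade, SUVmax_60, Ki_patlak, ve)
run$comparisons
run$lasso$selected
```

The cohort composition defaults to two grade-2, three grade-3 and five
grade-4 patients. The cohort run uses a 48×48×32 grid — region-level
quantification is insensitive to the coarser sampling, and it keeps a full
ten-patient simulation fast; single-study work can use the full default
geometry.

## Numerical choices and limitations

* Convolutions: FFT-based with trapezoid end-point correction (O(dt²)); 1-s
  default grid for forward simulation and compartment fitting, 2-s available
  where many replicate fits are needed.
* The multistart optimiser draws restarts from the lower part of the bound
  box (physiological rates); non-convergence of every start is flagged, never
  silent.
* Degenerate inputs are errors, not NaNs: empty masks, nonpositive baselines,
  single-class cohorts, input functions nonpositive over the Patlak window.
* Masks are resampled to the PET grid by nearest neighbour; all overlap
  metrics are computed there.
* Region-level (not voxelwise) kinetic and DCE fitting only; no partial
  volume correction, no delay/dispersion fitting, no motion handling; DICOM
  ingestion and image reconstruction are out of scope.
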