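# fpiaquant

Quantification pipeline for simultaneous dynamic PET/MRI studies of glioma
with an irreversibly trapped (short-chain fatty acid) radiotracer, together
with the statistics used to ask whether imaging features separate lower-grade
(WHO 2) from higher-grade (WHO 3–4) tumours.

Neuro-oncology imaging teams face a recurring problem: contrast-enhanced MRI
alone discriminates glioma grade poorly, and evaluating a new PET tracer
against multi-parametric MRI requires a long chain of quantification steps —
blood-data processing, kinetic modelling, static uptake measures, perfusion
and diffusion MRI fits, and a classifier over the joint feature set — each of
which is usually buried in site-specific scripts. `fpiaquant` implements that
chain as a tested, reusable R package, and pairs it with a seeded
digital-phantom generator so every estimator can be validated against known
ground truth.

## What it computes

**PET kinetics.** For a tracer with irreversible trapping the two-tissue
compartment model has impulse response

    h(t) = K1 * [ k3/(k2+k3) + k2/(k2+k3) * exp(-(k2+k3) t) ],   k4 = 0

and tissue curve `CT = (1-vb)·(h ⊗ Cp) + vb·Cb`. The package provides the
forward model (`tissue_response()`), Patlak graphical analysis
(`patlak_fit()`, slope = net influx rate Ki = K1·k3/(k2+k3)), a bounded
multistart nonlinear fit (`fit_2tc()`), and spectral analysis by non-negative
least squares over input-convolved exponentials (`spectral_analysis()`),
whose zero-decay component is an independent trapping estimate.

**Blood processing** (`build_input_function()` and friends): least-squares
cross-calibration of a continuous arterial detector against discrete samples,
metabolite (parent-fraction) correction, continuous/discrete merging, and
dose-per-weight–normalised population input functions.

**Static PET** (`compute_suv()`, `blood_correct()`, `tbr()`,
`threshold_mask()`, `dice()`, `volume_variation()`): SUV windows (last-26-min
mean or the frame nearest 60 min), blood-pool–corrected SUVc, tumour-to-brain
ratios, 30%/40%-of-max threshold masks restricted to the connected component
of the hottest voxel, and PET-vs-MRI overlap scores.

**MRI arms** (`dce_signal_to_concentration()`, `fit_extended_tofts()`,
`dsc_quantify()`, `asl_cbf()`, `fit_adc()`): extended Tofts DCE (Ktrans, kep,
ve, vp), leakage-corrected DSC perfusion with block-circulant SVD
deconvolution (CBV, CBVlc, CBF, MTT, TTP), QUIPSS-II pulsed-ASL CBF, and
log-linear ADC, with contralateral-white-matter normalisation.

**Statistics** (`wilcoxon_rank_sum()`, `group_compare()`,
`lasso_classify()`): an exact mid-rank enumeration Wilcoxon test (valid under
ties), pairwise grade comparisons, and L1-penalised classification with
stratified cross-validated lambda selection.

**Phantom** (`phantom_spec()`, `generate_study()`,
`simulate_cohort_tacs()`): complete synthetic PET/MRI studies — lesion,
contralateral, white-matter and sagittal-sinus geometry, bolus input
function, frame-integrated PET with PSF blur and duration-scaled noise,
DCE/DSC/ASL/DWI series — with the full generating truth recorded.

## Worked example

Simulate one grade-4 study and quantify it:

```r
library(fpiaquant)

st <- generate_study(phantom_spec(grade = 4, seed = 11, grid_shape = c(48, 48, 32)))
q  <- quantify_study(st)
q[, c("SUVmax_60", "TBRmax_60", "Ki_patlak", "K1", "ve", "CBV_rel", "ADC")]
#>   SUVmax_60 TBRmax_60 Ki_patlak     K1   ve CBV_rel      ADC
#> 1       1.9      7.15    0.0137 0.0883 0.18    3.08 0.000853

attr(q, "fits")$patlak
#> <patlak_fit> Ki = 0.01368 mL/cm^3/min, V0 = 0.3392 , r^2 = 0.9998 ( 10 frames, t* = 15 min )
```

The lesion's static uptake (SUVmax 1.9) sits well above contralateral brain
(TBRmax 7.2 in this noiseless-background phantom), the Patlak plot is linear
(r² ≈ 1) with a clearly non-zero influx rate Ki ≈ 0.014 mL/cm³/min, the
fitted delivery K1 ≈ 0.088 recovers the generating preset (0.085), and the
DCE-derived ve of 0.18 matches the grade-4 preset exactly. A full cohort —
two grade-2, three grade-3, five grade-4 patients — runs end to end with

```r
run <- run_pipeline(seed = 7)
run$features       # per-patient feature table
run$comparisons    # pairwise LGG/HGG rank-sum p-values
run$lasso$selected # features kept by the penalised classifier
```

and reproduces the expected grade structure: SUVmax and Ki increase grade
II < III < IV and the classifier retains PET uptake features.

Fitted objects have `tidy()`, `glance()` and `autoplot()` methods (Patlak
plots, kinetic spectra, TACs, coefficient bars).

## Scope

Region-level quantification (no voxelwise parametric maps), NIfTI input,
masks as inputs. Image reconstruction, DICOM handling, motion correction,
partial-volume correction and survival analysis are out of scope. See the
vignette (`vignettes/fpia-quantification.Rmd`) for the models, the phantom's
assumptions and what passing tests do and do not establish about real data.
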