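# synthlge

Synthetic gadolinium enhancement from cardiac T1 maps: simulation and
analysis of early synthetic gadolinium enhancement (ESGE) imaging of
myocardial scar.

## The problem

Conventional late gadolinium enhancement (LGE) cardiac MR requires a second
contrast bolus and roughly ten extra minutes of scanner time after
stress-perfusion imaging. An alternative is to acquire a pixel-wise
post-contrast T1 map a couple of minutes after the first bolus and compute
*synthetic* phase-sensitive inversion-recovery (PSIR) images from it at any
inversion time TI, because the ideal-inversion, full-recovery IR signal is a
closed form in the fitted T1:

    S(TI) = 1 − 2 exp(−TI / T1)

Scar retains more gadolinium than remote myocardium, so its T1 is shorter
and its signal at the myocardium-nulling TI = T1_myo · ln 2 is brighter.
Scar is then delineated with the standard binary threshold rule — a
myocardial pixel is infarct when its signal exceeds the mean of a
normal-myocardium reference ROI (≥ 100 pixels) by five standard
deviations — and bookkept on the AHA segment model: 6 segments on each
basal and mid-ventricular short-axis slice, 4 on the apical slice, i.e. 28
subsegments for the standard 5-slice set (2 basal, 2 mid, 1 apical). Scar
burden is reported as mass: pixels × pixel area × slice thickness ×
1.05 g/ml.

`synthlge` implements the full chain on a built-in synthetic left-ventricle
phantom, so every stage is testable without clinical data:

1. **phantom** — concentric-annulus LV slices with scar wedges of known
   angular span and transmurality, exact ground-truth masses, and a
   214-patient cohort generator (23 scar-positive) with two-reader
   quantification jitter;
2. **relaxometry** — MOLLI 4(1)3(1)2 sampling (9 images in 11 heartbeats,
   initial TI 100 ms, 80 ms increment), simulation of magnitude IR samples,
   and per-pixel three-parameter fitting S(t) = A − B·exp(−t/T1\*) with
   polarity restoration and Look-Locker correction T1 = T1\*(B/A − 1);
3. **synth_ir** — PSIR synthesis at arbitrary TI (default series: 40 images,
   TI 200…1175 ms in 25 ms steps) and myocardium-nulling TI selection;
4. **scar_quant** — AHA segment maps, 5-SD thresholding, mass computation,
   per-subsegment positivity calls;
5. **agreement** — contingency tables with Clopper-Pearson CIs,
   Bland-Altman, ICC(2,1), Wilcoxon/paired-t/Pearson, and `run_study()`
   which applies the whole analysis plan to a cohort.

## Worked example

```r
library(synthlge)

# a 5-slice phantom with one 70-degree, 60%-transmural scar wedge on slice 3
cfg <- phantom_config(scar_specs = list(scar_spec(3, 20, 70, 0.6)))
ph  <- make_lv_phantom(cfg)
ph$ground_truth
#> <lv_ground_truth> 5 slices, scar mass 0.00/0.00/1.10/0.00/0.00 g (total 1.098 g)

# simulate a MOLLI acquisition and fit one myocardial pixel
sam <- simulate_molli(ph$t1_maps[[3]], sampling_scheme(), noise_sd = 0.01, seed = 8)
sam
#> <molli_series> 9 magnitude images, 128 x 128 px, TIs 100, 180, 260, 957,
#>   1037, 1117, 1814, 1894, 2671 ms
fit_molli(data.frame(ti = sam$tis, magnitude = sam$images[40, 64, ]))
#> <ir_fit> T1 = 999.85 ms (T1* = 980.15, A = 0.9916, B = 2.003, rms = 0.00589)

# synthesize a PSIR image at the myocardium-nulling TI and quantify scar
gt     <- ph$ground_truth
remote <- gt$annulus[[3]] & !gt$scar_mask[[3]]
ti     <- optimal_ti(ph$t1_maps[[3]], remote, ti_grid())   # 350 ms
img    <- series_image(synthesize_series(ph$t1_maps[[3]], ti_grid()), ti)
set.seed(2); img <- img + matrix(rnorm(length(img), 0, 0.01), 128)
quantify_scar(list(img), list(gt$geometry[[3]]))
#> <scar_quant> 1 slices, 6 subsegments (2 positive), total 1.098 g at 5 SD
```

The recovered 1.098 g equals the ground-truth wedge mass: at 10× the noise
SD of contrast the 5-SD rule recovers the wedge pixel-exactly. The fitted
pixel sits in the background (T1 1000 ms) and comes back within 0.2 ms.

A full cohort study with the two-channel discordance pattern (one
false-negative and one false-positive patient among 23 scar-positive of
214):

```r
co <- make_cohort(cohort_spec(discordance = list(), seed = 4))
st <- run_study(co, digits = "display")
st
#> <agreement_report>
#>   patients: TP 22 FP 1 FN 1 TN 190; prevalence 10.7%
#>   subsegments: TP 77 FP 3 FN 1 TN 5911 (n = 5992)
#>   quantitative agreement in 22 concordant-positive patients (2 discordant excluded)
#>   r = 0.9900, mean difference -0.0577 +/- 0.1469 g, ICC 0.9878
```

Patient-level sensitivity rounds to 96% and NPV to 99.5%. Result objects
have `tidy()`, `glance()` and `autoplot()` methods (Bland-Altman plot, ICC
scatter, T1-map and IR-series rasters).

A thin command-line wrapper over the same functions ships in
`inst/cli/synthlge` with `simulate`, `fit`, `synthesize`, `quantify` and
`run-all` subcommands; `run_pipeline()` is the in-R equivalent.

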