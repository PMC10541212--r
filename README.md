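# rsi3c

Automated assessment of breast-tumor response to neoadjuvant therapy from
multi-b-value diffusion-weighted MRI (DWI).

Manual tumor sizing on contrast-enhanced MRI is the standard of care for
monitoring neoadjuvant treatment, but it is reader-dependent and requires
gadolinium. `rsi3c` implements an automated alternative built on a
three-component restriction-spectrum signal model: after a single manual
pre-treatment delineation, every later timepoint is sized automatically from
the diffusion data alone, and the resulting longitudinal measurements are
evaluated against the binary pathology endpoint (pathological complete
response, pCR) with a full diagnostic-statistics suite. A synthetic DWI
phantom generator makes the entire pipeline testable without patient data.

## The model and pipeline

The direction-averaged DWI signal of each voxel across b-values
(0, 500, 1500, 4000 s/mm² in the reference protocol) is decomposed as

    S(b) = C1·exp(−b·ADC1) + C2·exp(−b·ADC2) + C3·exp(−b·ADC3)

where the per-component apparent diffusivities `ADC_i` (restricted <
hindered < free/vascular, in mm²/s) are fixed across voxels and the
non-negative, unitless signal contributions `C_i` are fitted per voxel by
exact non-negative least squares. `C1` captures restricted diffusion
(cancer, fatty tissue), `C2` hindered diffusion (cancer, fibroglandular
tissue), `C3` fast diffusion and vasculature.

Per patient, the maps are normalized to the 95th percentile of
`sqrt(C1·C2)` inside a healthy contralateral control ROI. Joint (C1, C2)
histograms pooled over all patients' pre-treatment cancer and control ROIs
are converted through Bayes' rule into a lookup table of the posterior
probability of cancer, which maps each voxel of any timepoint to a
probability (the classifier map).

Tumor size is then measured automatically: the pre-treatment cancer ROI is
dilated by 1 cm into a *tumor-containing region* (augmented with any
classified component connected to it), the largest connected component of
voxels with posterior > 0.5 inside that region is extracted, and its longest
diameter in any plane is reported in cm — at every timepoint, using only the
single pre-treatment ROI. A conventional ADC map (log-linear fit over
b < 1000 s/mm²) provides the comparison metric.

The statistics layer scores absolute post-treatment values and relative
changes from pre-treatment (non-pCR is the positive class): Mann–Whitney ROC
AUC with DeLong variance, best-accuracy and specificity-constrained
(≥ 90 %) operating points, exact Clopper–Pearson intervals, exact McNemar
and DeLong paired comparisons at alpha 0.025.

## Worked example

```r
library(rsi3c)

# simulate a small longitudinal cohort (8 patients, half with pCR)
template <- phantom_config(noise_sigma = 0.09)      # Rician noise, SNR ~ 20
cohort <- generate_cohort(n_patients = 8, pcr_fraction = 0.5,
                          template = template, seed = 42)

# fit, train the pooled classifier, measure every timepoint
study <- run_phantom_study(cohort)
subset(study$dataset$records, timepoint == "post",
       select = c(patient_id, rsi_diameter_cm, dce_diameter_cm, mean_adc))
#>  patient_id rsi_diameter_cm dce_diameter_cm    mean_adc
#>         P01        0.000000        0.000000 0.001743989
#>         P02        0.000000        0.000000 0.001816647
#>         P03        0.000000        0.000000 0.001721152
#>         P04        0.000000        0.000000 0.001769712
#>         P05        1.581139        1.611926 0.001238464
#>         P06        2.000000        2.213285 0.001271483
#>         P07        1.581139        1.551093 0.001242235
#>         P08        4.000000        3.901343 0.001014060

# evaluate against the pathology endpoint
ev <- evaluate_cohort(study$dataset)
rsi <- ev$absolute$modalities$rsi
cat(sprintf("post-treatment RSI classifier: AUC %.2f, threshold %.2f cm\n",
            rsi$auc, rsi$threshold))
#> post-treatment RSI classifier: AUC 1.00, threshold 0.79 cm
```

The four simulated responders (P01–P04) measure 0 cm at post-treatment —
their lesions vanished and nothing in the tumor-containing region crosses
the 0.5 posterior threshold — while the non-responders retain diameters
between 1.6 and 4.0 cm; the automatic measurement tracks the synthetic
"manual" contrast-enhanced reading (`dce_diameter_cm`) closely, and mean
ADC is higher in responders, whose tumor bed has reverted to healthy
tissue. With complete separation, the post-treatment ROC AUC is 1 and the
chosen operating threshold (0.79 cm) splits the two groups.

Individual building blocks are exported too:

```r
mcnemar_exact(0, 6)
#> mcnemar_exact: statistic = 0, p = 0.03125 (alpha = 0.025)
clopper_pearson_ci(12, 17)
#>     lower     upper
#> 0.4404173 0.8968645
```

A file-based workflow (NIfTI volumes + FSL `.bval` sidecars + cohort CSV)
is available through `cmd_simulate()`, `cmd_fit()`, `cmd_train_classifier()`,
`cmd_measure()` and `cmd_evaluate()`, and from the shell via the thin
wrapper `inst/cli/rsi3c.R` (subcommands `simulate`, `fit`, `train`,
`measure`, `evaluate`).

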