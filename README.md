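# dtpa — dynamic texture parameter analysis for DSC-MRI time series

`dtpa` characterises brain tissue — enhancing lesions (EL), non-enhancing
lesions (NEL) and normal-appearing white matter (NAWM), as in multiple
sclerosis imaging — by tracking how **histogram-based texture statistics of
dynamic susceptibility contrast (DSCE) MRI difference images** evolve during
the passage of a gadolinium bolus. It is aimed at neuroimaging researchers
who want a quantitative, continuous grading of lesion microcirculation and
blood–brain-barrier leakage *without* pharmacokinetic perfusion modelling.

## Method in brief

From a 4D EPI series *S<sub>k</sub>(x)* the package computes
baseline-difference images *D<sub>k</sub>(x) = S<sub>0</sub>(x) −
S<sub>k</sub>(x)* and applies a twofold normalization: the NAWM
reference-region baseline mean is fixed to *C*<sub>ideal</sub> (coil load),
and the trapezoidal area of the reference difference curve over the
inflow+outflow periods is fixed to *AUC*<sub>ref</sub> = 200 (cardiac
output). The bolus passage is segmented automatically into four intervals —
baseline (BLP), inflow (IFP), outflow (OFP) and reperfusion (RPP) — from the
concentration curve *C(t) = −(1/TE) ln(S̄<sub>t</sub>/S̄<sub>0</sub>)*.

Eight texture parameter maps (TPMs) are computed per time point: the raw
series (ORIG), the difference series (DIFF) and six sliding-kernel maps of
DIFF — local mean (AVER), population variance (VARI), standard deviation
(STDEV), skewness (SKEW), excess kurtosis (KURT) and variance-of-variance
(VAVA, the local variance of the VARI map — a heterogeneity measure that,
unlike VARI, is not an edge detector). For each tissue region the six
statistics {mean, stdev, var, vava, skew, kurt} are averaged per interval,
giving 6 × 4 × 3 = 72 parameter cells per map and 8 × 72 = 576 candidate
pairwise comparisons, tested with an ANOVA-gated, Benjamini–Hochberg
corrected Wilcoxon rank-sum battery. Two delta markers summarise each
lesion on a continuous scale: ΔTPM-X = (RPP value) − (IFP value); ΔTPM-DIFF
grades barrier leakage, ΔTPM-VAVA heterogeneity evolution.

Because no public DSCE dataset exists for this problem, the package ships a
seeded synthetic phantom (`simulate_phantom()`) with per-tissue
gamma-variate bolus responses, recirculation, a leakage term for enhancing
lesions, spatial texture and additive noise — the ground truth against
which every pipeline stage is tested. See the methods vignette
(`vignettes/dtpa-methods.Rmd`) for the models, defaults and their
rationale.

## Worked example

```r
library(dtpa)

ph   <- simulate_phantom(phantom_effect_config(seed = 1))
tois <- c(list(ph$truth$reference_toi), ph$truth$tois)
res  <- run_dtpa(ph$series, tois)
res
#> <dtpa_result>
#> <bolus_phases> TOA 11, peak 15, post-peak minimum 24 (of 40 time points)
#>    BLP: 10, IFP: 5, OFP: 9, RPP: 16
#> <normalization_state> region 'REF': coil factor 4.00063 (c_ideal 100), AUC factor 1.04244 (auc_ref 200)
#>   17856 TOI records, 192 battery cells, 278 significant pairwise tests
```

The phase detector found contrast arrival at time index 11, the
concentration peak at 15 and the post-peak minimum at 24; both
normalization factors are echoed (the phantom's baseline is ~400, so fixing
the reference mean to 100 gives a coil factor of ~4). The battery view:

```r
glance(res$tests)
#>   n_cells n_gated n_tests_performed n_significant n_tests_possible alpha expected_false_positives
#> 1     192     123               369           278              576  0.05                     28.8
res$counts
#> Significant pairwise tests per texture map and interval
#>   tpm_type   BLP   IFP   OFP   RPP Total
#> 1 ORIG         6     9     9     9    33
#> 2 DIFF         3    12    11     9    35
#> 3 AVER         9    17    16    14    56
#> 4 VARI         8    16    14    10    48
#> 5 STDEV        5    15    14    12    46
#> 6 SKEW         0     1     2     4     7
#> 7 KURT         0     2     2     2     6
#> 8 VAVA         6    13    16    12    47
#> 9 Total       37    85    84    72   278
#> possible tests: 576; expected false positives at alpha = 0.05: 28.8
```

278 significant pairwise tests against an expectation of 28.8 under the
null: the designed lesion effects are detected far beyond chance, with the
variance-family maps (VARI/STDEV/VAVA/AVER) discriminating most strongly
and the shape statistics (SKEW/KURT) weakest — the 3×3 kernel gives them
little SNR. The leakage marker separates the classes on a continuous scale
(more negative = more leakage):

```r
aggregate(value ~ tissue_class, subset(res$delta, marker == "dTPM_DIFF"), mean)
#>   tissue_class     value
#> 1         NAWM -12.55639
#> 2           EL -29.51629
#> 3          NEL  -9.85078
```

Plots: `autoplot(res$curve, phases = res$phases)` shows the bolus passage
with interval shading, `autoplot(res$tpms$VAVA, time = 30)` renders one map
frame, and `plot_interval_profiles(res$records)` the per-tissue interval
profiles.

A command-line interface wraps the same pipeline
(`inst/cli/dtpa simulate|run|tpm|stats`, see `dtpa_main()`), reading 4D
NIfTI or DICOM series plus polygon/label-raster region files and writing
TSV reports whose headers echo the full configuration.

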