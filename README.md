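# genpol

General compact-polarimetric (CP) SAR analysis for crop monitoring:
synthesis of CP observations for an arbitrary transmit polarization
ellipse from quad-pol scattering matrices, the delta-alpha/alpha target
decomposition, and the downstream classification and phenology tooling
used to discriminate rice cropping systems across a growing season.

## Who this is for

Radar remote-sensing practitioners who work with quad-pol SAR time series
and want to (a) emulate what a compact-pol sensor with any transmit state
would have measured, (b) extract physically interpretable scattering
parameters from either full-pol or CP data, and (c) evaluate how well those
parameters separate crop classes — all validated on simulated scenes with
known ground truth, since the original satellite scenes of such studies are
rarely deposited.

## The method

For the per-pixel Sinclair matrix *S* and a transmit ellipse with
orientation θ and ellipticity χ (Jones amplitudes
*a* = cosθcosχ − j sinθsinχ, *b* = sinθcosχ + j cosθsinχ, |a|² + |b|² = 1),
the general CP channels are

    E1 = S_HH + (b/a) S_HV        E2 = S_VV + (a/b) S_HV

The decomposition angles, in degrees on [0°, 90°]:

    alpha_B   = arctan((T22 + T33) / T11)                    (full pol, from T3)
    alpha_BCP = arctan(<|E1 − E2|²> / <|E1 + E2|²>)          (compact pol)
    alpha_0   = arctan(|ρ − 1|² / |ρ + 1|²)                  (channel ratio only)
    Δalpha    = alpha − alpha_0                              (scattering randomness)

with ρ the complex co-polar channel ratio (amplitude ratio, circular-mean
phase difference). Surface scattering sits near 0°, volume near 45°,
double bounce near 90°; Δalpha is zero for coherent single-mechanism
targets and signed by the co-polar phase difference. The classic π/4 and
CTLR modes fall out of the general formalism at (θ, χ) = (π/4, 0) and
(·, −π/4); the package verifies both routes agree to 1e−9 degrees.

Around the decomposition: flat-binary raster I/O with JSON sidecar headers,
boxcar and Lee speckle filters, a fully developed speckle simulator driven
by per-class scattering-mixture covariances and a six-date rice phenology
schedule, difference-degree feature ranking, RBF-SVM classification
(C = 100, gamma = 1/#features) with producer's/user's accuracy and kappa,
and transmit-ellipse separability sweeps.

## Worked example

Simulate the default six-date, five-class scene (28 transplanted-hybrid
and 14 direct-sown-japonica rice parcels plus water/urban/shoal-naked-land),
extract the π/4-mode feature stack, rank features, classify, and score on
the held-out verification parcels:

```r
library(genpol)
stack <- buildSceneStack(seed = 11)
feats <- extractFeatureStack(stack$images, mode = "pi4", window = 7L)
sel   <- selectOptimalFeatures(feats, stack$mask, "T-H", "D-J", k = 8)
head(sel, 3)
#> [1] "alpha_B_1103_pi4" "alpha_B_0612_pi4" "dalpha_B_0612_pi4"
fit <- trainAndClassify(feats, stack$mask, classifierConfig(), seed = 1L,
                        features = sel)
accuracyReport(fit$prediction, stack$mask)
#> AccuracyReport
#>  class     PA     UA average
#>  water  98.78  97.10   97.94
#>  urban 100.00 100.00  100.00
#>    SNL  97.57  98.42   98.00
#>    T-H  98.96  98.13   98.54
#>    D-J  96.23  98.38   97.30
#>   OA = 98.32%, kappa = 0.977
```

The top-ranked feature is the harvest-date alpha — the date at which one
rice class has been harvested (bare soil, low alpha) while the other is
still vegetated — and the five-class overall accuracy exceeds 90% on a
scene constructed to be separable. See the vignette
(`vignettes/general-compact-polarimetry.Rmd`) for the model, the
simulator's assumptions and what these numbers do and do not show.

A thin CLI wraps the same functions:

```sh
exec/genpol simulate --date 6 --seed 4 out
exec/genpol decompose --flavor cp --mode pi4 --window 7 out_scene.bin dec
exec/genpol sweep --axis chi --step 1 out_scene.bin out_labels.bin sweep.csv
```

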