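# mewpdq

Joint regional quantification of Thorium-227 and Radium-223 from
low-count, multi-energy-window SPECT projections.

## The problem

Th-227 alpha-particle radiopharmaceutical therapies produce *two*
long-lived alpha emitters in the patient: the administered Th-227 and its
daughter Ra-223, which redistributes independently. Dosimetry needs the
mean activity concentration of **both** isotopes in each volume of
interest (VOI: lesion, bone, gut, background). SPECT can measure this, but
the setting is hostile — administered activities two to three orders of
magnitude below conventional SPECT, heavily overlapping emission spectra
(crosstalk), and the usual attenuation/collimator/scatter degradations.

`mewpdq` implements a multiple-energy-window projection-domain
quantification (MEW-PDQ) method: it skips voxel reconstruction entirely
and estimates the 2K regional uptake values directly from the projection
counts in several energy windows. With per-isotope regional system
matrices $H^{Th}, H^{Ra}$ (expected counts per unit uptake in each VOI),
stray-noise means $\psi$, and Poisson counts
$g \sim \mathrm{Pois}(H\lambda + \psi)$, the maximum-likelihood estimate
is found by the joint EM iteration

$$\lambda_k^{(t+1)} = \frac{\lambda_k^{(t)}}{\sum_m H_{mk}}\,
 \sum_m H_{mk}\,\frac{g_m}{(H\lambda^{(t)})_m+\psi_m},$$

applied to both isotope blocks with the shared composite denominator —
crosstalk is compensated by modelling, not subtraction.

The package is self-contained: bundled Th-227 / Ra-223-chain line spectra,
a simplified attenuated parallel-beam projector with distance-dependent
collimator response (compiled code), parametric pelvic phantoms with lumpy
intra-regional heterogeneity, virtual-imaging-trial population sampling,
Fisher-information/CRLB analysis of energy-window designs, and the
conventional reconstruction-based baselines (dual-isotope OSEM and
geometric-transfer-matrix partial-volume correction) for comparison.

## Worked example

```r
library(mewpdq)

## a small pelvic phantom with standard uptake (11 MBq, Th:Ra = 5:1)
phantom <- makePelvicPhantom(grid = phantomGrid(c(32, 32, 24), 8.85))
phantom
#> Phantom: 32x32x24 voxels @ 8.850 mm
#>  VOIs: background, bone, gut, lesion
#>  total activity: Th 9.17 MBq, Ra 1.83 MBq

## calibrated scanner: 8 views, 30 min, 2e5 expected counts
geometry <- calibrateSensitivity(phantom, scannerGeometry(nAngles = 8))
sysmat   <- buildSystemMatrix(phantom, geometry)

## one low-count acquisition and the joint estimate
proj <- simulateProjections(sysmat, regionalUptake(phantom), seed = 7)
proj
#> ProjectionData: 24576 bins (32x24x8 angles x 4 windows), 203279 total counts
est <- runMewPdq(proj, sysmat, maxIter = 1000)
est
#> UptakeEstimate after 1000 iterations (converged: FALSE)
#>    background   bone  gut lesion
#> Th       1004 2495.0 8554  25690
#> Ra        194  470.9 2335   1802
regionalUptake(phantom)
#> RegionalUptake (Bq/mL):
#>    background   bone  gut lesion
#> Th     1007.0 2517.0 8391  25170
#> Ra      189.7  474.2 2371   1897
```

From roughly 2×10⁵ counts the eight regional concentrations (Bq/mL) of
both isotopes are recovered within a few percent — including the Ra-223
lesion uptake, whose photons are massively outnumbered by Th-227's. The
precision limit of *any* unbiased estimator is available from the Fisher
information:

```r
round(crlbNsd(fisherInformation(sysmat, regionalUptake(phantom))), 3)
#> Th.background       Th.bone        Th.gut     Th.lesion Ra.background
#>         0.006         0.016         0.013         0.032         0.013
#>       Ra.bone        Ra.gut     Ra.lesion
#>         0.036         0.019         0.177
```

Higher-level drivers reproduce whole study designs from a configuration
and a seed: `runConvergenceStudy()`, `runSweep()` (lesion size, contrast,
Th:Ra ratio), `runVit()` (a virtual imaging trial over a sampled patient
population), `runRobustness()` (lumpy heterogeneity, rigid
misregistration), with `experimentConfig("test" | "desk" | "paper")`
profiles. A thin command-line front end is installed at
`inst/scripts/mewpdq`.

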