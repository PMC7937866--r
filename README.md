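# ivimmap

Optimal diffusion-model mapping for intravoxel incoherent motion (IVIM)
brain MRI.

IVIM imaging separates capillary perfusion from molecular diffusion in a
diffusion-weighted series acquired over many b-values. The voxel signal
is two-compartmental,

    S(b) = Se0 · E(b; D, K) + Sv0 · exp(−b·D*),      fp = Sv0 / (Sv0 + Se0)

and the reliability of the perfusion parameters — the perfusion fraction
`fp` (a cerebral-blood-volume surrogate) and the pseudo-diffusion
coefficient `D*` (inverse-transit-time surrogate) — hinges on modelling
the diffusion attenuation `E` correctly. Brain tissue is heterogeneous:
CSF diffuses like a Gaussian (`E = exp(−bD)`), white matter shows
diffusional kurtosis (`E = exp(−bD + b²D²K/6)`), gray matter behaves
like a Gamma-distributed mixture of compartments
(`E = (1 + bDK/3)^(−3/K)`). **ivimmap** fits all three candidates per
voxel on the high-b data (600–2,500 s/mm², per MPG direction), selects
the best by the corrected Akaike information criterion

    cAIC = 2P + n·ln(RSS/n) + 2P(P+1)/(n−P−1),

and then estimates `(Sv0, D*)` jointly from the perfusion residuals of
all six directions — yielding hybrid `fp`, `D*`, MD and apparent mean
kurtosis maps plus an integer-coded optimal-model map. A digital
phantom with known ground truth, Rician noise-floor correction, and
regional analysis with the standard exclusion rules are included. The
package is aimed at quantitative-MRI researchers working on perfusion
estimation without contrast agents.

## Worked example

Generate a noise-free three-tissue phantom, fit every voxel with
optimal-model selection, and summarize by region:

```r
library(ivimmap)

scheme  <- ivimScheme()                      # 17 b-values × 6 MPG directions
spec    <- defaultPhantomSpec(dims = c(12, 12, 2), margin = 1, widths = c(2, 2))
phantom <- generatePhantom(spec, scheme)

maps <- fitVolume(phantom$repeats[[1]], scheme, mask = phantom$labels > 0)
maps
#> ParameterMaps (mode: optimal )  12 x 12 x 2 voxels, 200 fitted
#>   model territory (%): gaussian 4.0, kurtosis 64.0, gamma 32.0
#>   fp %: median 5.40 | D* median 0.0052 | MD median 0.00079 | Kapp median 0.82
```

The model map reproduces the generating tissues exactly: the 8 CSF
voxels select Gaussian (4%), the 128 WM voxels Kurtosis (64%), the 64
GM voxels Gamma (32%). Regional means recover the seeded ground truth
(GM `fp` 6.6%, WM 5.4%, WM `D*` 5.2×10⁻³ mm²/s, ...):

```r
masks   <- buildRegionMasks(list(CSF = (phantom$labels == 1) * 1,
                                 WM  = (phantom$labels == 2) * 1,
                                 GM  = (phantom$labels == 3) * 1))
regionalSummary(applyExclusions(masks, maps), maps)
#> RegionalSummary over 3 regions
#>  region parameter         mean sd   n
#>     CSF        md 2.900000e-03  0   8
#>      WM        fp 5.400000e+00  0 128
#>      WM     dstar 5.200000e-03  0 128
#>      GM        fp 6.600000e+00  0  64
#>      GM     dstar 6.400000e-03  0  64
#>  ...
#> GM/WM ratios: fp = 1.22, dstar = 1.23
```

The cAIC analytics are available directly:

```r
caicScaleShift(10, 1/1000)   # -138.1551  (cAIC shift when data are ÷1000)
equalCaicRssRatio(11, 3)     # 69.96725   (% RSS for a 3- vs 2-parameter tie)
validityBounds(1e-3, 0.5)    # kurtosis 6000, gamma 9000  (s/mm² limits)
```

Real data enter through `readIVIMSeries()` (NIfTI + FSL-style
`.bval`/`.bvec`), with `estimateNCF()`/`correctSignal()` handling the
Rician noise floor, and maps leave through `writeParameterMaps()` with a
JSON sidecar recording units, model codes and flag bits. A thin command
line (`inst/cli/ivimtool`, subcommands `fit`, `phantom`, `regional`,
`territory`) wraps the same functions for shell use.

## Vignette

`vignettes/optimal-model-mapping.Rmd` documents the model, the two-step
segmented fit and its iterated refinement, every tunable parameter with
units and defaults, the numerical choices, what the phantom does and
does not emulate, and known limitations.
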