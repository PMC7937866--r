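---
title: "Optimal diffusion-model mapping for IVIM brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal diffusion-model mapping for IVIM brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimmap)
```

## The problem

Intravoxel incoherent motion (IVIM) imaging reads two kinds of motion out
of diffusion-weighted MRI: molecular diffusion in tissue and the
pseudo-random microcirculation of blood in capillaries. The voxel signal
as a function of diffusion weighting $b$ is modelled as two compartments,

$$S(b) = S_{e0}\,E(b; D, K) + S_{v0}\,e^{-b D^*},$$

an extravascular part with attenuation function $E$ and an intravascular
part decaying with the pseudo-diffusion coefficient $D^*$ (an order of
magnitude faster than tissue diffusion). The perfusion fraction

$$f_p = \frac{S_{v0}}{S_{v0} + S_{e0}}$$

is a surrogate for cerebral blood volume, and $D^*$ relates to the inverse
mean transit time. Because the intravascular compartment contributes only
a few percent of the signal, $f_p$ and $D^*$ inherit every systematic
error made in modelling the *diffusion* part — in particular the choice of
$E$.

Brain tissue is heterogeneous: free water in the ventricles diffuses like
a Gaussian, white matter is dominated by restricted diffusion along
axons, gray matter behaves like a mixture of many small compartments. No
single attenuation model fits all of them, and forcing one model on the
whole brain propagates bias into the perfusion maps. The approach
implemented here fits, per voxel, three candidate models and lets a
small-sample information criterion pick the best one — *optimal model
mapping* — and only then estimates the perfusion parameters.

## Candidate diffusion models

Three nested-in-spirit candidates for $E(b; D, K)$ (see `attenuation()`):

* **Gaussian** (2 parameters, $S_{e0}, D$): $E = e^{-bD}$, free water.
* **Kurtosis** (3 parameters): $E = \exp(-bD + b^2D^2K/6)$, the cumulant
  expansion of restricted diffusion, valid for $b \le 3/(DK)$.
* **Gamma** (3 parameters): $E = (1 + bDK/3)^{-3/K}$, the Laplace
  transform of a Gamma distribution of compartment diffusivities with
  shape $\alpha = 3/K$ and rate $\beta = 3/(KD)$ (`kurtosisToGamma()`).

Both non-Gaussian models reduce to the Gaussian one at $K = 0$, and they
agree with each other to better than 1% below $b \approx 600$ s/mm² for
typical brain $DK \approx 10^{-3}$ mm²/s; only the high-b tail separates
them (`validityBounds()` reports the relevant limits as diagnostics).
Numerically the Gamma form is evaluated as
$\exp(-(3/K)\log(1+bDK/3))$ with a second-order series branch below
$K = 10^{-5}$, so the $K \to 0$ limit is exact.

## Model selection by corrected AIC

Each candidate is scored per MPG direction with the corrected Akaike
information criterion of its high-b least-squares fit,

$$cAIC = 2P + n\ln(RSS/n) + \frac{2P(P+1)}{n-P-1},$$

with $P = 2$ or $3$ parameters and $n$ the number of fitted points. The
six per-direction scores are averaged and the candidate with the minimal
mean wins (`selectOptimalModel()`); exact ties go to the fewest
parameters, then to the fixed order Gaussian, Kurtosis, Gamma. A
candidate that fails to converge in any direction is excluded.

Only cAIC *differences* are meaningful: rescaling all signals by $\alpha$
shifts every cAIC by exactly $2n\ln\alpha$ (`caicScaleShift()`) without
changing the selection or any fitted parameter. `equalCaicRssRatio()`
quantifies the penalty: at $n = 11$ points a 3-parameter model must reach
70.0% of a 2-parameter model's RSS — and a 4-parameter model 43.5% — just
to break even, which is why the 4-parameter biexponential diffusion model
is not among the candidates.

## The two-step segmented fit

Per voxel (`fitVoxel()`, volume-wise `fitVolume()`):

1. **Diffusion step.** For every MPG direction, fit
   $S(b) \approx S_{e0} E(b; D, K)$ on the high-b window
   $b \in [600, 2500]$ s/mm² (11 of the 17 b-values), where the
   perfusion term is attenuated by at least $e^{-600 D^*}$. Select the
   optimal model from the mean cAIC. Average the six $S_{e0}$, $D$ and
   $K$ estimates into $\bar S_{e0}$, MD and the apparent mean kurtosis
   $\bar K_{app}$ (Gaussian-selected voxels contribute $K = 0$).
2. **Perfusion step.** Subtract the fitted extravascular curve from the
   *full* 17-point series of each direction
   (`extractPerfusionSeries()`); assuming isotropic capillary perfusion,
   fit a single $S_{v0} e^{-bD^*}$ jointly to all six residual series
   (`fitPerfusion()`); compute $f_p$ from $S_{v0}$ and $\bar S_{e0}$.

### Iterated refinement

A single pass leaves the perfusion remnant
($\approx e^{-600 D^*} S_{v0}$, 2–8% of $S_{v0}$ for brain $D^*$) inside
the high-b window, which biases $D$ by about 1% and $f_p$ by about 10%
even on noise-free data. The two steps are therefore iterated: the
current perfusion estimate is subtracted from the high-b signals before
the diffusion step is refitted. Viewed as a fixed-point map on
$(S_{v0}, D^*)$ the plain iteration contracts slowly (ratio 0.5–0.9
depending on $D^*$), so after every three passes the fixed point is
extrapolated through the locally fitted linear map
$z_{k+1} \approx A z_k + c$, i.e. jumped to $(I-A)^{-1}c$. The schedule
is a fixed nine passes with no data-dependent early exit, which makes
the fit deterministic and exactly scale-equivariant; on noise-free
voxels the generative parameters are recovered to $10^{-6}$ or better.
When the estimated map has an eigenvalue near one the fixed point is
hypersensitive (the model misfit's extrapolated $S_{e0}$ and the
perfusion estimate trade off almost freely); extrapolating through the
near-singular solve would only amplify rounding noise, so the
refinement stops there.

### Optimizer

All fits are bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
analytic Jacobians. Bounds encode wide physiological ranges:
$D \in [10^{-5}, 5\times10^{-3}]$ mm²/s (covering CSF),
$K \in [0, 5]$, $D^* \in [10^{-4}, 0.5]$ mm²/s,
$S_{e0}, S_{v0} \ge 0$ with generous upper signal bounds. $D$ and
$S_{e0}$ start from a log-linear fit over $b \in [600, 1000]$;
$D^*$ starts at $10^{-2}$ mm²/s. The 3-parameter objectives have a long
curved valley in $(D, K)$ along which LM can stall far from the minimum
(on exact Gamma data with $K = 1.55$ a single start settles at a
residual that should be zero), so the non-Gaussian fits restart from
$K \in \{0.3, 0.8, 1.5, 2.5\}$ and keep the lowest RSS; a later start
must win by a relative margin of $10^{-6}$ so that rounding noise cannot
flip the reported basin. All settings live in `ivimControl()`.

### Numerical choices

* **Per-voxel normalization.** Every voxel is normalized by its first
  $b=0$ signal before fitting and results are rescaled analytically
  (the cAIC as $cAIC_{norm} + 2n\log s$), so every internal comparison
  is scale-free. Rescaling the input by any $\alpha$ therefore changes
  nothing but $S_{e0}, S_{v0}$ (by $\alpha$) and the cAIC values (by
  $2n\ln\alpha$) — exactly on noise-free data. On noisy data the
  rescaled input carries independent per-element rounding which the
  iterated fit can amplify to about $10^{-7}$ relative for weakly
  identified voxels; the invariance is float-limited there, not exact.
* **RSS floor.** On noise-free data all candidates fit to machine
  precision and $\ln(RSS)$ would compare floating-point dust. The RSS
  entering the cAIC is floored at $n(10^{-10} s)^2$ (ten significant
  digits of agreement), so the parsimony penalty decides and the
  Gaussian model correctly wins in CSF.
* **Convergence flag.** `nls.lm`'s iteration-cap return is treated as a
  usable optimum (it occurs while dithering along the flat valley with
  the deviance long converged); only improper input or non-finite
  estimates mark a fit non-converged, which excludes it from selection.
* **Degenerate voxels.** All-negative perfusion residuals give
  $S_{v0} = 0$, $f_p = 0$, undefined $D^*$ and a flag; fits pinned at a
  bound, voxels with two or more zero-floored high-b points, and voxels
  where no candidate converges are flagged per bit (`ivimFlags()`)
  without aborting a volume run.

## Rician noise floor

Magnitude MRI noise is Rician: where the true signal approaches zero the
measured magnitude plateaus at the noise floor instead, which mimics
spurious high-b signal and biases $K$ upward. The noise correction
factor is estimated as the squared mode of the $S(0)$ image histogram
(`estimateNCF()`; Freedman–Diaconis bins; the mode is the
count-weighted centre of the near-maximal plateau of bins, which is
stable on smooth peaks and exact on discrete images) and measured
magnitudes are corrected as $\sqrt{\max(\hat S^2 - NCF, 0)}$
(`correctSignal()`) before both fitting steps. The default histogram is
taken over the whole field of view excluding exact zeros; a mask can
restrict it — advisable for data whose background occupies little of
the FOV, as in the digital phantom below.

## The digital phantom

`generatePhantom()` simulates the full acquisition: 17 b-values from 0
to 2,500 s/mm² in six MPG directions ([1,1,0], [0,1,1], [1,0,1],
[1,−1,0], [0,1,−1], [−1,0,1]), nested slabs of CSF, white and gray
matter on a configurable grid (default 32×32×8 with a 2-voxel
background margin and 5-voxel shells), per-region ground truth drawn
from published healthy-brain values (`tissueParams()`: e.g. GM Gamma
$D = 1.05\times10^{-3}$, $K = 1.0$, $f_p = 6.6\%$,
$D^* = 6.4\times10^{-3}$; WM Kurtosis $D = 0.79\times10^{-3}$,
$K = 0.82$, $f_p = 5.4\%$, $D^* = 5.2\times10^{-3}$; CSF Gaussian
$D = 2.9\times10^{-3}$, $f_p = 0$), Rician noise realized as
$\sqrt{(S+g_1)^2+g_2^2}$ per volume, and one to six repeats for
number-of-averages (NA) experiments. Perfusion and diffusion are
generated isotropically, matching the isotropic-perfusion fitting
assumption; a direction-dependent $D$ would exercise the per-direction
fits but is not simulated.

What the phantom does *not* emulate: realistic brain geometry and
partial-volume mixtures at tissue boundaries, spatially varying noise,
eddy-current or EPI distortion, motion, and within-region parameter
dispersion (each region is exactly homogeneous). Passing phantom tests
therefore demonstrates correctness of the estimator on data that follow
the model, not robustness to everything real acquisitions add.

A note on what the noisy phantom shows: at a $b=0$ SNR of 100 with six
averages, the kurtosis and gamma candidates are close to
indistinguishable — the best cross-model approximation differs from the
data by far less than the noise — so per-voxel model selection between
them is unreliable even though the underlying $D$ and $K$ estimates are
nearly unbiased. This mirrors the in-vivo observation that gray matter
is only partially Gamma-dominant, and it propagates into $f_p$, which
shifts by roughly a factor of two between the two models' fits of the
same voxel.

## Regional analysis

`buildRegionMasks()` collects voxels whose tissue probability strictly
exceeds 0.95 (a guard against partial volume and mis-registration;
probability maps are accepted as input, segmentation itself is out of
scope). `applyExclusions()` then drops voxels with $MD > D^*$ in tissue
regions (a failed perfusion fit) and voxels with $\bar K_{app} > 0.1$
in CSF (free water must be nearly Gaussian); the exclusion filters the
region mask as a whole, for all parameters. `regionalSummary()` reports
mean ± SD per region and the GM/WM ratios of the $f_p$ and $D^*$ means,
the quantities by which the method is compared against conventional
perfusion imaging.

## Problem sizes

The shipped tests run the full pipeline at desk scale: noise-free
round trips on a 12×12×2 grid (200 fitted voxels, three tissue
classes), the noisy NA6 experiment on a 16×16×3 grid (576 tissue
voxels), and the NA stability trend on 14×14×2. A default 32×32×8
phantom fits in a few minutes on one CPU via `fitVolume()` or the
`ivimtool` command line.

## Known limitations

* Model selection between the two 3-parameter candidates needs high
  SNR; below it, territory maps are noisy in exactly the way the NA
  experiment quantifies (`territoryChange()`).
* The segmented estimator is not a joint maximum-likelihood fit; for
  very low $D^*$ (approaching tissue $D$) the compartment split is
  weakly identified and the iterated refinement stops rather than
  committing to a hypersensitive split.
* Voxels are processed independently; no spatial regularization.
* $f_p$ maps are stored in percent, $D$-type maps in mm²/s; the model
  map uses codes 0 (unfit), 1 (Gaussian), 2 (Kurtosis), 3 (Gamma).
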