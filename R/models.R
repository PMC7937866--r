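#' Integer codes of the candidate diffusion models
#'
#' Stable coding used in optimal-model maps and file output:
#' 1 = Gaussian, 2 = Kurtosis, 3 = Gamma; 0 is reserved for
#' background/unfitted voxels.
#' @export
MODEL_CODES <- c(gaussian = 1L, kurtosis = 2L, gamma = 3L)

#' Number of free parameters of each diffusion model in the high-b fit
#' @noRd
.modelP <- c(gaussian = 2L, kurtosis = 3L, gamma = 3L)

#' Map between model names and integer codes
#'
#' @param model character vector of model names
#' @param code integer vector of model codes (0..3)
#' @return `modelCode` returns integer codes; `modelName` returns names
#'   ("none" for 0).
#' @examples
#' modelCode("gamma")    # 3
#' modelName(c(0, 1, 2)) # "none" "gaussian" "kurtosis"
#' @export
modelCode <- function(model) {
  out <- MODEL_CODES[match(model, names(MODEL_CODES))]
  if (any(is.na(out))) stop("unknown model name: ",
                            paste(model[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname modelCode
#' @export
modelName <- function(code) {
  nm <- c("none", names(MODEL_CODES))[match(code, 0:3)]
  if (any(is.na(nm))) stop("model codes must be in 0..3")
  nm
}

#' Diffusion signal attenuation E(b) of the three candidate models
#'
#' Evaluates the extravascular attenuation function of the Gaussian
#' (mono-exponential), Kurtosis or Gamma diffusion model:
#' \deqn{E_{gauss}(b) = e^{-bD}}
#' \deqn{E_{kurt}(b) = e^{-bD + b^2 D^2 K / 6}}
#' \deqn{E_{gamma}(b) = (1 + bDK/3)^{-3/K}}
#' All three coincide at \eqn{K = 0}; the Gamma form is evaluated as
#' \eqn{\exp(-(3/K)\log(1 + bDK/3))} with a series branch for
#' \eqn{K < 10^{-5}} so the \eqn{K \to 0} limit is exact.
#'
#' @param b b-value(s), s/mm^2 (non-negative).
#' @param D diffusion coefficient, mm^2/s (positive).
#' @param K diffusional kurtosis, dimensionless (non-negative; ignored by
#'   the Gaussian model).
#' @param model one of "gaussian", "kurtosis", "gamma".
#' @return attenuation value(s), dimensionless; E(0) = 1.
#' @examples
#' attenuation(1000, D = 1e-3, model = "gaussian")     # exp(-1)
#' attenuation(600, D = 1e-3, K = 1, model = "gamma")  # 1.2^-3
#' @export
attenuation <- function(b, D, K = 0, model = c("gaussian", "kurtosis",
                                               "gamma")) {
  model <- match.arg(model)
  if (any(!is.finite(b)) || any(b < 0)) stop("b-values must be >= 0")
  if (!is.finite(D) || D <= 0) stop("D must be > 0")
  if (!is.finite(K) || K < 0) stop("K must be >= 0")
  switch(model,
    gaussian = exp(-b * D),
    kurtosis = exp(-b * D + b^2 * D^2 * K / 6),
    gamma = {
      if (K < 1e-5) {
        # 2nd-order small-K expansion of -(3/K) log1p(bDK/3)
        exp(-b * D + b^2 * D^2 * K / 6 - b^3 * D^3 * K^2 / 27)
      } else {
        exp((-3 / K) * log1p(b * D * K / 3))
      }
    })
}

#' Two-compartment IVIM signal
#'
#' \deqn{S(b) = S_{e0} E(b; D, K) + S_{v0} e^{-b D^*}}
#' the extravascular diffusion compartment under the chosen model plus the
#' intravascular pseudo-diffusion compartment.
#'
#' @param b b-value(s), s/mm^2.
#' @param Se0 extravascular non-diffusion-weighted signal (>= 0).
#' @param D diffusion coefficient, mm^2/s.
#' @param K diffusional kurtosis.
#' @param Sv0 intravascular non-diffusion-weighted signal (>= 0).
#' @param Dstar pseudo-diffusion coefficient, mm^2/s (required when
#'   \code{Sv0 > 0}).
#' @param model diffusion model name.
#' @return signal value(s); S(0) = Se0 + Sv0.
#' @export
ivimSignal <- function(b, Se0, D, K = 0, Sv0 = 0, Dstar = NA_real_,
                       model = c("gaussian", "kurtosis", "gamma")) {
  model <- match.arg(model)
  if (Se0 < 0 || Sv0 < 0) stop("Se0 and Sv0 must be >= 0")
  s <- Se0 * attenuation(b, D, K, model)
  if (Sv0 > 0) {
    if (!is.finite(Dstar) || Dstar <= 0)
      stop("Dstar must be > 0 when Sv0 > 0")
    s <- s + Sv0 * exp(-b * Dstar)
  }
  s
}

#' Perfusion fraction from compartment signals
#'
#' \eqn{f_p = S_{v0} / (S_{v0} + S_{e0})}, the volume fraction of flowing
#' blood inferred from the non-diffusion-weighted signals of the two
#' compartments.
#'
#' @param Sv0 intravascular signal (>= 0).
#' @param Se0 extravascular signal (here the direction-averaged estimate;
#'   > 0 unless Sv0 > 0).
#' @return dimensionless fraction in [0, 1).
#' @export
perfusionFraction <- function(Sv0, Se0) {
  if (any(Sv0 < 0) || any(Se0 < 0)) stop("signals must be >= 0")
  tot <- Sv0 + Se0
  if (any(tot == 0)) stop("Sv0 + Se0 must be positive")
  Sv0 / tot
}

#' Corrected Akaike information criterion
#'
#' Small-sample AIC for a least-squares fit:
#' \deqn{cAIC = 2P + n \ln(RSS/n) + \frac{2P(P+1)}{n - P - 1}}
#'
#' @param n number of fitted data points (> P + 1).
#' @param P number of free parameters.
#' @param rss residual sum of squares (> 0).
#' @return the cAIC value (dimensionless; additive constants omitted as in
#'   the least-squares form, so only differences are meaningful).
#' @examples
#' caic(11, 2, 11)  # 5.5
#' @export
caic <- function(n, P, rss) {
  if (any(n <= P + 1)) stop("need n > P + 1")
  if (any(rss <= 0)) stop("rss must be > 0")
  2 * P + n * log(rss / n) + 2 * P * (P + 1) / (n - P - 1)
}

#' cAIC shift under rescaling of the fitted data
#'
#' Scaling all fitted signals by a factor \eqn{\alpha} multiplies the RSS by
#' \eqn{\alpha^2} and shifts every cAIC by \eqn{2 n \ln\alpha}, leaving all
#' cAIC differences — and hence model selection and the fitted parameters —
#' unchanged.
#'
#' @param n number of fitted data points.
#' @param alpha scale factor (> 0).
#' @return the additive cAIC shift.
#' @examples
#' caicScaleShift(10, 1 / 1000)  # about -138.2
#' @export
caicScaleShift <- function(n, alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  2 * n * log(alpha)
}

#' RSS ratio giving equal cAIC between models of different size
#'
#' For the same n data points, the residual sum of squares a model with
#' \code{p} parameters must reach — as a percentage of the RSS of a
#' reference model with \code{pRef} parameters — for the two models to have
#' identical cAIC. Quantifies how much better a larger model must fit to
#' break even under the cAIC penalty.
#'
#' @param n number of data points.
#' @param p number of parameters of the larger model.
#' @param pRef number of parameters of the reference model.
#' @return percentage 100 * RSS_p / RSS_pRef.
#' @examples
#' equalCaicRssRatio(11, 3)  # 70.0
#' equalCaicRssRatio(11, 4)  # 43.5
#' @export
equalCaicRssRatio <- function(n, p, pRef = 2) {
  if (n <= max(p, pRef) + 1) stop("need n > P + 1 for both models")
  pen <- function(P) 2 * P + 2 * P * (P + 1) / (n - P - 1)
  100 * exp((pen(pRef) - pen(p)) / n)
}

#' Gamma-distribution parameters equivalent to (D, K)
#'
#' Under the Gamma model the voxel is a continuum of compartments whose
#' diffusion coefficients follow a Gamma distribution with shape
#' \eqn{\alpha = 3/K} and rate \eqn{\beta = 3/(KD)}; its mean is D and its
#' variance satisfies \eqn{K = 3\sigma^2/D^2}.
#'
#' @param D diffusion coefficient, mm^2/s (> 0).
#' @param K diffusional kurtosis (> 0; K = 0 is the degenerate
#'   single-compartment limit — use the Gaussian model instead).
#' @return named list with `alpha` (dimensionless) and `beta` (s/mm^2).
#' @examples
#' kurtosisToGamma(1e-3, 1)  # alpha 3, beta 3000
#' @export
kurtosisToGamma <- function(D, K) {
  if (D <= 0) stop("D must be > 0")
  if (K <= 0) stop("K must be > 0 (K = 0 degenerates to the Gaussian model)")
  list(alpha = 3 / K, beta = 3 / (K * D))
}

#' @rdname kurtosisToGamma
#' @param alpha gamma shape (> 0)
#' @param beta gamma rate, s/mm^2 (> 0)
#' @return `gammaToKurtosis` returns a named list with `D` and `K`.
#' @export
gammaToKurtosis <- function(alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  D <- alpha / beta
  v <- alpha / beta^2
  list(D = D, K = 3 * v / D^2)
}

#' Model-validity b-value bounds
#'
#' The Kurtosis model requires \eqn{b \le 3/(DK)} for a monotonically
#' decreasing signal; the Kurtosis and Gamma models coincide only for
#' b-values well below \eqn{27/(6DK)}. Both bounds are diagnostics, not
#' fitting constraints.
#'
#' @param D diffusion coefficient, mm^2/s.
#' @param K diffusional kurtosis.
#' @return named numeric vector with `kurtosis` (= 3/(DK)) and `gamma`
#'   (= 27/(6DK)), in s/mm^2; both `Inf` when D*K = 0.
#' @examples
#' validityBounds(1e-3, 0.5)  # kurtosis bound 6000 s/mm^2
#' @export
validityBounds <- function(D, K) {
  dk <- D * K
  if (any(dk < 0)) stop("D*K must be >= 0")
  c(kurtosis = ifelse(dk == 0, Inf, 3 / dk),
    gamma = ifelse(dk == 0, Inf, 27 / (6 * dk)))
}
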