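#' Schnute growth parameters (Baker mark-recapture form)
#'
#' The growth curve used throughout the package is the Schnute model in
#' Baker's mark-recapture parameterisation: a von Bertalanffy-type curve
#' defined by the growth coefficient `K` (year^-1) and the true sizes
#' `L_T1`, `L_T2` at two fixed reference ages `T1` and `T2`. With `T1 = 0`
#' the first reference size is the size at birth (hatchling size); `T2` is
#' conventionally set at 14 years, around the captive longevity record of
#' the study species. The parameterisation is preferred over the classical
#' (K, L-infinity) pair because the two reference sizes are much less
#' correlated with K in mark-recapture fits.
#'
#' @param K growth coefficient (year^-1), strictly positive.
#' @param L_T1 true size (mm) at reference age `T1`.
#' @param L_T2 true size (mm) at reference age `T2`; must exceed `L_T1`.
#' @param T1,T2 reference ages in years, `T2 > T1`. Defaults 0 and 14.
#' @return An object of class `growth_params`.
#' @examples
#' gp <- growth_params(K = 0.5, L_T1 = 33, L_T2 = 70)
#' asymptotic_size(gp)
#' @export
growth_params <- function(K, L_T1 = 33, L_T2, T1 = 0, T2 = 14) {
  stopifnot(is.numeric(K), is.numeric(L_T1), is.numeric(L_T2))
  if (any(K <= 0)) stop("growth coefficient K must be > 0")
  if (T2 <= T1) stop("reference ages must satisfy T2 > T1")
  if (any(L_T2 <= L_T1)) stop("reference sizes must satisfy L_T2 > L_T1")
  structure(list(K = K, L_T1 = L_T1, L_T2 = L_T2, T1 = T1, T2 = T2),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "Schnute growth parameters: K = %.4g /yr, L(T1=%g) = %.4g mm, L(T2=%g) = %.4g mm, L-inf = %.4g mm\n",
    x$K, x$T1, x$L_T1, x$T2, x$L_T2, asymptotic_size(x)))
  invisible(x)
}

#' Asymptotic size of a growth trajectory
#'
#' Size approached as age goes to infinity,
#' \deqn{L_\infty = \frac{L_{T2} - L_{T1} e^{-K (T2 - T1)}}{1 - e^{-K (T2 - T1)}}.}
#' Always at least `L_T2`, and decreasing toward `L_T2` as `K` grows.
#'
#' @param params a [growth_params()] object.
#' @return Asymptotic size in mm.
#' @export
asymptotic_size <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  e <- exp(-params$K * (params$T2 - params$T1))
  (params$L_T2 - params$L_T1 * e) / (1 - e)
}

#' Predict size after an elapsed interval
#'
#' Baker's mark-recapture form of the Schnute curve: the true size `D` years
#' after the moment the animal measured `L_t`,
#' \deqn{L_{t+D} = L_t e^{-K D} + \left(L_{T2} - L_{T1} e^{-K(T2-T1)}\right)
#'   \frac{1 - e^{-K D}}{1 - e^{-K(T2-T1)}} .}
#' Equivalently \eqn{L_{t+D} = L_t e^{-KD} + L_\infty (1 - e^{-KD})}: the
#' trajectory relaxes exponentially toward the asymptote, so successive
#' one-year applications compose exactly (semigroup property).
#'
#' @param L_t current true size (mm); must lie in (0, asymptote).
#' @param D elapsed time (years), non-negative.
#' @param params a [growth_params()] object.
#' @return Predicted true size (mm) at time t + D.
#' @export
predict_size <- function(L_t, D, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(D < 0)) stop("elapsed time D must be >= 0")
  linf <- asymptotic_size(params)
  if (any(L_t <= 0) || any(L_t >= linf))
    stop("current size must lie in (0, asymptotic size)")
  ed <- exp(-params$K * D)
  L_t * ed + linf * (1 - ed)
}

#' Age at a given size
#'
#' The inverse of the age-to-size map obtained by rearranging the Schnute
#' curve anchored at (T1, L_T1):
#' \deqn{A(L) = \frac{\ln\!\left(1 - (1 - e^{-K(T2-T1)})
#'   \frac{L - L_{T1}}{L_{T2} - L_{T1}}\right)}{-K} + T1 .}
#' Defined for `L` in `[L_T1, L_inf)`; sizes at or beyond the asymptote have
#' no finite age.
#'
#' @param L size (mm).
#' @param params a [growth_params()] object.
#' @return Age in years.
#' @export
age_at_size <- function(L, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(L < params$L_T1))
    stop("size below L_T1 has no age on the curve")
  if (any(L >= asymptotic_size(params)))
    stop("size at or above the asymptote has no finite age")
  e <- exp(-params$K * (params$T2 - params$T1))
  arg <- 1 - (1 - e) * (L - params$L_T1) / (params$L_T2 - params$L_T1)
  log(arg) / (-params$K) + params$T1
}

#' Size at a given age
#'
#' The forward age-to-size map: the Schnute curve evaluated from the anchor
#' (T1, L_T1) with elapsed time `a - T1`.
#'
#' @param a age in years, `a >= T1`.
#' @param params a [growth_params()] object.
#' @return True size (mm) at age `a`.
#' @export
size_at_age <- function(a, params) {
  stopifnot(inherits(params, "growth_params"))
  if (any(a < params$T1)) stop("age must be >= T1")
  linf <- asymptotic_size(params)
  ed <- exp(-params$K * (a - params$T1))
  params$L_T1 * ed + linf * (1 - ed)
}

#' Size thresholds at sexual maturity
#'
#' Minimum snout-to-vent lengths at which animals are considered sexually
#' mature. Defaults are the literature minimum size at maturity for females
#' (50 mm) and the smallest male observed with secondary sexual characters
#' (femoral pores; 59 mm).
#'
#' @param female_svl,male_svl thresholds in mm.
#' @return An object of class `maturity_thresholds`.
#' @export
maturity_thresholds <- function(female_svl = 50, male_svl = 59) {
  stopifnot(female_svl > 0, male_svl > 0)
  structure(list(female_svl = female_svl, male_svl = male_svl),
            class = "maturity_thresholds")
}

#' Age at sexual maturity
#'
#' [age_at_size()] evaluated at the sex-specific maturity threshold.
#'
#' @param params a [growth_params()] object.
#' @param thresholds a [maturity_thresholds()] object.
#' @param sex `"male"` or `"female"`.
#' @return Age (years) at which the growth curve crosses the threshold.
#' @export
age_at_maturity <- function(params, thresholds = maturity_thresholds(),
                            sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(inherits(thresholds, "maturity_thresholds"))
  thr <- if (sex == "male") thresholds$male_svl else thresholds$female_svl
  if (thr >= asymptotic_size(params))
    stop("maturity threshold at or above the asymptotic size is never reached")
  age_at_size(thr, params)
}

#' Observe a size with measurement error
#'
#' Observed SVL is the true size plus independent Normal error with mean 0
#' and constant standard deviation `sigma_L` (mm). With `sigma_L > 0`,
#' apparent negative growth increments between consecutive captures occur
#' with positive probability, which is why the model never treats observed
#' sizes as exact.
#'
#' @param L_true true size(s), mm.
#' @param sigma_L measurement-error SD, mm, `>= 0`.
#' @param n number of draws per true size (default 1).
#' @return Observed size(s), mm. Uses the current R random number stream.
#' @export
observe_size <- function(L_true, sigma_L, n = 1L) {
  if (sigma_L < 0) stop("sigma_L must be >= 0")
  if (n == 1L) L_true + stats::rnorm(length(L_true), 0, sigma_L)
  else L_true + stats::rnorm(n * length(L_true), 0, sigma_L)
}

#' Growth hyperparameters (population level)
#'
#' Sex-specific hyperparameters for the individual growth random effects and
#' the measurement-error SD. Individual growth coefficients are lognormal
#' around a sex-specific median (`K_i = exp(logK_i)`,
#' `logK_i ~ N(mu_logK[sex], sd_logK[sex])`, guaranteeing `K_i > 0`);
#' individual `L_T2` values are Normal around a sex-specific mean, truncated
#' below at `L_T1 + 1` mm so that every individual curve is increasing; the
#' hatchling size `L_T1` has a shared Normal prior (individual values drawn
#' from it).
#'
#' @param mu_logK named numeric, log-scale K location per sex
#'   (`c(female=, male=)`).
#' @param sd_logK named numeric, log-scale K SD per sex, `> 0`.
#' @param mu_LT2 named numeric, mean size at T2 per sex (mm).
#' @param sd_LT2 named numeric, SD of size at T2 per sex (mm), `> 0`.
#' @param hatch_mean,hatch_sd hatchling-size prior mean and SD (mm).
#' @param sigma_L measurement-error SD (mm), `> 0`.
#' @return An object of class `growth_hyperparams`.
#' @export
growth_hyperparams <- function(mu_logK = c(female = log(0.41), male = log(0.56)),
                               sd_logK = c(female = 0.20, male = 0.20),
                               mu_LT2 = c(female = 65.5, male = 72.3),
                               sd_LT2 = c(female = 2.5, male = 2.5),
                               hatch_mean = 33, hatch_sd = 2,
                               sigma_L = 1) {
  stopifnot(all(sd_logK > 0), all(sd_LT2 > 0), hatch_sd > 0, sigma_L > 0)
  if (any(hatch_mean >= mu_LT2))
    stop("hatchling prior mean must lie below both sexes' mean L_T2")
  structure(list(mu_logK = mu_logK[c("female", "male")],
                 sd_logK = sd_logK[c("female", "male")],
                 mu_LT2 = mu_LT2[c("female", "male")],
                 sd_LT2 = sd_LT2[c("female", "male")],
                 hatch_mean = hatch_mean, hatch_sd = hatch_sd,
                 sigma_L = sigma_L),
            class = "growth_hyperparams")
}
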