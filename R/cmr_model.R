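#' Survival sub-model (logit scale)
#'
#' Annual apparent-survival probability for individual i over the interval
#' from occasion t to t+1:
#' \deqn{\mathrm{logit}\,\phi_{i,t} = \alpha_s + \beta_{s1}\,\mathrm{sex}_i
#'   + \beta_{s2}\,x_{i,t} + \beta_{s3}\,x_{i,t}^2
#'   + \beta_{s4}\,\mathrm{sex}_i x_{i,t}
#'   + \beta_{s5}\,\mathrm{sex}_i x_{i,t}^2 + \epsilon^\phi_t,}
#' where `x` is standardized SVL at occasion t, sex is coded 0 = female,
#' 1 = male, and the year effects are Normal(0, sigma_phi^2).
#'
#' @param alpha intercept (logit scale).
#' @param b_sex,b_svl,b_svl2,b_sex_svl,b_sex_svl2 coefficients.
#' @param year_effects numeric vector of interval-specific effects
#'   (one per survival interval), default none (all zero).
#' @param year_sd SD of the year random effects, `> 0` when estimated.
#' @return An object of class `survival_model`.
#' @export
survival_model <- function(alpha = 0, b_sex = 0, b_svl = 0, b_svl2 = 0,
                           b_sex_svl = 0, b_sex_svl2 = 0,
                           year_effects = numeric(0), year_sd = 1) {
  if (year_sd <= 0) stop("year_sd must be > 0")
  structure(list(alpha = alpha, b_sex = b_sex, b_svl = b_svl, b_svl2 = b_svl2,
                 b_sex_svl = b_sex_svl, b_sex_svl2 = b_sex_svl2,
                 year_effects = year_effects, year_sd = year_sd),
            class = "survival_model")
}

#' Recapture sub-model (logit scale)
#'
#' \deqn{\mathrm{logit}\,p_{i,t} = \alpha_p + \beta_{p1}\,\mathrm{sex}_i
#'   + \beta_{p2}\,x_{i,t} + \beta_{p3}\,\mathrm{sex}_i x_{i,t}
#'   + \epsilon^p_t.}
#' No quadratic size term: a hump-shaped size-recapture relation was not
#' entertained.
#'
#' @inheritParams survival_model
#' @param b_sex_svl sex-by-size interaction coefficient.
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(alpha = 0, b_sex = 0, b_svl = 0, b_sex_svl = 0,
                            year_effects = numeric(0), year_sd = 1) {
  if (year_sd <= 0) stop("year_sd must be > 0")
  structure(list(alpha = alpha, b_sex = b_sex, b_svl = b_svl,
                 b_sex_svl = b_sex_svl,
                 year_effects = year_effects, year_sd = year_sd),
            class = "detection_model")
}

#' Survival probability from the logit-linear model
#'
#' @param sex 0 (female) or 1 (male).
#' @param svl_std standardized SVL covariate.
#' @param year_effect interval-specific random effect (logit scale).
#' @param m a [survival_model()] object.
#' @return Probability in (0, 1). Vectorized over the inputs.
#' @export
survival_prob <- function(sex, svl_std, year_effect = 0, m) {
  stopifnot(inherits(m, "survival_model"))
  lp <- m$alpha + m$b_sex * sex + m$b_svl * svl_std + m$b_svl2 * svl_std^2 +
    m$b_sex_svl * sex * svl_std + m$b_sex_svl2 * sex * svl_std^2 + year_effect
  stats::plogis(lp)
}

#' Recapture probability from the logit-linear model
#'
#' @inheritParams survival_prob
#' @param m a [detection_model()] object.
#' @return Probability in (0, 1). Vectorized over the inputs.
#' @export
detection_prob <- function(sex, svl_std, year_effect = 0, m) {
  stopifnot(inherits(m, "detection_model"))
  lp <- m$alpha + m$b_sex * sex + m$b_svl * svl_std +
    m$b_sex_svl * sex * svl_std + year_effect
  stats::plogis(lp)
}

#' Impute a true-size trajectory from first capture onward
#'
#' Given the latent true size at the first-capture occasion, the growth
#' curve yields the whole subsequent trajectory by repeated one-year steps
#' of the Schnute map. This is the deterministic backbone used to fill in
#' body size whenever an animal that is alive goes undetected.
#'
#' @param L_first latent true size (mm) at the first-capture occasion.
#' @param params a [growth_params()] object.
#' @param f first-capture occasion (1-based).
#' @param n_occasions total number of occasions.
#' @return Numeric vector of length `n_occasions`; `NA` before `f`, strictly
#'   increasing true sizes from `f` onward.
#' @export
impute_trajectory <- function(L_first, params, f = 1L, n_occasions) {
  stopifnot(inherits(params, "growth_params"),
            f >= 1L, n_occasions >= f)
  if (L_first >= asymptotic_size(params))
    stop("size at first capture must be below the asymptotic size")
  out <- rep(NA_real_, n_occasions)
  idx <- seq.int(f, n_occasions)
  # closed form from the anchor; identical to repeated one-year steps by the
  # semigroup property, but safe arbitrarily close to the asymptote
  out[idx] <- predict_size(L_first, idx - f, params)
  out
}

# Linear predictors for one individual across occasions; internal.
.phi_vec <- function(sex, x, phi_model) {
  T <- length(x)
  ye <- phi_model$year_effects
  if (length(ye) == 0) ye <- rep(0, T - 1)
  survival_prob(sex, x[seq_len(T - 1)], ye, phi_model)
}

.p_vec <- function(sex, x, p_model) {
  T <- length(x)
  if (T < 2) return(numeric(0))
  ye <- p_model$year_effects
  if (length(ye) == 0) ye <- rep(0, T - 1)
  # detection applies at occasions 2..T (first release is conditioned on);
  # element t corresponds to occasion t + 1
  detection_prob(sex, x[2:T], ye, p_model)
}

#' Complete-data CJS log-likelihood for given alive states
#'
#' Log-probability of one set of latent alive indicators and the detections,
#' conditional on first capture: Bernoulli survival transitions
#' `z[t+1] ~ Bern(z[t] * phi[t])` from the first-capture occasion, Bernoulli
#' detections `y[t] ~ Bern(z[t] * p[t])` at occasions after first capture,
#' and Normal size-measurement terms at every capture. Inconsistent states
#' (detected while dead, resurrection) give `-Inf`.
#'
#' @param data a [capture_data()] object.
#' @param z 0/1 matrix of alive indicators, same shape as `data$y`.
#' @param states list with `L` (matrix of latent true sizes, mm) and `sex`
#'   (0/1 per individual).
#' @param phi_model a [survival_model()].
#' @param p_model a [detection_model()].
#' @param std a [standardization()].
#' @param sigma_L measurement-error SD (mm).
#' @return Scalar log-likelihood.
#' @export
cjs_complete_loglik <- function(data, z, states, phi_model, p_model, std,
                                sigma_L) {
  stopifnot(inherits(data, "capture_data"))
  z <- as.matrix(z)
  T <- data$n_occasions
  ll <- 0
  for (i in seq_len(data$n)) {
    f <- data$f[i]
    if (z[i, f] != 1L) return(-Inf)
    x <- standardize(states$L[i, ], std)
    phi <- .phi_vec(states$sex[i], x, phi_model)
    p <- .p_vec(states$sex[i], x, p_model)
    if (f < T) {
      for (t in f:(T - 1)) {
        # transition t -> t+1
        pr_alive <- z[i, t] * phi[t]
        ll <- ll + stats::dbinom(z[i, t + 1], 1, pr_alive, log = TRUE)
        # observation at t+1
        ll <- ll + stats::dbinom(data$y[i, t + 1], 1, z[i, t + 1] * p[t], log = TRUE)
        if (!is.finite(ll)) return(-Inf)
      }
    }
    # measurement terms at captures
    obs <- which(data$y[i, ] == 1L)
    ll <- ll + sum(stats::dnorm(data$svl[i, obs], states$L[i, obs], sigma_L,
                                log = TRUE))
  }
  ll
}

#' Marginal CJS log-likelihood (latent alive states summed out)
#'
#' The integrated likelihood used by the sampler: for each individual the
#' latent alive trajectory is marginalised analytically by summing over the
#' death time. Conditional on first capture at occasion f with last capture
#' at occasion l, the contribution is
#' the product of survival and detection/non-detection terms up to l times
#' the probability of never being seen again,
#' `chi[t] = (1 - phi[t]) + phi[t] (1 - p[t+1]) chi[t+1]`, `chi[T] = 1`,
#' plus Normal measurement terms for the observed sizes. Equals the
#' brute-force sum of [cjs_complete_loglik()] over all alive configurations.
#'
#' @inheritParams cjs_complete_loglik
#' @return Scalar log-likelihood.
#' @export
cjs_loglik <- function(data, states, phi_model, p_model, std, sigma_L) {
  stopifnot(inherits(data, "capture_data"))
  T <- data$n_occasions
  total <- 0
  for (i in seq_len(data$n)) {
    f <- data$f[i]; l <- data$last[i]
    x <- standardize(states$L[i, ], std)
    phi <- .phi_vec(states$sex[i], x, phi_model)
    p <- .p_vec(states$sex[i], x, p_model)
    ll <- 0
    if (l > f) {
      for (t in f:(l - 1)) {
        ll <- ll + log(phi[t]) +
          ifelse(data$y[i, t + 1] == 1L, log(p[t]), log1p(-p[t]))
      }
    }
    # chi recursion from T down to l
    chi <- 1
    if (l < T) {
      for (t in (T - 1):l)
        chi <- (1 - phi[t]) + phi[t] * (1 - p[t]) * chi
    }
    ll <- ll + log(chi)
    obs <- which(data$y[i, ] == 1L)
    ll <- ll + sum(stats::dnorm(data$svl[i, obs], states$L[i, obs], sigma_L,
                                log = TRUE))
    total <- total + ll
  }
  total
}

#' Latent-sex mixture contribution
#'
#' Individual sex follows `sex_i ~ Bernoulli(psi)` with `psi` the population
#' sex ratio (probability of being male). For a known-sex individual the
#' contribution is the Bernoulli mass plus the sex-conditional data
#' log-likelihood; for an unknown-sex individual the two sexes are mixed:
#' `log(psi * exp(ll_male) + (1 - psi) * exp(ll_female))`.
#'
#' @param ll_female,ll_male data log-likelihood of the individual under each
#'   sex assignment.
#' @param psi population sex ratio (probability male), in (0, 1).
#' @param sex `"female"`, `"male"` or `NA` for unknown.
#' @return Scalar marginal log contribution.
#' @export
sex_mixture_loglik <- function(ll_female, ll_male, psi, sex = NA) {
  if (psi <= 0 || psi >= 1) stop("psi must lie in (0, 1)")
  if (is.na(sex)) {
    m <- max(ll_male + log(psi), ll_female + log1p(-psi))
    m + log(exp(ll_male + log(psi) - m) + exp(ll_female + log1p(-psi) - m))
  } else if (sex == "male") {
    log(psi) + ll_male
  } else {
    log1p(-psi) + ll_female
  }
}
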