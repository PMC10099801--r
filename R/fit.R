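#' Sampler configuration
#'
#' MCMC settings for the integrated model. The historical defaults are five
#' chains of 150,000 iterations with a burn-in of 50,000 for a final model
#' fit and 10,000 for the variable-selection stage; both are freely
#' configurable and analyses at reduced scale simply pass smaller values.
#'
#' @param n_chains number of chains (at least 2 for split-Rhat).
#' @param n_iter total iterations per chain (including burn-in).
#' @param burnin burn-in iterations discarded (adaptation happens here and
#'   is frozen afterwards to preserve ergodicity).
#' @param thin thinning interval (default 1, no thinning).
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param adapt_interval iterations between proposal-scale adaptations
#'   during burn-in (target acceptance 0.30-0.45).
#' @param rhat_threshold convergence threshold for the split-Rhat flag.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 5L, n_iter = 150000L, burnin = 50000L,
                           thin = 1L, seed = 1L, adapt_interval = 50L,
                           rhat_threshold = 1.1) {
  if (n_iter <= burnin || burnin < 0) stop("need n_iter > burnin >= 0")
  if (n_chains < 1) stop("n_chains must be >= 1")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 rhat_threshold = rhat_threshold),
            class = "sampler_config")
}

#' Prior configuration
#'
#' Hyperparameters of the prior layer. Selectable coefficients (and the two
#' intercepts) get Normal(0, sigma_r^2) slabs with
#' sigma_r^2 ~ Inverse-Gamma(4, 5) (mean 5/3); the year-effect SDs get
#' half-Normal(0, 1) priors on the logit scale; the sex ratio is
#' Uniform(0, 1); growth hyperpriors are weakly informative apart from the
#' externally informed hatchling-size prior carried by
#' [growth_hyperparams()].
#'
#' @param slab_a,slab_b inverse-gamma shape and rate of the slab variance.
#' @param mu_logK_mean,mu_logK_sd Normal prior on the log-scale K location.
#' @param sd_logK_scale half-Normal scale for the K random-effect SD.
#' @param mu_LT2_mean,mu_LT2_sd Normal prior on the mean size at T2 (mm).
#' @param sd_LT2_scale half-Normal scale for the size-at-T2 SD (mm).
#' @param sigma_L_scale half-Normal scale for the measurement-error SD (mm).
#' @param sigma_year_scale half-Normal scale for the year-effect SDs.
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(slab_a = 4, slab_b = 5,
                         mu_logK_mean = -1, mu_logK_sd = 2,
                         sd_logK_scale = 1,
                         mu_LT2_mean = 60, mu_LT2_sd = 20,
                         sd_LT2_scale = 10,
                         sigma_L_scale = 5,
                         sigma_year_scale = 1) {
  structure(list(slab_a = slab_a, slab_b = slab_b,
                 mu_logK_mean = mu_logK_mean, mu_logK_sd = mu_logK_sd,
                 sd_logK_scale = sd_logK_scale,
                 mu_LT2_mean = mu_LT2_mean, mu_LT2_sd = mu_LT2_sd,
                 sd_LT2_scale = sd_LT2_scale,
                 sigma_L_scale = sigma_L_scale,
                 sigma_year_scale = sigma_year_scale),
            class = "prior_config")
}

# Assemble the data list consumed by the compiled sampler; internal.
.sampler_data <- function(data, std, priors, thresholds,
                          hatch_mean, hatch_sd, T1, T2,
                          pseudopriors = NULL, age_max = 30,
                          entry_age_mean = 3) {
  sex_known <- ifelse(is.na(data$sex), -1L,
                      ifelse(data$sex == "male", 1L, 0L))
  svl <- data$svl
  svl[is.na(svl)] <- -1  # never read where y == 0
  if (is.null(pseudopriors)) {
    pm <- rep(0, 8); ps <- rep(10, 8)
  } else {
    pm <- pseudopriors$mean; ps <- pseudopriors$sd
  }
  list(n = data$n, T = data$n_occasions,
       f0 = data$f - 1L, last0 = data$last - 1L,
       sex_known = as.integer(sex_known),
       y = data$y, svl = svl,
       std_mean = std$mean_svl, std_sd = std$sd_svl,
       T1 = T1, T2 = T2,
       hatch_mean = hatch_mean, hatch_sd = hatch_sd,
       thr_female = thresholds$female_svl, thr_male = thresholds$male_svl,
       age_max = age_max, entry_age_mean = entry_age_mean,
       priors = unclass(priors),
       pseudo_mean = pm, pseudo_sd = ps)
}

# Overdispersed but valid chain initial values; internal.
.sampler_inits <- function(data, std, chain, hatch_mean, T2) {
  n <- data$n; T <- data$n_occasions
  jit <- function(x, s) x + stats::rnorm(length(x), 0, s)
  sex <- ifelse(is.na(data$sex), stats::rbinom(n, 1, 0.5),
                as.integer(data$sex == "male"))
  first_obs <- data$svl[cbind(seq_len(n), data$f)]
  max_obs <- suppressWarnings(apply(data$svl, 1, max, na.rm = TRUE))
  max_obs[!is.finite(max_obs)] <- 55
  first_obs[is.na(first_obs)] <- max_obs[is.na(first_obs)]
  L1 <- rep(hatch_mean, n)
  L2 <- pmax(max_obs + 4, hatch_mean + 25) + abs(stats::rnorm(n, 0, 1))
  logK <- stats::rnorm(n, log(0.5) + 0.25 * (chain - 1.5) / 2, 0.1)
  # entry age consistent with the first observed size on the init curve
  K <- exp(logK)
  E <- exp(-K * T2)
  Linf <- (L2 - L1 * E) / (1 - E)
  Lf <- pmin(pmax(first_obs, L1 + 0.5), Linf - 0.5)

  list(coef = c(jit(1, 0.5), rep(0, 5), jit(0, 0.5), rep(0, 3))[c(1:10)],
       g = rep(1L, 8),
       eps_phi = rep(0, T - 1), eps_p = rep(0, T - 1),
       sigma_phi = stats::runif(1, 0.1, 0.5),
       sigma_p = stats::runif(1, 0.1, 0.8),
       psi = stats::runif(1, 0.35, 0.65),
       mu_logK = jit(c(log(0.45), log(0.55)), 0.15),
       sd_logK = stats::runif(2, 0.1, 0.3),
       mu_LT2 = jit(c(66, 71), 2),
       sd_LT2 = stats::runif(2, 1.5, 4),
       sigma_L = stats::runif(1, 0.7, 2),
       logK = logK, L1 = L1, L2 = L2, Lf = Lf,
       sex = as.integer(sex))
}

.default_ctrl <- function(config, ...) {
  ctrl <- list(likelihood_on = TRUE, sample_g = FALSE,
               update_coef = rep(1L, 10),
               update_eps_phi = TRUE, update_eps_p = TRUE,
               update_growth = TRUE, update_sigma_L = TRUE,
               update_psi = TRUE, update_sex = TRUE,
               n_iter = config$n_iter, burnin = config$burnin,
               thin = config$thin, adapt_interval = config$adapt_interval)
  utils::modifyList(ctrl, list(...))
}

#' Fit the integrated growth + capture-recapture model
#'
#' Runs the Metropolis-within-Gibbs sampler on a capture dataset: Schnute
#' growth with individual random effects imputes latent size trajectories,
#' which drive logit-linear survival and recapture with Normal year random
#' effects; sex may be latent; measurement error links latent and observed
#' sizes. Chains run sequentially with deterministically derived seeds;
#' split-Rhat is computed for every monitored scalar and parameters
#' exceeding the threshold are flagged (with a warning, never silently).
#'
#' @param data a [capture_data()] object.
#' @param config a [sampler_config()].
#' @param model inclusion vector of length 8 (see [predictor_names()]);
#'   default all ones (full model). Fixed during sampling.
#' @param std a [standardization()]; default computed from the observed
#'   sizes ([standardization_from_data()]).
#' @param priors a [prior_config()].
#' @param growth a [growth_hyperparams()] carrying the hatchling-size prior
#'   and reference ages are taken from `T1`, `T2`.
#' @param thresholds a [maturity_thresholds()] used for the derived
#'   at-maturity quantities monitored during sampling.
#' @param T1,T2 growth reference ages (years).
#' @param gvs logical: sample the inclusion indicators (requires
#'   `pseudopriors`).
#' @param pseudopriors a `pseudopriors` object from [pilot_run()].
#' @param inits optional named list of initial values merged over the
#'   generated ones (useful with the `update_*` controls to hold selected
#'   parameters fixed).
#' @param ... advanced control overrides passed to the sampler (e.g.
#'   `update_eps_phi = FALSE`, `likelihood_on = FALSE`,
#'   `update_coef = c(1, rep(0, 9))`).
#' @return An object of class `cmr_fit`: `chains` (list of draw matrices),
#'   `rhat`, `flagged` (parameters with Rhat above threshold),
#'   `acceptance`, `latent` (posterior-mean individual K, asymptotic size
#'   and male probability), plus the configuration used.
#' @export
fit_model <- function(data, config = sampler_config(),
                      model = rep(1L, 8), std = NULL,
                      priors = prior_config(),
                      growth = growth_hyperparams(),
                      thresholds = maturity_thresholds(),
                      T1 = 0, T2 = 14,
                      gvs = FALSE, pseudopriors = NULL, inits = NULL, ...) {
  stopifnot(inherits(data, "capture_data"))
  if (is.null(std)) std <- standardization_from_data(data)
  if (gvs && is.null(pseudopriors))
    stop("Gibbs variable selection requires pseudopriors from pilot_run()")
  dat <- .sampler_data(data, std, priors, thresholds,
                       growth$hatch_mean, growth$hatch_sd, T1, T2,
                       pseudopriors)
  chains <- vector("list", config$n_chains)
  acc <- vector("list", config$n_chains)
  latent <- NULL
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * ch)
    init <- .sampler_inits(data, std, ch, growth$hatch_mean, T2 - T1)
    init$g <- as.integer(model)
    if (!is.null(inits)) init <- utils::modifyList(init, inits)
    ctrl <- .default_ctrl(config, sample_g = gvs, ...)
    res <- run_chain_cpp(dat, init, ctrl)
    chains[[ch]] <- res$draws
    acc[[ch]] <- res$acceptance
    if (ch == 1L)
      latent <- data.frame(id = data$id,
                           mean_K = res$latent_mean_K,
                           mean_Linf = res$latent_mean_Linf,
                           pr_male = res$latent_mean_male,
                           mean_entry_age = res$latent_mean_entry_age)
  }
  rh <- rhat(chains)
  flagged <- names(rh)[!is.na(rh) & rh > config$rhat_threshold]
  if (length(flagged))
    warning(sprintf("split-Rhat > %.2f for: %s", config$rhat_threshold,
                    paste(flagged, collapse = ", ")), call. = FALSE)
  structure(list(chains = chains, rhat = rh, flagged = flagged,
                 acceptance = acc, latent = latent,
                 config = config, model = as.integer(model), std = std,
                 thresholds = thresholds, gvs = gvs,
                 n_individuals = data$n, n_occasions = data$n_occasions),
            class = "cmr_fit")
}

#' @export
print.cmr_fit <- function(x, ...) {
  cat(sprintf("Integrated growth-CJS fit: %d individuals, %d occasions\n",
              x$n_individuals, x$n_occasions))
  cat(sprintf("%d chains x %d draws kept%s\n", length(x$chains),
              nrow(x$chains[[1]]),
              if (x$gvs) " (variable selection on)" else ""))
  if (length(x$flagged))
    cat("NOT CONVERGED (Rhat above threshold):",
        paste(x$flagged, collapse = ", "), "\n")
  else cat("All monitored parameters passed the split-Rhat check\n")
  invisible(x)
}

#' Pooled posterior draws of a fit
#' @param fit a `cmr_fit` object.
#' @return Matrix of all post-burn-in draws, chains stacked.
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "cmr_fit"))
  do.call(rbind, fit$chains)
}

#' Posterior summary table
#'
#' @param object a `cmr_fit` object.
#' @param params optional character vector of monitored names.
#' @param ... unused.
#' @return Data frame with mean, median, equal-tailed 95% credible
#'   interval and split-Rhat per parameter.
#' @export
summary.cmr_fit <- function(object, params = NULL, ...) {
  d <- posterior_draws(object)
  if (is.null(params)) params <- colnames(d)
  d <- d[, params, drop = FALSE]
  out <- data.frame(
    param = params,
    mean = colMeans(d, na.rm = TRUE),
    median = apply(d, 2, stats::median, na.rm = TRUE),
    lo95 = apply(d, 2, stats::quantile, 0.025, na.rm = TRUE),
    hi95 = apply(d, 2, stats::quantile, 0.975, na.rm = TRUE),
    rhat = object$rhat[params],
    row.names = NULL)
  out
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' for every monitored column. Columns with (near-)zero total variance
#' (for example fixed inclusion indicators) return `NA`.
#'
#' @param chains list of draw matrices with identical column names.
#' @return Named numeric vector of Rhat values.
#' @export
rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1)
  cols <- colnames(chains[[1]])
  halves <- list()
  for (ch in chains) {
    m <- nrow(ch) %/% 2L
    if (m < 2L) return(stats::setNames(rep(NA_real_, length(cols)), cols))
    halves <- c(halves, list(ch[1:m, , drop = FALSE]),
                list(ch[(m + 1):(2 * m), , drop = FALSE]))
  }
  nh <- length(halves); m <- nrow(halves[[1]])
  out <- stats::setNames(numeric(length(cols)), cols)
  for (j in seq_along(cols)) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars); B <- m * stats::var(means)
    if (!is.finite(W) || W < 1e-12) { out[j] <- NA_real_; next }
    vhat <- (m - 1) / m * W + B / m
    out[j] <- sqrt(vhat / W)
  }
  out
}

#' Pilot run of the full model for pseudopriors
#'
#' Fits the full model (all inclusion indicators on) and moment-matches a
#' Normal pseudoprior to the marginal pilot posterior of each selectable
#' coefficient. These pseudopriors keep the chain mixing over models during
#' Gibbs variable selection: a coefficient currently excluded from the
#' likelihood is drawn from its pseudoprior instead of wandering in the
#' slab.
#'
#' @inheritParams fit_model
#' @return An object of class `pseudopriors`: data frame-like list with
#'   `mean` and `sd` (length 8, order of [predictor_names()]), plus the
#'   pilot `cmr_fit` as attribute `"pilot"`.
#' @export
pilot_run <- function(data, config = sampler_config(burnin = 10000L), ...) {
  fit <- fit_model(data, config = config, model = rep(1L, 8), gvs = FALSE, ...)
  d <- posterior_draws(fit)
  cols <- c("b_phi_sex", "b_phi_svl", "b_phi_svl2", "b_phi_sex_svl",
            "b_phi_sex_svl2", "b_p_sex", "b_p_svl", "b_p_sex_svl")
  m <- colMeans(d[, cols, drop = FALSE])
  s <- apply(d[, cols, drop = FALSE], 2, stats::sd)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("degenerate pilot posterior: zero-variance coefficient marginal")
  structure(list(mean = unname(m), sd = unname(s),
                 predictor = predictor_names()),
            class = "pseudopriors", pilot = fit)
}

#' Gibbs variable selection over the survival/recapture model space
#'
#' Samples binary inclusion indicators (Bernoulli(0.5) priors) alongside all
#' other parameters. Interaction and quadratic terms drop out of the
#' likelihood whenever a parent term is off, so the visited effective model
#' space is the admissible 10 x 5 grid. Reports the marginal inclusion
#' probability of each predictor (posterior mean of its effective
#' indicator) and the posterior probability of each visited model, and
#' applies both selection rules via [select_model()]. If chains disagree on
#' the top model the result is flagged.
#'
#' @inheritParams fit_model
#' @param pseudopriors a `pseudopriors` object from [pilot_run()].
#' @return An object of class `gvs_result`: `inclusion_probs`,
#'   `model_probs` (named by model index), `model_table` (data frame with
#'   notation and probabilities), `selection` (see [select_model()]),
#'   `chain_agreement`, and the underlying `cmr_fit`.
#' @export
run_gvs <- function(data, pseudopriors,
                    config = sampler_config(burnin = 10000L), ...) {
  stopifnot(inherits(pseudopriors, "pseudopriors"))
  fit <- fit_model(data, config = config, model = rep(1L, 8),
                   gvs = TRUE, pseudopriors = pseudopriors, ...)
  d <- posterior_draws(fit)
  mdl <- as.integer(d[, "mdl"])
  eff <- t(vapply(mdl, decode_model_index, integer(8)))
  incl <- stats::setNames(colMeans(eff), predictor_names())
  tab <- table(mdl) / length(mdl)
  model_probs <- stats::setNames(as.numeric(tab), names(tab))
  ord <- order(-model_probs)
  model_probs <- model_probs[ord]
  notation <- vapply(as.integer(names(model_probs)),
                     function(m) model_notation(decode_model_index(m)),
                     character(1))
  top_by_chain <- vapply(fit$chains, function(ch) {
    tt <- table(as.integer(ch[, "mdl"]))
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
  agreement <- length(unique(top_by_chain)) == 1L
  if (!agreement)
    warning("chains disagree on the highest-probability model: ",
            paste(top_by_chain, collapse = ", "), call. = FALSE)
  structure(list(inclusion_probs = incl, model_probs = model_probs,
                 model_table = data.frame(mdl = as.integer(names(model_probs)),
                                          notation = notation,
                                          prob = unname(model_probs)),
                 selection = select_model(incl, model_probs),
                 chain_agreement = agreement,
                 top_by_chain = top_by_chain,
                 fit = fit),
            class = "gvs_result")
}

#' @export
print.gvs_result <- function(x, ...) {
  cat("Gibbs variable selection over the 10 x 5 model space\n")
  cat("Pr(Included):\n")
  print(round(x$inclusion_probs, 3))
  cat("Top models:\n")
  print(utils::head(x$model_table, 7), row.names = FALSE)
  cat("Median-probability model:", x$selection$median_notation, "\n")
  if (!is.null(x$selection$best_notation))
    cat(sprintf("Best model: %s (posterior probability %.3f)\n",
                x$selection$best_notation, x$selection$best_prob))
  invisible(x)
}

# Compiled-likelihood cross-check helper; internal but used in tests.
.model_loglik <- function(data, state, std,
                          priors = prior_config(),
                          growth = growth_hyperparams(),
                          thresholds = maturity_thresholds(),
                          T1 = 0, T2 = 14, model = rep(1L, 8)) {
  dat <- .sampler_data(data, std, priors, thresholds,
                       growth$hatch_mean, growth$hatch_sd, T1, T2)
  init <- state
  init$g <- as.integer(model)
  ctrl <- .default_ctrl(sampler_config(n_chains = 2, n_iter = 2, burnin = 1))
  model_loglik_cpp(dat, init, ctrl)
}
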