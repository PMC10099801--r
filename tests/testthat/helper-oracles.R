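# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written by a different route than the
# package code it checks (closed forms, brute-force enumeration, m-arrays).

# closed-form von Bertalanffy route to the growth curve: L(a) anchored at
# (0, L0) relaxing to Linf -- independent of the package's two-reference-size
# parameterisation
vb_size <- function(L0, Linf, K, t) Linf - (Linf - L0) * exp(-K * t)

# random tiny capture dataset (<= 3 individuals, <= 4 occasions)
random_tiny_dataset <- function(n = NULL, T = NULL) {
  if (is.null(n)) n <- sample(1:3, 1)
  if (is.null(T)) T <- sample(2:4, 1)
  y <- matrix(0L, n, T)
  svl <- matrix(NA_real_, n, T)
  for (i in seq_len(n)) {
    f <- sample.int(T, 1)
    y[i, f] <- 1L
    if (f < T)
      for (t in (f + 1):T) y[i, t] <- rbinom(1, 1, 0.5)
    obs <- which(y[i, ] == 1L)
    svl[i, obs] <- sort(runif(length(obs), 40, 70))
  }
  sex <- sample(c("male", "female"), n, replace = TRUE)
  capture_data(y = y, svl = svl, sex = sex)
}

# random parameter set for the tiny-likelihood tests
random_tiny_state <- function(data) {
  T <- data$n_occasions
  phi_m <- survival_model(alpha = rnorm(1, 0.8, 0.7), b_sex = rnorm(1, 0, 0.5),
                          b_svl = rnorm(1, 0, 0.5), b_svl2 = rnorm(1, 0, 0.3),
                          b_sex_svl = rnorm(1, 0, 0.3),
                          b_sex_svl2 = rnorm(1, 0, 0.2),
                          year_effects = rnorm(T - 1, 0, 0.3))
  p_m <- detection_model(alpha = rnorm(1, 0, 0.7), b_sex = rnorm(1, 0, 0.5),
                         b_svl = rnorm(1, 0, 0.5), b_sex_svl = rnorm(1, 0, 0.3),
                         year_effects = rnorm(T - 1, 0, 0.3))
  L <- matrix(NA_real_, data$n, T)
  for (i in seq_len(data$n)) {
    gp <- growth_params(K = runif(1, 0.3, 0.8), L_T1 = 33,
                        L_T2 = runif(1, 62, 75))
    L[i, ] <- impute_trajectory(runif(1, 40, 58), gp, f = data$f[i],
                                n_occasions = T)
    # trajectory entries before first capture are unused by the likelihood
    if (data$f[i] > 1) L[i, seq_len(data$f[i] - 1)] <- 50
  }
  list(L = L, sex = as.integer(data$sex == "male"),
       phi_model = phi_m, p_model = p_m,
       std = standardization(55, 8), sigma_L = runif(1, 0.5, 2))
}

# brute-force marginal likelihood: enumerate every alive configuration
enum_cjs_loglik <- function(data, states, phi_model, p_model, std, sigma_L) {
  T <- data$n_occasions
  total <- 0
  for (i in seq_len(data$n)) {
    yi <- data$y[i, , drop = FALSE]
    svli <- data$svl[i, , drop = FALSE]
    sub <- capture_data(yi, svli, data$sex[i], svl_window = c(1, 200))
    sti <- list(L = states$L[i, , drop = FALSE], sex = states$sex[i])
    f <- data$f[i]
    ks <- T - f
    lls <- numeric(0)
    for (m in 0:(2^ks - 1)) {
      z <- matrix(0L, 1, T)
      z[1, f] <- 1L
      if (ks > 0)
        z[1, (f + 1):T] <- as.integer(intToBits(m))[seq_len(ks)]
      ll <- cjs_complete_loglik(sub, z, sti, phi_model, p_model, std, sigma_L)
      if (is.finite(ll)) lls <- c(lls, ll)
    }
    mx <- max(lls)
    total <- total + mx + log(sum(exp(lls - mx)))
  }
  total
}

# m-array of a detection-history matrix: rows = release occasion, columns
# 1..T-1 = occasion of next recapture minus one, last column = never seen again
build_marray <- function(y) {
  T <- ncol(y)
  M <- matrix(0, T - 1, T)
  for (i in seq_len(nrow(y))) {
    obs <- which(y[i, ] == 1L)
    for (k in seq_along(obs)) {
      t <- obs[k]
      if (t == T) next
      if (k < length(obs)) M[t, obs[k + 1] - 1] <- M[t, obs[k + 1] - 1] + 1
      else M[t, T] <- M[t, T] + 1
    }
  }
  M
}

# classical constant-(phi, p) CJS maximum likelihood from the m-array
marray_mle <- function(y) {
  M <- build_marray(y)
  T <- ncol(y)
  nll <- function(par) {
    phi <- plogis(par[1]); p <- plogis(par[2])
    ll <- 0
    for (t in seq_len(T - 1)) {
      pr <- numeric(T)
      for (j in t:(T - 1)) pr[j] <- phi^(j - t + 1) * p * (1 - p)^(j - t)
      pr[T] <- 1 - sum(pr[t:(T - 1)])
      keep <- M[t, ] > 0
      ll <- ll + sum(M[t, keep] * log(pr[keep]))
    }
    -ll
  }
  est <- stats::optim(c(qlogis(0.7), qlogis(0.5)), nll)$par
  c(phi = plogis(est[1]), p = plogis(est[2]))
}

# reduced sampler settings used by the heavier tests
quick_config <- function(n_chains = 2L, n_iter = 1200L, burnin = 600L,
                         seed = 11L) {
  sampler_config(n_chains = n_chains, n_iter = n_iter, burnin = burnin,
                 seed = seed)
}
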