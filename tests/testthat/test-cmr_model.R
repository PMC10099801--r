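test_that("standardization is an exact affine bijection", {
  s <- standardization(58.4, 8.2)
  expect_equal(standardize(58.4, s), 0)
  expect_equal(standardize(58.4 + 8.2, s), 1)
  expect_equal(standardize(70, s), 1.4146, tolerance = 1e-4)
  expect_equal(unstandardize(standardize(63.7, s), s), 63.7)
  expect_error(standardization(50, 0), "sd_svl")
})

test_that("logit-linear survival and recapture probabilities", {
  m0 <- survival_model()
  expect_equal(survival_prob(0, 0, 0, m0), 0.5)
  expect_equal(survival_prob(1, 2, 0, m0), 0.5)  # all coefficients zero
  expect_lt(survival_prob(0, 0, 0, survival_model(alpha = -10)), 1e-4)
  expect_equal(survival_prob(0, 1, 0,
                             survival_model(alpha = 1.5, b_svl = -0.5)),
               0.7311, tolerance = 1e-4)
  # quadratic and interaction terms enter the predictor
  m <- survival_model(alpha = 0, b_svl2 = 1, b_sex_svl2 = -1)
  expect_equal(survival_prob(1, 2, 0, m), 0.5)
  expect_equal(survival_prob(0, 2, 0, m), plogis(4))

  d0 <- detection_model()
  expect_equal(detection_prob(0, 0, 0, d0), 0.5)
  expect_equal(detection_prob(1, 0, 0, detection_model(b_sex = 1)),
               0.7311, tolerance = 1e-4)
})

test_that("imputed size trajectories follow the growth map", {
  gp <- growth_params(K = 0.5, L_T1 = 33, L_T2 = 70)
  expect_equal(impute_trajectory(50, gp, f = 1, n_occasions = 1), 50)
  tr <- impute_trajectory(50, gp, f = 1, n_occasions = 3)
  linf <- asymptotic_size(gp)
  expect_equal(tr, vb_size(50, linf, 0.5, 0:2), tolerance = 1e-12)
  expect_equal(tr, c(50, 57.88, 62.66), tolerance = 1e-2)
  expect_true(all(diff(tr) > 0))
  # two one-year steps equal one two-year step (semigroup)
  expect_equal(tr[3], predict_size(50, 2, gp), tolerance = 1e-9)
  # enormous K pins the trajectory to the asymptote after entry
  gph <- growth_params(K = 30, L_T1 = 33, L_T2 = 70)
  trh <- impute_trajectory(40, gph, f = 1, n_occasions = 4)
  expect_equal(trh[-1], rep(asymptotic_size(gph), 3), tolerance = 1e-8)
  # NA before a later first capture
  tr2 <- impute_trajectory(50, gp, f = 3, n_occasions = 5)
  expect_true(all(is.na(tr2[1:2])) && !anyNA(tr2[3:5]))
  expect_error(impute_trajectory(75, gp, 1, 3), "below the asymptotic")
})

test_that("marginal CJS likelihood equals brute-force enumeration over alive states", {
  set.seed(202)
  for (rep in 1:60) {
    data <- random_tiny_dataset()
    st <- random_tiny_state(data)
    marg <- cjs_loglik(data, st, st$phi_model, st$p_model, st$std, st$sigma_L)
    enum <- enum_cjs_loglik(data, st, st$phi_model, st$p_model, st$std,
                            st$sigma_L)
    expect_equal(marg, enum, tolerance = 1e-10)
  }
})

test_that("complete-data likelihood handles degenerate cases", {
  # single individual seen only once contributes only its measurement term
  data <- capture_data(matrix(1L, 1, 1), matrix(51, 1, 1), "female")
  st <- list(L = matrix(50, 1, 1), sex = 0L)
  phi_m <- survival_model(alpha = 0.3)
  p_m <- detection_model(alpha = -0.2)
  std <- standardization(55, 8)
  ll <- cjs_loglik(data, st, phi_m, p_m, std, sigma_L = 2)
  expect_equal(ll, dnorm(51, 50, 2, log = TRUE))

  # certain survival and detection with an all-ones history and exact sizes:
  # nothing but (vanishing) measurement terms remain
  T <- 4
  L <- impute_trajectory(45, growth_params(K = 0.5, L_T1 = 33, L_T2 = 70),
                         1, T)
  data2 <- capture_data(matrix(1L, 1, T), matrix(L, 1), "male")
  st2 <- list(L = matrix(L, 1), sex = 1L)
  ll2 <- cjs_loglik(data2, st2, survival_model(alpha = 50),
                    detection_model(alpha = 50), std, sigma_L = 1)
  expect_equal(ll2, sum(dnorm(0, 0, 1, log = TRUE) * rep(1, T)),
               tolerance = 1e-8)

  # a state resurrecting the individual has probability zero
  z <- matrix(c(1L, 0L, 1L, 1L), 1)
  expect_identical(
    cjs_complete_loglik(data2, z, st2, phi_m, p_m, std, 1), -Inf)
})

test_that("latent-sex mixture contribution", {
  # flat data likelihood: the prior odds carry through
  expect_equal(sex_mixture_loglik(0, 0, 0.5, NA), log(1))
  expect_equal(sex_mixture_loglik(-3, -1, 0.5, "male"), log(0.5) - 1)
  expect_equal(sex_mixture_loglik(-3, -1, 0.5, "female"), log(0.5) - 3)
  expect_equal(sex_mixture_loglik(-3, -1, 0.7, NA),
               log(0.7 * exp(-1) + 0.3 * exp(-3)))
  expect_error(sex_mixture_loglik(0, 0, 1.2), "psi")
})

test_that("compiled sampler likelihood agrees with the R implementation", {
  set.seed(31)
  sim <- generate(generator_config(n_individuals = 40))
  data <- sim$data
  T <- data$n_occasions
  std <- standardization(57, 9)
  # a full arbitrary state
  n <- data$n
  gp_K <- runif(n, 0.35, 0.7)
  L1 <- rnorm(n, 33, 1)
  L2 <- runif(n, 64, 74)
  first_obs <- data$svl[cbind(seq_len(n), data$f)]
  Lf <- pmin(first_obs, 62)
  sex01 <- ifelse(is.na(data$sex), 0L, as.integer(data$sex == "male"))
  L <- matrix(NA_real_, n, T)
  for (i in seq_len(n))
    L[i, ] <- impute_trajectory(Lf[i], growth_params(gp_K[i], L1[i], L2[i]),
                                data$f[i], T)
  eps_phi <- rnorm(T - 1, 0, 0.3); eps_p <- rnorm(T - 1, 0, 0.3)
  phi_m <- survival_model(1.2, 0.3, -0.4, 0.1, -0.2, 0.05,
                          year_effects = eps_phi)
  p_m <- detection_model(-0.2, 0.5, 0.3, -0.1, year_effects = eps_p)
  sigL <- 1.3
  r_ll <- cjs_loglik(data, list(L = L, sex = sex01), phi_m, p_m, std, sigL)

  state <- list(
    coef = c(phi_m$alpha, phi_m$b_sex, phi_m$b_svl, phi_m$b_svl2,
             phi_m$b_sex_svl, phi_m$b_sex_svl2,
             p_m$alpha, p_m$b_sex, p_m$b_svl, p_m$b_sex_svl),
    eps_phi = eps_phi, eps_p = eps_p,
    sigma_phi = 0.3, sigma_p = 0.3, psi = 0.5,
    mu_logK = c(log(0.4), log(0.55)), sd_logK = c(0.2, 0.2),
    mu_LT2 = c(65, 72), sd_LT2 = c(2.5, 2.5), sigma_L = sigL,
    logK = log(gp_K), L1 = L1, L2 = L2, Lf = Lf, sex = sex01)
  cpp <- sizecmr:::.model_loglik(data, state, std)
  expect_equal(cpp$total, r_ll, tolerance = 1e-9)
})
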