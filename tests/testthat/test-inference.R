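test_that("model-index encoding is a bijection with the documented examples", {
  expect_identical(encode_model_index(rep(0, 8)), 1L)
  expect_identical(encode_model_index(c(1, rep(0, 7))), 3L)
  expect_identical(encode_model_index(c(1, 1, 0, 1, 0, 1, 1, 0)), 215L)
  grid <- as.matrix(expand.grid(rep(list(0:1), 8)))
  codes <- apply(grid, 1, encode_model_index)
  expect_identical(length(unique(codes)), 256L)
  for (k in seq_len(nrow(grid)))
    expect_identical(decode_model_index(codes[k]),
                     as.integer(grid[k, ]))
})

test_that("hierarchy constraint yields the 10 x 5 admissible model space", {
  am <- admissible_models()
  expect_identical(nrow(am), 50L)
  expect_identical(nrow(unique(am[, 1:5])), 10L)  # survival sub-models
  expect_identical(nrow(unique(am[, 6:8])), 5L)   # recapture sub-models
  # every admissible model is a fixed point of the hierarchy map
  for (k in seq_len(nrow(am)))
    expect_identical(effective_inclusion(am[k, ]), as.integer(am[k, ]))
  # a dangling interaction or quadratic is masked
  expect_identical(effective_inclusion(c(0, 0, 1, 1, 1, 0, 0, 1)),
                   rep(0L, 8))
})

test_that("model selection rules: median-probability and best model", {
  incl <- c(1, 1, 0.186, 0.447, 0.035, 1, 0.804, 0.164)
  sel <- select_model(incl)
  expect_identical(sel$median_model, c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L))
  expect_identical(sel$median_notation, "phi(sex + svl), p(sex + svl)")
  expect_identical(select_model(rep(0, 8))$median_notation, "phi(.), p(.)")
  # posterior-probability ties break toward the smaller model
  probs <- c(0.3, 0.3)
  names(probs) <- c(encode_model_index(c(1, 1, 0, 0, 0, 0, 0, 0)),
                    encode_model_index(c(1, 0, 0, 0, 0, 0, 0, 0)))
  sel2 <- select_model(rep(0.4, 8), probs)
  expect_identical(sel2$best_model, c(1L, rep(0L, 7)))
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(40)
  same <- list(cbind(x = rnorm(400)), cbind(x = rnorm(400)))
  expect_lt(rhat(same)[["x"]], 1.05)
  apart <- list(cbind(x = rnorm(400)), cbind(x = rnorm(400, 5)))
  expect_gt(rhat(apart)[["x"]], 2)
  flat <- list(cbind(x = rep(1, 400)), cbind(x = rep(1, 400)))
  expect_true(is.na(rhat(flat)[["x"]]))
})

test_that("sex-ratio posterior matches the conjugate Beta closed form", {
  # 332 known males, 385 known females, flat data likelihood: psi draws
  # must follow Beta(333, 386)
  n <- 717
  y <- cbind(rep(1L, n), rep(0L, n))
  svl <- cbind(rep(50, n), NA_real_)
  sex <- c(rep("male", 332), rep("female", 385))
  data <- capture_data(y, svl, sex)
  fit <- fit_model(data,
    config = sampler_config(n_chains = 2, n_iter = 2000, burnin = 200,
                            seed = 3),
    model = rep(0L, 8), std = standardization(50, 5),
    likelihood_on = FALSE, update_coef = rep(0L, 10),
    update_eps_phi = FALSE, update_eps_p = FALSE, update_growth = FALSE,
    update_sigma_L = FALSE, update_sex = FALSE)
  psi <- posterior_draws(fit)[, "psi"]
  expect_lt(abs(mean(psi) - 333 / 719), 0.002)
  expect_lt(abs(sd(psi) - sqrt(333 * 386 / (719^2 * 720))), 0.002)
})

test_that("fits are reproducible under a fixed master seed", {
  set.seed(50)
  sim <- generate(generator_config(n_individuals = 30))
  cfg <- sampler_config(n_chains = 2, n_iter = 300, burnin = 100, seed = 123)
  f1 <- suppressWarnings(fit_model(sim$data, config = cfg))
  f2 <- suppressWarnings(fit_model(sim$data, config = cfg))
  expect_identical(f1$chains, f2$chains)
  f3 <- suppressWarnings(fit_model(sim$data,
    config = sampler_config(n_chains = 2, n_iter = 300, burnin = 100,
                            seed = 124)))
  expect_false(identical(f1$chains[[1]], f3$chains[[1]]))
})

test_that("pilot run produces usable Normal pseudopriors", {
  set.seed(51)
  sim <- generate(generator_config(n_individuals = 60))
  pp <- suppressWarnings(pilot_run(sim$data,
    config = sampler_config(n_chains = 2, n_iter = 900, burnin = 400,
                            seed = 6),
    std = sim$truth$config$std))
  expect_identical(pp$predictor, predictor_names())
  expect_length(pp$mean, 8)
  expect_true(all(is.finite(pp$mean)))
  expect_true(all(pp$sd > 0))
})
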