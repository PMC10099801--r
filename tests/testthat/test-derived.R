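# assemble a minimal fitted object from an explicit draw matrix
fake_fit <- function(draws, std = standardization(57, 9), T = 10) {
  structure(list(chains = list(draws), rhat = NULL, flagged = character(0),
                 std = std, model = rep(1L, 8), gvs = FALSE,
                 n_individuals = 0L, n_occasions = T),
            class = "cmr_fit")
}

fake_draws <- function(n = 1000, T = 10, ...) {
  over <- list(...)
  cols <- c("alpha_phi", "b_phi_sex", "b_phi_svl", "b_phi_svl2",
            "b_phi_sex_svl", "b_phi_sex_svl2", "alpha_p", "b_p_sex",
            "b_p_svl", "b_p_sex_svl", "psi",
            paste0("eps_phi[", 1:(T - 1), "]"),
            paste0("eps_p[", 2:T, "]"),
            "mdl", "K_f", "K_m", "Linf_f", "Linf_m",
            "phi_mat_f", "phi_mat_m")
  d <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  d[, "mdl"] <- encode_model_index(rep(1, 8))
  d[, "psi"] <- 0.5
  d[, "K_f"] <- 0.41; d[, "K_m"] <- 0.56
  d[, "Linf_f"] <- 65.6; d[, "Linf_m"] <- 72.3
  d[, "phi_mat_f"] <- 0.8; d[, "phi_mat_m"] <- 0.8
  for (nm in names(over)) d[, nm] <- over[[nm]]
  d
}

test_that("expected life span under constant survival", {
  expect_equal(life_span(exp(-1)), 1.0)
  expect_equal(life_span(0.5), 1.4427, tolerance = 1e-4)
  phis <- c(0.3, 0.5, 0.8, 0.95)
  expect_true(all(diff(life_span(phis)) > 0))
  # against Monte-Carlo lifetimes of the constant-hazard process
  set.seed(60)
  for (phi in phis) {
    lt <- rexp(2e5, rate = -log(phi))
    se <- sd(lt) / sqrt(length(lt))
    expect_lt(abs(mean(lt) - life_span(phi)), 3 * se)
  }
  expect_error(life_span(1), "phi")
  expect_error(life_span(0), "phi")
})

test_that("posterior life span summarises survival-at-maturity draws", {
  f1 <- fake_fit(fake_draws(phi_mat_f = exp(-1), phi_mat_m = exp(-1)))
  ls1 <- life_span_posterior(f1)
  expect_equal(ls1$female$median, 1.0)
  expect_equal(ls1$female$hi95 - ls1$female$lo95, 0)
  d <- fake_draws(n = 2)
  d[, "phi_mat_m"] <- c(0.5, 0.8)
  ls2 <- life_span_posterior(fake_fit(d))
  expect_true(ls2$male$median >= life_span(0.5) &&
              ls2$male$median <= life_span(0.8))
  expect_identical(ls2$male$n_excluded, 0L)
})

test_that("size-dependent survival curve reflects the coefficient draws", {
  flat <- survival_vs_size(fake_fit(fake_draws(n = 50)))
  expect_true(all(abs(flat$mean - 0.5) < 1e-12))
  dec <- survival_vs_size(fake_fit(fake_draws(n = 50, alpha_phi = 1.4,
                                              b_phi_svl = -0.6)))
  for (s in c("male", "female"))
    expect_true(all(diff(dec$mean[dec$sex == s]) < 0))
  # an excluded coefficient is masked draw by draw
  d <- fake_draws(n = 50, b_phi_svl = -0.6)
  d[, "mdl"] <- encode_model_index(c(1, 0, 0, 0, 0, 1, 1, 0))
  masked <- survival_vs_size(fake_fit(d))
  expect_true(all(abs(masked$mean - 0.5) < 1e-12))
})

test_that("age-dependent survival is the size curve composed with growth", {
  d <- fake_draws(n = 1, alpha_phi = 1.2, b_phi_svl = -0.5, b_phi_sex = 0.3,
                  K_f = 0.41, K_m = 0.56, Linf_f = 65.6, Linf_m = 72.3)
  fit <- fake_fit(d)
  ages <- c(0, 1, 2, 5, 9)
  age_curve <- survival_vs_age(fit, ages = ages, hatch_mean = 33)
  for (s in 0:1) {
    K <- if (s == 1) 0.56 else 0.41
    linf <- if (s == 1) 72.3 else 65.6
    sizes <- vb_size(33, linf, K, ages)
    size_curve <- survival_vs_size(fit, sizes = sizes)
    lab <- ifelse(s == 1, "male", "female")
    expect_equal(age_curve$mean[age_curve$sex == lab],
                 size_curve$mean[size_curve$sex == lab], tolerance = 1e-12)
  }
  # with identical growth the sex gap must come from the sex coefficient
  d2 <- fake_draws(n = 1, b_phi_sex = 0, K_m = 0.41, Linf_m = 65.6)
  ac <- survival_vs_age(fake_fit(d2), ages = ages)
  expect_equal(ac$mean[ac$sex == "male"], ac$mean[ac$sex == "female"],
               tolerance = 1e-12)
})

test_that("annual series summarise the year random effects", {
  const <- annual_series(fake_fit(fake_draws(n = 40, alpha_phi = 1.4,
                                             alpha_p = -0.3)))
  phi_rows <- const[const$series == "phi", ]
  expect_true(all(abs(phi_rows$mean - plogis(1.4)) < 1e-12))
  p_rows <- const[const$series == "p", ]
  expect_true(all(abs(p_rows$mean - plogis(-0.3)) < 1e-12))

  # stronger year variation in recapture than in survival shows up as a
  # wider spread of the annual recapture series
  set.seed(61)
  T <- 10
  d <- fake_draws(n = 400)
  ephi <- rnorm(T - 1, 0, 0.2); ep <- rnorm(T - 1, 0, 0.9)
  for (t in 1:(T - 1)) {
    d[, paste0("eps_phi[", t, "]")] <- ephi[t] + rnorm(400, 0, 0.05)
    d[, paste0("eps_p[", t + 1, "]")] <- ep[t] + rnorm(400, 0, 0.05)
  }
  ser <- annual_series(fake_fit(d))
  expect_gt(sd(ser$mean[ser$series == "p"]),
            sd(ser$mean[ser$series == "phi"]))
})
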