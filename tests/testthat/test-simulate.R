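test_that("generator is deterministic under a fixed seed", {
  set.seed(77); a <- generate(generator_config(n_individuals = 50))
  set.seed(77); b <- generate(generator_config(n_individuals = 50))
  expect_identical(a$data$y, b$data$y)
  expect_identical(a$data$svl, b$data$svl)
  expect_identical(a$truth$K, b$truth$K)
})

test_that("limit behaviours of the capture process", {
  # certain survival and detection: every history is all ones from entry
  set.seed(10)
  sim <- generate(generator_config(
    n_individuals = 60,
    phi_model = survival_model(alpha = 50, year_effects = rep(0, 9)),
    p_model = detection_model(alpha = 50, year_effects = rep(0, 9))))
  y <- sim$data$y
  for (i in seq_len(nrow(y)))
    expect_true(all(y[i, sim$data$f[i]:10] == 1L))

  # no recaptures after entry: first captures only
  set.seed(11)
  sim2 <- generate(generator_config(
    n_individuals = 60,
    p_model = detection_model(alpha = -50, year_effects = rep(0, 9))))
  expect_identical(n_captures(sim2$data), 60L)
  expect_true(all(rowSums(sim2$data$y) == 1L))
})

test_that("constant survival reproduces the binomial fraction", {
  set.seed(12)
  sim <- generate(generator_config(
    n_individuals = 3000, entry_probs = c(1, rep(0, 9)),
    phi_model = survival_model(alpha = qlogis(0.8), year_effects = rep(0, 9)),
    p_model = detection_model(alpha = 50, year_effects = rep(0, 9))))
  alive <- sim$truth$alive
  for (t in 1:5) {
    at_risk <- sum(alive[, t])
    frac <- sum(alive[, t + 1]) / at_risk
    se <- sqrt(0.8 * 0.2 / at_risk)
    expect_lt(abs(frac - 0.8), 3 * se)
  }
})

test_that("true trajectories satisfy the growth semigroup exactly", {
  set.seed(13)
  sim <- generate(generator_config(n_individuals = 40))
  tr <- sim$truth
  for (i in seq_len(40)) {
    gp <- growth_params(tr$K[i], tr$L_T1[i], tr$L_T2[i])
    L <- tr$L_true[i, ]
    occ <- which(!is.na(L))
    if (length(occ) > 1)
      for (k in seq_len(length(occ) - 1))
        expect_equal(L[occ[k + 1]], predict_size(L[occ[k]], 1, gp),
                     tolerance = 1e-12)
    # entry size comes from growing the hatchling size to the entry age
    expect_equal(L[occ[1]], size_at_age(tr$entry_age[i], gp),
                 tolerance = 1e-12)
  }
})

test_that("sex ratio and unsexed fraction converge to the truth", {
  set.seed(14)
  sim <- generate(generator_config(n_individuals = 4000, psi = 0.463))
  emp <- mean(sim$truth$sex == "male")
  expect_lt(abs(emp - 0.463), 3 * sqrt(0.463 * 0.537 / 4000))
  expect_lt(abs(mean(is.na(sim$data$sex)) - 0.02), 0.01)
})

test_that("study-scale preset matches the footprint of the field study", {
  for (s in 1:2) {
    set.seed(s)
    sim <- mimic_study()
    d <- sim$data
    expect_true(abs(d$n - 730) <= 60)
    expect_true(n_captures(d) > 1300 && n_captures(d) < 2000)
    rng <- range(d$svl, na.rm = TRUE)
    expect_true(rng[1] > 25 && rng[2] < 85)
    expect_true(mean(is.na(d$sex)) < 0.06)
  }
})

test_that("measurement error controls apparent negative growth increments", {
  neg_increments <- function(sim) {
    any(apply(sim$data$svl, 1, function(r) {
      o <- r[!is.na(r)]
      length(o) > 1 && any(diff(o) < 0)
    }))
  }
  base <- growth_hyperparams()
  g0 <- base; g0$sigma_L <- 1e-12   # effectively exact measurement
  set.seed(15)
  sim0 <- generate(generator_config(n_individuals = 150, growth = g0))
  expect_false(neg_increments(sim0))
  g1 <- base; g1$sigma_L <- 1.5
  set.seed(16)
  sim1 <- generate(generator_config(n_individuals = 150, growth = g1))
  expect_true(neg_increments(sim1))
})
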