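test_that("growth curve reproduces closed-form values and identities", {
  gp <- growth_params(K = 0.5, L_T1 = 33, L_T2 = 70)

  # zero elapsed time is the identity; the two reference points are exact
  expect_equal(predict_size(50, 0, gp), 50)
  expect_equal(predict_size(gp$L_T1, gp$T2 - gp$T1, gp), gp$L_T2)
  expect_equal(size_at_age(0, gp), 33)
  expect_equal(size_at_age(14, gp), 70)

  # against the independent von Bertalanffy closed form
  linf <- asymptotic_size(gp)
  expect_equal(linf, 70.034, tolerance = 1e-4)
  expect_equal(predict_size(50, 1, gp), vb_size(50, linf, 0.5, 1),
               tolerance = 1e-12)
  expect_equal(predict_size(50, 1, gp), 57.88, tolerance = 1e-3)
  expect_equal(size_at_age(2, gp), 56.41, tolerance = 1e-3)
  expect_equal(age_at_size(size_at_age(2, gp), gp), 2, tolerance = 1e-10)

  # asymptote: huge K collapses L-infinity onto L_T2; D -> infinity limit
  expect_equal(asymptotic_size(growth_params(K = 50, L_T1 = 33, L_T2 = 70)),
               70, tolerance = 1e-6)
  expect_equal(predict_size(40, 1000, gp), linf, tolerance = 1e-6)
})

test_that("growth curve properties hold over random parameter draws", {
  set.seed(7)
  for (rep in 1:25) {
    gp <- growth_params(K = runif(1, 0.1, 1.5), L_T1 = runif(1, 28, 38),
                        L_T2 = runif(1, 60, 80))
    L0 <- runif(1, gp$L_T1, 0.95 * asymptotic_size(gp))
    d1 <- runif(1, 0, 5); d2 <- runif(1, 0, 5)
    # semigroup: stepping d1 then d2 equals one step of d1 + d2
    expect_equal(predict_size(predict_size(L0, d1, gp), d2, gp),
                 predict_size(L0, d1 + d2, gp), tolerance = 1e-9)
    # age/size round trip, within the domain where the size is
    # distinguishable from the asymptote in double precision (K a < ~16)
    a <- runif(1, 0, min(30, 16 / gp$K))
    expect_equal(age_at_size(size_at_age(a, gp), gp), a, tolerance = 1e-8)
    # monotone increasing in age, bounded by the asymptote
    ages <- seq(0, min(40, 16 / gp$K), length.out = 60)
    sz <- size_at_age(ages, gp)
    expect_true(all(diff(sz) > 0))
    expect_true(all(sz < asymptotic_size(gp)))
  }
  # asymptotic size is monotone decreasing in K
  ks <- seq(0.2, 1.5, by = 0.1)
  linfs <- vapply(ks, function(k)
    asymptotic_size(growth_params(K = k, L_T1 = 33, L_T2 = 70)), numeric(1))
  expect_true(all(diff(linfs) < 0))
})

test_that("age at maturity uses the sex-specific threshold", {
  thr <- maturity_thresholds()   # 50 mm female, 59 mm male
  gpf <- growth_params(K = 0.41, L_T1 = 33, L_T2 = 65)
  expect_equal(age_at_maturity(gpf, thr, "female"), 1.84, tolerance = 1e-2)
  expect_equal(age_at_maturity(gpf, thr, "female"),
               age_at_size(50, gpf), tolerance = 1e-12)
  # threshold at the anchor size is reached at age T1 = 0
  expect_equal(age_at_maturity(gpf, maturity_thresholds(female_svl = 33 + 1e-9),
                               "female"), 0, tolerance = 1e-6)
  expect_error(age_at_maturity(growth_params(K = 0.4, L_T1 = 33, L_T2 = 55),
                               maturity_thresholds(male_svl = 80), "male"),
               "never reached")
})

test_that("domain violations are rejected", {
  gp <- growth_params(K = 0.5, L_T1 = 33, L_T2 = 70)
  expect_error(growth_params(K = -1, L_T1 = 33, L_T2 = 70), "K must be")
  expect_error(growth_params(K = 0.5, L_T1 = 70, L_T2 = 33), "L_T2 > L_T1")
  expect_error(predict_size(50, -1, gp), "D must be")
  expect_error(predict_size(90, 1, gp), "asymptotic")
  expect_error(age_at_size(75, gp), "asymptote")
  expect_error(size_at_age(-0.5, gp), ">= T1")
})

test_that("size observation model is unbiased Normal noise", {
  # zero error observes the truth exactly
  expect_equal(observe_size(60, 0), 60)
  set.seed(123)
  draws <- observe_size(60, sigma_L = 1, n = 1e5)
  expect_equal(mean(draws), 60, tolerance = 0.01)
  expect_equal(sd(draws), 1, tolerance = 0.01)
  # noisy remeasurement of a slow grower can show apparent shrinkage
  gp <- growth_params(K = 0.4, L_T1 = 33, L_T2 = 70)
  set.seed(5)
  l1 <- observe_size(68, 1.5, n = 2000)
  l2 <- observe_size(predict_size(68, 1, gp), 1.5, n = 2000)
  expect_true(mean(l2 - l1 < 0) > 0.05)
})
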