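test_that("split Fourier basis is multivariate-orthonormal under quadrature", {
  grid <- seq(0, 15, by = 0.25)
  b <- split_fourier_basis(6, 3, grid)
  expect_equal(dim(b$psi), c(61, 6, 3))
  w <- dynFPCA:::trapezoid_weights(grid)
  G <- matrix(0, 6, 6)
  for (q in 1:3) G <- G + t(b$psi[, , q]) %*% (w * b$psi[, , q])
  expect_lt(max(abs(G - diag(6))), 1e-2)

  # single-component, single-variable case is the constant function
  b1 <- split_fourier_basis(1, 1, grid)
  expect_equal(unique(round(b1$psi[, 1, 1], 12)), 1 / sqrt(15))
  expect_equal(sum(w * b1$psi[, 1, 1]^2), 1, tolerance = 1e-12)
})

test_that("sampled scores match the target variances and are independent", {
  vars <- c(1, 5/6, 2/3, 1/2, 1/3, 1/6)
  withr::with_seed(1, {
    s <- sample_scores(1e5, vars)
  })
  expect_equal(unname(apply(s, 2, var)), vars, tolerance = 0.02)
  cors <- cor(s)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.02)
  expect_error(sample_scores(10, c(1, 0)), "positive")
  expect_error(sample_scores(10, c(1, -1)), "positive")
})

test_that("true mean functions evaluate to their closed forms", {
  # time scale: quadratic vertex at t = 9, log(1) = 0 at t = 0
  expect_equal(evaluate_mean("time_on_study", 9)[, 1], 20)
  expect_equal(evaluate_mean("time_on_study", 0)[, 2], 0)
  expect_equal(evaluate_mean("time_on_study", 10)[, 3], 6)
  # age scale: quadratic attains its maximum 20 at age-at-observation 73
  expect_equal(evaluate_mean("age_at_observation", 3, 70)[, 1], 20)
  u <- seq(41, 99, by = 0.5)
  expect_true(all(evaluate_mean("age_at_observation", 0, u)[, 1] <= 20))
  expect_error(evaluate_mean("age_at_observation", 0, 40), "40")
  expect_error(evaluate_mean("age_at_observation", 5), "age")
})

test_that("longitudinal simulation adds exactly the configured noise", {
  grid <- seq(0, 15, by = 0.25)
  basis <- split_fourier_basis(6, 3, grid)
  cfg0 <- sim_config(n_subjects = 50, noise_sd = 0, seed = 1)
  withr::with_seed(4, {
    scores <- sample_scores(50, cfg0$score_variances)
    ages <- runif(50, 40, 90)
    # zero noise: observations equal the underlying process exactly
    lng <- simulate_longitudinal(cfg0, scores, basis, ages)
    y1 <- lng$long$value[lng$long$variable == "var1"]
    expect_equal(matrix(y1, 50), lng$X[[1]], ignore_attr = TRUE)
    # zero scores and zero noise: trajectories equal the mean function
    lng0 <- simulate_longitudinal(cfg0, scores * 0, basis, ages)
    mu1 <- evaluate_mean("time_on_study", grid)[, 1]
    expect_equal(lng0$X[[1]][7, ], mu1, ignore_attr = TRUE)
    expect_equal(matrix(lng0$long$value[lng0$long$variable == "var1"], 50)[3, ],
                 mu1, ignore_attr = TRUE)
  })
  # measurement-error variance close to its nominal 0.1^2
  cfg <- sim_config(n_subjects = 1600, noise_sd = 0.1, seed = 1)
  withr::with_seed(5, {
    scores <- sample_scores(1600, cfg$score_variances)
    ages <- runif(1600, 40, 90)
    lng <- simulate_longitudinal(cfg, scores, basis, ages)
    eps <- matrix(lng$long$value[lng$long$variable == "var2"], 1600) -
      lng$X[[2]]
    expect_equal(var(as.vector(eps)), 0.01, tolerance = 0.05)
  })
})

test_that("with zero hazard loadings event times are Weibull(3, 8.4)", {
  grid <- seq(0, 15, by = 0.25)
  basis <- split_fourier_basis(6, 3, grid)
  withr::with_seed(6, {
    scores <- sample_scores(2e4, c(1, 5/6, 2/3, 1/2, 1/3, 1/6))
    tt <- simulate_survival(scores, basis, alpha = c(0, 0, 0),
                            shape = 3, scale = 8.4, keep_cumhaz = FALSE)
  })
  expect_equal(mean(tt$times), 8.4 * gamma(1 + 1/3), tolerance = 0.01)
})

test_that("with a constant hazard event times are exponential", {
  # Weibull with shape 1 and scale 1/c is the Exponential(rate c) hazard
  grid <- seq(0, 15, by = 0.25)
  basis <- split_fourier_basis(2, 1, grid)
  withr::with_seed(7, {
    scores <- sample_scores(1e4, c(1, 0.5))
    tt <- simulate_survival(scores, basis, alpha = 0, shape = 1,
                            scale = 1 / 0.3, cap = 100, keep_cumhaz = FALSE)
    ks <- suppressWarnings(ks.test(tt$times, pexp, rate = 0.3))
  })
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the numerical inversion solves exp(-Lambda(T)) = U", {
  grid <- seq(0, 15, by = 0.25)
  basis <- split_fourier_basis(6, 3, grid)
  withr::with_seed(8, {
    scores <- sample_scores(5, c(1, 5/6, 2/3, 1/2, 1/3, 1/6))
    u_draws <- local({set.seed(9); runif(5)})
    set.seed(9)
    tt <- simulate_survival(scores, basis, alpha = c(1, -1, 2),
                            shape = 3, scale = 8.4)
    set.seed(9)
    fine <- simulate_survival(scores, basis, alpha = c(1, -1, 2),
                              shape = 3, scale = 8.4, step = 0.001)
  })
  # agreement with a 10x refined quadrature oracle
  expect_equal(tt$times, fine$times, tolerance = 1e-4)
  # residual of the inversion on its own interpolant is numerically zero
  for (i in 1:5) {
    lam <- approx(tt$tfine, tt$cumhaz[i, ], xout = tt$times[i])$y
    expect_equal(exp(-lam), u_draws[i], tolerance = 1e-10)
  }
})

test_that("censoring-rate calibration hits the target fraction", {
  withr::with_seed(10, {
    tt <- simulate_survival(
      sample_scores(1e4, c(1, 5/6, 2/3, 1/2, 1/3, 1/6)),
      split_fourier_basis(6, 3, seq(0, 15, by = 0.25)),
      alpha = c(1, -1, 2), shape = 3, scale = 8.4,
      keep_cumhaz = FALSE)$times
    r40 <- calibrate_censoring(0.40, tt)
    r20 <- calibrate_censoring(0.20, tt)
    # achieved fraction on an independent replicate of T and C draws
    t2 <- simulate_survival(
      sample_scores(1e4, c(1, 5/6, 2/3, 1/2, 1/3, 1/6)),
      split_fourier_basis(6, 3, seq(0, 15, by = 0.25)),
      alpha = c(1, -1, 2), shape = 3, scale = 8.4,
      keep_cumhaz = FALSE)$times
    cens <- rexp(1e4, rate = r40)
    frac <- mean(t2 > pmin(cens, 15))
  })
  expect_equal(frac, 0.40, tolerance = 0.02)
  expect_gt(r40, r20)  # more censoring needs a larger rate
  expect_error(calibrate_censoring(1.2, tt), "between 0 and 1")
  expect_error(calibrate_censoring(0.4, rep(1e9, 10)), "horizon")
})

test_that("simulated scenarios are deterministic and internally consistent", {
  cfg <- scenario_config(2, n_subjects = 200, seed = 77)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$dataset$long, s2$dataset$long)
  expect_identical(s1$dataset$baseline, s2$dataset$baseline)
  # observed time = min(T, C, horizon); delta = 1 iff T attains it
  expect_equal(s1$dataset$baseline$time,
               pmin(s1$uncensored_times, s1$censor_times, 15))
  expect_identical(s1$dataset$baseline$event,
                   as.integer(s1$uncensored_times <=
                                pmin(s1$censor_times, 15)))
  # truth oracle: nonincreasing survival curves starting at 1
  pr <- true_survival(s1, times = c(3, 5, 8, 12), t_LM = 3)
  expect_true(all(abs(pr[, 1] - 1) < 1e-12))
  expect_true(all(diff(t(pr)) <= 1e-12))
  # cumulative hazards are nonnegative, nondecreasing, 0 at t = 0
  expect_true(all(s1$cumhaz[, 1] == 0))
  expect_true(all(s1$cumhaz >= 0))
  expect_true(all(apply(s1$cumhaz, 1, function(x) all(diff(x) >= 0))))
})

test_that("scenario 2 attains its calibrated censored fraction", {
  st <- simulate_scenario(scenario_config(2, n_subjects = 1600, seed = 31))
  expect_equal(1 - mean(st$dataset$baseline$event), 0.40, tolerance = 0.03)
})

test_that("visit thinning keeps the baseline visit", {
  st <- simulate_scenario(sim_config(n_subjects = 30, seed = 3),
                          retain_prob = 0.5)
  per_subj <- table(st$dataset$long$id[st$dataset$long$variable == "var1"])
  expect_true(all(per_subj < 61))
  first <- tapply(st$dataset$long$time, st$dataset$long$id, min)
  expect_true(all(first == 0))
})
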