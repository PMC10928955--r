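test_that("mean smoother reproduces constant data and recovers a known mean", {
  # constant data
  grid <- seq(0, 15, by = 0.25)
  long <- expand.grid(id = sprintf("s%02d", 1:20), time = grid,
                      stringsAsFactors = FALSE)
  long$variable <- "v"; long$value <- 7
  baseline <- data.frame(id = sprintf("s%02d", 1:20), age = 50,
                         time = 16, event = 1)
  d <- longitudinal_dataset(long, baseline, grid)
  mu <- estimate_mean(d, "v", "study")
  expect_equal(mu$values, rep(7, length(grid)), tolerance = 1e-6)

  # dense noiseless simulated data: RMSE of the fitted mean under 0.05
  st <- simulate_scenario(sim_config(n_subjects = 200, noise_sd = 0,
                                     censoring = "none", seed = 55))
  mu1 <- estimate_mean(st$dataset, "var1", "study")
  truth <- evaluate_mean("time_on_study", grid)[, 1]
  expect_lt(sqrt(mean((mean_value(mu1, grid) - truth)^2)), 0.05)
})

test_that("age-scale mean pools translated observations", {
  st <- age_study()
  mu <- estimate_mean(st$dataset, "var1", "age")
  # the pooled support is ages at observation: baseline age + visit time
  ages <- st$dataset$baseline$age
  expect_gte(min(mu$eval_grid), min(ages))
  expect_lte(max(mu$eval_grid) - max(ages + 15), 1e-9)
  # a subject aged 60 seen at t = 2 is evaluated at age 62
  v60 <- mean_value(mu, 2, 60)
  v62 <- mean_value(mu, 0, 62)
  expect_equal(v60, v62)
  # recovery of the true age-scale mean away from the boundary
  ug <- seq(55, 90, by = 1)
  truth <- evaluate_mean("age_at_observation", 0, ug)[, 1]
  expect_lt(sqrt(mean((mean_value(mu, 0, ug) - truth)^2)), 0.3)
})

test_that("mean estimation fails informatively on insufficient support", {
  d <- toy_dataset()
  expect_error(estimate_mean(d, "v", "study"), "v")
})

test_that("covariance smoothing recovers the error variance and a known surface", {
  st <- noisy_study()  # noise sd 0.1 -> sigma^2 = 0.01
  mu <- estimate_mean(st$dataset, "var1", "study")
  cv <- estimate_covariance(st$dataset, "var1", mu)
  expect_lt(abs(cv$sigma2 - 0.01), 0.005)  # within 50% of the truth
  expect_lt(max(abs(cv$surface - t(cv$surface))), 1e-10)

  # rank-one truth: a single constant eigenfunction with variance 2
  grid <- seq(0, 15, by = 0.25)
  b1 <- split_fourier_basis(1, 1, grid)
  cfg <- sim_config(n_subjects = 400, Q = 1, M_true = 1,
                    score_variances = 2, noise_sd = 0, alpha = 0,
                    censoring = "none", seed = 66)
  st1 <- simulate_scenario(cfg)
  mu1 <- estimate_mean(st1$dataset, "var1", "study")
  cv1 <- estimate_covariance(st1$dataset, "var1", mu1)
  truth <- 2 * tcrossprod(b1$psi[, 1, 1])
  expect_lt(max(abs(cv1$surface - truth)), 1e-2)
})

test_that("raw diagonal exceeds the off-diagonal surface by about sigma^2", {
  st <- noisy_study()
  mu <- estimate_mean(st$dataset, "var2", "study")
  cv <- estimate_covariance(st$dataset, "var2", mu)
  rng <- range(cv$grid)
  interior <- cv$grid >= rng[1] + 0.25 * diff(rng) &
    cv$grid <= rng[1] + 0.75 * diff(rng)
  excess <- mean(cv$diag_smooth[interior] - diag(cv$surface)[interior])
  expect_equal(excess, 0.01, tolerance = 0.5)
})

test_that("eigendecomposition is orthonormal, sorted and PVE-truncated", {
  grid <- seq(0, 15, by = 0.25)
  b <- split_fourier_basis(6, 1, grid)
  phi <- b$psi[, , 1]
  lams <- c(1, 5/6, 2/3, 1/2, 1/3, 1/6)
  surface <- phi %*% diag(lams) %*% t(phi)
  cov <- structure(list(grid = grid, surface = surface, sigma2 = 0),
                   class = "covariance_model")
  # the variance spectrum of the study design truncates at M = 5 for 95%
  u <- eigendecompose(cov, pve_target = 0.95)
  expect_equal(u$M_q, 5L)
  expect_equal(u$eigenvalues, lams[1:5], tolerance = 1e-8)
  w <- dynFPCA:::trapezoid_weights(grid)
  G <- t(u$eigenfunctions) %*% (w * u$eigenfunctions)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  expect_true(all(diff(u$eigenvalues) <= 0))
  # sign convention: largest-magnitude entry positive
  for (m in 1:5)
    expect_gt(u$eigenfunctions[which.max(abs(u$eigenfunctions[, m])), m], 0)
  # pve_target = 1 keeps every positive eigenvalue
  expect_equal(eigendecompose(cov, pve_target = 1)$M_q,
               sum(eigen(surface)$values > 1e-10))
  # rank-one identity
  r1 <- 2 * tcrossprod(phi[, 2])
  cov1 <- structure(list(grid = grid, surface = r1, sigma2 = 0),
                    class = "covariance_model")
  u1 <- eigendecompose(cov1, 0.95)
  expect_equal(u1$M_q, 1L)
  expect_equal(u1$eigenvalues, 2, tolerance = 1e-6)
  expect_lt(min(max(abs(u1$eigenfunctions - phi[, 2])),
                max(abs(u1$eigenfunctions + phi[, 2]))), 1e-6)
})

test_that("PACE scores match quadrature integrals on dense noiseless data", {
  st <- dense_study()
  u <- fit_ufpca(st$dataset, "var1", "study", pve_target = 0.95)
  sc <- pace_scores(st$dataset, "var1", u)
  w <- dynFPCA:::trapezoid_weights(u$grid)
  Y <- dynFPCA:::obs_matrix(st$dataset, "var1")
  mu <- mean_value(u$mean, u$grid)
  resid <- sweep(Y, 2, mu)
  quad <- resid %*% (w * u$eigenfunctions)
  expect_lt(max(abs(sc - quad)), 1e-3)
  # conditional-expectation shrinkage: score variance at most lambda
  stn <- noisy_study()
  un <- fit_ufpca(stn$dataset, "var1", "study", pve_target = 0.95)
  scn <- pace_scores(stn$dataset, "var1", un)
  expect_true(all(apply(scn, 2, var) <= un$eigenvalues * 1.001))
})

test_that("a subject lying on the mean gets exactly zero scores", {
  st <- dense_study()
  u <- fit_ufpca(st$dataset, "var1", "study", pve_target = 0.95)
  d <- st$dataset
  keep <- d$baseline$id[1]
  d1 <- subset_subjects(d, keep)
  d1$long$value <- mean_value(u$mean, d1$long$time)
  sc <- pace_scores(d1, "var1", u)
  expect_equal(unname(sc[1, ]), rep(0, u$M_q), tolerance = 1e-10)
})

test_that("degenerate PACE keeps the leading components and zeroes the rest", {
  st <- dense_study()
  u <- fit_ufpca(st$dataset, "var1", "study", pve_target = 0.95)
  u$sigma2 <- 0  # force the singular branch
  expect_gt(u$M_q, 1)
  d <- st$dataset
  d1 <- subset_subjects(d, d$baseline$id[1])
  # a single observation before the landmark: one solvable component
  d1$long <- d1$long[d1$long$variable == "var1" & d1$long$time == 0, ,
                     drop = FALSE]
  sc <- pace_scores(d1, "var1", u)
  expect_true(all(sc[1, 2:u$M_q] == 0))
  expect_true(is.finite(sc[1, 1]))
  # a subject with no observations: all-zero with a warning
  d0 <- d1; d0$long <- d0$long[0, , drop = FALSE]
  expect_warning(sc0 <- pace_scores(d0, "var1", u), "without observations")
  expect_equal(unname(sc0[1, ]), rep(0, u$M_q))
})

test_that("PACE recovers true univariate scores on dense low-noise data", {
  st <- dense_study()
  u <- fit_ufpca(st$dataset, "var1", "study", pve_target = 0.95)
  sc <- pace_scores(st$dataset, "var1", u)
  # true univariate scores are quadrature projections of the centred truth
  w <- dynFPCA:::trapezoid_weights(u$grid)
  eta <- st$true_scores %*% t(st$basis$psi[, , 1])
  true_sc <- eta %*% (w * u$eigenfunctions)
  for (m in seq_len(u$M_q))
    if (u$eigenvalues[m] >= 1/3)
      expect_gt(abs(cor(sc[, m], true_sc[, m])), 0.9)
})
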