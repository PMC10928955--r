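#' Simulation configuration
#'
#' Defines one simulated study: n subjects followed quarter-yearly over 15
#' years, Q = 3 longitudinal variables built from M = 6 multivariate
#' eigenfunctions with Gaussian scores of decreasing variance, a Weibull
#' baseline hazard whose log-relative risk is driven by the current value
#' of the (centred) longitudinal trajectories, and exponential plus
#' administrative censoring.
#'
#' @param n_subjects number of subjects.
#' @param grid planned visit times in years (default quarter-yearly on
#'   \[0, 15\]).
#' @param Q number of longitudinal variables.
#' @param M_true number of true eigenfunctions.
#' @param score_variances true score variances nu_m, positive and
#'   nonincreasing, length `M_true`.
#' @param noise_sd standard deviation of the iid Gaussian measurement error.
#' @param mean_mechanism `"time_on_study"` or `"age_at_observation"` —
#'   whether the mean functions act on study time or on age at observation.
#' @param age_range interval from which baseline ages are drawn uniformly.
#' @param alpha hazard loadings on the Q current trajectory values.
#' @param weibull_shape,weibull_scale Weibull baseline hazard parameters
#'   (years for the scale).
#' @param censoring `"none"`, `"light"` (~20% censored), `"median"` (~40%)
#'   or `"heavy"` (~60%), or an explicit nonnegative exponential rate.
#' @param admin_horizon administrative censoring time (end of study).
#' @param seed integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1600L,
                       grid = seq(0, 15, by = 0.25),
                       Q = 3L,
                       M_true = 6L,
                       score_variances = c(1, 5/6, 2/3, 1/2, 1/3, 1/6),
                       noise_sd = 0.1,
                       mean_mechanism = c("time_on_study", "age_at_observation"),
                       age_range = c(40, 90),
                       alpha = c(1, -1, 2),
                       weibull_shape = 3,
                       weibull_scale = 8.4,
                       censoring = "median",
                       admin_horizon = 15,
                       seed = 1L) {
  mean_mechanism <- match.arg(mean_mechanism)
  stopifnot(n_subjects >= 1L, Q >= 1L, M_true >= 1L,
            length(score_variances) == M_true,
            length(alpha) == Q,
            weibull_shape > 0, weibull_scale > 0, noise_sd >= 0,
            admin_horizon > 0)
  if (is.unsorted(grid, strictly = TRUE) || grid[1L] != 0)
    stop("grid must be strictly increasing and start at 0")
  if (any(score_variances <= 0))
    stop("score variances must be strictly positive")
  if (any(diff(score_variances) > 0))
    stop("score variances must be nonincreasing")
  if (is.character(censoring)) {
    censoring <- match.arg(censoring, c("none", "light", "median", "heavy"))
  } else {
    stopifnot(is.numeric(censoring), censoring >= 0)
  }
  structure(list(n_subjects = as.integer(n_subjects), grid = grid,
                 Q = as.integer(Q), M_true = as.integer(M_true),
                 score_variances = score_variances, noise_sd = noise_sd,
                 mean_mechanism = mean_mechanism, age_range = age_range,
                 alpha = alpha, weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale, censoring = censoring,
                 admin_horizon = admin_horizon, seed = as.integer(seed)),
            class = "sim_config")
}

#' Configuration for one of the six study scenarios
#'
#' Scenarios 1-3 use time-on-study mean functions with light / median /
#' heavy censoring; scenarios 4-6 are the same censoring ladder with
#' age-at-observation mean functions.
#'
#' @param scenario integer 1-6.
#' @param n_subjects,seed passed to [sim_config].
#' @param ... further overrides passed to [sim_config].
#' @return A `sim_config`.
#' @export
scenario_config <- function(scenario, n_subjects = 1600L, seed = 1L, ...) {
  stopifnot(scenario %in% 1:6)
  mech <- if (scenario <= 3) "time_on_study" else "age_at_observation"
  cens <- c("light", "median", "heavy")[(scenario - 1L) %% 3L + 1L]
  sim_config(n_subjects = n_subjects, mean_mechanism = mech,
             censoring = cens, seed = seed, ...)
}

#' Multivariate eigenfunctions by splitting an orthonormal Fourier basis
#'
#' The first `M` orthonormal Fourier functions on the concatenated interval
#' \[0, Q * span(grid)\] are cut into `Q` consecutive pieces; piece q of
#' function m becomes the q-th variable block of multivariate eigenfunction
#' m.  The resulting vector-valued functions are orthonormal in the
#' multivariate inner product sum_q \int psi_m^(q) psi_m'^(q) dt.
#'
#' @param M number of eigenfunctions (the constant function is the first
#'   Fourier element).
#' @param Q number of variable blocks.
#' @param grid visit times on which the blocks are tabulated.
#' @return An object of class `true_basis`: list with `grid`, `M`, `Q`,
#'   `psi` (array grid x M x Q) and `fun(t)` evaluating the blocks at
#'   arbitrary times (an array length(t) x M x Q).
#' @export
split_fourier_basis <- function(M, Q, grid) {
  stopifnot(M >= 1L, Q >= 1L, length(grid) >= 2L)
  span <- max(grid) - min(grid)
  L <- Q * span
  fourier_eval <- function(x) {
    # orthonormal Fourier system on [0, L]: 1/sqrt(L), then
    # sqrt(2/L) sin(2 pi r x / L), sqrt(2/L) cos(2 pi r x / L), r = 1, 2, ...
    vapply(seq_len(M), function(m) {
      if (m == 1L) return(rep(1 / sqrt(L), length(x)))
      r <- m %/% 2L
      if (m %% 2L == 0L) sqrt(2 / L) * sin(2 * pi * r * x / L)
      else               sqrt(2 / L) * cos(2 * pi * r * x / L)
    }, numeric(length(x)))
  }
  fun <- function(t) {
    out <- array(NA_real_, dim = c(length(t), M, Q))
    for (q in seq_len(Q))
      out[, , q] <- fourier_eval((q - 1L) * span + (t - min(grid)))
    out
  }
  structure(list(grid = grid, M = as.integer(M), Q = as.integer(Q),
                 psi = fun(grid), fun = fun),
            class = "true_basis")
}

#' Draw independent Gaussian scores with prescribed variances
#'
#' @param n number of subjects (rows).
#' @param variances positive score variances (columns).
#' @return n x length(variances) matrix of independent mean-zero normals.
#' @export
sample_scores <- function(n, variances) {
  if (any(variances <= 0)) stop("score variances must be strictly positive")
  matrix(stats::rnorm(n * length(variances),
                      sd = rep(sqrt(variances), each = n)),
         nrow = n)
}

#' True mean functions of the simulated longitudinal variables
#'
#' Time-on-study scale: mu(t) = (20 - (t/3 - 3)^2, log(t + 1),
#' exp(-(t - 10)/5) + 5).  Age-at-observation scale, with u = age + t:
#' mu(u) = (20 - ((u - 73)/5)^2, log((u - 40)/6) - 10,
#' exp(-(u - 40)/20) + 5); the log term requires u > 40.
#'
#' @param mechanism `"time_on_study"` or `"age_at_observation"`.
#' @param t vector of study times (years).
#' @param age baseline age (scalar or vector recycled against `t`);
#'   required for the age mechanism.
#' @return matrix length(t) x 3 of mean values.
#' @export
evaluate_mean <- function(mechanism = c("time_on_study", "age_at_observation"),
                          t, age = NULL) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "time_on_study") {
    cbind(20 - (t / 3 - 3)^2,
          log(t + 1),
          exp(-(t - 10) / 5) + 5)
  } else {
    if (is.null(age)) stop("age is required for the age_at_observation mean")
    u <- age + t
    if (any(u <= 40))
      stop("age + t must exceed 40 (log domain of the age-scale mean)")
    cbind(20 - ((u - 73) / 5)^2,
          log((u - 40) / 6) - 10,
          exp(-(u - 40) / 20) + 5)
  }
}

#' Simulate noisy longitudinal observations from scores and basis
#'
#' The underlying process is X_i^(q)(t) = mu^(q) + sum_m rho_im
#' psi_m^(q)(t) with the mean evaluated per the configured mechanism; the
#' observation adds iid Gaussian error.  All planned visits are observed
#' (the simulation is dense); the optional `retain_prob` thins visits at
#' random, always keeping the baseline visit.
#'
#' @param config a [sim_config].
#' @param scores n x M_true matrix of true scores.
#' @param basis a [split_fourier_basis] result.
#' @param ages baseline ages, length n.
#' @param retain_prob per-visit Bernoulli retention probability (1 = dense).
#' @return list with `long` (tidy data.frame id/variable/time/value),
#'   `X` (list of Q noiseless matrices n x grid) and `ids`.
#' @export
simulate_longitudinal <- function(config, scores, basis, ages,
                                  retain_prob = 1) {
  n <- nrow(scores)
  stopifnot(ncol(scores) == basis$M, length(ages) == n,
            config$Q == basis$Q)
  grid <- config$grid
  ids <- sprintf("S%04d", seq_len(n))
  X <- vector("list", config$Q)
  long <- vector("list", config$Q)
  keep <- matrix(TRUE, n, length(grid))
  if (retain_prob < 1) {
    keep <- matrix(stats::runif(n * length(grid)) <= retain_prob,
                   n, length(grid))
    keep[, 1L] <- TRUE  # baseline visit always observed
  }
  for (q in seq_len(config$Q)) {
    eta <- scores %*% t(basis$psi[, , q])   # n x grid, centred process
    mu <- if (config$mean_mechanism == "time_on_study") {
      matrix(evaluate_mean("time_on_study", grid)[, q],
             n, length(grid), byrow = TRUE)
    } else {
      t(vapply(ages, function(a)
        evaluate_mean("age_at_observation", grid, a)[, q],
        numeric(length(grid))))
    }
    X[[q]] <- mu + eta
    Y <- X[[q]] + if (config$noise_sd > 0)
      matrix(stats::rnorm(n * length(grid), sd = config$noise_sd),
             n, length(grid)) else 0
    idx <- which(keep, arr.ind = TRUE)
    long[[q]] <- data.frame(
      id = ids[idx[, 1L]],
      variable = paste0("var", q),
      time = grid[idx[, 2L]],
      value = Y[idx])
  }
  list(long = do.call(rbind, long), X = X, ids = ids)
}

# Weibull baseline hazard h0(t) = (shape/scale) (t/scale)^(shape-1)
weibull_hazard <- function(t, shape, scale) {
  (shape / scale) * (t / scale)^(shape - 1)
}

#' Simulate uncensored event times from the trajectory-driven hazard
#'
#' Each subject's hazard is h_i(t) = h0(t) exp(sum_q alpha_q eta_i^(q)(t))
#' with eta_i^(q)(t) = sum_m rho_im psi_m^(q)(t) the centred trajectory
#' value and h0 a Weibull hazard.  The cumulative hazard is accumulated by
#' trapezoidal quadrature on a fine sub-grid; the event time solves
#' exp(-Lambda_i(T)) = U_i exactly on the piecewise-linear interpolant of
#' Lambda_i.  Beyond the last basis time the trajectories are held at
#' their final value; times whose target cumulative hazard is not reached
#' by `cap` are returned as `cap` (they are administratively censored
#' downstream).
#'
#' @param scores n x M matrix of true scores.
#' @param basis a [split_fourier_basis] result.
#' @param alpha hazard loadings, length Q.
#' @param shape,scale Weibull baseline parameters.
#' @param cap upper bound for the numerical inversion (years).
#' @param step quadrature step of the fine sub-grid (years).
#' @param keep_cumhaz store the full n x |tfine| cumulative-hazard matrix
#'   (the truth oracle); disable for very large n when only the event
#'   times are needed.
#' @return list with `times` (uncensored event times), `tfine` (the fine
#'   grid) and `cumhaz` (n x length(tfine) matrix of Lambda_i, or `NULL`).
#' @export
simulate_survival <- function(scores, basis, alpha, shape, scale,
                              cap = 30, step = 0.01, keep_cumhaz = TRUE) {
  stopifnot(length(alpha) == basis$Q)
  n <- nrow(scores)
  tfine <- seq(0, cap, by = step)
  tclamp <- pmin(tfine, max(basis$grid))
  psi_fine <- basis$fun(tclamp)            # |tfine| x M x Q
  h0 <- weibull_hazard(tfine, shape, scale)
  u <- stats::runif(n)
  times <- numeric(n)
  cumhaz <- if (keep_cumhaz) matrix(NA_real_, n, length(tfine)) else NULL
  # subject blocks keep the n x |tfine| hazard workspace bounded
  blocks <- split(seq_len(n), ceiling(seq_len(n) / 2000L))
  for (idx in blocks) {
    lp <- matrix(0, length(idx), length(tfine))
    for (q in seq_len(basis$Q))
      lp <- lp + alpha[q] *
        (scores[idx, , drop = FALSE] %*% t(psi_fine[, , q]))
    haz <- exp(lp) * matrix(h0, length(idx), length(tfine), byrow = TRUE)
    if (any(!is.finite(haz)))
      stop("non-finite hazard for subject(s) ",
           paste(utils::head(idx[rowSums(!is.finite(haz)) > 0], 5L),
                 collapse = ", "))
    # trapezoid cumulative hazard along the fine grid
    inc <- (haz[, -1L, drop = FALSE] + haz[, -ncol(haz), drop = FALSE]) *
      step / 2
    ch <- cbind(0, t(apply(inc, 1L, cumsum)))
    if (keep_cumhaz) cumhaz[idx, ] <- ch
    times[idx] <- invert_cumhaz(ch, tfine, -log(u[idx]))
  }
  list(times = times, tfine = tfine, cumhaz = cumhaz)
}

# invert piecewise-linear Lambda_i at target values (vectorised over rows);
# rows whose Lambda never reaches the target return max(tfine)
invert_cumhaz <- function(cumhaz, tfine, target) {
  n <- nrow(cumhaz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ch <- cumhaz[i, ]
    if (target[i] >= ch[length(ch)]) { out[i] <- tfine[length(tfine)]; next }
    j <- findInterval(target[i], ch)  # ch[j] <= target < ch[j+1]
    dl <- ch[j + 1L] - ch[j]
    frac <- if (dl > 0) (target[i] - ch[j]) / dl else 0
    out[i] <- tfine[j] + frac * (tfine[j + 1L] - tfine[j])
  }
  out
}

#' Calibrate the exponential censoring rate to a target censored fraction
#'
#' Given a sample of uncensored event times, finds the exponential rate r
#' such that the expected fraction of censored observations — where a
#' subject is censored when C_i < T_i or T_i exceeds the administrative
#' horizon — matches `target_fraction`.  Conditional on T the censoring
#' probability is 1 - e^(-rT) for T <= horizon and 1 otherwise, so the
#' expected fraction is computed analytically over the sample and the rate
#' found by bisection.
#'
#' @param target_fraction desired censored proportion, in (0, 1).
#' @param times sample of uncensored event times T_i.
#' @param admin_horizon administrative censoring time.
#' @param tol tolerance on the achieved fraction.
#' @return the calibrated exponential rate (0 if administrative censoring
#'   alone exceeds the target).
#' @export
calibrate_censoring <- function(target_fraction, times, admin_horizon = 15,
                                tol = 1e-4) {
  if (target_fraction <= 0 || target_fraction >= 1)
    stop("target censored fraction must lie strictly between 0 and 1")
  frac <- function(r)
    mean(ifelse(times <= admin_horizon, 1 - exp(-r * times), 1))
  if (all(times > admin_horizon))
    stop("all event times exceed the horizon; any rate censors everything")
  if (frac(0) >= target_fraction) return(0)
  lo <- 0; hi <- 1
  while (frac(hi) < target_fraction) {
    hi <- hi * 2
    if (hi > 1e6) stop("censoring target unattainable by rate calibration")
  }
  while (hi - lo > 1e-10 && abs(frac((lo + hi) / 2) - target_fraction) > tol) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target_fraction) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

censoring_target <- function(censoring) {
  switch(censoring, none = NA_real_, light = 0.20, median = 0.40,
         heavy = 0.60)
}

#' Simulate a complete study with truth oracle
#'
#' Composes the basis construction, score sampling, longitudinal and
#' survival simulation and censoring calibration into one seeded draw,
#' returning the observable dataset together with the simulation truth
#' (scores, basis, per-subject cumulative hazards) needed to compute exact
#' conditional survival probabilities.
#'
#' @param config a [sim_config] (see [scenario_config] for the six named
#'   scenarios).
#' @param retain_prob optional per-visit retention probability (default
#'   dense).
#' @return An object of class `simulated_study`: list with `dataset` (a
#'   [longitudinal_dataset]), `true_scores`, `basis`, `ages`,
#'   `uncensored_times`, `censor_times`, `censor_rate`, `tfine`, `cumhaz`
#'   (n x |tfine| true cumulative hazards, capped at the inversion horizon)
#'   and `config`.
#' @export
simulate_scenario <- function(config, retain_prob = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    n <- config$n_subjects
    basis <- split_fourier_basis(config$M_true, config$Q, config$grid)
    scores <- sample_scores(n, config$score_variances)
    ages <- stats::runif(n, config$age_range[1L], config$age_range[2L])
    lng <- simulate_longitudinal(config, scores, basis, ages, retain_prob)
    surv <- simulate_survival(scores, basis, config$alpha,
                              config$weibull_shape, config$weibull_scale)
    Ttrue <- surv$times
    rate <- if (is.character(config$censoring)) {
      tgt <- censoring_target(config$censoring)
      if (is.na(tgt)) 0 else
        calibrate_censoring(tgt, Ttrue, config$admin_horizon)
    } else config$censoring
    C <- if (rate > 0) stats::rexp(n, rate = rate) else rep(Inf, n)
    tobs <- pmin(Ttrue, C, config$admin_horizon)
    event <- as.integer(Ttrue <= pmin(C, config$admin_horizon))
    baseline <- data.frame(id = lng$ids, age = ages, time = tobs,
                           event = event)
    dataset <- longitudinal_dataset(lng$long, baseline, config$grid,
                                    covariates = character())
    structure(list(dataset = dataset,
                   true_scores = scores, basis = basis, ages = ages,
                   uncensored_times = Ttrue, censor_times = C,
                   censor_rate = rate,
                   paper_lambda = if (is.character(config$censoring))
                     c(none = NA, light = 1.48, median = 2.16,
                       heavy = 2.88)[config$censoring] else NA_real_,
                   tfine = surv$tfine, cumhaz = surv$cumhaz,
                   config = config),
              class = "simulated_study")
  })
}

#' True conditional survival probabilities from the simulation oracle
#'
#' pi_i(t | t_LM) = exp(-(Lambda_i(t) - Lambda_i(t_LM))) with Lambda_i the
#' stored per-subject cumulative hazard (linear interpolation on the fine
#' quadrature grid).
#'
#' @param study a [simulate_scenario] result.
#' @param ids subject ids (default all).
#' @param times evaluation times, `>= t_LM`.
#' @param t_LM conditioning (landmark) time.
#' @return matrix length(ids) x length(times) of true probabilities.
#' @export
true_survival <- function(study, ids = study$dataset$baseline$id,
                          times, t_LM = 0) {
  stopifnot(inherits(study, "simulated_study"), all(times >= t_LM))
  rows <- match(as.character(ids), study$dataset$baseline$id)
  if (anyNA(rows)) stop("subject(s) missing from the truth oracle")
  interp <- function(tt) {
    j <- findInterval(tt, study$tfine, all.inside = TRUE)
    w <- (tt - study$tfine[j]) / (study$tfine[j + 1L] - study$tfine[j])
    study$cumhaz[rows, j, drop = FALSE] * (1 - w) +
      study$cumhaz[rows, j + 1L, drop = FALSE] * w
  }
  lam_lm <- interp(t_LM)[, 1L]
  out <- vapply(seq_along(times), function(k) {
    exp(-(interp(times[k])[, 1L] - lam_lm))
  }, numeric(length(rows)))
  out <- matrix(out, nrow = length(rows),
                dimnames = list(as.character(ids), NULL))
  out
}
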