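# Univariate FPCA: smooth mean (study-time or age scale), smoothed
# covariance surface with measurement-error variance, quadrature
# eigendecomposition with PVE truncation, and PACE scores.

trapezoid_weights <- function(grid) {
  m <- length(grid)
  if (m == 1L) return(1)
  w <- numeric(m)
  w[1L] <- (grid[2L] - grid[1L]) / 2
  w[m] <- (grid[m] - grid[m - 1L]) / 2
  if (m > 2L) w[2:(m - 1L)] <- (grid[3:m] - grid[1:(m - 2L)]) / 2
  w
}

# sign convention: entry of largest magnitude positive
fix_sign <- function(v) {
  j <- which.max(abs(v))
  if (v[j] < 0) -v else v
}

#' Smooth mean function of one longitudinal variable
#'
#' Fits a penalized thin-plate regression spline (GCV-selected smoothing
#' parameter) to the pooled training observations of one variable.  On the
#' study-time scale the abscissae are the visit times; on the age scale
#' ("age-based centring") each observation is translated to the subject's
#' age at observation, baseline age + visit time, and the pooled
#' translated points are smoothed.  Pooled points sharing an abscissa are
#' aggregated to weighted means, which leaves the penalized fit unchanged.
#' The basis dimension shrinks automatically when the pooled support is
#' short (as after strict landmarking).
#'
#' @param data a [longitudinal_dataset].
#' @param variable variable name (member of `data$variables`).
#' @param time_scale `"study"` or `"age"`.
#' @param k basis dimension; default `min(10, n_distinct_abscissae - 1)`.
#' @return An object of class `mean_function`: list with `time_scale`,
#'   `eval_grid`, `values` and `smoother_meta` (k, smoothing parameter,
#'   GCV score).  Evaluate with [mean_value].
#' @export
estimate_mean <- function(data, variable, time_scale = c("study", "age"),
                          k = NULL) {
  time_scale <- match.arg(time_scale)
  rows <- data$long[data$long$variable == variable &
                      !is.na(data$long$value), , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no non-missing observations for variable ", variable)
  x <- if (time_scale == "study") rows$time else
    rows$time + data$baseline$age[match(rows$id, data$baseline$id)]
  y <- rows$value
  if (time_scale == "study") {
    # abscissae lie on the planned grid: aggregate to weighted cell means
    ux <- sort(unique(x))
    f <- match(x, ux)
    w <- tabulate(f, length(ux))
    y <- rowsum(y, f)[, 1L] / w
    x <- ux
  } else {
    w <- rep(1, length(y))
  }
  nd <- length(unique(x))
  if (is.null(k)) k <- min(10L, nd - 1L)
  if (nd < 4L || k < 3L)
    stop("too few distinct pooled abscissae (", nd,
         ") to smooth the mean of variable ", variable)
  fit <- mgcv::gam(y ~ s(x, bs = "tp", k = k), weights = w,
                   data = data.frame(x = x, y = y, w = w), method = "GCV.Cp")
  eval_grid <- if (time_scale == "study") data$grid else
    seq(min(x), max(x), length.out = 512L)
  values <- as.numeric(mgcv::predict.gam(fit,
                                         newdata = data.frame(x = eval_grid)))
  structure(list(time_scale = time_scale, eval_grid = eval_grid,
                 values = values,
                 smoother_meta = list(k = k, sp = unname(fit$sp),
                                      gcv = unname(fit$gcv.ubre))),
            class = "mean_function")
}

#' Evaluate a fitted mean function
#'
#' Linear interpolation on the stored evaluation grid (constant
#' extrapolation at the boundary).  On the age scale the abscissa is
#' `age + t`.
#'
#' @param mean a [estimate_mean] result.
#' @param t study times.
#' @param age baseline age (required for an age-scale mean).
#' @return numeric vector of mean values.
#' @export
mean_value <- function(mean, t, age = NULL) {
  x <- if (mean$time_scale == "study") t else {
    if (is.null(age)) stop("age required to evaluate an age-scale mean")
    age + t
  }
  stats::approx(mean$eval_grid, mean$values, xout = x, rule = 2)$y
}

#' Smoothed covariance surface and measurement-error variance
#'
#' Forms all within-subject cross-products of mean-centred residuals,
#' drops the diagonal (whose expectation is inflated by the
#' measurement-error variance sigma^2), and fits a tensor-product smooth
#' to the off-diagonal products, aggregated per grid cell with counts as
#' weights.  sigma^2 is estimated as the average excess of the smoothed
#' raw diagonal over the surface diagonal on the central 50% of the
#' observed time domain, clamped at zero.  The surface lives on the
#' subset of planned visit times that carry at least one observation (the
#' truncated grid after strict landmarking).
#'
#' @param data a [longitudinal_dataset].
#' @param variable variable name.
#' @param mean a [estimate_mean] result for the same variable (either
#'   time scale; residuals are centred accordingly, but the surface always
#'   lives on study time).
#' @param k_margin marginal basis dimension of the tensor product smooth
#'   (default `min(5, n_grid_used - 1)`).
#' @return An object of class `covariance_model`: list with `grid`
#'   (grid points used), `surface`, `sigma2`, `raw_diag`, `meta`.
#' @export
estimate_covariance <- function(data, variable, mean, k_margin = NULL) {
  Y <- obs_matrix(data, variable)
  ages <- data$baseline$age
  grid <- data$grid
  # centred residuals; 0 where unobserved, with an indicator for counting
  R <- Y
  for (i in seq_len(nrow(Y))) {
    obs <- !is.na(Y[i, ])
    if (!any(obs)) next
    R[i, obs] <- Y[i, obs] - mean_value(mean, grid[obs], ages[i])
  }
  O <- !is.na(R)
  if (!any(rowSums(O) >= 2L))
    stop("no subject with at least two observations of variable ", variable)
  R0 <- R; R0[!O] <- 0
  S <- crossprod(R0)            # sums of products per grid cell
  N <- crossprod(O * 1)         # pair counts per grid cell
  used <- which(colSums(O) > 0L)
  grid_used <- grid[used]
  S <- S[used, used, drop = FALSE]; N <- N[used, used, drop = FALSE]
  G <- S / ifelse(N > 0, N, NA)  # raw cell-mean products
  m <- length(grid_used)
  if (is.null(k_margin)) k_margin <- min(5L, m - 1L)
  if (m < 4L || k_margin < 3L)
    stop("too few observed grid points (", m,
         ") to smooth the covariance of variable ", variable)
  off <- which(N > 0 & row(N) != col(N), arr.ind = TRUE)
  df <- data.frame(g = G[off], s = grid_used[off[, 1L]],
                   t = grid_used[off[, 2L]], w = N[off])
  fit <- mgcv::gam(g ~ te(s, t, k = c(k_margin, k_margin)), weights = w,
                   data = df, method = "GCV.Cp")
  nd <- expand.grid(s = grid_used, t = grid_used)
  surf <- matrix(as.numeric(mgcv::predict.gam(fit, newdata = nd)), m, m)
  surf <- (surf + t(surf)) / 2
  # smoothed raw diagonal vs surface diagonal on the interior 50%
  dj <- which(diag(N) > 0)
  ddf <- data.frame(d = diag(G)[dj], t = grid_used[dj], w = diag(N)[dj])
  kd <- min(10L, length(dj) - 1L)
  sigma2 <- 0
  diag_smooth <- rep(NA_real_, m)
  if (kd >= 3L) {
    dfit <- mgcv::gam(d ~ s(t, bs = "tp", k = kd), weights = w, data = ddf,
                      method = "GCV.Cp")
    diag_smooth <- as.numeric(mgcv::predict.gam(dfit,
                                                newdata = data.frame(t = grid_used)))
    rng <- range(grid_used)
    interior <- grid_used >= rng[1L] + 0.25 * diff(rng) &
      grid_used <= rng[1L] + 0.75 * diff(rng)
    if (any(interior))
      sigma2 <- max(0, mean(diag_smooth[interior] - diag(surf)[interior]))
  }
  structure(list(grid = grid_used, surface = surf, sigma2 = sigma2,
                 diag_smooth = diag_smooth,
                 meta = list(k_margin = k_margin, sp = unname(fit$sp))),
            class = "covariance_model")
}

#' Eigendecomposition of a covariance surface with PVE truncation
#'
#' Solves the weighted eigenproblem on the grid (trapezoidal quadrature
#' weights), yielding eigenfunctions orthonormal under the quadrature
#' inner product.  Eigenvalues <= 0 are discarded before the proportion of
#' variance explained is computed; the smallest M with cumulative
#' eigenvalue ratio >= `pve_target` is retained.  Eigenfunction signs are
#' fixed so the entry of largest magnitude is positive.
#'
#' @param cov a [estimate_covariance] result.
#' @param pve_target required proportion of variance explained, in (0, 1].
#' @param mean optionally, the [estimate_mean] result to embed so the
#'   returned object is self-contained for scoring.
#' @return An object of class `ufpca`: list with `grid`, `mean`,
#'   `eigenvalues` (length M_q), `eigenfunctions` (grid x M_q),
#'   `all_eigenvalues` (full positive spectrum), `M_q`, `pve_target`,
#'   `pve_attained`, `surface`, `sigma2`.
#' @export
eigendecompose <- function(cov, pve_target = 0.95, mean = NULL) {
  stopifnot(pve_target > 0, pve_target <= 1)
  if (max(abs(cov$surface - t(cov$surface))) > 1e-10)
    stop("covariance surface is not symmetric")
  w <- trapezoid_weights(cov$grid)
  sw <- sqrt(w)
  A <- cov$surface * tcrossprod(sw)
  eig <- eigen(A, symmetric = TRUE)
  # strictly positive spectrum, excluding numerical noise
  pos <- eig$values > max(eig$values) * 1e-12
  if (!any(pos)) stop("covariance surface has no positive eigenvalue")
  lam <- eig$values[pos]
  phi <- eig$vectors[, pos, drop = FALSE] / sw
  cum <- cumsum(lam) / sum(lam)
  M_q <- which(cum >= pve_target)[1L]
  phi <- apply(phi[, seq_len(M_q), drop = FALSE], 2L, fix_sign)
  phi <- matrix(phi, nrow = length(cov$grid))
  structure(list(grid = cov$grid, mean = mean,
                 eigenvalues = lam[seq_len(M_q)], eigenfunctions = phi,
                 all_eigenvalues = lam, M_q = M_q,
                 pve_target = pve_target, pve_attained = cum[M_q],
                 surface = cov$surface, sigma2 = cov$sigma2),
            class = "ufpca")
}

#' Fit a univariate FPCA model for one variable
#'
#' Convenience wrapper chaining [estimate_mean], [estimate_covariance] and
#' [eigendecompose].
#'
#' @param data a [longitudinal_dataset].
#' @param variable variable name.
#' @param time_scale `"study"` or `"age"` (age-based centring of the mean).
#' @param pve_target proportion of variance explained for truncation.
#' @param k,k_margin optional basis dimensions for mean and covariance.
#' @return A `ufpca` object (see [eigendecompose]).
#' @export
fit_ufpca <- function(data, variable, time_scale = c("study", "age"),
                      pve_target = 0.95, k = NULL, k_margin = NULL) {
  time_scale <- match.arg(time_scale)
  mu <- estimate_mean(data, variable, time_scale, k = k)
  cv <- estimate_covariance(data, variable, mu, k_margin = k_margin)
  eigendecompose(cv, pve_target = pve_target, mean = mu)
}

#' PACE conditional-expectation scores
#'
#' Best linear prediction of the principal component scores from each
#' subject's available observations:
#' xi_hat_i = Lambda Phi_i' (Sigma_Xi + sigma^2 I)^{-1} (Y_i - mu_i),
#' with all model quantities restricted to the subject's observed visit
#' times.  Subjects sharing an observation pattern share one linear solve.
#' When the restricted system is computationally singular (e.g. sigma^2
#' estimated as 0 with fewer observations than retained components), the
#' maximal solvable number of leading components — the number of available
#' observations — is computed through a pseudo-inverse and the remaining
#' components are set to exactly 0.  A subject with no observations gets
#' an all-zero score vector with a warning.
#'
#' @param data a [longitudinal_dataset] of the subjects to score.
#' @param variable variable name.
#' @param ufpca a fitted [fit_ufpca] model (its mean, surface, sigma2 and
#'   eigenpairs are frozen — scoring test subjects uses training
#'   estimates only).
#' @return n x M_q matrix of scores, rownames = subject ids.
#' @export
pace_scores <- function(data, variable, ufpca) {
  Y <- obs_matrix(data, variable)
  # restrict to the model grid (columns of the planned grid kept by the model)
  cols <- match(ufpca$grid, data$grid)
  if (anyNA(cols))
    stop("model grid is not a subset of the data grid for ", variable)
  Y <- Y[, cols, drop = FALSE]
  ages <- data$baseline$age
  n <- nrow(Y)
  M <- ufpca$M_q
  lam <- ufpca$eigenvalues
  Phi <- ufpca$eigenfunctions
  out <- matrix(0, n, M, dimnames = list(data$baseline$id, NULL))
  pat <- apply(!is.na(Y), 1L, function(o) paste(which(o), collapse = ","))
  n_empty <- 0L
  for (p in unique(pat)) {
    subj <- which(pat == p)
    if (p == "") { n_empty <- n_empty + length(subj); next }
    idx <- as.integer(strsplit(p, ",", fixed = TRUE)[[1L]])
    m_obs <- length(idx)
    Phi_o <- Phi[idx, , drop = FALSE]
    SigY <- ufpca$surface[idx, idx, drop = FALSE] +
      diag(ufpca$sigma2, m_obs)
    # residuals for the whole pattern block
    Res <- Y[subj, idx, drop = FALSE]
    for (s in seq_along(subj))
      Res[s, ] <- Res[s, ] -
        mean_value(ufpca$mean, ufpca$grid[idx], ages[subj[s]])
    B <- tryCatch({
      if (ufpca$sigma2 <= 1e-12 && m_obs < M) stop("rank deficient")
      if (m_obs > 1L && rcond(SigY) < 1e-10) stop("ill-conditioned")
      lam * t(solve(SigY, Phi_o))
    }, error = function(e) NULL)
    if (is.null(B)) {
      # degenerate case (sigma^2 ~ 0): weighted least-squares projection
      # onto the maximal solvable number of leading components — the
      # sigma^2 -> 0 limit of the conditional expectation, which on a
      # fully observed subject is the quadrature-integral score — with
      # the remaining components exactly zero
      p_max <- min(m_obs, M)
      wo <- trapezoid_weights(ufpca$grid[idx])
      Phi_p <- Phi_o[, seq_len(p_max), drop = FALSE]
      A <- crossprod(Phi_p, wo * Phi_p)
      Bp <- tryCatch(solve(A, t(wo * Phi_p)), error = function(e) {
        sv <- svd(A)
        dinv <- ifelse(sv$d > max(sv$d) * 1e-10, 1 / sv$d, 0)
        sv$v %*% (dinv * t(sv$u)) %*% t(wo * Phi_p)
      })
      B <- matrix(0, M, m_obs)
      B[seq_len(p_max), ] <- Bp
    }
    out[subj, ] <- Res %*% t(B)
  }
  if (n_empty > 0L)
    warning(n_empty, " subject(s) without observations of ", variable,
            " scored as all-zero")
  out
}
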