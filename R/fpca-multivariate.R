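# Multivariate FPCA through the univariate-multivariate correspondence:
# eigendecompose the covariance of the stacked univariate scores; its
# eigenvectors map stacked scores to multivariate scores and univariate
# eigenfunctions to multivariate eigenfunction blocks.

#' Combine univariate FPCA models into a multivariate decomposition
#'
#' Given Q fitted univariate models and the stacked matrix of their
#' training PACE scores, eigendecomposes the empirical covariance of the
#' stacked scores (divisor n - 1).  Column m of the eigenvector matrix is
#' the correspondence vector c_m; the multivariate eigenfunction blocks
#' are psi_m^(q) = sum_j [c_m]_j^(q) phi_j^(q), the multivariate scores
#' are the projections rho_im = <stacked scores of i, c_m>, and the
#' multivariate eigenvalues are the covariance eigenvalues.  All
#' sum_q M_q components are retained.
#'
#' @param ufpca_list named list of Q `ufpca` models (names = variables).
#' @param training_scores n x sum(M_q) matrix of stacked univariate
#'   scores, columns ordered by variable then component (rownames =
#'   subject ids).
#' @return list with `model` (class `mfpca`) and `scores` (n x M matrix
#'   of training multivariate scores).
#' @export
combine_univariate <- function(ufpca_list, training_scores) {
  if (nrow(training_scores) < 2L)
    stop("at least two subjects are required")
  Mq <- vapply(ufpca_list, function(u) u$M_q, integer(1))
  if (ncol(training_scores) != sum(Mq))
    stop("stacked score matrix has ", ncol(training_scores),
         " columns; expected sum(M_q) = ", sum(Mq))
  Sig <- stats::cov(training_scores)
  eig <- eigen(Sig, symmetric = TRUE)
  M <- sum(Mq)
  V <- apply(eig$vectors, 2L, fix_sign)
  V <- matrix(V, nrow = M)
  nu <- pmax(eig$values, 0)
  blocks <- lapply(seq_along(ufpca_list), function(q) {
    rows <- sum(Mq[seq_len(q - 1L)]) + seq_len(Mq[q])
    ufpca_list[[q]]$eigenfunctions %*% V[rows, , drop = FALSE]
  })
  names(blocks) <- names(ufpca_list)
  model <- structure(
    list(univariate = ufpca_list, correspondence = V,
         eigenvalues = nu, eigenfunction_blocks = blocks,
         M = M, block_sizes = Mq),
    class = "mfpca")
  list(model = model, scores = training_scores %*% V)
}

#' Fit a multivariate FPCA model on a training dataset
#'
#' Fits one univariate FPCA per variable ([fit_ufpca]), computes training
#' PACE scores, stacks them and applies [combine_univariate].
#'
#' @param data a [longitudinal_dataset] (training set).
#' @param time_scale `"study"` or `"age"` (age-based centring).
#' @param pve_target per-variable proportion of variance explained.
#' @param variables variables to include (default all).
#' @return list with `model` (`mfpca`) and `scores` (training score
#'   matrix, rownames = subject ids).
#' @export
fit_mfpca <- function(data, time_scale = c("study", "age"),
                      pve_target = 0.95, variables = data$variables) {
  time_scale <- match.arg(time_scale)
  ufpca_list <- lapply(variables, function(v)
    fit_ufpca(data, v, time_scale, pve_target))
  names(ufpca_list) <- variables
  stacked <- do.call(cbind, lapply(variables, function(v)
    pace_scores(data, v, ufpca_list[[v]])))
  combine_univariate(ufpca_list, stacked)
}

#' Score new subjects with a frozen multivariate FPCA model
#'
#' Univariate PACE scores are computed with the training mean, covariance
#' surface and error variance (nothing is re-estimated), then projected
#' through the stored correspondence vectors.
#'
#' @param data a [longitudinal_dataset] of subjects to score.
#' @param model an `mfpca` model from [fit_mfpca]/[combine_univariate].
#' @return n x M matrix of multivariate scores, rownames = subject ids.
#' @export
score_new_subjects <- function(data, model) {
  vars <- names(model$univariate)
  absent <- vars[!vars %in% data$variables]
  if (length(absent) > 0L)
    stop("variable(s) in the model but absent from the data: ",
         paste(absent, collapse = ", "))
  stacked <- do.call(cbind, lapply(vars, function(v)
    pace_scores(data, v, model$univariate[[v]])))
  stacked %*% model$correspondence
}

#' Reconstruct fitted trajectories from multivariate scores
#'
#' X_hat_i^(q)(t) = mu^(q) + sum_{m<=M} rho_im psi_m^(q)(t) on the model
#' grid, with the mean evaluated on study time or at age + t for an
#' age-scale (ABC) model.
#'
#' @param scores n x M score matrix.
#' @param model an `mfpca` model.
#' @param ages baseline ages (required iff the model mean is age-scale).
#' @param M truncation level (default all components).
#' @return named list (per variable) of n x grid matrices.
#' @export
reconstruct_trajectories <- function(scores, model, ages = NULL,
                                     M = model$M) {
  stopifnot(M >= 1L, M <= model$M, ncol(scores) == model$M)
  vars <- names(model$univariate)
  age_scale <- model$univariate[[1L]]$mean$time_scale == "age"
  if (age_scale && is.null(ages))
    stop("ages are required to reconstruct with an age-scale mean")
  if (age_scale && length(ages) != nrow(scores))
    stop("length(ages) must match nrow(scores)")
  out <- lapply(vars, function(v) {
    u <- model$univariate[[v]]
    fitted <- scores[, seq_len(M), drop = FALSE] %*%
      t(model$eigenfunction_blocks[[v]][, seq_len(M), drop = FALSE])
    if (age_scale) {
      for (i in seq_len(nrow(fitted)))
        fitted[i, ] <- fitted[i, ] + mean_value(u$mean, u$grid, ages[i])
    } else {
      fitted <- sweep(fitted, 2L, mean_value(u$mean, u$grid), "+")
    }
    fitted
  })
  names(out) <- vars
  out
}
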