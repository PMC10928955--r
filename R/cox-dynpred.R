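# Proportional-hazards layer: (optionally LASSO-penalised) Cox model on
# baseline covariates and mFPCA scores, Breslow baseline hazard, and
# conditional survival prediction from the landmark time.

#' Fit the dynamic Cox model on baseline covariates and scores
#'
#' Unpenalized fits maximise Efron's tie-corrected partial likelihood
#' (via [survival::coxph]); LASSO fits penalise only the score
#' coefficients gamma (penalty factor 0 on the baseline covariates beta),
#' with the penalty strength chosen by inner cross-validated partial
#' likelihood deviance ([glmnet::cv.glmnet], `lambda.min`).  The Breslow
#' cumulative baseline hazard (at covariate value zero) is computed from
#' the fitted linear predictors; under strict landmarking no event
#' precedes the landmark, so S0(t_LM) = 1 automatically.
#'
#' @param baseline data.frame with columns `id`, `time` (observed event or
#'   censoring time), `event` (0/1) and any covariate columns.
#' @param scores n x M score matrix aligned with `baseline$id` (rownames
#'   = subject ids).
#' @param t_LM landmark time recorded with the model.
#' @param covariates names of baseline covariate columns entering the
#'   linear predictor unpenalized (may be empty).
#' @param penalty `"none"` or `"lasso"`.
#' @param nfolds inner CV folds for the LASSO strength.
#' @param lambda optional fixed LASSO penalty strength, bypassing the
#'   inner cross-validation.
#' @return An object of class `dynamic_cox`: list with `beta`, `gamma`,
#'   `covariates`, `baseline_cumhaz` (data.frame time/hazard),
#'   `landmark_time`, `penalty` (list with `type`, `lambda`).
#' @export
fit_dynamic_cox <- function(baseline, scores, t_LM = 0,
                            covariates = character(),
                            penalty = c("none", "lasso"), nfolds = 5L,
                            lambda = NULL) {
  penalty <- match.arg(penalty)
  if (sum(baseline$event) == 0L) stop("no events in the training data")
  ids <- as.character(baseline$id)
  if (!is.null(rownames(scores))) {
    rows <- match(ids, rownames(scores))
    if (anyNA(rows)) stop("scores missing for some training subjects")
    scores <- scores[rows, , drop = FALSE]
  }
  M <- ncol(scores)
  colnames(scores) <- paste0("score", seq_len(M))
  Z <- if (length(covariates) > 0L)
    as.matrix(baseline[, covariates, drop = FALSE]) else
      matrix(numeric(0), nrow(baseline), 0L)
  X <- cbind(Z, scores)
  if (any(!is.finite(X))) stop("non-finite values in the design matrix")
  y <- survival::Surv(baseline$time, baseline$event)
  if (penalty == "none") {
    lambda <- NA_real_
    fit <- survival::coxph(y ~ X, ties = "efron")
    coefs <- stats::setNames(as.numeric(stats::coef(fit)), colnames(X))
  } else {
    pf <- c(rep(0, ncol(Z)), rep(1, M))
    if (is.null(lambda)) {
      cvfit <- glmnet::cv.glmnet(X, y, family = "cox", penalty.factor = pf,
                                 nfolds = nfolds,
                                 type.measure = "deviance")
      lambda <- cvfit$lambda.min
      cf <- stats::coef(cvfit, s = "lambda.min")
    } else {
      fit <- glmnet::glmnet(X, y, family = "cox", penalty.factor = pf)
      cf <- stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y,
                        penalty.factor = pf)
    }
    coefs <- stats::setNames(as.numeric(cf), colnames(X))
  }
  lp <- as.numeric(X %*% coefs)
  bh <- breslow_cumhaz(baseline$time, baseline$event, lp)
  structure(list(
    beta = coefs[seq_len(ncol(Z))],
    gamma = coefs[ncol(Z) + seq_len(M)],
    covariates = covariates,
    baseline_cumhaz = bh,
    landmark_time = t_LM,
    penalty = list(type = penalty, lambda = lambda, nfolds = nfolds)),
    class = "dynamic_cox")
}

# Breslow cumulative baseline hazard at covariate value 0:
# H0(t) = sum_{event times s <= t} d(s) / sum_{j at risk at s} exp(lp_j)
breslow_cumhaz <- function(time, event, lp) {
  et <- sort(unique(time[event == 1]))
  elp <- exp(lp)
  inc <- vapply(et, function(s) {
    sum(event == 1 & time == s) / sum(elp[time >= s])
  }, numeric(1))
  data.frame(time = et, hazard = cumsum(inc))
}

#' Baseline survival function of a fitted dynamic Cox model
#'
#' S0(t) = exp(-H0(t)) with H0 the right-continuous Breslow step
#' function (1 before the first event time).
#'
#' @param model a [fit_dynamic_cox] result.
#' @param t evaluation times, `>= 0`.
#' @return numeric vector of baseline survival probabilities.
#' @export
baseline_survival <- function(model, t) {
  if (any(t < 0)) stop("evaluation times must be nonnegative")
  bh <- model$baseline_cumhaz
  H <- c(0, bh$hazard)[findInterval(t, bh$time) + 1L]
  exp(-H)
}

#' Dynamic conditional survival predictions
#'
#' pi_hat_i(t | t_LM) = (S0(t) / S0(t_LM)) ^ exp(beta' Z_i + gamma' rho_i)
#' for horizon times t > t_LM, clipped to \[0, 1\] against floating-point
#' drift.
#'
#' @param model a [fit_dynamic_cox] result.
#' @param baseline data.frame with `id` and the model's covariate columns.
#' @param scores n x M score matrix (rownames = subject ids, aligned or
#'   matched by id).
#' @param horizon evaluation times, all `>= t_LM`.
#' @return An object of class `prediction_result`: list with
#'   `subject_ids`, `landmark_time`, `horizon_times`, `probabilities`
#'   (n x length(horizon) matrix).
#' @export
predict_survival <- function(model, baseline, scores, horizon) {
  if (any(horizon < model$landmark_time))
    stop("horizon times must not precede the landmark time")
  if (ncol(scores) != length(model$gamma))
    stop("score dimension (", ncol(scores), ") does not match gamma (",
         length(model$gamma), ")")
  ids <- as.character(baseline$id)
  if (!is.null(rownames(scores))) {
    rows <- match(ids, rownames(scores))
    if (anyNA(rows)) stop("scores missing for some subjects")
    scores <- scores[rows, , drop = FALSE]
  }
  lp <- as.numeric(scores %*% model$gamma)
  if (length(model$covariates) > 0L)
    lp <- lp + as.numeric(as.matrix(baseline[, model$covariates,
                                             drop = FALSE]) %*% model$beta)
  s0_lm <- baseline_survival(model, model$landmark_time)
  s0 <- baseline_survival(model, horizon)
  prob <- outer(exp(lp), s0 / s0_lm, function(e, s) s^e)
  prob <- pmin(pmax(prob, 0), 1)
  structure(list(subject_ids = ids, landmark_time = model$landmark_time,
                 horizon_times = horizon, probabilities = prob),
            class = "prediction_result")
}
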