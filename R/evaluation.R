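# Validation layer: time-dependent AUC and Brier score with
# inverse-probability-of-censoring weights, MSE against the simulation
# truth, and repeated k-fold cross-validation with the strict/relaxed
# ordering of landmarking and fold-splitting.

# Kaplan-Meier estimate of the censoring survival G(u) = P(C > u) on the
# given sample; returns a function of (u, left) with left = TRUE giving
# the left limit G(u-)
km_censor <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  st <- sf$time; ss <- sf$surv
  function(u, left = FALSE) {
    pos <- if (left) findInterval(u, st, left.open = TRUE)
    else findInterval(u, st)
    c(1, ss)[pos + 1L]
  }
}

risk_at <- function(predictions, t) {
  j <- match(TRUE, abs(predictions$horizon_times - t) < 1e-9)
  if (is.na(j)) stop("t = ", t, " is not among the prediction horizons")
  1 - predictions$probabilities[, j]
}

#' Time-dependent AUC with IPCW
#'
#' Cumulative-cases / dynamic-controls AUC at horizon `t`: cases are
#' subjects with an observed event in (t_LM, t], controls are subjects
#' still at risk past `t`; case weights are 1/G(T_i-) with G the
#' Kaplan-Meier censoring survival estimated among the landmark survivors
#' being evaluated.  Under no censoring this reduces to the Mann-Whitney
#' statistic between cases and controls.  Returns `NA` (with a message)
#' when there are no cases or no controls.
#'
#' @param predictions a [predict_survival] result for the test subjects.
#' @param baseline data.frame with `id`, `time`, `event` for the same
#'   subjects.
#' @param t evaluation horizon (> landmark time, member of the prediction
#'   horizons).
#' @return AUC in \[0, 1\], or `NA`.
#' @export
td_auc <- function(predictions, baseline, t) {
  stopifnot(t > predictions$landmark_time)
  stopifnot(identical(as.character(baseline$id), predictions$subject_ids))
  risk <- risk_at(predictions, t)
  case <- baseline$time <= t & baseline$event == 1
  ctrl <- baseline$time > t
  if (!any(case) || !any(ctrl)) {
    message("tdAUC undefined at t = ", t, ": no ",
            if (!any(case)) "cases" else "controls")
    return(NA_real_)
  }
  G <- km_censor(baseline$time, baseline$event)
  wc <- 1 / G(baseline$time[case], left = TRUE)
  rc <- risk[case]; rj <- risk[ctrl]
  conc <- vapply(seq_along(rc), function(i)
    sum(rc[i] > rj) + 0.5 * sum(rc[i] == rj), numeric(1))
  sum(wc * conc) / (sum(wc) * length(rj))
}

#' Brier score with IPCW
#'
#' Mean squared distance at horizon `t` between the predicted survival
#' probability and the observed survival status, weighted by the inverse
#' Kaplan-Meier censoring survival (weight 1/G(T_i-) for observed events
#' by `t`, 1/G(t) for subjects still at risk, 0 for earlier censorings).
#'
#' @inheritParams td_auc
#' @return Brier score in \[0, 1\], or `NA` if a censoring weight
#'   denominator is zero.
#' @export
brier_score <- function(predictions, baseline, t) {
  stopifnot(t > predictions$landmark_time)
  stopifnot(identical(as.character(baseline$id), predictions$subject_ids))
  pi_hat <- 1 - risk_at(predictions, t)
  G <- km_censor(baseline$time, baseline$event)
  died <- baseline$time <= t & baseline$event == 1
  alive <- baseline$time > t
  g_died <- G(baseline$time[died], left = TRUE)
  g_t <- G(t)
  if ((any(died) && any(g_died <= 0)) || (any(alive) && g_t <= 0)) {
    message("Brier score undefined at t = ", t,
            ": zero censoring-weight denominator")
    return(NA_real_)
  }
  contrib <- numeric(nrow(baseline))
  contrib[died] <- (0 - pi_hat[died])^2 / g_died
  contrib[alive] <- (1 - pi_hat[alive])^2 / g_t
  mean(contrib)
}

#' Mean squared error against the simulation truth
#'
#' MSE(t) = sum_i (pi_i(t | t_LM) - pi_hat_i(t | t_LM))^2 / n' over the
#' n' prediction subjects, using the truth oracle's exact conditional
#' survival probabilities.
#'
#' @param predictions a [predict_survival] result.
#' @param truth matrix of true probabilities with the same layout as
#'   `predictions$probabilities` (e.g. from [true_survival]).
#' @param t single horizon, or `NULL` for all horizons at once.
#' @return numeric vector of MSE values (one per requested horizon).
#' @export
mse_truth <- function(predictions, truth, t = NULL) {
  if (!all(dim(truth) == dim(predictions$probabilities)))
    stop("truth matrix does not match the prediction layout")
  cols <- if (is.null(t)) seq_along(predictions$horizon_times) else
    vapply(t, function(tt)
      match(TRUE, abs(predictions$horizon_times - tt) < 1e-9), integer(1))
  if (anyNA(cols)) stop("horizon(s) not found in the predictions")
  colMeans((truth[, cols, drop = FALSE] -
              predictions$probabilities[, cols, drop = FALSE])^2)
}

#' Repeated cross-validated benchmark of landmarking / centring variants
#'
#' Runs repeated k-fold cross-validation of the full pipeline for each
#' requested method variant.  Under strict landmarking the data are
#' landmarked first and folds are drawn among the landmark survivors;
#' under relaxed landmarking folds are drawn among all subjects and only
#' the prediction fold is landmarked.  Per fold: the mFPCA model is
#' fitted on the training view only, test subjects are scored with the
#' frozen model, the Cox model is fitted and conditional survival curves
#' are predicted; tdAUC, Brier score and (when a truth oracle is
#' available) MSE are evaluated on the landmarked test fold.  Metrics are
#' averaged over folds, then over repeats.
#'
#' @param study a `simulated_study` (with truth oracle) or a plain
#'   [longitudinal_dataset].
#' @param methods data.frame with columns `landmark` ("strict"/"relaxed"),
#'   `abc` (logical: age-based centring) and `penalty` ("none"/"lasso").
#' @param t_LM landmark time.
#' @param horizons evaluation horizons (> t_LM).
#' @param k,repeats folds and repetitions.
#' @param pve_target per-variable PVE for the mFPCA truncation.
#' @param seed master seed; every fold's randomness derives from it.
#' @param include_truth also evaluate the oracle's own probabilities as a
#'   reference method (`"truth"`), when available.
#' @return An object of class `experiment_result`: list with `raw` (tidy
#'   per-fold data.frame), `summary` (means over folds then repeats) and
#'   the call parameters.
#' @export
run_cv_experiment <- function(study, methods, t_LM, horizons,
                              k = 5L, repeats = 5L, pve_target = 0.95,
                              seed = 1L, include_truth = TRUE) {
  stopifnot(nrow(methods) >= 1L, all(horizons > t_LM))
  has_oracle <- inherits(study, "simulated_study")
  data <- if (has_oracle) study$dataset else study
  landmarked <- strict_landmark(data, t_LM)
  plans <- list(
    strict = make_fold_plan(data, "strict", t_LM, k, repeats, seed = seed),
    relaxed = make_fold_plan(data, "relaxed", t_LM, k, repeats, seed = seed))
  rows <- list()
  for (mi in seq_len(nrow(methods))) {
    mode <- methods$landmark[mi]
    abc <- methods$abc[mi]
    pen <- methods$penalty[mi]
    label <- paste0(mode, "_", if (abc) "abc" else "std", "_", pen)
    plan <- plans[[mode]]
    for (r in seq_len(repeats)) {
      assign <- plan$assignments[[r]]
      for (f in seq_len(k)) {
        test_ids <- names(assign)[assign == f]
        train_ids <- names(assign)[assign != f]
        fold_res <- tryCatch(
          withr_seed(seed + 7919L * r + 104729L * f + mi, {
            if (mode == "strict") {
              train <- subset_subjects(landmarked, train_ids)
              test <- subset_subjects(landmarked, test_ids)
            } else {
              views <- relaxed_landmark_views(
                subset_subjects(data, train_ids),
                subset_subjects(data, test_ids), t_LM)
              train <- views$train
              test <- views$test
            }
            fit <- fit_mfpca(train, time_scale = if (abc) "age" else "study",
                             pve_target = pve_target)
            cox <- fit_dynamic_cox(train$baseline, fit$scores, t_LM,
                                   covariates = data$covariates,
                                   penalty = pen)
            test_scores <- score_new_subjects(test, fit$model)
            pred <- predict_survival(cox, test$baseline, test_scores,
                                     horizons)
            evaluate_fold(pred, test$baseline, horizons, study, t_LM,
                          has_oracle)
          }),
          error = function(e) {
            message("fold skipped (", label, ", repeat ", r, ", fold ", f,
                    "): ", conditionMessage(e))
            NULL
          })
        if (is.null(fold_res)) next
        fold_res$method <- label
        fold_res$landmark <- mode
        fold_res$abc <- abc
        fold_res$penalty <- pen
        fold_res$rep <- r
        fold_res$fold <- f
        rows[[length(rows) + 1L]] <- fold_res
      }
    }
  }
  if (include_truth && has_oracle) {
    plan <- plans$strict
    for (r in seq_len(repeats)) {
      assign <- plan$assignments[[r]]
      for (f in seq_len(k)) {
        test_ids <- names(assign)[assign == f]
        test <- subset_subjects(landmarked, test_ids)
        truth <- true_survival(study, test$baseline$id, horizons, t_LM)
        pred <- structure(list(subject_ids = test$baseline$id,
                               landmark_time = t_LM,
                               horizon_times = horizons,
                               probabilities = truth),
                          class = "prediction_result")
        fold_res <- evaluate_fold(pred, test$baseline, horizons, study,
                                  t_LM, has_oracle)
        fold_res$method <- "truth"
        fold_res$landmark <- "strict"
        fold_res$abc <- FALSE
        fold_res$penalty <- "none"
        fold_res$rep <- r
        fold_res$fold <- f
        rows[[length(rows) + 1L]] <- fold_res
      }
    }
  }
  raw <- do.call(rbind, rows)
  summary <- aggregate_experiment(raw)
  structure(list(raw = raw, summary = summary, t_LM = t_LM,
                 horizons = horizons, k = k, repeats = repeats,
                 pve_target = pve_target, seed = seed),
            class = "experiment_result")
}

evaluate_fold <- function(pred, baseline, horizons, study, t_LM,
                          has_oracle) {
  mse <- if (has_oracle) {
    truth <- true_survival(study, baseline$id, horizons, t_LM)
    mse_truth(pred, truth)
  } else rep(NA_real_, length(horizons))
  auc <- vapply(horizons, function(t)
    suppressMessages(td_auc(pred, baseline, t)), numeric(1))
  bs <- vapply(horizons, function(t)
    suppressMessages(brier_score(pred, baseline, t)), numeric(1))
  nar <- vapply(horizons, function(t) sum(baseline$time > t), numeric(1))
  data.frame(time = rep(horizons, 3L),
             metric = rep(c("tdAUC", "brier", "mse"),
                          each = length(horizons)),
             value = c(auc, bs, mse),
             n_at_risk = rep(nar, 3L))
}

# mean over folds within repeat, then mean over repeats
aggregate_experiment <- function(raw) {
  per_rep <- stats::aggregate(value ~ method + landmark + abc + penalty +
                                rep + time + metric,
                              data = raw, FUN = mean, na.rm = TRUE,
                              na.action = stats::na.pass)
  out <- stats::aggregate(value ~ method + landmark + abc + penalty +
                            time + metric,
                          data = per_rep, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  out[order(out$method, out$metric, out$time), , drop = FALSE]
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>  t_LM =", x$t_LM, " k =", x$k,
      " repeats =", x$repeats, "\n")
  agg <- stats::aggregate(value ~ method + metric, data = x$summary,
                          FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  wide <- stats::reshape(agg, idvar = "method", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}
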