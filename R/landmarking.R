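#' Strict landmarking
#'
#' Removes every subject whose observed event or censoring time is at or
#' before the landmark time `t_LM` (keeping exactly those with
#' `time > t_LM`) and truncates the longitudinal record of the survivors
#' at `t_LM` (visits with time <= t_LM are kept).  Survival outcomes of the
#' retained subjects are unchanged.  Applied to both training and test
#' data in the strict landmarking workflow.
#'
#' @param data a [longitudinal_dataset].
#' @param t_LM landmark time in years, `>= 0`.
#' @return the landmarked [longitudinal_dataset].
#' @export
strict_landmark <- function(data, t_LM) {
  stopifnot(inherits(data, "longitudinal_dataset"), t_LM >= 0)
  keep <- data$baseline$id[data$baseline$time > t_LM]
  if (length(keep) == 0L)
    stop("no subject survives past the landmark time ", t_LM)
  out <- subset_subjects(data, keep)
  out$long <- out$long[out$long$time <= t_LM, , drop = FALSE]
  rownames(out$long) <- NULL
  out
}

#' Relaxed landmark views of a train/test split
#'
#' Relaxed landmarking trains on the complete follow-up of every training
#' subject (including those with an event before `t_LM`) and landmarks
#' only the prediction set: the test view is [strict_landmark] applied to
#' the test data.
#'
#' @param train,test disjoint [longitudinal_dataset]s.
#' @param t_LM landmark time in years.
#' @return list with elements `train` (untouched) and `test` (landmarked).
#' @export
relaxed_landmark_views <- function(train, test, t_LM) {
  overlap <- intersect(train$baseline$id, test$baseline$id)
  if (length(overlap) > 0L)
    stop("train and test subject sets overlap: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  list(train = train, test = strict_landmark(test, t_LM))
}

#' Cross-validation fold plan with landmark-aware ordering
#'
#' Builds repeated k-fold assignments honouring the prescribed order of
#' operations: under strict landmarking the data are landmarked first and
#' folds are drawn from the landmark survivors only; under relaxed
#' landmarking folds are drawn from all subjects and only the prediction
#' fold is landmarked later, at evaluation time.
#'
#' @param data a [longitudinal_dataset].
#' @param mode `"strict"` or `"relaxed"`.
#' @param t_LM landmark time in years.
#' @param k number of folds (>= 2).
#' @param repeats number of independent repetitions.
#' @param seed integer seed making the assignments reproducible.
#' @return An object of class `fold_plan`: list with `mode`, `t_LM`, `k`,
#'   `repeats`, `seed` and `assignments`, a list of length `repeats` of
#'   named integer vectors (fold label per subject id).
#' @export
make_fold_plan <- function(data, mode = c("strict", "relaxed"), t_LM,
                           k = 5L, repeats = 1L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(k >= 2L, repeats >= 1L)
  ids <- if (mode == "strict") {
    data$baseline$id[data$baseline$time > t_LM]
  } else {
    data$baseline$id
  }
  if (length(ids) < k)
    stop("fewer subjects (", length(ids), ") than folds (", k, ")")
  assignments <- withr_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      # random permutation, then folds of size differing by at most one
      f <- rep_len(seq_len(k), length(ids))
      stats::setNames(f[sample.int(length(ids))], ids)
    })
  })
  structure(list(mode = mode, t_LM = t_LM, k = k, repeats = repeats,
                 seed = seed, assignments = assignments),
            class = "fold_plan")
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
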