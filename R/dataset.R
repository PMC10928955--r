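#' Longitudinal dataset with right-censored survival outcomes
#'
#' Bundles sparse longitudinal measurements on a planned visit grid with
#' per-subject baseline covariates and a right-censored time-to-event
#' outcome.  This is the common currency of the package: the simulation
#' engine produces it, the landmarking step filters it, and the FPCA and
#' Cox layers consume it.
#'
#' @param long data.frame with columns `id`, `variable`, `time`, `value`
#'   (long/tidy format; `value` may be `NA` for missed measurements).
#'   `time` is time-on-study in years and must lie on `grid` (off-grid
#'   times are snapped to the nearest planned visit, ties to the earlier
#'   one).
#' @param baseline data.frame with one row per subject: columns `id`,
#'   `age` (baseline age in years), `time` (observed event or censoring
#'   time, years), `event` (1 = event observed, 0 = censored), plus any
#'   further baseline covariate columns.
#' @param grid numeric vector of planned visit times, strictly increasing,
#'   starting at 0.
#' @param covariates character vector naming the baseline covariate columns
#'   to be used in the survival model (may be empty; `age` is only a
#'   covariate if listed here).
#' @param snap logical; snap off-grid visit times to the nearest planned
#'   visit time (default `TRUE`).
#'
#' @return An object of class `longitudinal_dataset`: a list with elements
#'   `long`, `baseline`, `grid`, `variables`, `covariates`.
#' @export
longitudinal_dataset <- function(long, baseline, grid,
                                 covariates = character(), snap = TRUE) {
  need_long <- c("id", "variable", "time", "value")
  miss <- setdiff(need_long, names(long))
  if (length(miss) > 0L)
    stop("longitudinal table lacks column(s): ", paste(miss, collapse = ", "))
  need_base <- c("id", "age", "time", "event")
  miss <- setdiff(need_base, names(baseline))
  if (length(miss) > 0L)
    stop("baseline table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(baseline$id))
    stop("duplicate subject ids in baseline table")
  if (is.unsorted(grid, strictly = TRUE) || grid[1L] != 0)
    stop("grid must be strictly increasing and start at 0")
  if (!all(baseline$event %in% c(0, 1)))
    stop("event indicator must be coded 0/1")
  if (any(baseline$time <= 0))
    stop("observed times must be positive")
  miss_cov <- setdiff(covariates, names(baseline))
  if (length(miss_cov) > 0L)
    stop("covariate column(s) absent from baseline table: ",
         paste(miss_cov, collapse = ", "))

  long$id <- as.character(long$id)
  baseline$id <- as.character(baseline$id)
  if (!all(long$id %in% baseline$id))
    stop("longitudinal table contains ids absent from the baseline table")
  if (snap) long$time <- snap_to_grid(long$time, grid)
  key <- paste(long$id, long$variable, long$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, variable, time) measurement rows")
  ord <- order(long$id, long$variable, long$time)
  long <- long[ord, , drop = FALSE]
  rownames(long) <- NULL
  rownames(baseline) <- NULL

  structure(
    list(long = long, baseline = baseline, grid = grid,
         variables = sort(unique(as.character(long$variable))),
         covariates = covariates),
    class = "longitudinal_dataset")
}

#' Snap times to the nearest planned grid time
#'
#' Irregular real-world visit times are mapped to the closest planned
#' assessment time; exact midpoints snap to the earlier grid point.
#'
#' @param times numeric vector of observed times.
#' @param grid planned visit times (strictly increasing).
#' @return numeric vector of grid members, same length as `times`.
#' @export
snap_to_grid <- function(times, grid) {
  # findInterval on midpoints; a time exactly at a midpoint falls in the
  # lower interval, i.e. ties snap to the earlier grid point
  mids <- (grid[-length(grid)] + grid[-1L]) / 2
  grid[findInterval(times, mids, left.open = TRUE) + 1L]
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  cat("<longitudinal_dataset>\n")
  cat("  subjects:  ", nrow(x$baseline), "\n", sep = "")
  cat("  variables: ", paste(x$variables, collapse = ", "), "\n", sep = "")
  cat("  grid:      ", length(x$grid), " visits on [",
      min(x$grid), ", ", max(x$grid), "] years\n", sep = "")
  cat("  events:    ", sum(x$baseline$event), " (",
      round(100 * mean(x$baseline$event), 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.longitudinal_dataset <- function(x) {
  c(subjects = nrow(x$baseline), variables = length(x$variables),
    visits = length(x$grid))
}

#' Restrict a dataset to a subset of subjects
#'
#' @param data a [longitudinal_dataset].
#' @param ids character vector of subject ids to keep.
#' @return a [longitudinal_dataset] containing only the requested subjects.
#' @export
subset_subjects <- function(data, ids) {
  ids <- as.character(ids)
  miss <- setdiff(ids, data$baseline$id)
  if (length(miss) > 0L)
    stop("unknown subject id(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  out <- data
  out$baseline <- data$baseline[data$baseline$id %in% ids, , drop = FALSE]
  out$long <- data$long[data$long$id %in% ids, , drop = FALSE]
  rownames(out$baseline) <- rownames(out$long) <- NULL
  out
}

# observation matrix (subjects x grid) for one variable; NA where unobserved
obs_matrix <- function(data, variable) {
  ids <- data$baseline$id
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(data$grid),
              dimnames = list(ids, NULL))
  rows <- data$long[data$long$variable == variable, , drop = FALSE]
  j <- match(rows$time, data$grid)
  m[cbind(match(rows$id, ids), j)] <- rows$value
  m
}
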