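# Delimited-text I/O: long-format longitudinal tables, baseline tables,
# experiment results and a JSON provenance echo of the run configuration.

#' Read a longitudinal study from delimited text
#'
#' The longitudinal table must have a header row with columns
#' `id, variable, time, value`; the baseline table needs
#' `id, age, time, event` plus any covariate columns.  Unparseable values
#' become missing (with a logged count); off-grid visit times are snapped
#' to the nearest planned grid time, ties to the earlier point.
#'
#' @param long_path path to the longitudinal measurements table.
#' @param baseline_path path to the baseline/survival table.
#' @param grid planned visit times; `NULL` derives it from the observed
#'   times.
#' @param covariates baseline covariate columns for the survival model.
#' @param sep field delimiter (default comma).
#' @return a [longitudinal_dataset].
#' @export
read_long_table <- function(long_path, baseline_path, grid = NULL,
                            covariates = character(), sep = ",") {
  long <- utils::read.table(long_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  baseline <- utils::read.table(baseline_path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  for (col in c("id", "variable", "time", "value"))
    if (!col %in% names(long))
      stop("longitudinal table lacks column: ", col)
  for (col in c("id", "age", "time", "event"))
    if (!col %in% names(baseline))
      stop("baseline table lacks column: ", col)
  val <- suppressWarnings(as.numeric(long$value))
  n_bad <- sum(is.na(val) & !(long$value %in% c("", "NA")))
  if (n_bad > 0L)
    message(n_bad, " unparseable value(s) recorded as missing")
  long$value <- val
  long$time <- as.numeric(long$time)
  if (is.null(grid)) grid <- sort(unique(long$time))
  longitudinal_dataset(long, baseline, grid, covariates = covariates)
}

#' Write a longitudinal study as delimited text
#'
#' Inverse of [read_long_table]; writes `<prefix>_long.csv` and
#' `<prefix>_baseline.csv` with full numeric precision.
#'
#' @param data a [longitudinal_dataset].
#' @param prefix output path prefix.
#' @param sep field delimiter.
#' @return invisibly, the two file paths.
#' @export
write_long_table <- function(data, prefix, sep = ",") {
  paths <- paste0(prefix, c("_long.csv", "_baseline.csv"))
  utils::write.table(format(data$long, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     paths[1L], sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(format(data$baseline, digits = 17, trim = TRUE),
                     paths[2L], sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Write experiment results and a configuration echo
#'
#' Writes the tidy per-fold table (`<prefix>_raw.csv`), the aggregated
#' summary (`<prefix>_summary.csv`) and a JSON echo of the run parameters
#' (`<prefix>_config.json`) sufficient to reproduce the run with the same
#' seed.
#'
#' @param result an [run_cv_experiment] result.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_results <- function(result, prefix) {
  stopifnot(inherits(result, "experiment_result"))
  paths <- paste0(prefix, c("_raw.csv", "_summary.csv", "_config.json"))
  utils::write.csv(result$raw, paths[1L], row.names = FALSE)
  utils::write.csv(result$summary, paths[2L], row.names = FALSE)
  cfg <- result[c("t_LM", "horizons", "k", "repeats", "pve_target", "seed")]
  jsonlite::write_json(cfg, paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Serialize a fitted model to JSON text
#'
#' Stores every numeric component (grids, mean values, eigenpairs, error
#' variances, correspondence matrix, Cox coefficients, Breslow baseline)
#' to full precision, sufficient to score unseen subjects exactly after
#' [read_model_json].
#'
#' @param model an `mfpca` or `dynamic_cox` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "mfpca")) {
    payload <- list(
      type = "mfpca",
      correspondence = model$correspondence,
      eigenvalues = model$eigenvalues,
      block_sizes = model$block_sizes,
      M = model$M,
      univariate = lapply(model$univariate, function(u)
        list(grid = u$grid, eigenvalues = u$eigenvalues,
             eigenfunctions = u$eigenfunctions,
             all_eigenvalues = u$all_eigenvalues,
             M_q = u$M_q, pve_target = u$pve_target,
             pve_attained = u$pve_attained,
             surface = u$surface, sigma2 = u$sigma2,
             mean = u$mean[c("time_scale", "eval_grid", "values",
                             "smoother_meta")])))
  } else if (inherits(model, "dynamic_cox")) {
    payload <- list(
      type = "dynamic_cox",
      beta = as.list(model$beta), gamma = as.list(model$gamma),
      covariates = model$covariates,
      baseline_cumhaz = model$baseline_cumhaz,
      landmark_time = model$landmark_time,
      penalty = model$penalty)
  } else stop("unsupported model class")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model serialized by [write_model_json]
#'
#' @param path JSON file written by [write_model_json].
#' @return an `mfpca` or `dynamic_cox` object.
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (p$type == "mfpca") {
    uni <- lapply(p$univariate, function(u) {
      u$eigenfunctions <- matrix(unlist(u$eigenfunctions),
                                 nrow = length(u$grid))
      u$surface <- matrix(unlist(u$surface), nrow = length(u$grid))
      u$mean <- structure(u$mean, class = "mean_function")
      structure(u, class = "ufpca")
    })
    Mtot <- p$M
    V <- matrix(unlist(p$correspondence), Mtot)
    # rebuild the eigenfunction blocks from the univariate parts
    blocks <- vector("list", length(uni))
    off <- 0L
    for (q in seq_along(uni)) {
      rows <- off + seq_len(uni[[q]]$M_q)
      blocks[[q]] <- uni[[q]]$eigenfunctions %*% V[rows, , drop = FALSE]
      off <- off + uni[[q]]$M_q
    }
    names(blocks) <- names(uni)
    structure(list(univariate = uni, correspondence = V,
                   eigenvalues = p$eigenvalues,
                   eigenfunction_blocks = blocks, M = Mtot,
                   block_sizes = unlist(p$block_sizes)),
              class = "mfpca")
  } else if (p$type == "dynamic_cox") {
    structure(list(beta = unlist(p$beta), gamma = unlist(p$gamma),
                   covariates = unlist(p$covariates),
                   baseline_cumhaz = as.data.frame(p$baseline_cumhaz),
                   landmark_time = p$landmark_time,
                   penalty = p$penalty),
              class = "dynamic_cox")
  } else stop("unknown model type: ", p$type)
}
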