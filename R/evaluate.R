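#' Mean squared percentage error
#'
#' The study's headline error metric: the mean squared prediction error
#' normalized by the mean of the true targets, times 100,
#' `MSPE = mean((y_test - y_pred)^2) / mean(y_test) * 100`. The
#' normalization makes the score independent of the target's amplitude
#' offset while keeping an interpretable percentage-like scale (note the
#' irregular units: the metric scales linearly, not quadratically, when both
#' arrays are scaled by a constant). A conventional alternative normalizing
#' by the squared mean is available via `denominator`.
#'
#' @param y_test true target values (mean must be positive, as it is for the
#'   1-5 SPSL scale).
#' @param y_pred predicted values, same length.
#' @param denominator `"mean"` (default, the study's definition) or
#'   `"mean_squared"` (normalizes by `mean(y_test)^2`).
#' @return Non-negative scalar.
#' @examples
#' mspe(c(1, 2, 3, 4), c(2, 2, 3, 4))  # 0.25 / 2.5 * 100 = 10
#' @export
mspe <- function(y_test, y_pred, denominator = c("mean", "mean_squared")) {
  denominator <- match.arg(denominator)
  if (length(y_test) != length(y_pred)) stop("length mismatch")
  m <- mean(y_test)
  if (m <= 0) stop("mean of y_test must be positive")
  den <- if (denominator == "mean") m else m^2
  mean((y_test - y_pred)^2) / den * 100
}

#' Squared Pearson correlation between truth and predictions
#'
#' The study's correlation score: the square of the Pearson correlation
#' coefficient between true and predicted values (not the coefficient of
#' determination, which is available via `type = "cod"` and can be negative).
#' Constant inputs have no defined correlation; `NA` is returned with a
#' warning rather than 0.
#'
#' @param y_test,y_pred numeric vectors of equal length.
#' @param type `"pearson"` (default) or `"cod"`.
#' @return Scalar in `[0, 1]` for `"pearson"`; `NA` if either input is
#'   constant.
#' @export
r_squared <- function(y_test, y_pred, type = c("pearson", "cod")) {
  type <- match.arg(type)
  if (length(y_test) != length(y_pred)) stop("length mismatch")
  if (type == "cod")
    return(1 - sum((y_test - y_pred)^2) / sum((y_test - mean(y_test))^2))
  if (stats::sd(y_test) == 0 || stats::sd(y_pred) == 0) {
    warning("constant input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(y_test, y_pred)^2
}

#' Absolute prediction error at each survey
#'
#' @param y_test,y_pred length-8 vectors ordered T1..T8.
#' @return Named numeric vector (`T1`..`T8`) of absolute errors.
#' @export
per_survey_abs_error <- function(y_test, y_pred) {
  if (length(y_test) != length(y_pred)) stop("length mismatch")
  ae <- abs(y_test - y_pred)
  names(ae) <- paste0("T", seq_along(ae))
  ae
}

#' Score one participant's test predictions
#'
#' @param y_test the participant's eight true survey answers (T1..T8).
#' @param y_pred the model's eight test predictions.
#' @param participant,family,interpolation identifying tags carried into the
#'   cohort aggregation.
#' @param ... passed to [mspe()] and [r_squared()].
#' @return An object of class `eval_result`: one-row data.frame with `mspe`,
#'   `r2` and the eight per-survey absolute errors (`ae_T1`..`ae_T8`).
#' @export
evaluate_predictions <- function(y_test, y_pred, participant = NA,
                                 family = NA_character_,
                                 interpolation = NA_character_, ...) {
  ae <- per_survey_abs_error(y_test, y_pred)
  out <- data.frame(participant = participant, family = family,
                    interpolation = interpolation,
                    mspe = mspe(y_test, y_pred, ...),
                    r2 = r_squared(y_test, y_pred),
                    t(ae))
  names(out)[6:13] <- paste0("ae_", names(ae))
  class(out) <- c("eval_result", "data.frame")
  out
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Aggregate per-participant results across a cohort
#'
#' Builds the cohort report: for every (regressor family x interpolation
#' method) cell, the mean and SEM (sample sd over sqrt of the participant
#' count) of MSPE and R2; the best cell (minimum mean MSPE); and, for the
#' best cell, the per-survey mean absolute error with SEM. With fewer than
#' two participants the SEMs are reported as `NA`.
#'
#' @param results data.frame of rows from [evaluate_predictions()] (one per
#'   participant per cell), or a list of such rows.
#' @return An object of class `aggregate_report`: list with `cells`,
#'   `best` (list `family`/`interpolation`), `per_survey` and
#'   `n_participants`.
#' @export
aggregate_results <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  stopifnot(is.data.frame(results),
            all(c("family", "interpolation", "mspe", "r2") %in% names(results)))
  cells <- expand.grid(family = unique(results$family),
                       interpolation = unique(results$interpolation),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_ <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$family == cells$family[i] &
                     results$interpolation == cells$interpolation[i], ]
    data.frame(mspe_mean = mean(sub$mspe), mspe_sem = sem(sub$mspe),
               r2_mean = mean(sub$r2, na.rm = TRUE), r2_sem = sem(sub$r2),
               n = nrow(sub))
  })
  cells <- cbind(cells, do.call(rbind, stats_))
  bi <- which.min(cells$mspe_mean)
  best <- list(family = cells$family[bi], interpolation = cells$interpolation[bi])
  sub <- results[results$family == best$family &
                   results$interpolation == best$interpolation, ]
  ae_cols <- grep("^ae_T", names(sub), value = TRUE)
  per_survey <- data.frame(
    survey = sub("ae_", "", ae_cols),
    abs_error_mean = vapply(ae_cols, function(c) mean(sub[[c]]), numeric(1)),
    abs_error_sem = vapply(ae_cols, function(c) sem(sub[[c]]), numeric(1)),
    row.names = NULL
  )
  structure(
    list(cells = cells, best = best, per_survey = per_survey,
         n_participants = length(unique(results$participant))),
    class = "aggregate_report"
  )
}

#' Lay out a cohort report as a performance table
#'
#' One row per regressor family, one `MSPE` / `R2` column pair per
#' interpolation method, each cell formatted `mean +/- SEM`.
#'
#' @param report an `aggregate_report`.
#' @param digits significant digits in the formatted cells.
#' @return A data.frame, rows = families.
#' @export
format_report_table <- function(report, digits = 4) {
  stopifnot(inherits(report, "aggregate_report"))
  fams <- unique(report$cells$family)
  interps <- unique(report$cells$interpolation)
  fmt <- function(m, s) {
    ifelse(is.na(s), signif(m, digits),
           paste0(signif(m, digits), " ± ", signif(s, 3)))
  }
  out <- data.frame(family = fams)
  for (ip in interps) {
    sub <- report$cells[report$cells$interpolation == ip, ]
    sub <- sub[match(fams, sub$family), ]
    out[[paste0("MSPE_", ip)]] <- fmt(sub$mspe_mean, sub$mspe_sem)
    out[[paste0("R2_", ip)]] <- fmt(sub$r2_mean, sub$r2_sem)
  }
  out
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf("Cohort report over %d participants (%d cells)\n",
              x$n_participants, nrow(x$cells)))
  print(format_report_table(x), row.names = FALSE)
  cat(sprintf("Best cell: %s / %s interpolation\n",
              x$best$family, x$best$interpolation))
  invisible(x)
}
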