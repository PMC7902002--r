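# Comparison metrics: mean intercrop genetic value, intercrop genetic
# variance, prediction accuracy, and the paired log-ratio statistic used to
# compare program designs over simulation replicates.

#' Mean intercrop genetic value of the DH stage
#'
#' The mean of the two crops' mean true intercrop genetic values,
#' `(mean(a_ic_A) + mean(a_ic_B)) / 2`, optionally centered by subtracting
#' the value stored at the end of the burn-in.
#'
#' @param aic_A,aic_B True intercrop genetic values of the two crops' DH
#'   cohorts.
#' @param center Value to subtract (the end-of-burn-in mean; default 0).
#' @return A single number.
#' @export
mean_intercrop_value <- function(aic_A, aic_B, center = 0) {
  if (length(aic_A) == 0L || length(aic_B) == 0L)
    stop("both DH cohorts must be non-empty")
  (mean(aic_A) + mean(aic_B)) / 2 - center
}

#' Intercrop genetic variance of the DH stage
#'
#' Population variance (divide by n) of the individual true intercrop
#' genetic values pooled over both crops' DH cohorts.
#'
#' @param aic_A,aic_B True intercrop genetic values per crop.
#' @return A single number.
#' @export
intercrop_variance <- function(aic_A, aic_B) {
  x <- c(aic_A, aic_B)
  if (length(x) < 2L) stop("need at least two genotypes to measure variance")
  mean((x - mean(x))^2)
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted and true performance. For the
#' genomic-selection programs the predictor is gGIA; for the phenotypic
#' program it is the DH-stage monocrop phenotype.
#'
#' @param predictions,truths Paired numeric vectors (n >= 3).
#' @return The correlation, or `NA` with a warning for zero-variance input.
#' @export
prediction_accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(predictions) < 3L)
    stop("need paired vectors of length >= 3")
  if (stats::sd(predictions) == 0 || stats::sd(truths) == 0) {
    warning("zero-variance input; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(predictions, truths)
}

#' Paired log-ratio of two programs over replicates
#'
#' Compares seed-paired per-replicate values (typically year-20 cumulative
#' intercrop genetic gain) of two program arms: a paired t test is performed
#' on the log-transformed values and the mean log difference and its
#' confidence interval are back-transformed to a ratio. Replicates in which
#' either value is non-positive cannot be log-transformed and are excluded
#' with a message.
#'
#' @param values_x,values_y Per-replicate values of the two programs, paired
#'   by position (common random numbers through the burn-in).
#' @param conf_level Confidence level of the interval.
#' @return An object of class `ratio_estimate`: `ratio`, `conf_int`, `n`
#'   (replicates used), `n_excluded`, and the t-test `p_value` (NA when the
#'   log-differences are constant).
#' @export
gain_ratio <- function(values_x, values_y, conf_level = 0.95) {
  if (length(values_x) != length(values_y))
    stop("replicate vectors must be paired (equal length)")
  ok <- values_x > 0 & values_y > 0
  if (any(!ok))
    message(sum(!ok), " replicate(s) with non-positive values excluded from the ratio")
  if (sum(ok) < 1L) stop("no replicates with positive values in both arms")
  d <- log(values_x[ok]) - log(values_y[ok])
  est <- exp(mean(d))
  tt <- if (length(d) >= 2L)
    tryCatch(stats::t.test(d, conf.level = conf_level), error = function(e) NULL)
  else NULL
  if (!is.null(tt) && all(is.finite(tt$conf.int))) {
    ci <- exp(as.numeric(tt$conf.int))
    p <- tt$p.value
  } else {
    # fewer than two replicates, or constant log-differences
    ci <- c(est, est)
    p <- NA_real_
  }
  structure(list(ratio = est, conf_int = ci, n = sum(ok),
                 n_excluded = sum(!ok), p_value = p,
                 conf_level = conf_level),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("ratio %.3f [%.3f, %.3f] (%d replicates%s)\n",
              x$ratio, x$conf_int[1], x$conf_int[2], x$n,
              if (x$n_excluded) paste0(", ", x$n_excluded, " excluded") else ""))
  invisible(x)
}
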