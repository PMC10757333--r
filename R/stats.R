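## stats: calibration/validation statistics and model-utility
## classification as conventionally reported for NIRS models.

#' Standard error of calibration (SEC)
#'
#' sqrt(sum(e^2) / (n - 1 - k)) where k is the number of PLS factors:
#' the residual standard error with degrees of freedom charged for the
#' factors and the intercept.
#'
#' @param residuals Calibration residuals (fitted minus reference).
#' @param n_factors Number of PLS factors k.
#' @return SEC, in trait units.
#' @export
sec <- function(residuals, n_factors) {
  n <- length(residuals)
  df <- n - 1 - n_factors
  if (df <= 0) stop("degrees of freedom <= 0 (n = ", n, ", k = ",
                    n_factors, ")")
  sqrt(sum(residuals^2) / df)
}

#' Validation error statistics
#'
#' bias = mean(predicted - reference); SEP = sqrt(sum(e^2) / n)
#' (uncorrected); SEP(C) = sqrt(sum((e - bias)^2) / (n - 1))
#' (bias-corrected).
#'
#' @param y Reference (laboratory) values.
#' @param y_hat Predicted values, paired with \code{y}.
#' @return List with \code{SEP}, \code{SEP_C}, \code{bias}.
#' @export
validation_errors <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat lengths differ")
  n <- length(y)
  if (n < 2) stop("need n >= 2 validation samples")
  e <- y_hat - y
  bias <- mean(e)
  list(SEP = sqrt(sum(e^2) / n),
       SEP_C = sqrt(sum((e - bias)^2) / (n - 1)),
       bias = bias)
}

#' Coefficient of determination (RSQ)
#'
#' \code{mode = "external"}: squared Pearson correlation between
#' predicted and reference values, the convention for validation-set
#' reporting (invariant to affine recalibration of the predictions).
#' \code{mode = "calibration"}: 1 - SSE/SST against the reference mean,
#' clamped to [0, 1].
#'
#' @inheritParams validation_errors
#' @param mode "external" or "calibration".
#' @return RSQ in [0, 1].
#' @export
rsq <- function(y, y_hat, mode = c("external", "calibration")) {
  mode <- match.arg(mode)
  if (length(y) != length(y_hat)) stop("y and y_hat lengths differ")
  if (length(y) < 3) stop("need n >= 3")
  if (stats::var(y) <= 0) stop("y has zero variance")
  if (mode == "external") {
    if (stats::var(y_hat) <= 0) {
      if (all(y_hat == y)) return(1)
      stop("predictions have zero variance")
    }
    stats::cor(y, y_hat)^2
  } else {
    min(max(1 - sum((y_hat - y)^2) / sum((y - mean(y))^2), 0), 1)
  }
}

#' Ratio of performance deviation (RPD)
#'
#' SD of the validation reference values (n-1 denominator) divided by
#' SEP. RPD >= 3 marks a model useful for quantification, RPD < 2 for
#' screening at best.
#'
#' @param sd_val Standard deviation of the validation reference values.
#' @param sep Standard error of prediction.
#' @return RPD (Inf when SEP is 0).
#' @examples
#' rpd(1.374, 0.312)  # 4.40...
#' @export
rpd <- function(sd_val, sep) {
  if (sep < 0 || sd_val < 0) stop("sd_val and sep must be >= 0")
  if (sep == 0) return(Inf)
  sd_val / sep
}

#' Paired t-test of predictions against reference values
#'
#' Two-sided paired t-test on the differences (predicted minus
#' reference); p > 0.05 indicates no systematic disagreement between the
#' model and the laboratory. All-zero differences return t = 0, p = 1.
#'
#' @inheritParams validation_errors
#' @return List with \code{t} and \code{p}.
#' @export
paired_t <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat lengths differ")
  d <- y_hat - y
  if (all(d == 0)) return(list(t = 0, p = 1))
  if (stats::sd(d) == 0) {
    stop("constant nonzero differences: t statistic undefined")
  }
  ht <- stats::t.test(y_hat, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Classify model utility from RPD
#'
#' "high" for RPD >= 3 (quantification), "poor" for RPD < 2, otherwise
#' "screening". Boundary values fall in the better class.
#'
#' @param rpd_value RPD, >= 0.
#' @return "high", "screening" or "poor".
#' @examples
#' classify_rpd(4.4)  # "high"
#' @export
classify_rpd <- function(rpd_value) {
  if (rpd_value < 0) stop("RPD must be >= 0")
  if (rpd_value >= 3) "high" else if (rpd_value < 2) "poor" else "screening"
}

#' Validation report for a calibrated model
#'
#' Predicts the validation set (no outlier removal at validation) and
#' assembles SEP, SEP(C), bias, SD, RPD, external RSQ, the paired t-test
#' and the RPD utility class.
#'
#' @param model An \code{mpls_model} from \code{\link{calibrate}}.
#' @param spectra Validation \code{\link{spectra_set}} (raw; the model's
#'   treatment is applied) or treated matrix.
#' @param y Validation reference values.
#' @return List of class \code{validation_stats}: \code{n_val},
#'   \code{SEP}, \code{SEP_C}, \code{bias}, \code{SD_val}, \code{RPD},
#'   \code{RSQ_ext}, \code{t_stat}, \code{p_value}, \code{utility},
#'   \code{predicted}.
#' @export
validation_report <- function(model, spectra, y) {
  y <- as.numeric(y)
  y_hat <- predict(model, spectra)
  if (length(y_hat) != length(y)) stop("y length != number of spectra")
  err <- validation_errors(y, y_hat)
  sd_val <- stats::sd(y)
  rpd_val <- rpd(sd_val, err$SEP)
  rsq_ext <- if (err$SEP == 0) 1 else rsq(y, y_hat, "external")
  tt <- paired_t(y, y_hat)
  structure(list(n_val = length(y), SEP = err$SEP, SEP_C = err$SEP_C,
                 bias = err$bias, SD_val = sd_val, RPD = rpd_val,
                 RSQ_ext = rsq_ext, t_stat = tt$t, p_value = tt$p,
                 utility = classify_rpd(min(rpd_val, Inf)),
                 predicted = y_hat),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf(
    "validation: n=%d, SEP=%.4g, SEP(C)=%.4g, bias=%.3g, RPD=%.2f, RSQ=%.3f, p=%.3f [%s]\n",
    x$n_val, x$SEP, x$SEP_C, x$bias, x$RPD, x$RSQ_ext, x$p_value, x$utility))
  invisible(x)
}

#' Worked-example validation statistics
#'
#' Published validation-set statistics (SEP, SD of the reference values,
#' and the reported RPD, one decimal) for a combined rice bean / adzuki
#' bean flour NIRS model, for the traits where the reported RPD is
#' consistent with the identity RPD = SD/SEP. Used as worked examples for
#' \code{\link{rpd}}.
#'
#' @return Data frame with columns \code{trait}, \code{SEP}, \code{SD},
#'   \code{RPD_reported}.
#' @export
reference_validation_examples <- function() {
  data.frame(
    trait = c("protein", "dietary_fiber", "starch", "phytate",
              "cuprac", "fat", "fe", "red"),
    SEP = c(0.312, 0.993, 1.241, 0.058, 0.777, 0.557, 9.816, 15.018),
    SD = c(1.374, 2.571, 3.339, 0.28, 1.521, 0.617, 15.99, 54.167),
    RPD_reported = c(4.4, 2.6, 2.7, 4.8, 2.0, 1.1, 1.6, 3.6),
    stringsAsFactors = FALSE
  )
}

#' Tabulate search or validation results
#'
#' Flattens calibration/validation statistic pairs into a one-row data
#' frame mirroring the usual model-report table columns.
#'
#' @param treatment A \code{math_treatment}.
#' @param cal A \code{calibration_stats}.
#' @param val A \code{validation_stats}.
#' @return One-row data frame.
#' @export
stats_row <- function(treatment, cal, val) {
  data.frame(treatment = format(treatment),
             n_factors = cal$n_factors,
             n_outliers = cal$n_outliers_removed,
             SEC = cal$SEC, SECV = cal$SECV, SD_cal = cal$SD_cal,
             RSQ_cal = cal$RSQ_cal,
             SEP = val$SEP, SEP_C = val$SEP_C, bias = val$bias,
             SD_val = val$SD_val, RPD = val$RPD, RSQ_ext = val$RSQ_ext,
             p_value = val$p_value, utility = val$utility,
             stringsAsFactors = FALSE)
}
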