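## mpls: modified partial least squares calibration with cross-validated
## factor selection and iterative outlier elimination.

pls_input_checks <- function(X, y, n_factors) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (nrow(X) < n_factors + 2) {
    stop("need n_samples >= n_factors + 2 (", n_factors + 2, "), got ",
         nrow(X))
  }
  if (stats::var(y) <= 0) stop("y has zero variance")
  list(X = X, y = y)
}

#' PLS1 regression by NIPALS
#'
#' Standard single-response partial least squares, used as the reference
#' algorithm for the modified PLS fit: at full rank its fitted values
#' coincide with ordinary least squares.
#'
#' @param X Numeric matrix of processed spectra (samples x wavelengths).
#' @param y Numeric response (trait values).
#' @param n_factors Number of latent factors to extract.
#' @return An object of class \code{mpls_model} (with no residual
#'   scaling).
#' @seealso \code{\link{fit_mpls}}, \code{\link{predict.mpls_model}}
#' @export
fit_pls1_nipals <- function(X, y, n_factors) {
  inp <- pls_input_checks(X, y, n_factors)
  X <- inp$X; y <- inp$y
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  Tm <- matrix(0, n, n_factors)
  for (k in seq_len(n_factors)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("n_factors too large: no covariance left at factor ", k)
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) stop("n_factors too large: degenerate score at factor ", k)
    pk <- drop(crossprod(Xc, t)) / tt
    qk <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pk)
    yc <- yc - qk * t
    W[, k] <- w; P[, k] <- pk; q[k] <- qk; Tm[, k] <- t
  }
  ## cumulative fitted values per factor count
  contrib <- sweep(Tm, 2, q, `*`)
  fitted_all <- if (n_factors == 1) matrix(y_mean + contrib, ncol = 1)
                else y_mean + t(apply(contrib, 1, cumsum))
  structure(list(method = "pls1", x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, q = q, scales = NULL,
                 n_factors = n_factors,
                 fitted = fitted_all[, n_factors],
                 fitted_by_factor = fitted_all,
                 y = y),
            class = "mpls_model")
}

#' Modified PLS (mPLS) regression
#'
#' NIPALS-style PLS1 in which, after each factor is extracted, the
#' spectral residual at every wavelength is divided by the standard
#' deviation of that wavelength's residuals across samples
#' (Shenk-Westerhaus residual standardisation). The per-factor scaling
#' vectors are stored so that prediction replays the same path. With
#' \code{scale_residuals = FALSE} the fit reduces exactly to
#' \code{\link{fit_pls1_nipals}}.
#'
#' Wavelengths whose residual standard deviation underflows are dropped
#' from further factors (their scale is fixed at 1; the residual there is
#' already zero) and recorded in \code{dropped_wavelengths}.
#'
#' @inheritParams fit_pls1_nipals
#' @param scale_residuals Standardise spectral residuals between factors
#'   (the "modified" in mPLS).
#' @return An object of class \code{mpls_model}.
#' @export
fit_mpls <- function(X, y, n_factors, scale_residuals = TRUE) {
  inp <- pls_input_checks(X, y, n_factors)
  X <- inp$X; y <- inp$y
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  Tm <- matrix(0, n, n_factors)
  S <- if (scale_residuals) matrix(1, p, n_factors) else NULL
  dropped <- integer(0)
  for (k in seq_len(n_factors)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("n_factors too large: no covariance left at factor ", k)
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) stop("n_factors too large: degenerate score at factor ", k)
    pk <- drop(crossprod(Xc, t)) / tt
    qk <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pk)
    yc <- yc - qk * t
    W[, k] <- w; P[, k] <- pk; q[k] <- qk; Tm[, k] <- t
    if (scale_residuals) {
      sdv <- sqrt(colSums(Xc^2) / (n - 1))
      zero <- sdv < 1e-12
      if (any(zero)) dropped <- union(dropped, which(zero))
      sdv[zero] <- 1
      S[, k] <- sdv
      Xc <- sweep(Xc, 2, sdv, `/`)
    }
  }
  contrib <- sweep(Tm, 2, q, `*`)
  fitted_all <- if (n_factors == 1) matrix(y_mean + contrib, ncol = 1)
                else y_mean + t(apply(contrib, 1, cumsum))
  structure(list(method = if (scale_residuals) "mpls" else "pls1",
                 x_mean = x_mean, y_mean = y_mean,
                 W = W, P = P, q = q, scales = S,
                 n_factors = n_factors,
                 fitted = fitted_all[, n_factors],
                 fitted_by_factor = fitted_all,
                 dropped_wavelengths = dropped,
                 y = y),
            class = "mpls_model")
}

#' Predict from an mPLS model
#'
#' Replays the stored centering / factor / residual-scaling path. If
#' \code{newdata} is a \code{\link{spectra_set}} on the model's original
#' grid, the model's math treatment (with its frozen scatter parameters)
#' is applied first; a plain matrix is assumed to be already treated.
#'
#' @param object An \code{mpls_model} (typically from
#'   \code{\link{calibrate}}).
#' @param newdata Matrix of treated spectra, or a raw \code{spectra_set}.
#' @param ncomp Number of factors to use (default: the model's).
#' @param all_components Return an n x ncomp matrix of cumulative
#'   predictions for 1..ncomp factors instead of a vector.
#' @param ... Unused.
#' @return Predicted trait values.
#' @export
predict.mpls_model <- function(object, newdata, ncomp = object$n_factors,
                               all_components = FALSE, ...) {
  if (inherits(newdata, "spectra_set")) {
    if (is.null(object$treatment)) {
      stop("model carries no treatment; supply a treated matrix")
    }
    treated <- apply_treatment(newdata, object$treatment,
                               scatter_params = object$scatter_params)
    if (!is.null(object$wavelengths) &&
        (length(treated$wavelengths) != length(object$wavelengths) ||
         max(abs(treated$wavelengths - object$wavelengths)) > 1e-6)) {
      stop("wavelength grid mismatch between model and new spectra")
    }
    newdata <- treated$values
  }
  X <- as_row_matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("grid mismatch: model has ", length(object$x_mean),
         " wavelengths, newdata has ", ncol(X))
  }
  if (ncomp < 1 || ncomp > object$n_factors) {
    stop("ncomp must be in 1..", object$n_factors)
  }
  Xc <- sweep(X, 2, object$x_mean)
  out <- matrix(object$y_mean, nrow(X), ncomp)
  acc <- rep(object$y_mean, nrow(X))
  for (k in seq_len(ncomp)) {
    t <- drop(Xc %*% object$W[, k])
    acc <- acc + t * object$q[k]
    out[, k] <- acc
    Xc <- Xc - tcrossprod(t, object$P[, k])
    if (!is.null(object$scales)) {
      Xc <- sweep(Xc, 2, object$scales[, k], `/`)
    }
  }
  if (all_components) out else drop(out[, ncomp])
}

#' @export
print.mpls_model <- function(x, ...) {
  cat("mPLS model (", x$method, "), ", x$n_factors, " factors, ",
      length(x$x_mean), " wavelengths\n", sep = "")
  if (!is.null(x$treatment)) cat("  treatment:", format(x$treatment), "\n")
  if (length(x$removed_outlier_ids)) {
    cat("  outliers removed:", paste(x$removed_outlier_ids, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Cross-validation plan
#'
#' Assigns the n calibration samples to \code{n_groups} contiguous blocks
#' of a seeded shuffle. \code{n_groups = n} gives leave-one-out.
#'
#' @param n Number of samples.
#' @param n_groups Number of CV groups (default 5).
#' @param seed Integer seed.
#' @return Integer vector of group labels, one per sample.
#' @export
cv_plan <- function(n, n_groups = 5, seed = 1) {
  if (n_groups < 2 || n_groups > n) stop("n_groups must be in 2..n")
  perm <- with_seed(seed, sample.int(n))
  bounds <- floor(seq(0, n, length.out = n_groups + 1))
  assignment <- integer(n)
  for (g in seq_len(n_groups)) {
    assignment[perm[(bounds[g] + 1):bounds[g + 1]]] <- g
  }
  assignment
}

#' Cross-validated error curve (SECV)
#'
#' Group-wise cross-validation of an mPLS fit: for each factor count
#' k = 1..max_factors, SECV(k) = sqrt(sum of squared held-out prediction
#' errors / n).
#'
#' @inheritParams fit_mpls
#' @param max_factors Largest factor count to evaluate.
#' @param n_groups,seed Passed to \code{\link{cv_plan}} when no
#'   \code{plan} is given.
#' @param plan Explicit group-assignment vector.
#' @return List of class \code{cv_result}: \code{secv} (length
#'   \code{max_factors}), \code{residuals} (n x max_factors matrix of
#'   held-out errors, prediction minus reference), \code{plan}.
#' @export
cross_validate <- function(X, y, max_factors, n_groups = 5, seed = 1,
                           plan = NULL, scale_residuals = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(plan)) plan <- cv_plan(n, n_groups, seed)
  if (length(plan) != n) stop("plan length != n")
  groups <- sort(unique(plan))
  smallest_train <- n - max(table(plan))
  if (smallest_train < max_factors + 2) {
    stop("infeasible CV plan: a group leaves only ", smallest_train,
         " training samples; need >= ", max_factors + 2)
  }
  preds <- matrix(NA_real_, n, max_factors)
  for (g in groups) {
    hold <- which(plan == g)
    fit <- fit_mpls(X[-hold, , drop = FALSE], y[-hold], max_factors,
                    scale_residuals = scale_residuals)
    preds[hold, ] <- predict(fit, X[hold, , drop = FALSE],
                             ncomp = max_factors, all_components = TRUE)
  }
  res <- preds - y
  structure(list(secv = sqrt(colSums(res^2) / n), residuals = res,
                 plan = plan),
            class = "cv_result")
}

#' Select the number of PLS factors
#'
#' Parsimony rule: the smallest factor count whose SECV is within 2% of
#' the minimum SECV on the curve.
#'
#' @param secv_curve Numeric vector, SECV per factor count.
#' @return Chosen factor count (integer).
#' @examples
#' select_factors(c(3, 1.00, 0.99, 1.5))  # 2
#' @export
select_factors <- function(secv_curve) {
  if (!length(secv_curve)) stop("empty SECV curve")
  which(secv_curve <= 1.02 * min(secv_curve))[1]
}

#' Outlier-elimination policy
#'
#' Calibration samples whose held-out residual satisfies
#' |residual| / SECV > \code{t_critical} are eliminated, in at most
#' \code{max_passes} rounds and never more than \code{max_removed}
#' samples in total.
#'
#' @param t_critical Threshold on |residual|/SECV (default 2.5).
#' @param max_passes Maximum removal rounds (default 2).
#' @param max_removed Cumulative cap on removals (default 6).
#' @return An object of class \code{outlier_policy}.
#' @export
outlier_policy <- function(t_critical = 2.5, max_passes = 2,
                           max_removed = 6) {
  if (t_critical <= 0) stop("t_critical must be > 0")
  if (max_removed < 0) stop("max_removed must be >= 0")
  structure(list(t_critical = t_critical, max_passes = max_passes,
                 max_removed = max_removed),
            class = "outlier_policy")
}

#' Calibrate one trait under one math treatment
#'
#' The full calibration loop: apply the math treatment, cross-validate to
#' pick the factor count, flag calibration samples whose cross-validation
#' residual exceeds the outlier policy's threshold, remove them (within
#' the policy's caps) and repeat, then fit the final mPLS model on the
#' retained samples.
#'
#' When SECV is numerically zero relative to the trait spread
#' (SECV < 1e-8 * SD(y)) the model is treated as exact and no outliers
#' are flagged; otherwise machine-precision residuals on noiseless data
#' would be flagged spuriously.
#'
#' @param spectra A raw \code{\link{spectra_set}} (calibration samples).
#' @param y Trait values, one per sample (same order as \code{spectra}).
#' @param treatment A \code{\link{math_treatment}} or treatment string.
#' @param policy An \code{\link{outlier_policy}}.
#' @param max_factors Largest factor count considered (default 10).
#' @param n_groups,seed Cross-validation plan settings.
#' @param scale_residuals Use mPLS residual scaling (default TRUE).
#' @return List of class \code{calibration}: \code{model} (an
#'   \code{mpls_model} carrying the treatment, frozen scatter parameters
#'   and removed outlier ids) and \code{stats} (a
#'   \code{calibration_stats}).
#' @export
calibrate <- function(spectra, y, treatment, policy = outlier_policy(),
                      max_factors = 10, n_groups = 5, seed = 1,
                      scale_residuals = TRUE) {
  if (is.character(treatment)) treatment <- parse_treatment(treatment)
  stopifnot(inherits(spectra, "spectra_set"))
  y <- as.numeric(y)
  if (length(y) != nrow(spectra$values)) stop("y length != sample count")
  treated <- apply_treatment(spectra, treatment)
  X <- treated$values
  ids <- rownames(X)
  n_input <- nrow(X)
  active <- seq_len(n_input)
  removed_ids <- character(0)
  pass <- 0L
  cv <- NULL
  k <- NULL
  repeat {
    cv <- cross_validate(X[active, , drop = FALSE], y[active], max_factors,
                         n_groups = n_groups, seed = seed,
                         scale_residuals = scale_residuals)
    k <- select_factors(cv$secv)
    if (pass >= policy$max_passes) break
    secv_k <- cv$secv[k]
    if (secv_k < 1e-8 * stats::sd(y[active])) break
    ratio <- abs(cv$residuals[, k]) / secv_k
    flagged <- which(ratio > policy$t_critical)
    if (!length(flagged)) break
    if (length(flagged) == length(active)) {
      stop("all calibration samples flagged as outliers")
    }
    allowed <- policy$max_removed - length(removed_ids)
    if (allowed <= 0) {
      warning("outlier cap (", policy$max_removed, ") reached; ",
              length(flagged), " flagged sample(s) retained")
      break
    }
    if (length(flagged) > allowed) {
      warning("outlier cap (", policy$max_removed, ") reached; removing ",
              allowed, " worst of ", length(flagged), " flagged samples")
      flagged <- flagged[order(ratio[flagged], decreasing = TRUE)][seq_len(allowed)]
    }
    removed_ids <- c(removed_ids, ids[active][flagged])
    active <- active[-flagged]
    pass <- pass + 1L
  }
  model <- fit_mpls(X[active, , drop = FALSE], y[active], k,
                    scale_residuals = scale_residuals)
  model$treatment <- treatment
  model$scatter_params <- attr(treated, "scatter_params")
  model$wavelengths <- treated$wavelengths
  model$removed_outlier_ids <- removed_ids
  model$secv_curve <- cv$secv
  residuals <- model$fitted - y[active]
  n_used <- length(active)
  sec_val <- sec(residuals, k)
  sst <- sum((y[active] - mean(y[active]))^2)
  rsq_cal <- min(max(1 - sum(residuals^2) / sst, 0), 1)
  stats <- structure(list(n_used = n_used,
                          n_outliers_removed = length(removed_ids),
                          n_factors = k,
                          SEC = sec_val,
                          SECV = cv$secv[k],
                          RSQ_cal = rsq_cal,
                          SD_cal = stats::sd(y[active])),
                     class = "calibration_stats")
  structure(list(model = model, stats = stats), class = "calibration")
}

#' @export
print.calibration_stats <- function(x, ...) {
  cat(sprintf(
    "calibration: n=%d (outliers removed %d), factors=%d, SEC=%.4g, SECV=%.4g, RSQ=%.3f\n",
    x$n_used, x$n_outliers_removed, x$n_factors, x$SEC, x$SECV, x$RSQ_cal))
  invisible(x)
}

#' Save and load mPLS models as JSON
#'
#' Versioned JSON serialisation of a calibrated model (treatment, grid,
#' centering, factors, residual scalings, removed outliers) so
#' predictions are reproducible across sessions.
#'
#' @param model An \code{mpls_model}.
#' @param path JSON file path.
#' @return \code{read_mpls_model}: the restored \code{mpls_model}.
#' @export
write_mpls_model <- function(model, path) {
  doc <- list(
    format = "nirbean-mpls-model",
    version = 1L,
    method = model$method,
    n_factors = model$n_factors,
    x_mean = model$x_mean,
    y_mean = model$y_mean,
    W = model$W, P = model$P, q = model$q,
    scales = model$scales,
    wavelengths = model$wavelengths,
    treatment = if (is.null(model$treatment)) NULL
                else format(model$treatment),
    scatter_params = model$scatter_params,
    removed_outlier_ids = model$removed_outlier_ids,
    secv_curve = model$secv_curve
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_mpls_model
#' @export
read_mpls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "nirbean-mpls-model")) {
    stop("not an mPLS model file: ", path)
  }
  model <- list(method = doc$method,
                x_mean = as.numeric(doc$x_mean),
                y_mean = as.numeric(doc$y_mean),
                W = as.matrix(doc$W), P = as.matrix(doc$P),
                q = as.numeric(doc$q),
                scales = if (is.null(doc$scales)) NULL else as.matrix(doc$scales),
                n_factors = as.integer(doc$n_factors),
                wavelengths = as.numeric(doc$wavelengths),
                treatment = if (is.null(doc$treatment)) NULL
                            else parse_treatment(doc$treatment),
                scatter_params = if (is.null(doc$scatter_params)) NULL else
                  lapply(doc$scatter_params, function(v)
                    if (is.null(v)) NULL else as.numeric(v)),
                removed_outlier_ids = as.character(doc$removed_outlier_ids %||%
                                                     character(0)),
                secv_curve = as.numeric(doc$secv_curve %||% numeric(0)))
  class(model) <- "mpls_model"
  model
}
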