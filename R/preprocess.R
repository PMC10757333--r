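## preprocess: scatter corrections and gap-segment derivative math
## treatments in the "derivative, gap, smooth1, smooth2" (d,g,s1,s2)
## convention of scanning-monochromator calibration software.

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

restore_shape <- function(out, x) {
  if (is.matrix(x)) out else drop(out)
}

#' Standard normal variate (SNV)
#'
#' Per-spectrum z-scoring: subtract the spectrum mean and divide by its
#' sample standard deviation (n-1 denominator). Removes particle-size
#' scatter; invariant to per-spectrum affine transforms.
#'
#' @param x Numeric vector (one spectrum) or matrix (samples x
#'   wavelengths).
#' @return Same shape as \code{x}; each spectrum has mean 0 and SD 1.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  m <- as_row_matrix(x)
  mu <- rowMeans(m)
  sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  if (any(sd <= 0 | !is.finite(sd))) {
    stop("degenerate (constant) spectrum in row ",
         which(sd <= 0 | !is.finite(sd))[1])
  }
  restore_shape((m - mu) / sd, x)
}

#' Detrend a spectrum
#'
#' Subtracts the least-squares polynomial of the given degree in
#' wavelength from each spectrum, removing baseline curvature. The
#' residual is orthogonal to the polynomial basis.
#'
#' @param x Numeric vector or matrix (samples x wavelengths).
#' @param degree Polynomial degree (default 2, quadratic baseline).
#' @param wavelengths Wavelength axis; defaults to the column index.
#' @return Same shape as \code{x}.
#' @export
detrend <- function(x, degree = 2, wavelengths = NULL) {
  m <- as_row_matrix(x)
  p <- ncol(m)
  if (degree >= p) stop("degree must be < number of points (", p, ")")
  wl <- if (is.null(wavelengths)) seq_len(p) else wavelengths
  if (length(wl) != p) stop("wavelengths length mismatch")
  basis <- cbind(1, stats::poly(wl, degree = degree))
  q <- qr.Q(qr(basis))
  restore_shape(m - (m %*% q) %*% t(q), x)
}

#' SNV followed by detrend (SNV-DT)
#'
#' @inheritParams detrend
#' @return Same shape as \code{x}; mean of each output spectrum is 0
#'   because the polynomial fit includes an intercept.
#' @export
snv_dt <- function(x, degree = 2, wavelengths = NULL) {
  detrend(snv(x), degree = degree, wavelengths = wavelengths)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum by ordinary least
#' squares, x ~ a + b * reference, and returns (x - a) / b. The default
#' reference is the mean spectrum of the set.
#'
#' @param x Numeric matrix (samples x wavelengths) or
#'   \code{\link{spectra_set}}.
#' @param reference Reference spectrum; defaults to the column mean.
#' @return List with \code{corrected} (same type as \code{x}) and
#'   \code{fit}, a \code{scatter_fit} holding per-sample intercepts
#'   \code{a}, slopes \code{b}, the reference, and (for WMSC) weights.
#' @export
msc <- function(x, reference = NULL) {
  wmsc_engine(x, reference = reference, weights = NULL, label = "MSC")
}

#' Weighted multiplicative scatter correction (WMSC)
#'
#' MSC with a per-wavelength weighted least-squares fit. Default weights
#' are the stabilised inverse across-sample variance,
#' w = 1 / (var + 1e-6 * max var), which down-weights wavelengths where
#' chemistry (not scatter) drives the variation. Uniform weights reduce
#' WMSC to MSC exactly.
#'
#' @inheritParams msc
#' @param weights Per-wavelength nonnegative weights, not all zero;
#'   \code{NULL} for the inverse-variance default.
#' @return As \code{\link{msc}}.
#' @export
wmsc <- function(x, weights = NULL, reference = NULL) {
  m <- if (inherits(x, "spectra_set")) x$values else as.matrix(x)
  if (is.null(weights)) {
    if (nrow(m) < 2) stop("default WMSC weights need >= 2 samples")
    v <- apply(m, 2, stats::var)
    weights <- 1 / (v + 1e-6 * max(v))
  }
  wmsc_engine(x, reference = reference, weights = weights, label = "WMSC")
}

wmsc_engine <- function(x, reference, weights, label) {
  m <- if (inherits(x, "spectra_set")) x$values else as.matrix(x)
  p <- ncol(m)
  if (is.null(reference)) {
    if (nrow(m) < 2) stop(label, " needs >= 2 samples or an explicit reference")
    reference <- colMeans(m)
  }
  if (length(reference) != p) stop("reference length mismatch")
  w <- if (is.null(weights)) rep(1, p) else weights
  if (length(w) != p || any(w < 0) || all(w == 0)) {
    stop("weights must be nonnegative, length ", p, ", not all zero")
  }
  sw <- sum(w)
  rbar <- sum(w * reference) / sw
  sxx <- sum(w * (reference - rbar)^2)
  if (sxx <= 0) stop("reference spectrum has no weighted variation")
  a <- numeric(nrow(m))
  b <- numeric(nrow(m))
  out <- m
  for (i in seq_len(nrow(m))) {
    xi <- m[i, ]
    xbar <- sum(w * xi) / sw
    b[i] <- sum(w * (reference - rbar) * (xi - xbar)) / sxx
    a[i] <- xbar - b[i] * rbar
    if (abs(b[i]) <= 1e-8) {
      stop("degenerate ", label, " fit (|slope| <= 1e-8) for sample ",
           rownames(m)[i] %||% i)
    }
    out[i, ] <- (xi - a[i]) / b[i]
  }
  fit <- structure(list(a = a, b = b, reference = reference,
                        weights = weights, method = label),
                   class = "scatter_fit")
  corrected <- if (inherits(x, "spectra_set")) {
    spectra_set(out, x$wavelengths, crop = if (is.null(x$crop)) NULL
                else unname(x$crop))
  } else restore_shape(out, x)
  list(corrected = corrected, fit = fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moving-average smoothing
#'
#' Boxcar mean over \code{s} consecutive points, valid region only: the
#' output has n - s + 1 points and no fabricated edge values. \code{s = 1}
#' is the identity.
#'
#' @param x Numeric vector or matrix (samples x wavelengths).
#' @param s Window length in points, 1 <= s <= n.
#' @return Smoothed spectrum/spectra, n - s + 1 points.
#' @examples
#' moving_average(c(1, 2, 3, 4), 2)  # 1.5 2.5 3.5
#' @export
moving_average <- function(x, s) {
  m <- as_row_matrix(x)
  n <- ncol(m)
  s <- as.integer(s)
  if (s < 1) stop("window s must be >= 1")
  if (s > n) stop("window s = ", s, " exceeds spectrum length ", n)
  if (s == 1) return(x)
  nout <- n - s + 1L
  acc <- m[, seq_len(nout), drop = FALSE]
  for (k in seq_len(s - 1L)) {
    acc <- acc + m[, k + seq_len(nout), drop = FALSE]
  }
  restore_shape(acc / s, x)
}

## Wavelength axes for the valid-region operators: a moving average is
## labelled by the window centre, a gap difference by its left point.
ma_wavelengths <- function(wl, s) {
  if (s == 1) return(wl)
  n <- length(wl)
  (wl[seq_len(n - s + 1)] + wl[s:n]) / 2
}

gap_wavelengths <- function(wl, g, d) {
  if (d == 0) return(wl)
  wl[seq_len(length(wl) - d * g)]
}

#' Gap-segment derivative
#'
#' The math-treatment pipeline: smooth with a moving average of
#' \code{s1} points, apply the forward gap difference
#' D_g(x)(i) = x(i + g) - x(i) \code{d} times, then smooth with
#' \code{s2} points. Edges are truncated (valid region only);
#' \code{d = 0, s1 = s2 = 1} is the identity. The operator is linear and
#' annihilates polynomials of degree < d.
#'
#' @param x Numeric vector or matrix (samples x wavelengths).
#' @param d Derivative order, 0--4.
#' @param g Gap in grid points, >= 1.
#' @param s1,s2 First and second smoothing windows (1 = none).
#' @return Transformed spectrum/spectra, length n - d*g - s1 - s2 + 2.
#' @examples
#' gap_segment_derivative(seq_len(20), d = 1, g = 6)  # constant 6
#' @export
gap_segment_derivative <- function(x, d, g, s1 = 1, s2 = 1) {
  m <- as_row_matrix(x)
  n <- ncol(m)
  d <- as.integer(d); g <- as.integer(g)
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  if (d < 0 || d > 4) stop("derivative order d must be in 0..4")
  if (g < 1 || s1 < 1 || s2 < 1) stop("g, s1, s2 must be >= 1")
  need <- d * g + s1 + s2 - 1L
  if (n < need) {
    stop("spectrum length ", n, " too short; treatment needs >= ", need,
         " points")
  }
  out <- moving_average(m, s1)
  for (k in seq_len(d)) {
    p <- ncol(out)
    out <- out[, (1L + g):p, drop = FALSE] - out[, 1L:(p - g), drop = FALSE]
  }
  out <- moving_average(out, s2)
  restore_shape(out, x)
}

#' Math treatments
#'
#' A math treatment is the full preprocessing recipe "d,g,s1,s2" plus a
#' scatter-correction method: derivative order, gap (points), first and
#' second moving-average windows (1 = no smoothing), and one of
#' none / SNV / DT / SNV-DT / MSC / WMSC applied before the derivative.
#'
#' \code{parse_treatment} accepts the canonical "d,g,s1,s2" form,
#' optionally suffixed ":SCATTER" (e.g. \code{"3,6,6,1:SNV-DT"}), and the
#' compact digit-run forms that appear in published model tables
#' (\code{"2,441"} = 2,4,4,1; \code{"310,102"} = 3,10,10,2).
#'
#' @param d,g,s1,s2 Treatment integers (see above).
#' @param scatter Scatter method name.
#' @return An object of class \code{math_treatment}.
#' @examples
#' parse_treatment("3,6,6,1:SNV-DT")
#' format(math_treatment(2, 4, 4, 1, "WMSC"))
#' @export
math_treatment <- function(d, g, s1, s2, scatter = "none") {
  d <- as.integer(d); g <- as.integer(g)
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  if (is.na(d) || d < 0 || d > 4) stop("d must be an integer in 0..4")
  if (any(is.na(c(g, s1, s2))) || g < 1 || s1 < 1 || s2 < 1) {
    stop("g, s1, s2 must be integers >= 1")
  }
  scatter <- normalize_scatter(scatter)
  structure(list(d = d, g = g, s1 = s1, s2 = s2, scatter = scatter),
            class = "math_treatment")
}

scatter_methods <- c("none", "SNV", "DT", "SNV_DT", "MSC", "WMSC")

normalize_scatter <- function(scatter) {
  s <- gsub("-", "_", toupper(trimws(scatter)))
  if (s %in% c("NONE", "")) s <- "none"
  if (!s %in% scatter_methods) {
    stop("unknown scatter method '", scatter, "'; expected one of ",
         paste(scatter_methods, collapse = ", "))
  }
  s
}

#' @rdname math_treatment
#' @param text Treatment string.
#' @export
parse_treatment <- function(text, scatter = NULL) {
  parts <- strsplit(trimws(text), ":", fixed = TRUE)[[1]]
  if (length(parts) > 2) stop("malformed treatment string: ", text)
  if (length(parts) == 2) {
    if (!is.null(scatter)) stop("scatter given both in string and argument")
    scatter <- parts[2]
  }
  if (is.null(scatter)) scatter <- "none"
  fields <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  if (length(fields) == 4) {
    nums <- suppressWarnings(as.integer(fields))
  } else {
    digits <- gsub("[, ]", "", parts[1])
    if (!grepl("^[0-9]+$", digits)) stop("malformed treatment string: ", text)
    nums <- switch(as.character(nchar(digits)),
      "4" = as.integer(strsplit(digits, "")[[1]]),
      ## d, two-digit gap and smooth1, one-digit smooth2 (e.g. 310102)
      "6" = as.integer(c(substr(digits, 1, 1), substr(digits, 2, 3),
                         substr(digits, 4, 5), substr(digits, 6, 6))),
      stop("cannot parse treatment digits '", digits, "'"))
  }
  if (anyNA(nums)) stop("malformed treatment string: ", text)
  math_treatment(nums[1], nums[2], nums[3], nums[4], scatter)
}

#' @rdname math_treatment
#' @param x A \code{math_treatment}.
#' @param ... Unused.
#' @export
format.math_treatment <- function(x, ...) {
  base <- paste(x$d, x$g, x$s1, x$s2, sep = ",")
  if (x$scatter == "none") base
  else paste0(base, ":", gsub("_", "-", x$scatter))
}

#' @export
print.math_treatment <- function(x, ...) {
  cat("math_treatment", format(x), "\n")
  invisible(x)
}

#' Apply a math treatment to a spectra set
#'
#' Scatter correction is applied first, on the full-length log(1/R)
#' spectra, then the gap-segment derivative pipeline. The output carries
#' its (truncated, possibly shifted) wavelength axis. For MSC/WMSC the
#' reference spectrum and weights are estimated from the set unless frozen
#' parameters from a calibration run are supplied, and are returned in the
#' \code{"scatter_params"} attribute so validation spectra can be treated
#' consistently.
#'
#' @param set A \code{\link{spectra_set}}.
#' @param treatment A \code{\link{math_treatment}} or treatment string.
#' @param scatter_params Frozen MSC/WMSC parameters (list with
#'   \code{reference} and \code{weights}) from a previous call.
#' @return A treated \code{spectra_set} with attributes \code{treatment}
#'   and (for MSC/WMSC) \code{scatter_params}.
#' @export
apply_treatment <- function(set, treatment, scatter_params = NULL) {
  if (is.character(treatment)) treatment <- parse_treatment(treatment)
  stopifnot(inherits(set, "spectra_set"), inherits(treatment, "math_treatment"))
  m <- set$values
  wl <- set$wavelengths
  params <- NULL
  if (treatment$scatter == "SNV") {
    m <- snv(m)
  } else if (treatment$scatter == "DT") {
    m <- detrend(m, degree = 2, wavelengths = wl)
  } else if (treatment$scatter == "SNV_DT") {
    m <- snv_dt(m, degree = 2, wavelengths = wl)
  } else if (treatment$scatter %in% c("MSC", "WMSC")) {
    ref <- scatter_params$reference
    wts <- scatter_params$weights
    res <- if (treatment$scatter == "MSC") {
      msc(m, reference = ref)
    } else if (is.null(wts) && is.null(scatter_params)) {
      wmsc(m, reference = ref)
    } else {
      wmsc_engine(m, reference = ref, weights = wts, label = "WMSC")
    }
    m <- res$corrected
    params <- list(reference = res$fit$reference, weights = res$fit$weights)
  }
  out <- gap_segment_derivative(m, treatment$d, treatment$g,
                                treatment$s1, treatment$s2)
  wl2 <- ma_wavelengths(wl, treatment$s1)
  wl2 <- gap_wavelengths(wl2, treatment$g, treatment$d)
  wl2 <- ma_wavelengths(wl2, treatment$s2)
  res <- spectra_set(out, wl2,
                     crop = if (is.null(set$crop)) NULL else unname(set$crop))
  attr(res, "treatment") <- treatment
  attr(res, "scatter_params") <- params
  res
}
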