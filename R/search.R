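## search: exhaustive math-treatment grid search and best-model selection.

#' Math-treatment search grid
#'
#' The Cartesian grid of preprocessing recipes swept during model
#' development. Defaults cover derivative orders 1--4, gaps 4--16 in
#' steps of 2, smoothing windows {1,2,4,6} x {1,2}, and the scatter
#' methods none / SNV / SNV-DT / WMSC (896 treatments).
#'
#' @param derivative_orders,gaps,smooth1,smooth2 Integer sets.
#' @param scatter Scatter method names.
#' @return An object of class \code{search_grid}.
#' @export
search_grid <- function(derivative_orders = c(1, 2, 3, 4),
                        gaps = c(4, 6, 8, 10, 12, 14, 16),
                        smooth1 = c(1, 2, 4, 6),
                        smooth2 = c(1, 2),
                        scatter = c("none", "SNV", "SNV_DT", "WMSC")) {
  if (!length(derivative_orders) || !length(gaps) || !length(smooth1) ||
      !length(smooth2) || !length(scatter)) {
    stop("all grid dimensions must be nonempty")
  }
  scatter <- vapply(scatter, normalize_scatter, character(1),
                    USE.NAMES = FALSE)
  structure(list(derivative_orders = sort(unique(derivative_orders)),
                 gaps = sort(unique(gaps)),
                 smooth1 = sort(unique(smooth1)),
                 smooth2 = sort(unique(smooth2)),
                 scatter = unique(scatter)),
            class = "search_grid")
}

#' Enumerate the treatments of a search grid
#'
#' Full Cartesian product in deterministic lexicographic order
#' (scatter, derivative, gap, smooth1, smooth2).
#'
#' @param grid A \code{\link{search_grid}}.
#' @return List of \code{\link{math_treatment}} objects.
#' @export
enumerate_treatments <- function(grid) {
  stopifnot(inherits(grid, "search_grid"))
  combos <- expand.grid(s2 = grid$smooth2, s1 = grid$smooth1,
                        g = grid$gaps, d = grid$derivative_orders,
                        scatter = grid$scatter,
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    math_treatment(combos$d[i], combos$g[i], combos$s1[i], combos$s2[i],
                   combos$scatter[i])
  })
}

#' Evaluate one math treatment
#'
#' Runs the full calibration loop under one treatment and scores it on
#' the validation set. Degenerate treatments (e.g. a gap exceeding the
#' spectrum) are reported as skipped, not errors, so one bad combination
#' cannot abort a sweep.
#'
#' @param treatment A \code{\link{math_treatment}} or string.
#' @param cal_spectra,cal_y Calibration spectra (raw) and trait values.
#' @param val_spectra,val_y Validation spectra (raw) and trait values.
#' @param policy An \code{\link{outlier_policy}}.
#' @param max_factors,n_groups,seed Passed to \code{\link{calibrate}}.
#' @param scale_residuals Use mPLS residual scaling.
#' @return List: \code{ok} (logical); on success \code{calibration},
#'   \code{validation}, \code{row} (one-row data frame); on failure
#'   \code{reason}.
#' @export
evaluate_treatment <- function(treatment, cal_spectra, cal_y,
                               val_spectra, val_y,
                               policy = outlier_policy(),
                               max_factors = 10, n_groups = 5, seed = 1,
                               scale_residuals = TRUE) {
  if (is.character(treatment)) treatment <- parse_treatment(treatment)
  res <- tryCatch({
    cal <- calibrate(cal_spectra, cal_y, treatment, policy = policy,
                     max_factors = max_factors, n_groups = n_groups,
                     seed = seed, scale_residuals = scale_residuals)
    val <- validation_report(cal$model, val_spectra, val_y)
    list(ok = TRUE, calibration = cal, validation = val,
         row = stats_row(treatment, cal$stats, val))
  }, error = function(e) {
    list(ok = FALSE, reason = conditionMessage(e))
  })
  res$treatment <- treatment
  res
}

#' Exhaustive treatment search for one trait
#'
#' Evaluates every treatment in the grid on a fixed
#' calibration/validation split and ranks the results. The default
#' criterion ranks by validation RSQ (descending), breaking ties by RPD,
#' then fewer factors, then the treatment string; \code{"rpd"} swaps the
#' first two keys.
#'
#' @inheritParams evaluate_treatment
#' @param grid A \code{\link{search_grid}}.
#' @param criterion "rsq" or "rpd".
#' @return List of class \code{search_result}: \code{table} (ranked data
#'   frame), \code{best} (top row), \code{best_treatment},
#'   \code{skipped} (treatments that could not be evaluated, with
#'   reasons).
#' @export
search_best <- function(grid, cal_spectra, cal_y, val_spectra, val_y,
                        criterion = c("rsq", "rpd"),
                        policy = outlier_policy(),
                        max_factors = 10, n_groups = 5, seed = 1,
                        scale_residuals = TRUE) {
  criterion <- match.arg(criterion)
  treatments <- enumerate_treatments(grid)
  rows <- list()
  kept <- list()
  skipped <- list()
  for (tr in treatments) {
    ev <- evaluate_treatment(tr, cal_spectra, cal_y, val_spectra, val_y,
                             policy = policy, max_factors = max_factors,
                             n_groups = n_groups, seed = seed,
                             scale_residuals = scale_residuals)
    if (ev$ok) {
      rows[[length(rows) + 1L]] <- ev$row
      kept[[length(kept) + 1L]] <- tr
    } else {
      skipped[[length(skipped) + 1L]] <-
        data.frame(treatment = format(tr), reason = ev$reason,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no treatment could be evaluated")
  tab <- do.call(rbind, rows)
  ord <- if (criterion == "rsq") {
    order(-tab$RSQ_ext, -tab$RPD, tab$n_factors, tab$treatment)
  } else {
    order(-tab$RPD, -tab$RSQ_ext, tab$n_factors, tab$treatment)
  }
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 best = tab[1, , drop = FALSE],
                 best_treatment = kept[ord][[1]],
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else NULL,
                 criterion = criterion),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("treatment search:", nrow(x$table), "evaluated",
      if (!is.null(x$skipped)) paste0("(", nrow(x$skipped), " skipped)"),
      "- criterion", x$criterion, "\n")
  cat("best:", x$best$treatment, sprintf("RSQ_ext=%.3f RPD=%.2f\n",
                                         x$best$RSQ_ext, x$best$RPD))
  invisible(x)
}
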