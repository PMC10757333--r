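test_that("PLS1 fits a rank-1 noiseless problem with one factor", {
  set.seed(10)
  v <- rnorm(30)
  c_scores <- rnorm(12, 5, 2)
  X <- outer(c_scores, v)
  for (fit in list(fit_pls1_nipals(X, c_scores, 1),
                   fit_mpls(X, c_scores, 1))) {
    expect_lt(max(abs(fit$fitted - c_scores)), 1e-9)
  }
})

test_that("full-rank PLS1 and mPLS(scale off) agree with OLS", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 15), 20, 15)
    y <- rnorm(20)
    ols <- lm.fit(cbind(1, X), y)$fitted.values
    pls <- fit_pls1_nipals(X, y, 15)
    mp <- fit_mpls(X, y, 15, scale_residuals = FALSE)
    expect_lt(max(abs(pls$fitted - ols)), 1e-6)
    expect_lt(max(abs(mp$fitted - pls$fitted)), 1e-8)
  }
})

test_that("fitting is equivariant under sample permutation", {
  prob <- mixture_problem(noise = 0.01)
  perm <- sample(nrow(prob$X))
  a <- fit_pls1_nipals(prob$X, prob$y, 3)
  b <- fit_pls1_nipals(prob$X[perm, ], prob$y[perm], 3)
  expect_equal(b$fitted, a$fitted[perm], tolerance = 1e-9)
})

test_that("mPLS residual scaling keeps training error comparable to PLS1", {
  ## noise well above the exact-fit floor, so SEC reflects model quality
  prob <- mixture_problem(noise = 0.1)
  sec_m <- numeric(5); sec_p <- numeric(5)
  sse_m <- numeric(5); sse_p <- numeric(5)
  for (k in 1:5) {
    m <- fit_mpls(prob$X, prob$y, k)
    p <- fit_pls1_nipals(prob$X, prob$y, k)
    sse_m[k] <- sum((m$fitted - prob$y)^2)
    sse_p[k] <- sum((p$fitted - prob$y)^2)
    sec_m[k] <- sec(m$fitted - prob$y, k)
    sec_p[k] <- sec(p$fitted - prob$y, k)
  }
  expect_true(all(diff(sse_m) <= 1e-10))  # training SSE monotone in k
  expect_true(all(diff(sse_p) <= 1e-10))
  expect_true(all(diff(sec_m) <= 1e-10))  # SEC too, on this fixture
  expect_true(all(diff(sec_p) <= 1e-10))
  expect_lte(sec_m[5], 1.5 * sec_p[5])
})

test_that("prediction replays the stored path", {
  prob <- mixture_problem(noise = 0.01)
  m <- fit_mpls(prob$X, prob$y, 4)
  expect_equal(predict(m, prob$X), m$fitted, tolerance = 1e-9)
  ## duplicated row gives duplicated prediction
  two <- predict(m, prob$X[c(1, 1), ])
  expect_equal(two[1], two[2])
  ## mean spectrum with a 1-factor model predicts the mean response
  m1 <- fit_mpls(prob$X, prob$y, 1)
  expect_equal(unname(predict(m1, colMeans(prob$X))), mean(prob$y),
               tolerance = 1e-9)
  expect_error(predict(m, prob$X[, 1:10]), "grid mismatch")
})

test_that("cross-validation: exact recovery, determinism, LOO oracle", {
  ## noiseless two-constituent spectra; y a linear blend of both
  set.seed(5)
  wl <- seq_len(40)
  pure <- cbind(exp(-(wl - 12)^2 / 60), exp(-(wl - 28)^2 / 90))
  C <- cbind(rnorm(20, 10, 2), rnorm(20, 5, 1))
  X <- C %*% t(pure)
  y2 <- C[, 1] + 0.5 * C[, 2]
  cv <- cross_validate(X, y2, max_factors = 2, n_groups = 5, seed = 2)
  expect_lt(cv$secv[2], 1e-6 * sd(y2))
  cv_again <- cross_validate(X, y2, max_factors = 2, n_groups = 5,
                             seed = 2)
  expect_identical(cv$secv, cv_again$secv)

  ## leave-one-out matches brute-force refits
  noisy <- mixture_problem(n = 14, p = 20, noise = 0.05, seed = 6)
  loo <- cross_validate(noisy$X, noisy$y, max_factors = 3,
                        n_groups = nrow(noisy$X), seed = 1)
  brute <- sapply(seq_len(nrow(noisy$X)), function(i) {
    f <- fit_mpls(noisy$X[-i, ], noisy$y[-i], 3)
    predict(f, noisy$X[i, , drop = FALSE], ncomp = 3)
  })
  expect_equal(sqrt(mean((brute - noisy$y)^2)), loo$secv[3],
               tolerance = 1e-10)
  expect_error(cross_validate(noisy$X, noisy$y, max_factors = 12,
                              n_groups = 5), "infeasible")
})

test_that("factor selection follows the 2% parsimony rule", {
  expect_equal(select_factors(c(5, 4, 3, 2, 1)), 5)
  expect_equal(select_factors(rep(2, 6)), 1)
  expect_equal(select_factors(c(3, 1.00, 0.99, 1.5)), 2)
  expect_equal(select_factors(c(1.05, 1.0, 0.999)), 2)
  expect_error(select_factors(numeric(0)), "empty")
})

test_that("calibration removes an injected outlier and nothing else", {
  ds <- make_benchmark_dataset("clean", seed = 21)
  sp <- split_calibration_validation(ds$spectra, 5, seed = 4)
  cal_set <- ds$spectra[sp$calibration_ids]
  y <- ds$refs$protein[match(sp$calibration_ids, ds$refs$sample_id)]

  ## scatter "none": clean-preset spectra are exactly linear in the
  ## traits, so cross-validation residuals are numerically zero
  clean_run <- calibrate(cal_set, y, "1,4,4,1", seed = 9)
  expect_equal(clean_run$stats$n_outliers_removed, 0)
  expect_equal(clean_run$stats$n_used, length(y))

  y_bad <- y
  bad_idx <- 7
  y_bad[bad_idx] <- y_bad[bad_idx] + 10 * sd(y)
  bad_run <- calibrate(cal_set, y_bad, "1,4,4,1", seed = 9)
  expect_identical(bad_run$model$removed_outlier_ids,
                   sp$calibration_ids[bad_idx])
  expect_lte(bad_run$stats$n_outliers_removed, 6)
})

test_that("outlier removals never exceed the policy cap", {
  ds <- make_benchmark_dataset("noisy", seed = 31)
  sp <- split_calibration_validation(ds$spectra, 5, seed = 5)
  y <- ds$refs$protein[match(sp$calibration_ids, ds$refs$sample_id)]
  ## corrupt many samples; the cap must still hold
  y[1:10] <- y[1:10] + 8 * sd(y)
  run <- suppressWarnings(
    calibrate(ds$spectra[sp$calibration_ids], y, "1,4,4,1:SNV", seed = 9))
  expect_lte(run$stats$n_outliers_removed, 6)
})

test_that("calibration is reproducible and serialises to JSON", {
  ds <- make_benchmark_dataset("paper_like", seed = 13)
  sp <- split_calibration_validation(ds$spectra, 5, seed = 2)
  y <- ds$refs$starch[match(sp$calibration_ids, ds$refs$sample_id)]
  a <- calibrate(ds$spectra[sp$calibration_ids], y, "2,4,4,1:WMSC", seed = 3)
  b <- calibrate(ds$spectra[sp$calibration_ids], y, "2,4,4,1:WMSC", seed = 3)
  expect_identical(a$model$fitted, b$model$fitted)
  expect_identical(a$stats, b$stats)

  path <- withr::local_tempfile(fileext = ".json")
  write_mpls_model(a$model, path)
  back <- read_mpls_model(path)
  val <- ds$spectra[sp$validation_ids]
  expect_equal(predict(back, val), predict(a$model, val), tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_mpls(X, rep(1, 10), 2), "zero variance")
  expect_error(fit_mpls(X, rnorm(10), 9), "n_samples")
})
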