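test_that("SNV closed form, idempotence and affine invariance", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-12)
  expect_equal(snv(5 * x + 2), snv(x), tolerance = 1e-12)
  m <- rbind(x, 3 * x - 1)
  s <- snv(m)
  expect_equal(unname(rowMeans(s)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(s, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(snv(rep(2, 10)), "degenerate")
})

test_that("detrend removes polynomial baselines and nothing else", {
  wl <- seq(400, 598, 2)
  quad <- 0.5 + 0.01 * wl - 2e-5 * wl^2
  expect_equal(detrend(quad, 2, wl), rep(0, length(wl)), tolerance = 1e-9)
  set.seed(2)
  x <- rnorm(length(wl))
  expect_equal(detrend(x + quad, 2, wl), detrend(x, 2, wl),
               tolerance = 1e-9)
  ## residual orthogonal to the polynomial basis: refitting finds ~0
  r <- detrend(x, 2, wl)
  refit <- lm(r ~ wl + I(wl^2))
  expect_lt(max(abs(coef(refit))), 1e-9)
  expect_error(detrend(c(1, 2), degree = 2), "degree")
})

test_that("SNV-DT composes the two public operations", {
  wl <- seq(400, 478, 2)
  set.seed(3)
  x <- rnorm(length(wl))
  expect_equal(snv_dt(x, wavelengths = wl),
               detrend(snv(x), 2, wl), tolerance = 1e-12)
  expect_lt(abs(mean(snv_dt(x, wavelengths = wl))), 1e-9)
  ## quadratic-only input: nonzero SD so SNV passes, detrend zeroes it
  quad <- (wl - 440)^2
  expect_equal(snv_dt(quad, wavelengths = wl), rep(0, length(wl)),
               tolerance = 1e-9)
})

test_that("MSC inverts affine scatter against the reference", {
  set.seed(4)
  ref <- abs(rnorm(40)) + seq(0, 1, length.out = 40)
  x <- 1 + 2 * ref
  res <- msc(rbind(x, ref), reference = ref)
  expect_equal(unname(res$corrected[1, ]), ref, tolerance = 1e-9)
  expect_equal(res$fit$a, c(1, 0), tolerance = 1e-8)
  expect_equal(res$fit$b, c(2, 1), tolerance = 1e-8)
  ## refit oracle: corrected spectra regress on ref with a=0, b=1
  m <- rbind(0.5 + 1.5 * ref + rnorm(40, sd = 1e-3),
             -0.2 + 0.8 * ref + rnorm(40, sd = 1e-3))
  cor2 <- msc(m, reference = ref)$corrected
  for (i in 1:2) {
    fit <- lm(cor2[i, ] ~ ref)
    expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-2)
  }
  flat <- rbind(rep(1e-10, 40) * ref, ref)
  expect_error(msc(flat, reference = ref), "degenerate")
})

test_that("WMSC reduces to MSC under uniform weights and matches an
           independent minimiser of the weighted SSE", {
  set.seed(5)
  ref <- cumsum(abs(rnorm(10)))
  m <- rbind(1 + 2 * ref + rnorm(10, sd = 0.05),
             0.3 + 0.7 * ref + rnorm(10, sd = 0.05))
  u <- wmsc(m, weights = rep(1, 10), reference = ref)
  mm <- msc(m, reference = ref)
  expect_equal(u$corrected, mm$corrected, tolerance = 1e-9)
  expect_equal(u$fit$a, mm$fit$a, tolerance = 1e-9)

  w <- c(0.2, 1, 3, 0.5, 2, 0.1, 1, 1, 4, 0.7)
  fit <- wmsc(m, weights = w, reference = ref)$fit
  for (i in 1:2) {
    sse <- function(par) sum(w * (m[i, ] - par[1] - par[2] * ref)^2)
    opt <- optim(c(0, 1), sse, control = list(reltol = 1e-14,
                                              maxit = 5000))
    expect_equal(c(fit$a[i], fit$b[i]), opt$par, tolerance = 1e-4)
    expect_lte(sse(c(fit$a[i], fit$b[i])), opt$value + 1e-10)
  }

  ## exact affine recovery: x = 1 + 2*ref corrected back to ref
  aff <- wmsc(rbind(1 + 2 * ref, ref), weights = w, reference = ref)
  expect_equal(unname(aff$corrected[1, ]), ref, tolerance = 1e-9)

  ## default weights are inverse across-sample variance (stabilised)
  expect_error(wmsc(m, weights = rep(0, 10)), "not all zero")
})

test_that("moving average is the valid-region boxcar mean", {
  expect_equal(moving_average(c(1, 2, 3, 4), 1), c(1, 2, 3, 4))
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1.5, 2.5, 3.5))
  ramp <- 3 * seq_len(30) + 2
  for (s in c(2, 5, 7)) {
    out <- moving_average(ramp, s)
    expect_length(out, 30 - s + 1)
    expect_equal(unique(round(diff(out), 12)), 3)
  }
  expect_error(moving_average(1:3, 4), "exceeds")
})

test_that("gap derivative: ramps, constants, quadratics, linearity", {
  i <- seq_len(50)
  expect_equal(gap_segment_derivative(i, d = 1, g = 6),
               rep(6, 44))
  expect_equal(gap_segment_derivative(rep(3.2, 30), d = 2, g = 4),
               rep(0, 22))
  for (g in c(2, 5, 9)) {
    expect_equal(gap_segment_derivative(i^2, d = 2, g = g),
                 rep(2 * g^2, 50 - 2 * g), tolerance = 1e-10)
  }
  ## polynomial of degree < d is annihilated
  cubic <- 1 + i - 0.5 * i^2 + 0.01 * i^3
  out <- gap_segment_derivative(cubic, d = 4, g = 3)
  expect_lt(max(abs(out)) / max(abs(cubic)), 1e-8)
  ## linearity
  set.seed(6)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(gap_segment_derivative(2 * x + 3 * y, 2, 4, 3, 2),
               2 * gap_segment_derivative(x, 2, 4, 3, 2) +
                 3 * gap_segment_derivative(y, 2, 4, 3, 2),
               tolerance = 1e-10)
  expect_error(gap_segment_derivative(1:5, d = 2, g = 4), ">= 9")
  expect_equal(gap_segment_derivative(x, 0, 1, 1, 1), x)
})

test_that("treatment strings parse in canonical and compact table forms", {
  tr <- parse_treatment("3,6,6,1:SNV-DT")
  expect_equal(unclass(tr)[c("d", "g", "s1", "s2")],
               list(d = 3L, g = 6L, s1 = 6L, s2 = 1L))
  expect_equal(tr$scatter, "SNV_DT")
  expect_equal(format(tr), "3,6,6,1:SNV-DT")

  compact <- parse_treatment("2,441")
  expect_equal(format(compact), "2,4,4,1")
  long <- parse_treatment("310,102", scatter = "WMSC")
  expect_equal(format(long), "3,10,10,2:WMSC")
  expect_equal(format(parse_treatment("310102")), "3,10,10,2")

  expect_error(parse_treatment("9,1,1,1"), "0..4")
  expect_error(parse_treatment("abc"), "malformed")
  expect_error(math_treatment(1, 0, 1, 1), ">= 1")
})

test_that("apply_treatment composes scatter and derivative deterministically", {
  set <- random_spectra_set(5, 60, seed = 8)
  ident <- apply_treatment(set, "0,1,1,1")
  expect_equal(ident$values, set$values)
  expect_equal(ident$wavelengths, set$wavelengths)

  manual <- gap_segment_derivative(set$values, 2, 4, 4, 1)
  auto <- apply_treatment(set, "2,4,4,1")
  expect_equal(auto$values, manual)
  expect_length(auto$wavelengths, ncol(manual))

  ## hand-composed reference for the flagship treatment
  hand <- gap_segment_derivative(
    detrend(snv(set$values), 2, set$wavelengths), 3, 6, 6, 1)
  expect_equal(apply_treatment(set, "3,6,6,1:SNV-DT")$values, hand,
               tolerance = 1e-12)

  ## purity: repeated application is identical
  expect_identical(apply_treatment(set, "3,6,6,1:SNV-DT")$values,
                   apply_treatment(set, "3,6,6,1:SNV-DT")$values)

  ## frozen MSC parameters reproduce the calibration-time correction
  res <- apply_treatment(set, "1,4,1,1:MSC")
  params <- attr(res, "scatter_params")
  again <- apply_treatment(set, "1,4,1,1:MSC", scatter_params = params)
  expect_equal(again$values, res$values, tolerance = 1e-12)
})
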