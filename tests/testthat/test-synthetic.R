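test_that("component library peaks where the chemistry says", {
  lib <- default_component_library()
  moisture <- lib$components$moisture$values
  peak_wl <- lib$wavelengths[which.max(moisture)]
  expect_lte(abs(peak_wl - 1964), 50)  # within one band width
  for (cmp in lib$components) {
    expect_true(all(cmp$values >= 0))
  }
  lib2 <- default_component_library()
  expect_identical(lib, lib2)
})

test_that("trait distribution registry matches the reference population", {
  d <- table1_distributions()
  expect_length(d, 18)
  expect_equal(d$starch$max, 47.3)
  expect_equal(d$protein$mean, 22)
  expect_equal(d$phytate$sd, 0.346)
  for (t in d) {
    expect_lt(t$min, t$max)
    expect_gte(t$mean, t$min)
    expect_lte(t$mean, t$max)
    expect_gt(t$sd, 0)
  }
  expect_error(trait_distribution("x", 5, 1, 6, 10), "within")
})

test_that("concentration sampling is truncated, seeded, and well-calibrated", {
  d <- table1_distributions()
  conc <- sample_concentrations(d, 200, seed = 3)
  for (t in d) {
    v <- conc[[t$trait]]
    expect_true(all(v >= t$min & v <= t$max))
  }
  expect_identical(conc, sample_concentrations(d, 200, seed = 3))

  ## sample mean vs the closed-form truncated-normal mean
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  big <- sample_concentrations(d[c("protein", "fat", "anthocyanin")],
                               10000, seed = 5)
  for (nm in c("protein", "fat", "anthocyanin")) {
    t <- d[[nm]]
    expect_equal(mean(big[[nm]]),
                 trunc_mean(t$mean, t$sd, t$min, t$max),
                 tolerance = 0.02 * (t$max - t$min), ignore_attr = TRUE)
  }
})

test_that("spectra are exact Beer-Lambert mixtures in the noiseless case", {
  lib <- default_component_library(small_grid(200, 1900, 2))
  conc <- data.frame(sample_id = "A", protein = 1)
  out <- generate_spectra(conc, lib,
                          scatter_noise_model(0, 0, 0, baseline = 0),
                          seed = 1)
  pure <- lib$components$protein$values / (100 * max(lib$components$protein$values))
  expect_equal(unname(out$spectra$values[1, ]), pure, tolerance = 1e-12)

  ds1 <- make_benchmark_dataset("paper_like", seed = 4)
  ds2 <- make_benchmark_dataset("paper_like", seed = 4)
  expect_identical(ds1$spectra$values, ds2$spectra$values)
  expect_identical(ds1$refs, ds2$refs)
  expect_error(generate_spectra(data.frame(sample_id = "A", fe = 1), lib),
               "no library constituent")
})

test_that("MSC undoes simulated scatter on replicates of one composition", {
  d <- table1_distributions()
  one <- sample_concentrations(d, 1, seed = 9)
  reps <- one[rep(1, 15), ]
  reps$sample_id <- paste0("R", 1:15)
  out <- generate_spectra(reps, noise = scatter_noise_model(0.1, 0.02, 0),
                          seed = 2)
  clean <- out$clean_spectra$values[1, ]
  corrected <- msc(out$spectra$values, reference = clean)$corrected
  expect_lt(max(abs(corrected - rep(clean, each = 15))), 1e-6)

  ## SNV and MSC each remove >= 90% of between-replicate variance
  var_between <- function(m) sum(apply(m, 2, var))
  v0 <- var_between(out$spectra$values)
  expect_lt(var_between(msc(out$spectra$values)$corrected), 0.1 * v0)
  ## SNV rescales each spectrum; map back to absorbance scale to compare
  snv_back <- snv(out$spectra$values) * sd(clean) + mean(clean)
  expect_lt(var_between(snv_back), 0.1 * v0)
})

test_that("benchmark presets are sized, grouped and learnable", {
  ds <- make_benchmark_dataset("paper_like", seed = 10)
  expect_equal(nrow(ds$spectra$values), 40)
  expect_equal(unname(table(ds$spectra$crop)), c(20L, 20L),
               ignore_attr = TRUE)

  ## clean preset: a factor-per-constituent mPLS model recovers the
  ## spectrally active traits almost perfectly
  clean <- make_benchmark_dataset("clean", seed = 10)
  sp <- split_calibration_validation(clean$spectra, 5, seed = 1)
  cal_ids <- sp$calibration_ids; val_ids <- sp$validation_ids
  Xcal <- clean$spectra[cal_ids]$values
  Xval <- clean$spectra[val_ids]$values
  for (trait in c("protein", "starch", "moisture")) {
    y <- setNames(clean$refs[[trait]], clean$refs$sample_id)
    m <- fit_mpls(Xcal, y[cal_ids], 8)
    expect_gte(rsq(y[val_ids], predict(m, Xval), "external"), 0.999)
  }
})
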