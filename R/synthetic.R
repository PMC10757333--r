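## synthetic_data: generator of flour-like NIR spectra with known ground
## truth, standing in for the undeposited 40-accession bean dataset.

#' Absorption band
#'
#' One Gaussian absorption band: amplitude * exp(-(lambda - center)^2 /
#' (2 width^2)).
#'
#' @param center_nm Band centre (nm), within 400--2490.
#' @param width_nm Gaussian SD (nm), > 0.
#' @param amplitude Peak absorbance, >= 0.
#' @return An object of class \code{band}.
#' @export
band <- function(center_nm, width_nm, amplitude = 1) {
  if (width_nm <= 0) stop("width_nm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (center_nm < 400 || center_nm > 2490) {
    stop("center_nm must lie in 400..2490")
  }
  structure(list(center_nm = center_nm, width_nm = width_nm,
                 amplitude = amplitude), class = "band")
}

eval_bands <- function(bands, wl) {
  out <- numeric(length(wl))
  for (b in bands) {
    out <- out + b$amplitude * exp(-(wl - b$center_nm)^2 / (2 * b$width_nm^2))
  }
  out
}

#' Built-in pure-component band library
#'
#' Pure spectra for the flour constituents, built from the seven major
#' absorption bands of bean flour spectra: 1194 nm (C-H stretch second
#' overtone), 1499 nm (O-H stretch second overtone), 1730 nm (C-H stretch
#' first overtone), 1964 nm (O-H first overtone, moisture), and 2124,
#' 2310, 2345 nm (C-H combination / amide C-O combination tones). Each
#' constituent is given a distinct combination of these bands; the
#' band-to-constituent amplitudes are simulator parameters, not fits to
#' real pure spectra.
#'
#' @param grid A \code{\link{wavelength_grid}}.
#' @return Object of class \code{component_library}: wavelength axis plus
#'   a named list of components (bands and evaluated pure spectrum).
#' @export
default_component_library <- function(grid = wavelength_grid()) {
  wl <- grid_wavelengths(grid)
  defs <- list(
    protein = list(band(2124, 45, 1.0), band(2345, 40, 0.5),
                   band(1194, 30, 0.2)),
    starch = list(band(2310, 50, 1.0), band(1499, 45, 0.6),
                  band(2124, 40, 0.25)),
    dietary_fiber = list(band(1730, 40, 0.8), band(2345, 45, 0.9),
                         band(1499, 35, 0.3)),
    fat = list(band(1730, 35, 1.0), band(1194, 25, 0.6),
               band(2310, 40, 0.4)),
    sugar = list(band(1499, 40, 0.9), band(2124, 45, 0.5),
                 band(1964, 50, 0.2)),
    moisture = list(band(1964, 50, 1.0), band(1499, 45, 0.35)),
    phytate = list(band(2345, 35, 0.7), band(1194, 30, 0.5),
                   band(1964, 40, 0.2))
  )
  components <- lapply(defs, function(bands) {
    list(bands = bands, values = eval_bands(bands, wl))
  })
  structure(list(wavelengths = wl, components = components),
            class = "component_library")
}

#' Trait distribution
#'
#' Truncated-normal population parameters for one trait, in trait units.
#'
#' @param trait Trait name.
#' @param mean,sd Normal parameters before truncation.
#' @param min,max Truncation bounds; min < max and min <= mean <= max.
#' @return An object of class \code{trait_distribution}.
#' @export
trait_distribution <- function(trait, mean, sd, min, max) {
  if (!(min < max)) stop("min must be < max")
  if (mean < min || mean > max) stop("mean must lie within [min, max]")
  if (sd <= 0) stop("sd must be > 0")
  structure(list(trait = trait, mean = mean, sd = sd, min = min, max = max),
            class = "trait_distribution")
}

#' Reference trait distributions for bean flours
#'
#' The descriptive statistics (mean, SD, range) of the 40 rice bean and
#' adzuki bean accessions used to parameterise the simulator: proximates,
#' phytate and phenol in % dry basis, FRAP/CUPRAC in GAE g/100 g,
#' minerals in ppm, colour channels 0--255.
#'
#' @return Named list of \code{\link{trait_distribution}} objects.
#' @export
table1_distributions <- function() {
  spec <- list(
    list("moisture", 10.4, 1.37, 7.83, 12.3),
    list("protein", 22, 1.28, 19, 25),
    list("dietary_fiber", 17.4, 3.29, 11.1, 26.4),
    list("fat", 1.96, 0.958, 0.68, 4.47),
    list("ash", 2.81, 0.768, 1.32, 4.4),
    list("sugar", 4.89, 0.947, 2.76, 6.81),
    list("starch", 41.1, 3.75, 30.7, 47.3),
    list("phytate", 0.929, 0.346, 0.394, 1.88),
    list("phenol", 0.349, 0.101, 0.178, 0.68),
    list("anthocyanin", 2.59, 4.43, 0.117, 18.7),
    list("frap", 2.5, 1.16, 0.62, 5.06),
    list("cuprac", 6.01, 1.71, 3.15, 9.38),
    list("fe", 45.4, 17.6, 13.8, 77.5),
    list("cu", 4.69, 1.92, 1.92, 9.79),
    list("zn", 28, 4.59, 20.3, 38.5),
    list("red", 166, 64.7, 54, 253),
    list("green", 133, 73, 41, 236),
    list("blue", 111, 54, 54, 201)
  )
  out <- lapply(spec, function(s) do.call(trait_distribution, s))
  names(out) <- vapply(out, `[[`, character(1), "trait")
  out
}

rtruncnorm1 <- function(n, mean, sd, min, max) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= min & draw <= max])
  }
  out[seq_len(n)]
}

#' Sample trait concentrations
#'
#' Independent truncated-normal draws per trait, deterministic given the
#' seed.
#'
#' @param distributions Named list of \code{\link{trait_distribution}}s.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param ids Sample ids (default S1..Sn).
#' @return Data frame: \code{sample_id} plus one column per trait.
#' @export
sample_concentrations <- function(distributions, n, seed = 1, ids = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (d in distributions) {
      out[[d$trait]] <- rtruncnorm1(n, d$mean, d$sd, d$min, d$max)
    }
  })
  out
}

#' Scatter and noise model
#'
#' Per-sample scatter and instrument noise applied to simulated
#' absorbance spectra: multiplicative factor b ~ lognormal(0, sigma_b),
#' additive offset a ~ normal(0, sigma_a), white noise sd sigma_n per
#' grid point, plus a fixed polynomial baseline in the normalised
#' wavelength u = (lambda - start)/(end - start).
#'
#' @param sigma_b Lognormal sigma of the multiplicative factor (>= 0).
#' @param sigma_a SD of the additive offset (absorbance units, >= 0).
#' @param sigma_n SD of per-point white noise (absorbance units, >= 0).
#' @param baseline Polynomial coefficients (constant first) in u.
#' @return An object of class \code{scatter_noise_model}.
#' @export
scatter_noise_model <- function(sigma_b = 0, sigma_a = 0, sigma_n = 0,
                                baseline = c(0.3, 0.4, -0.1)) {
  if (sigma_b < 0 || sigma_a < 0 || sigma_n < 0) {
    stop("sigma parameters must be >= 0")
  }
  structure(list(sigma_b = sigma_b, sigma_a = sigma_a, sigma_n = sigma_n,
                 baseline = baseline),
            class = "scatter_noise_model")
}

eval_baseline <- function(coefs, wl) {
  u <- (wl - wl[1]) / (wl[length(wl)] - wl[1])
  out <- numeric(length(wl))
  for (j in seq_along(coefs)) out <- out + coefs[j] * u^(j - 1)
  out
}

#' Generate synthetic flour spectra
#'
#' Beer-Lambert style mixing: for sample j,
#' x_j(lambda) = b_j * (baseline(lambda) + sum_k c_jk * e_k(lambda) /
#' scale_k) + a_j + eps_j(lambda), where e_k are the pure component
#' spectra, scale_k = 100 * max(e_k) expresses concentrations as
#' fractions of a unit-peak band, and (a_j, b_j, eps) come from the
#' scatter/noise model. Traits with no component in the library (e.g.
#' minerals) contribute no spectral signal, mirroring their poor NIR
#' absorption.
#'
#' @param concentrations Data frame from
#'   \code{\link{sample_concentrations}} (ground truth; retained in the
#'   result).
#' @param library A \code{\link{default_component_library}}.
#' @param noise A \code{\link{scatter_noise_model}}.
#' @param seed Integer seed for the scatter/noise draws.
#' @param crop Optional per-sample crop labels.
#' @return List of class \code{synthetic_dataset}: \code{spectra}
#'   (a \code{\link{spectra_set}}), \code{refs} (the concentrations),
#'   \code{scatter} (the drawn a, b per sample), \code{noise},
#'   \code{seed}.
#' @export
generate_spectra <- function(concentrations, library = default_component_library(),
                             noise = scatter_noise_model(), seed = 1,
                             crop = NULL) {
  stopifnot(inherits(library, "component_library"))
  wl <- library$wavelengths
  comp_names <- names(library$components)
  present <- intersect(comp_names, names(concentrations))
  if (!length(present)) stop("no library constituent found in concentrations")
  n <- nrow(concentrations)
  base <- eval_baseline(noise$baseline, wl)
  pure <- vapply(library$components[present], function(cmp) {
    cmp$values / (100 * max(cmp$values))
  }, numeric(length(wl)))
  conc <- as.matrix(concentrations[present])
  clean <- sweep(tcrossprod(conc, pure), 2, base, `+`)
  with_seed(seed, {
    b <- stats::rlnorm(n, 0, noise$sigma_b)
    a <- stats::rnorm(n, 0, noise$sigma_a)
    eps <- if (noise$sigma_n > 0) {
      matrix(stats::rnorm(n * length(wl), 0, noise$sigma_n), n)
    } else 0
  })
  values <- clean * b + a + eps
  rownames(values) <- concentrations$sample_id
  structure(list(spectra = spectra_set(values, wl, crop = crop),
                 refs = concentrations,
                 clean_spectra = spectra_set(clean, wl, crop = crop),
                 scatter = list(a = a, b = b),
                 noise = noise, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$spectra$values), "samples, seed",
      x$seed, "\n")
  print(x$spectra)
  invisible(x)
}

#' Benchmark datasets
#'
#' Reproducible synthetic datasets for end-to-end tests. All presets have
#' 40 samples in two pseudo-crop groups of 20 ("rice bean",
#' "adzuki bean"); the second group's spectrally active trait means are
#' shifted by +0.3 SD to mimic between-crop composition differences.
#' Presets differ only in the scatter/noise model:
#' \describe{
#'   \item{clean}{no scatter, no noise - exact linear mixtures.}
#'   \item{scattered}{multiplicative/additive scatter, no white noise.}
#'   \item{noisy}{scatter plus strong white noise.}
#'   \item{paper_like}{moderate scatter and instrument-level noise - the
#'     standard end-to-end fixture.}
#' }
#'
#' @param preset One of "clean", "scattered", "noisy", "paper_like".
#' @param seed Integer seed; regeneration with the same (preset, seed) is
#'   identical.
#' @param n Total samples (split evenly between the two groups).
#' @return A \code{synthetic_dataset} (see
#'   \code{\link{generate_spectra}}); its \code{spectra} carry crop
#'   labels usable by \code{\link{split_calibration_validation}}.
#' @export
make_benchmark_dataset <- function(preset = c("paper_like", "clean",
                                              "scattered", "noisy"),
                                   seed = 1, n = 40) {
  preset <- match.arg(preset)
  noise <- switch(preset,
    clean = scatter_noise_model(0, 0, 0),
    scattered = scatter_noise_model(0.1, 0.02, 0),
    noisy = scatter_noise_model(0.1, 0.02, 5e-4),
    paper_like = scatter_noise_model(0.08, 0.01, 3e-5))
  dists <- table1_distributions()
  library <- default_component_library()
  spectral <- names(library$components)
  n1 <- floor(n / 2)
  n2 <- n - n1
  shifted <- lapply(dists, function(d) {
    if (!d$trait %in% spectral) return(d)
    trait_distribution(d$trait,
                       mean = min(max(d$mean + 0.3 * d$sd, d$min), d$max),
                       sd = d$sd, min = d$min, max = d$max)
  })
  conc1 <- sample_concentrations(dists, n1, seed = seed,
                                 ids = sprintf("RB%02d", seq_len(n1)))
  conc2 <- sample_concentrations(shifted, n2, seed = seed + 1,
                                 ids = sprintf("AB%02d", seq_len(n2)))
  conc <- rbind(conc1, conc2)
  crop <- c(rep("rice bean", n1), rep("adzuki bean", n2))
  out <- generate_spectra(conc, library = library, noise = noise,
                          seed = seed + 2, crop = crop)
  out$preset <- preset
  out
}
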