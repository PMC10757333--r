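# Shared fixtures: small grids and random spectra built in code.

small_grid <- function(n = 20, start = 400, step = 2) {
  wavelength_grid(start, start + step * (n - 1), step)
}

random_spectra_matrix <- function(n, p, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p, sd = sd), n, p)
  rownames(m) <- paste0("S", seq_len(n))
  m
}

random_spectra_set <- function(n, p, seed = 1) {
  g <- small_grid(p)
  spectra_set(random_spectra_matrix(n, p, seed), grid_wavelengths(g))
}

## A tiny 3-constituent mixture problem with known linear structure:
## X = C %*% t(pure) + noise, y = one column of C.
mixture_problem <- function(n = 24, p = 60, noise = 0, seed = 42) {
  set.seed(seed)
  wl <- seq_len(p)
  pure <- cbind(exp(-(wl - 15)^2 / 50), exp(-(wl - 30)^2 / 80),
                exp(-(wl - 48)^2 / 40))
  C <- cbind(rnorm(n, 10, 2), rnorm(n, 5, 1), rnorm(n, 20, 3))
  X <- C %*% t(pure) + matrix(rnorm(n * p, sd = noise), n, p)
  rownames(X) <- paste0("S", seq_len(n))
  list(X = X, C = C, y = C[, 1], pure = pure, wl = wl)
}
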