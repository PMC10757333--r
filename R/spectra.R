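## spectra_core: wavelength grid, spectra containers, I/O, split.

#' Wavelength grid
#'
#' A regularly spaced wavelength grid in nanometres. The instrument default
#' (400--2490 nm in 2 nm steps, 1046 points) matches scanning
#' monochromator NIRS instruments used for flour analysis.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm); must exceed \code{start_nm} and lie
#'   on the step lattice.
#' @param step_nm Spacing (nm), > 0.
#' @return An object of class \code{wavelength_grid}.
#' @examples
#' g <- wavelength_grid()
#' n_points(g)  # 1046
#' @export
wavelength_grid <- function(start_nm = 400, end_nm = 2490, step_nm = 2) {
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (end_nm <= start_nm) stop("end_nm must exceed start_nm")
  k <- (end_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-8) {
    stop("end_nm must equal start_nm plus a whole number of steps")
  }
  structure(list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm),
            class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param grid A \code{wavelength_grid}.
#' @export
n_points <- function(grid) {
  as.integer(round((grid$end_nm - grid$start_nm) / grid$step_nm)) + 1L
}

#' @rdname wavelength_grid
#' @export
grid_wavelengths <- function(grid) {
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

#' @rdname wavelength_grid
#' @param index 1-based grid index.
#' @export
index_to_wavelength <- function(grid, index) {
  stopifnot(all(index >= 1), all(index <= n_points(grid)))
  grid$start_nm + (index - 1) * grid$step_nm
}

#' @rdname wavelength_grid
#' @param wavelength_nm Wavelength (nm) lying on the grid.
#' @export
wavelength_to_index <- function(grid, wavelength_nm) {
  idx <- (wavelength_nm - grid$start_nm) / grid$step_nm + 1
  if (any(abs(idx - round(idx)) > 1e-8) || any(idx < 1) ||
      any(idx > n_points(grid))) {
    stop("wavelength not on grid: ", paste(wavelength_nm, collapse = ", "))
  }
  as.integer(round(idx))
}

#' Spectra set
#'
#' Container for a set of absorbance spectra, log10(1/R), sharing one
#' wavelength axis. Values are a samples x wavelengths matrix with unique
#' sample ids as row names; an optional per-sample crop label supports
#' stratified splitting.
#'
#' @param values Numeric matrix, samples in rows; row names are sample ids.
#' @param wavelengths Numeric vector of wavelengths (nm), one per column,
#'   strictly increasing.
#' @param crop Optional character vector of crop labels (e.g. "rice bean",
#'   "adzuki bean"), one per sample.
#' @return An object of class \code{spectra_set}.
#' @export
spectra_set <- function(values, wavelengths, crop = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop("duplicate sample_id: ", dup)
  }
  if (length(wavelengths) != ncol(values)) {
    stop("wavelengths length (", length(wavelengths),
         ") != number of columns (", ncol(values), ")")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (!all(is.finite(values))) stop("spectra contain non-finite values")
  if (!is.null(crop)) {
    if (length(crop) != nrow(values)) stop("crop length != number of samples")
    crop <- as.character(crop)
    names(crop) <- rownames(values)
  }
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 crop = crop),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", nrow(x$values), "samples x", ncol(x$values),
      "wavelengths [", min(x$wavelengths), "-", max(x$wavelengths), "nm ]\n")
  if (!is.null(x$crop)) {
    tab <- table(x$crop)
    cat("  crops:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`[.spectra_set` <- function(x, i, ...) {
  v <- x$values[i, , drop = FALSE]
  spectra_set(v, x$wavelengths,
              crop = if (is.null(x$crop)) NULL else unname(x$crop[rownames(v)]))
}

sample_ids <- function(set) rownames(set$values)

#' Convert reflectance to absorbance
#'
#' Converts reflectance fractions R in (0, 1] to the absorbance-like
#' quantity log10(1/R) used throughout the package. Reflectance is only
#' accepted at import; absorbance is the canonical internal unit.
#'
#' @param R Numeric vector or matrix of reflectance fractions, 0 < R <= 1.
#' @return log10(1/R), same shape as \code{R}.
#' @examples
#' reflectance_to_absorbance(c(1, 0.1))  # 0, 1
#' @export
reflectance_to_absorbance <- function(R) {
  bad <- which(!is.finite(R) | R <= 0)
  if (length(bad)) {
    stop("reflectance must be > 0; offending index: ", bad[1])
  }
  if (any(R > 1)) warning("reflectance > 1 found; check units")
  log10(1 / R)
}

#' Average repeated scans of one sample
#'
#' Pointwise arithmetic mean of repeated scans (e.g. the 32 monochromator
#' passes recorded per flour sample), computed in absorbance space.
#'
#' @param scans A \code{spectra_set} whose rows are repeated scans of one
#'   sample, or a numeric matrix (scans x wavelengths).
#' @param sample_id Id assigned to the averaged spectrum.
#' @return Numeric vector (the averaged spectrum) with the wavelength axis
#'   as names when available.
#' @export
average_scans <- function(scans, sample_id = NULL) {
  if (inherits(scans, "spectra_set")) {
    m <- scans$values
    if (is.null(sample_id)) sample_id <- rownames(m)[1]
  } else {
    m <- as.matrix(scans)
  }
  if (nrow(m) < 1) stop("need at least one scan")
  out <- colMeans(m)
  attr(out, "sample_id") <- sample_id
  out
}

#' Read and write spectra files
#'
#' Wide delimited text: first column \code{sample_id}, optional
#' \code{crop} column, remaining column headers are wavelengths in nm.
#' Delimiter is auto-detected from the extension (.csv = comma, otherwise
#' tab). Values are written with 15 significant digits so that a
#' write/read round trip reproduces the data.
#'
#' @param path File path.
#' @return \code{read_spectra}: a \code{\link{spectra_set}}.
#' @export
read_spectra <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("spectra file needs sample_id plus wavelengths")
  if (names(df)[1] != "sample_id") {
    stop("first column must be 'sample_id', got '", names(df)[1], "'")
  }
  crop <- NULL
  if (ncol(df) >= 2 && names(df)[2] == "crop") {
    crop <- as.character(df[[2]])
    df <- df[, -2, drop = FALSE]
  }
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header: ",
         names(df)[-1][which(is.na(wl))[1]])
  }
  if (length(wl) > 1 && any(diff(wl) <= 0)) {
    stop("header wavelengths must be strictly increasing")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in ", path, ": ", ids[duplicated(ids)][1],
         " (row ", which(duplicated(ids))[1] + 1, ")")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric spectral values in ", path)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite value at row ", bad[1, 1] + 1, ", column ", bad[1, 2])
  }
  rownames(m) <- ids
  colnames(m) <- NULL
  spectra_set(m, wl, crop = crop)
}

#' @rdname read_spectra
#' @param set A \code{spectra_set}.
#' @export
write_spectra <- function(set, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = sample_ids(set), stringsAsFactors = FALSE)
  if (!is.null(set$crop)) df$crop <- unname(set$crop)
  vals <- format(set$values, digits = 15, trim = TRUE, scientific = FALSE)
  m <- as.data.frame(vals, stringsAsFactors = FALSE)
  names(m) <- format(set$wavelengths, trim = TRUE, scientific = FALSE)
  utils::write.table(cbind(df, m), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Trait registry
#'
#' Canonical trait names and units handled by the reference-table reader
#' and the synthetic generator. Proximates, phytate and phenol are percent
#' on a dry basis; FRAP and CUPRAC are gallic-acid equivalents, g/100 g;
#' minerals are ppm; colour channels are 0--255.
#'
#' @return Character vector of trait names.
#' @export
trait_registry <- function() {
  c("moisture", "protein", "dietary_fiber", "fat", "ash", "sugar",
    "starch", "phytate", "phenol", "anthocyanin", "frap", "cuprac",
    "fe", "cu", "zn", "red", "green", "blue")
}

#' Read a reference trait table
#'
#' Accepts wide CSV/TSV (\code{sample_id} plus one column per trait) or
#' long format (\code{sample_id}, \code{trait}, \code{value}). Trait names
#' must come from \code{\link{trait_registry}} unless \code{registry} is
#' extended.
#'
#' @param path File path.
#' @param registry Allowed trait names.
#' @return Wide data frame keyed by \code{sample_id}.
#' @export
read_reference_table <- function(path, registry = trait_registry()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("reference table needs 'sample_id'")
  if (all(c("trait", "value") %in% names(df))) {
    unknown <- setdiff(unique(df$trait), registry)
    if (length(unknown)) stop("unknown trait(s): ",
                              paste(unknown, collapse = ", "))
    wide <- stats::reshape(df[c("sample_id", "trait", "value")],
                           idvar = "sample_id", timevar = "trait",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    df <- wide
    rownames(df) <- NULL
  } else {
    unknown <- setdiff(names(df)[-match("sample_id", names(df))], registry)
    if (length(unknown)) stop("unknown trait(s): ",
                              paste(unknown, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  }
  num <- df[setdiff(names(df), "sample_id")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      !all(is.finite(as.matrix(num)))) {
    stop("reference values must all be finite numbers")
  }
  df
}

#' @rdname read_reference_table
#' @param refs Wide reference data frame.
#' @export
write_reference_table <- function(refs, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(refs, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split samples into calibration and validation sets
#'
#' Draws \code{n_val_per_crop} validation samples uniformly at random
#' without replacement within each crop group (unstratified when no crop
#' labels are present); the remainder is the calibration set. The split is
#' deterministic given \code{seed}.
#'
#' @param set A \code{spectra_set} (crop labels, if any, drive the
#'   stratification).
#' @param n_val_per_crop Validation samples per crop group (default 5,
#'   i.e. 15 + 15 calibration and 5 + 5 validation for two groups of 20).
#' @param seed Integer seed.
#' @return List of class \code{split_result}: \code{calibration_ids},
#'   \code{validation_ids}, \code{seed}.
#' @export
split_calibration_validation <- function(set, n_val_per_crop = 5, seed = 1) {
  ids <- sample_ids(set)
  groups <- if (is.null(set$crop)) rep("all", length(ids)) else unname(set$crop)
  val <- character(0)
  with_seed(seed, {
    for (g in sort(unique(groups))) {
      gid <- ids[groups == g]
      if (length(gid) <= n_val_per_crop) {
        stop("crop group '", g, "' has ", length(gid),
             " samples; needs more than ", n_val_per_crop)
      }
      val <- c(val, sample(gid, n_val_per_crop))
    }
  })
  structure(list(calibration_ids = setdiff(ids, val),
                 validation_ids = val[order(match(val, ids))],
                 seed = seed),
            class = "split_result")
}
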